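#' Classify a Qs score into a structural band
#'
#' Score bands are defined at psi = 30 degrees (alpha = 60):
#'
#' * `qs > 2`            : `ZG4_prone` — very high scores characteristic of
#'   repeats adopting left-handed (Z-) G-quadruplexes.
#' * `1.2 < qs <= 2`     : `G4_candidate` — above the quadruplex-formation
#'   threshold.
#' * `0.7 <= qs <= 1.2`  : `tetrahelix_band` — just below the quadruplex
#'   threshold; the band of non-G4 tetrahelical candidates (AGAG-quartet
#'   motifs and the GGGAGCGA-repeat reference structure).
#' * `qs < -1.2`         : `imotif_candidate` — the mirror of the
#'   quadruplex threshold under complement antisymmetry: a strongly
#'   negative score marks a C-rich strand.
#' * otherwise           : `none`.
#'
#' The upper edge of the tetrahelical band coincides with the quadruplex
#' threshold: every score at or above 0.7 that does not clear 1.2 falls in
#' the band (the band's nominal 0.7-1.1 description reflects the scores of
#' its known members at 2-decimal precision, whose reference sequence
#' scores 1.113 unrounded).
#'
#' @param qs Numeric vector of Qs scores computed at psi = 30 degrees.
#' @return Character vector of labels.
#' @examples
#' classify_qs(c(2.12, 1.11, 0.69, 0, -2.5))
#' @export
classify_qs <- function(qs) {
  stopifnot(is.numeric(qs))
  out <- rep_len("none", length(qs))
  out[qs >= 0.7 & qs <= 1.2] <- "tetrahelix_band"
  out[qs > 1.2] <- "G4_candidate"
  out[qs > 2] <- "ZG4_prone"
  out[qs < -1.2] <- "imotif_candidate"
  out
}

#' Find dinucleotide repeat tracts
#'
#' Locates maximal runs of a two-base repeat unit such as GT or GA.
#' Rotations are phase-normalized (a TGTG... run is reported as unit GT),
#' and reverse-complement matches are reported on the minus strand (an
#' AC-repeat on the plus strand is a GT-repeat on the minus strand).
#' Tracts are maximal and non-overlapping per unit, taken greedily left to
#' right; `count` is the number of complete units, the tract coordinates
#' span those complete units only (`end - start == 2 * count`), and a
#' trailing half unit inside the same alternating run is flagged in
#' `half_trailing`.
#'
#' Dinucleotide microsatellites of this kind become structurally relevant
#' in the six-to-eight-repeat range, hence the default `min_repeats = 6`
#' with a `confident` tier at `confident_repeats = 8`.
#'
#' @param x A character string or `sequence_record`.
#' @param min_repeats Minimum number of complete units (>= 2).
#' @param units Character vector of 2-mers over distinct bases
#'   (default `c("GT", "GA")`).
#' @param confident_repeats Count at or above which a tract is flagged
#'   `confident` (default 8).
#' @param both_strands Also search the reverse complement (default TRUE).
#' @return A data.frame of class `repeat_tracts` with columns `record_id`,
#'   `unit`, `strand`, `start`, `end` (0-based half-open, plus-strand
#'   coordinates), `count`, `half_trailing`, `confident`.
#' @examples
#' find_dinucleotide_repeats(strrep("GT", 6), min_repeats = 6)
#' @export
find_dinucleotide_repeats <- function(x, min_repeats = 6,
                                      units = c("GT", "GA"),
                                      confident_repeats = 8,
                                      both_strands = TRUE) {
  stopifnot(min_repeats >= 2)
  units <- toupper(units)
  bad <- nchar(units) != 2L |
    substr(units, 1, 1) == substr(units, 2, 2) |
    !grepl("^[ACGT]{2}$", units)
  if (any(bad)) {
    stop("degenerate or invalid unit(s): ", paste(units[bad], collapse = ", "))
  }
  rec <- as_sequence_record(x)
  n <- rec$n
  res <- list()
  for (u in units) {
    res[[length(res) + 1L]] <- unit_tracts(rec$seq, u, "+", rec$id)
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rec$seq)))
      t_rc <- unit_tracts(rc, u, "-", rec$id)
      if (nrow(t_rc) > 0L) {
        s <- n - t_rc$end
        t_rc$end <- n - t_rc$start
        t_rc$start <- s
      }
      res[[length(res) + 1L]] <- t_rc
    }
  }
  out <- do.call(rbind, res)
  out <- out[out$count >= min_repeats, , drop = FALSE]
  out <- out[order(out$start, out$unit, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$confident <- out$count >= confident_repeats
  class(out) <- c("repeat_tracts", "data.frame")
  out
}

# Maximal full-unit tracts of one unit on one strand of seq (already the
# strand's 5'->3' string); coordinates 0-based half-open in that string.
unit_tracts <- function(seq, unit, strand, record_id) {
  empty <- data.frame(record_id = character(0), unit = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), count = integer(0),
                      half_trailing = logical(0))
  n <- nchar(seq)
  if (n < 2L) return(empty)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  x <- substr(unit, 1, 1); y <- substr(unit, 2, 2)
  a <- ch[-n]; b <- ch[-1L]
  ok <- (a == x & b == y) | (a == y & b == x)   # adjacent pair alternates
  r <- rle(ok)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) return(empty)
  out <- empty
  for (k in runs) {
    s <- starts[k]                  # run covers ch[s .. stops[k] + 1]
    e <- stops[k] + 1L
    # Two possible phases (unit and its rotation); keep the one with more
    # complete units -- GT and TG tracts are the same microsatellite.
    first_x <- if (ch[s] == x) s else s + 1L
    count_x <- (e - first_x + 1L) %/% 2L
    first_y <- if (ch[s] == y) s else s + 1L
    count_y <- (e - first_y + 1L) %/% 2L
    if (count_x >= count_y) { first <- first_x; count <- count_x }
    else                    { first <- first_y; count <- count_y }
    if (count < 1L) next
    tract_end <- first + 2L * count - 1L
    out <- rbind(out, data.frame(
      record_id = record_id, unit = unit, strand = strand,
      start = first - 1L, end = tract_end,
      count = count, half_trailing = tract_end < e
    ))
  }
  out
}

#' Score, classify and annotate whole sequences
#'
#' Convenience report for a set of oligonucleotides: Qs at psi = 15 and 30
#' degrees, the structural band at 30 degrees, and whether the sequence
#' contains a qualifying dinucleotide repeat tract.
#'
#' @param seqs Named character vector of sequences (or list of
#'   `sequence_record`).
#' @param min_repeats Passed to [find_dinucleotide_repeats()].
#' @return A data.frame with columns `id`, `n`, `qs15`, `qs30`, `label`,
#'   `repeat_tract` (unit of the longest tract, or NA).
#' @examples
#' classify_sequences(c("(TG)_6" = strrep("GT", 6)))
#' @export
classify_sequences <- function(seqs, min_repeats = 6) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  m15 <- projection_model(psi = 15)
  m30 <- projection_model(psi = 30)
  rows <- lapply(names(seqs), function(id) {
    rec <- as_sequence_record(seqs[[id]], id = id)
    q30 <- qs_score(rec, m30)
    tr <- find_dinucleotide_repeats(rec, min_repeats = min_repeats)
    data.frame(
      id = id, n = rec$n,
      qs15 = qs_score(rec, m15), qs30 = q30,
      label = classify_qs(q30),
      repeat_tract = if (nrow(tr) > 0) tr$unit[which.max(tr$count)] else NA_character_
    )
  })
  do.call(rbind, rows)
}
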