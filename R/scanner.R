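#' Scanner configuration
#'
#' Bundles the parameters of the sliding-window scan.  Scores are windowed
#' Qs values; the default threshold 1.2 is the quadruplex-prediction
#' cutoff at psi = 30 degrees.
#'
#' @param psi Inclination angle in degrees (default 30).
#' @param window Window size in nt (default 25, spanning the shortest
#'   motif-forming dinucleotide tracts with margin); must be >= 2.
#' @param step Step between window starts in nt (default 1).
#' @param threshold Absolute Qs cutoff for emitting a call (default 1.2).
#' @param merge_adjacent Merge overlapping same-strand calls into maximal
#'   intervals, keeping the extremal score (default TRUE).
#' @param amplitude Base vector magnitude passed to [projection_model()].
#' @param include_partial Score a final truncated window when the sequence
#'   length is not reached exactly (default FALSE: short windows are biased
#'   low by the (n-1)/n factor).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(psi = 30, window = 25, step = 1, threshold = 1.2,
                        merge_adjacent = TRUE, amplitude = 3,
                        include_partial = FALSE) {
  stopifnot(window >= 2, step >= 1, threshold >= 0)
  structure(
    list(psi = psi, window = as.integer(window), step = as.integer(step),
         threshold = threshold, merge_adjacent = isTRUE(merge_adjacent),
         amplitude = amplitude, include_partial = isTRUE(include_partial)),
    class = "scan_config"
  )
}

#' Sliding-window Qs profile of a sequence
#'
#' Applies [qs_score()] over sliding windows.  Windows are reported at
#' 0-based half-open coordinates `[start, start + window)`.  Windows that
#' would extend beyond the sequence end are omitted (unless
#' `include_partial`); a sequence shorter than the window is scored as a
#' single whole-sequence window.
#'
#' The computation is linear in sequence length: the trapezoid half-sums
#' are accumulated once and each window score is a cumulative-sum
#' difference divided by the window length.
#'
#' @param x A character string or `sequence_record`.
#' @param cfg A [scan_config()].
#' @return An object of class `score_profile`: a data.frame with columns
#'   `start`, `end`, `qs`, carrying `record_id`, `psi`, `window` and
#'   `step` as attributes.
#' @examples
#' p <- scan_sequence(strrep("GT", 27), scan_config(psi = 15, window = 54))
#' round(p$qs, 2)  # 1.85
#' @export
scan_sequence <- function(x, cfg = scan_config()) {
  rec <- as_sequence_record(x)
  model <- projection_model(psi = cfg$psi, amplitude = cfg$amplitude)
  h <- height_profile(rec, model)
  n <- length(h)
  w <- cfg$window

  if (n == 0L) {
    starts <- integer(0); ends <- integer(0); qs <- numeric(0)
  } else if (n < w) {
    starts <- 0L; ends <- n; qs <- qs_from_heights(h)
  } else {
    trap <- (h[-n] + h[-1L]) / 2
    ct <- c(0, cumsum(trap))                     # ct[i+1] = sum of first i trapezoids
    s1 <- seq.int(1L, n - w + 1L, by = cfg$step) # 1-based window starts
    qs <- (ct[s1 + w - 1L] - ct[s1]) / w
    starts <- s1 - 1L
    ends <- starts + w
    if (cfg$include_partial) {
      last_full <- s1[length(s1)]
      s2 <- last_full + cfg$step
      if (s2 <= n - 1L) {                        # at least 2 nt left
        part <- seq.int(s2, n - 1L, by = cfg$step)
        qs <- c(qs, (ct[n] - ct[part]) / (n - part + 1L))
        starts <- c(starts, part - 1L)
        ends <- c(ends, rep.int(n, length(part)))
      }
    }
  }

  structure(
    data.frame(start = starts, end = ends, qs = qs),
    record_id = rec$id, psi = cfg$psi, window = cfg$window, step = cfg$step,
    class = c("score_profile", "data.frame")
  )
}

#' Call candidate motif intervals from a score profile
#'
#' Windows with `qs >= threshold` become plus-strand calls; windows with
#' `qs <= -threshold` become minus-strand calls.  By the complement
#' antisymmetry of the score, a strongly negative plus-strand window marks
#' a G-rich minus strand, i.e. a C-rich / i-motif candidate on the plus
#' strand.  When `cfg$merge_adjacent`, overlapping or abutting same-strand
#' calls are merged to maximal intervals, retaining the extremal (largest
#' magnitude) window score.  Each call is labelled with [classify_qs()]
#' applied to its extremal score; the score bands are defined at
#' psi = 30 degrees.
#'
#' @param profile A [scan_sequence()] result.
#' @param cfg A [scan_config()].
#' @return A data.frame of class `motif_calls` with columns `record_id`,
#'   `start`, `end` (0-based half-open), `strand`, `qs`, `label`.
#' @export
call_intervals <- function(profile, cfg = scan_config()) {
  stopifnot(inherits(profile, "score_profile"))
  thr <- cfg$threshold
  keep_plus  <- profile$qs >= thr
  keep_minus <- profile$qs <= -thr
  pieces <- list(
    merge_strand(profile[keep_plus, , drop = FALSE], "+", cfg$merge_adjacent),
    merge_strand(profile[keep_minus, , drop = FALSE], "-", cfg$merge_adjacent)
  )
  calls <- do.call(rbind, pieces)
  calls <- calls[order(calls$start, calls$strand), , drop = FALSE]
  rownames(calls) <- NULL
  structure(
    data.frame(record_id = rep_len(attr(profile, "record_id") %||% "seq",
                                   nrow(calls)),
               calls, label = classify_qs(calls$qs)),
    class = c("motif_calls", "data.frame")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Merge overlapping/abutting windows on one strand into maximal intervals,
# keeping the extremal score.
merge_strand <- function(win, strand, merge) {
  if (nrow(win) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), qs = numeric(0)))
  }
  win <- win[order(win$start), , drop = FALSE]
  extremal <- if (strand == "+") max else min
  if (!merge) {
    return(data.frame(start = win$start, end = win$end,
                      strand = strand, qs = win$qs))
  }
  grp <- cumsum(c(1L, win$start[-1L] > cummax(win$end[-nrow(win)])))
  out <- lapply(split(win, grp), function(g) {
    data.frame(start = min(g$start), end = max(g$end),
               strand = strand, qs = extremal(g$qs))
  })
  do.call(rbind, out)
}

#' Scan a FASTA file
#'
#' Reads a (possibly gzipped, multi-record) FASTA file, scans every record
#' and calls candidate intervals.
#'
#' @param path FASTA file path.
#' @param cfg A [scan_config()].
#' @return A list with `profiles` (named list of `score_profile`) and
#'   `calls` (one combined `motif_calls` data.frame).
#' @export
scan_fasta <- function(path, cfg = scan_config()) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  profiles <- stats::setNames(vector("list", length(seqs)), ids)
  calls <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    rec <- normalize_sequence(as.character(seqs[[i]]), id = ids[i])
    profiles[[i]] <- scan_sequence(rec, cfg)
    calls[[i]] <- call_intervals(profiles[[i]], cfg)
  }
  combined <- do.call(rbind, calls)
  rownames(combined) <- NULL
  class(combined) <- c("motif_calls", "data.frame")
  list(profiles = profiles, calls = combined)
}

#' Write calls as BED6
#'
#' Coordinates are 0-based half-open (BED convention).  The BED score
#' column is `round(1000 * min(|Qs| / 3, 1))`; the name column is the
#' classifier label.
#'
#' @param calls A `motif_calls` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  bed <- data.frame(
    chrom = calls$record_id,
    start = calls$start,
    end = calls$end,
    name = calls$label,
    score = round(1000 * pmin(abs(calls$qs) / 3, 1)),
    strand = calls$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write calls as a human-readable TSV
#'
#' Unlike the BED output, coordinates here are 1-based inclusive; the
#' header comment states the convention.  Scores are full precision.
#'
#' @inheritParams write_bed
#' @export
write_calls_tsv <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  tab <- data.frame(
    record_id = calls$record_id,
    start = calls$start + 1L,
    end = calls$end,
    strand = calls$strand,
    qs = calls$qs,
    label = calls$label
  )
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
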