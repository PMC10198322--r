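# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.  Mersenne-Twister, so output is reproducible across platforms.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(expr)
}

#' Construct a dinucleotide repeat oligonucleotide
#'
#' @param unit 2-mer repeat unit (e.g. `"GT"`, `"GA"`).
#' @param count Number of repeats (>= 1).
#' @param name Record id; defaults to the `(<unit>)_<count>` convention.
#' @return A `sequence_record` of length `2 * count`.
#' @examples
#' make_repeat_oligo("GT", 6)$seq  # "GTGTGTGTGTGT"
#' @export
make_repeat_oligo <- function(unit, count, name = NULL) {
  stopifnot(nchar(unit) == 2L, count >= 1)
  name <- name %||% sprintf("(%s)_%d", toupper(unit), count)
  normalize_sequence(strrep(toupper(unit), count), id = name)
}

#' Random background genome
#'
#' i.i.d. bases with a configurable GC fraction (G and C equiprobable,
#' likewise A and T).  Deterministic under a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param length Genome length in nt.
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param name Record id.
#' @return A `sequence_record`.
#' @export
make_random_genome <- function(seed, length, gc = 0.5, name = "random") {
  stopifnot(length >= 0, gc >= 0, gc <= 1)
  if (length == 0L) return(normalize_sequence("", id = name))
  seq <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  normalize_sequence(seq, id = name)
}

#' Random genome with motif spike-ins and a truth table
#'
#' Generates a random background and overwrites it with the given
#' sequences at stated 0-based offsets, returning both the sequence and a
#' BED-like truth table for recall benchmarking of the scanner and
#' classifier.
#'
#' @param seed Integer RNG seed for the background.
#' @param length Background length in nt.
#' @param spikes List of `list(record, position)` pairs (position 0-based);
#'   `record` may be a string or `sequence_record`.  Spikes must fit
#'   within the genome and must not overlap each other.
#' @param gc Background GC fraction.
#' @param name Record id.
#' @return A list with `record` (the spiked `sequence_record`) and
#'   `truth` (data.frame `start`, `end`, `name`, 0-based half-open).
#' @examples
#' g <- make_spiked_genome(1, 1000, list(list(make_repeat_oligo("GT", 9), 500)))
#' g$truth
#' @export
make_spiked_genome <- function(seed, length, spikes = list(), gc = 0.5,
                               name = "spiked") {
  bg <- make_random_genome(seed, length, gc = gc, name = name)
  if (length(spikes) == 0L) {
    return(list(record = bg,
                truth = data.frame(start = integer(0), end = integer(0),
                                   name = character(0))))
  }
  recs <- lapply(spikes, function(sp) as_sequence_record(sp[[1]]))
  pos <- vapply(spikes, function(sp) as.integer(sp[[2]]), integer(1))
  ends <- pos + vapply(recs, function(r) r$n, integer(1))
  if (any(pos < 0L) || any(ends > length)) stop("spike does not fit in genome")
  o <- order(pos)
  if (any(pos[o][-1L] < ends[o][-length(ends)])) stop("spikes overlap")
  chars <- strsplit(bg$seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(recs)) {
    chars[(pos[i] + 1L):ends[i]] <- strsplit(recs[[i]]$seq, "", fixed = TRUE)[[1]]
  }
  list(
    record = normalize_sequence(paste(chars, collapse = ""), id = name),
    truth = data.frame(start = pos[o], end = ends[o],
                       name = vapply(recs, function(r) r$id, character(1))[o])
  )
}

#' Simulate a two-state melting curve
#'
#' Generates the signal of the [fit_two_state()] model on a temperature
#' grid, optionally adding seeded Gaussian noise whose standard deviation
#' is a stated fraction of the folded-unfolded amplitude at Tm.
#'
#' @param tm Mid-transition temperature, deg C.
#' @param dH van't Hoff enthalpy, kJ/mol (negative).
#' @param baselines Named numeric `c(b_f, m_f, b_u, m_u)`; default flat
#'   baselines at 1 (folded) and 0 (unfolded).
#' @param noise Noise sd as a fraction of the transition amplitude
#'   (default 0).
#' @param seed RNG seed for the noise (required when `noise > 0`).
#' @param grid Temperature grid in deg C (default 0-100 by 0.5).
#' @param molecularity Strands in the folded species (default 1).
#' @return A [melt_curve()].
#' @examples
#' cv <- simulate_melt(tm = 60, dH = -200, noise = 0.01, seed = 7)
#' @export
simulate_melt <- function(tm, dH,
                          baselines = c(b_f = 1, m_f = 0, b_u = 0, m_u = 0),
                          noise = 0, seed = NULL,
                          grid = seq(0, 100, by = 0.5), molecularity = 1) {
  stopifnot(all(grid >= -C_TO_K), noise >= 0)
  b <- baselines
  th <- fraction_folded(grid + C_TO_K, tm + C_TO_K, dH, molecularity)
  s <- (b[["b_f"]] + b[["m_f"]] * grid) * th +
       (b[["b_u"]] + b[["m_u"]] * grid) * (1 - th)
  if (noise > 0) {
    if (is.null(seed)) stop("a seed is required for noisy simulation")
    amp <- abs((b[["b_f"]] + b[["m_f"]] * tm) - (b[["b_u"]] + b[["m_u"]] * tm))
    s <- s + with_seed(seed, stats::rnorm(length(grid), sd = noise * amp))
  }
  melt_curve(grid, s)
}

#' Write sequence records to a FASTA file
#'
#' @param recs A `sequence_record` or list of them.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(recs, path) {
  if (inherits(recs, "sequence_record")) recs <- list(recs)
  set <- Biostrings::DNAStringSet(vapply(recs, function(r) r$seq, character(1)))
  names(set) <- vapply(recs, function(r) r$id, character(1))
  Biostrings::writeXStringSet(set, path, compress = grepl("\\.gz$", path))
  invisible(path)
}
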