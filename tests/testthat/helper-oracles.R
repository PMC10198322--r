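# Independent oracles and small generators shared across test files.

# Signed height of one base, written out longhand (kept independent of the
# package's height_map).
oracle_height <- function(base, psi, A0 = 3) {
  s <- sin(psi * pi / 180)
  switch(base, G = A0, C = -A0, T = A0 * s, A = -A0 * s, N = 0,
         stop("bad base"))
}

# Shoelace polygon-area oracle for the Qs score: vertices (i, h_i) closed
# along the temperature axis.  Independent of the trapezoid-sum code path.
oracle_qs_shoelace <- function(seq, psi, A0 = 3) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n <= 1) return(0)
  h <- vapply(ch, oracle_height, numeric(1), psi = psi, A0 = A0)
  x <- c(seq_len(n), n, 1)
  y <- c(h, 0, 0)
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  shoelace <- 0.5 * sum(x * ys - xs * y)
  -shoelace / n   # the polygon as listed runs clockwise for positive heights
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

complement_seq <- function(seq) chartr("ACGT", "TGCA", seq)

reverse_seq <- function(seq) {
  paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Regex oracle for dinucleotide tract finding: best full-unit match of the
# unit or its rotation with at least min repeats, per match region.
oracle_tracts_regex <- function(seq, unit, min_repeats) {
  rot <- paste0(substr(unit, 2, 2), substr(unit, 1, 1))
  hits <- list()
  for (pat in c(unit, rot)) {
    m <- gregexpr(sprintf("(?:%s){%d,}", pat, min_repeats), seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      hits[[length(hits) + 1]] <- data.frame(
        start = m[i] - 1L, end = m[i] - 1L + len[i], count = len[i] %/% 2L,
        phase = pat)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(0), end = integer(0), count = integer(0)))
  }
  h <- do.call(rbind, hits)
  # the two phases of one alternating run overlap; keep the one with more
  # complete units (ties: the given-unit phase), matching the finder's
  # phase-normalization contract
  h <- h[order(-h$count, h$phase != unit, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    ov <- h$start < h$end[i] & h$end > h$start[i]
    ov[i] <- FALSE
    keep[ov] <- FALSE
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

# The printed reference panel: dinucleotide repeat oligos and the
# GGGAGCGA-repeat reference sequence, with their published scores at
# psi = 15 and 30 degrees.
reference_panel <- function() {
  data.frame(
    id = c("(TG)_6", "(TG)_9", "(TG)_18", "(TG)_27",
           "(GA)_6", "(GA)_9", "(GA)_18", "(GA)_27", "VK"),
    seq = c(strrep("GT", 6), strrep("GT", 9), strrep("GT", 18), strrep("GT", 27),
            strrep("GA", 6), strrep("GA", 9), strrep("GA", 18), strrep("GA", 27),
            "GGGAGCGAGGGAGCGAGGGAGCGAGGGAGCG"),
    nts = c(12L, 18L, 36L, 54L, 12L, 18L, 36L, 54L, 31L),
    qs15 = c(1.73, 1.78, 1.84, 1.85, 1.02, 1.05, 1.08, 1.09, 1.28),
    qs30 = c(2.06, 2.12, 2.18, 2.20, 0.69, 0.71, 0.73, 0.74, 1.11)
  )
}
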