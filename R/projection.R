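#' Semi-orthogonal projection model
#'
#' Constructs the per-nucleotide signed-height model underlying the Qs score.
#' The four bases are drawn as vectors of magnitude `amplitude` from a base
#' line: the complementary G and C point up and down within the G/C
#' projection plane (sigma), while A and T lie in a second plane (rho)
#' inclined towards sigma by the angle psi (so the planes subtend
#' alpha = 90 - psi degrees).  Projected onto the sigma axis, G and C keep
#' their full height while A and T contribute `amplitude * sin(psi)`; at
#' psi = 0 the planes are orthogonal and A/T project to zero.
#'
#' The sign convention (T positive, A negative, matching G positive,
#' C negative) makes the height of a base the exact negative of the height
#' of its complement, which is what gives the Qs score its strand
#' antisymmetry: the score of a reverse complement is minus the score of
#' the forward strand.
#'
#' @param psi Inclination from orthogonality in degrees, `0 <= psi < 90`.
#'   The default 30 (alpha = 60 degrees) is the setting at which the score
#'   thresholds for quadruplex prediction are defined.
#' @param amplitude Base vector magnitude (dimensionless), default 3.
#'
#' @return An object of class `projection_model`: a list with elements
#'   `psi_degrees`, `alpha_degrees` (always `90 - psi_degrees`),
#'   `amplitude`, and `height_map`, a named numeric vector over
#'   `A`, `C`, `G`, `T`, `N` (the ambiguity placeholder, height 0).
#' @examples
#' m <- projection_model(psi = 30)
#' m$height_map        # G +3, C -3, T +1.5, A -1.5, N 0
#' @seealso [qs_score()], [height()]
#' @export
projection_model <- function(psi = 30, amplitude = 3) {
  stopifnot(is.numeric(psi), length(psi) == 1L, psi >= 0, psi < 90,
            is.numeric(amplitude), length(amplitude) == 1L, amplitude > 0)
  s <- sin(psi * pi / 180)
  hm <- c(A = -amplitude * s, C = -amplitude, G = amplitude,
          T = amplitude * s, N = 0)
  structure(
    list(psi_degrees = psi, alpha_degrees = 90 - psi,
         amplitude = amplitude, height_map = hm),
    class = "projection_model"
  )
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("Semi-orthogonal projection model (psi = %g deg, alpha = %g deg, A0 = %g)\n",
              x$psi_degrees, x$alpha_degrees, x$amplitude))
  print(round(x$height_map, 4))
  invisible(x)
}

#' Normalize raw sequence text into a sequence record
#'
#' Uppercases, maps U to T (RNA input is scored as its DNA analog), and
#' replaces every character outside `{A, C, G, T, U}` with the neutral
#' placeholder `N` (height 0).  Replacement is lossy but never fatal, so
#' genome-scale FASTA input with ambiguity codes scans without aborting;
#' the number of replaced characters is recorded on the result.
#'
#' @param raw A single character string (any case; may be empty).
#' @param id Identifier carried on the record, default `"seq"`.
#'
#' @return An object of class `sequence_record`: a list with `id`, `seq`
#'   (normalized string over A/C/G/T/N), `n` (its length) and `replaced`
#'   (count of characters replaced by `N`).
#' @examples
#' normalize_sequence("gtgt")$seq    # "GTGT"
#' normalize_sequence("UGUG")$seq    # "TGTG"
#' normalize_sequence("GTNGT")$replaced  # 1
#' @export
normalize_sequence <- function(raw, id = "seq") {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  s <- chartr("u", "t", toupper(raw))
  s <- chartr("U", "T", s)
  bad <- gregexpr("[^ACGT]", s)[[1]]
  replaced <- if (bad[1] == -1L) 0L else length(bad)
  if (replaced > 0L) s <- gsub("[^ACGT]", "N", s)
  structure(
    list(id = id, seq = s, n = nchar(s), replaced = replaced),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  shown <- if (x$n > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(sprintf("<%s> %d nt%s\n  %s\n", x$id, x$n,
              if (x$replaced > 0) sprintf(" (%d ambiguous -> N)", x$replaced) else "",
              shown))
  invisible(x)
}

# Accept a plain string or a sequence_record everywhere a sequence is needed.
as_sequence_record <- function(x, id = "seq") {
  if (inherits(x, "sequence_record")) return(x)
  normalize_sequence(x, id = id)
}

#' Signed projection height of a base
#'
#' @param base Character vector of single bases over `A, C, G, T, N`.
#' @param model A [projection_model()].
#' @return Numeric vector of signed heights on the sigma (G/C) axis.
#' @examples
#' height(c("G", "C", "T", "A"), projection_model(psi = 30))
#' @export
height <- function(base, model = projection_model()) {
  stopifnot(inherits(model, "projection_model"))
  h <- model$height_map[base]
  if (anyNA(h)) {
    stop("unknown base symbol(s) after normalization: ",
         paste(unique(base[is.na(h)]), collapse = ", "))
  }
  unname(h)
}

# Height profile of a whole normalized sequence, as a numeric vector.
height_profile <- function(rec, model) {
  if (rec$n == 0L) return(numeric(0))
  height(strsplit(rec$seq, "", fixed = TRUE)[[1]], model)
}

#' Qs score: per-nucleotide signed area under the projection polyline
#'
#' With nucleotides at unit spacing and signed heights `h_1 .. h_n`, the
#' score is the signed trapezoid area under the polyline joining
#' consecutive vector endpoints, divided by the nucleotide count:
#'
#' \deqn{Q_s = \frac{1}{n} \sum_{i=1}^{n-1} \frac{h_i + h_{i+1}}{2}}
#'
#' The polyline spans positions 1..n only (no closure to zero height at
#' the ends), so a homopolymer of G attains the upper bound
#' `amplitude * (n-1)/n`.  Sequences of length 0 or 1 subtend no area and
#' score 0.
#'
#' At the default psi = 30 degrees, scores above 1.2 predict G-quadruplex
#' formation, scores above 2 flag Z-G4-prone repeats, the 0.7-1.2 band
#' flags other tetrahelical candidates, and strongly negative scores mark
#' C-rich i-motif candidates (see [classify_qs()]).
#'
#' @param x A character string or a `sequence_record`.
#' @param model A [projection_model()]; alternatively pass `psi` directly.
#' @param psi Convenience: inclination in degrees used to build a default
#'   model when `model` is missing.
#' @return A single numeric score.
#' @examples
#' qs_score(strrep("GT", 6), psi = 15)   # 1.73 (2 dp)
#' qs_score(strrep("GA", 6), psi = 30)   # 0.69 (2 dp)
#' @export
qs_score <- function(x, model = projection_model(psi), psi = 30) {
  rec <- as_sequence_record(x)
  h <- height_profile(rec, model)
  qs_from_heights(h)
}

# Trapezoid-sum score from a height vector; shared by qs_score and the
# vectorized scanner.
qs_from_heights <- function(h) {
  n <- length(h)
  if (n <= 1L) return(0)
  sum((h[-n] + h[-1L]) / 2) / n
}
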