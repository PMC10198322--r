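# Gas constant, kJ mol^-1 K^-1
R_GAS <- 8.31446261815324e-3
C_TO_K <- 273.15

#' Melting curve container
#'
#' @param temperature Temperatures in degrees Celsius, strictly increasing.
#' @param signal Observed signal (arbitrary units, e.g. ellipticity at
#'   ~265 nm).
#' @param wavelength_nm,heating_rate Optional metadata (nm, deg C / min);
#'   recorded only, not modelled.
#' @return A data.frame of class `melt_curve` with columns `temperature`
#'   and `signal`.
#' @export
melt_curve <- function(temperature, signal, wavelength_nm = NA_real_,
                       heating_rate = NA_real_) {
  stopifnot(is.numeric(temperature), is.numeric(signal),
            length(temperature) == length(signal),
            all(is.finite(temperature)), all(is.finite(signal)))
  if (any(diff(temperature) <= 0)) {
    stop("temperature grid must be strictly increasing")
  }
  structure(
    data.frame(temperature = temperature, signal = signal),
    wavelength_nm = wavelength_nm, heating_rate = heating_rate,
    class = c("melt_curve", "data.frame")
  )
}

#' Read a melting curve from a two-column CSV/TSV file
#'
#' The first two columns are taken as temperature (deg C) and signal; a
#' header line is detected and skipped if the first field is not numeric.
#' The separator is inferred (comma or tab).
#'
#' @param path File path.
#' @return A [melt_curve()].
#' @export
read_melt_curve <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- is.na(suppressWarnings(as.numeric(strsplit(first, sep)[[1]][1])))
  tab <- utils::read.table(path, sep = sep, header = header,
                           comment.char = "#")
  melt_curve(tab[[1]], tab[[2]])
}

#' Equilibrium fraction folded of a two-state transition
#'
#' For an intramolecular (molecularity 1) two-state transition with
#' van't Hoff enthalpy `dH` and mid-transition temperature `tm`, the
#' folded/unfolded equilibrium constant is
#' `K(T) = exp(-(dH/R) * (1/T - 1/tm))` and the fraction folded is
#' `K / (1 + K)`; at `T = tm` this is exactly 0.5.  The entropy is implied
#' by the mid-point convention (`dS = dH / tm`).
#'
#' For molecularity `m > 1` (an m-mer folding from m strands) the reduced
#' equilibrium `K * m * (1 - theta)^m = theta` is solved numerically, with
#' `K` referenced so that `theta(tm) = 0.5`; concentration is absorbed
#' into the reference (reduced-concentration convention).
#'
#' @param temp_K Temperature(s) in Kelvin.
#' @param tm_K Mid-transition temperature in Kelvin.
#' @param dH van't Hoff enthalpy in kJ/mol (negative for a transition
#'   written folded -> unfolded that melts on heating).
#' @param molecularity Number of strands in the folded species (default 1).
#' @return Fraction folded in `[0, 1]` (overflow clamps to 0/1).
#' @examples
#' fraction_folded(333.15, 333.15, -200)  # 0.5 at the midpoint
#' @export
fraction_folded <- function(temp_K, tm_K, dH, molecularity = 1) {
  stopifnot(all(temp_K > 0), tm_K > 0)
  lnK <- -(dH / R_GAS) * (1 / temp_K - 1 / tm_K)
  lnK <- pmin(pmax(lnK, -700), 700)
  if (molecularity == 1) {
    return(stats::plogis(lnK))
  }
  m <- molecularity
  # reference so theta(tm) = 0.5: K_tm * m * 0.5^m = 0.5
  lnK <- lnK + log(0.5 / (m * 0.5 ^ m))
  vapply(lnK, function(l) {
    K <- exp(pmin(l, 700))
    f <- function(th) K * m * (1 - th) ^ m - th
    if (f(1 - 1e-12) >= 0) return(1)
    if (f(1e-12) <= 0) return(0)
    stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }, numeric(1))
}

#' Tm from the first derivative of a melting curve
#'
#' Smooths the curve with a Savitzky-Golay filter, takes its first
#' derivative with respect to temperature, and returns the temperature of
#' the extremal derivative -- the mid-transition point of a symmetric
#' two-state sigmoid.  Used both as an independent Tm estimate and as the
#' initializer for [fit_two_state()].
#'
#' A curve with no transition (flat or linearly drifting signal) has an
#' essentially constant derivative; if the extremal deviation of the
#' derivative from its median does not exceed `prominence` times the
#' median absolute deviation, the function fails with an error.
#'
#' @param curve A [melt_curve()] (>= 10 points).  A non-uniform grid is
#'   interpolated onto a uniform one of the same size.
#' @param window Savitzky-Golay window length in points (odd; default 21,
#'   shrunk if the curve is short).
#' @param order Polynomial order of the filter (default 3).
#' @param prominence Peak-prominence factor for the no-transition check
#'   (default 5).
#' @return Tm in degrees Celsius.
#' @examples
#' cv <- simulate_melt(tm = 60, dH = -200)
#' tm_from_derivative(cv)
#' @export
tm_from_derivative <- function(curve, window = 21, order = 3,
                               prominence = 5) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- nrow(curve)
  if (n < 10L) stop("need at least 10 points")
  tt <- curve$temperature
  ss <- curve$signal
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) {   # resample non-uniform grids
    tu <- seq(tt[1], tt[n], length.out = n)
    ss <- stats::approx(tt, ss, xout = tu)$y
    tt <- tu
    dt <- diff(tt)
  }
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (window %% 2L == 0L) window <- window - 1L
  order <- min(order, window - 1L)
  d1 <- signal::sgolayfilt(ss, p = order, n = window, m = 1, ts = dt[1])
  # Peak search over the interior only: the asymmetric edge kernels of the
  # filter have inflated variance.
  hw <- (window - 1L) %/% 2L
  interior <- seq.int(hw + 1L, n - hw)
  dev <- abs(d1 - stats::median(d1))
  peak <- interior[which.max(dev[interior])]
  # Noise floor: point noise estimated from high-frequency successive
  # differences of the raw signal, propagated through the central
  # derivative kernel; the absolute term rejects exactly linear
  # (drift-only) curves whose derivative is constant.
  kern <- signal::sgolay(p = order, n = window, m = 1)[hw + 1L, ]
  sd_point <- stats::mad(diff(ss)) / sqrt(2)
  sd_deriv <- sd_point * sqrt(sum(kern ^ 2)) / dt[1]
  floor_ <- prominence * sd_deriv +
    1e-8 * (diff(range(ss)) + 1e-300) / (tt[n] - tt[1])
  if (!(dev[peak] > floor_)) {
    stop("no transition detected: derivative extremum does not exceed the noise floor")
  }
  # Refine the grid argmax by the vertex of a quadratic fitted over the
  # peak's half-height region: averages out argmax jitter on broad,
  # noisy transitions.
  above <- dev >= 0.5 * dev[peak]
  lo <- peak; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- peak; while (hi < n && above[hi + 1L]) hi <- hi + 1L
  if (hi - lo >= 4L) {
    idx <- lo:hi
    qf <- stats::lm(dev[idx] ~ tt[idx] + I(tt[idx] ^ 2))
    a <- stats::coef(qf)[[3]]; b <- stats::coef(qf)[[2]]
    if (is.finite(a) && a < 0) {
      vertex <- -b / (2 * a)
      if (vertex >= tt[lo] && vertex <= tt[hi]) return(vertex)
    }
  }
  tt[peak]
}

#' Fit a two-state melting model to a curve
#'
#' Nonlinear least squares of
#' `S(T) = (b_f + m_f T) * theta(T) + (b_u + m_u T) * (1 - theta(T))`
#' where `theta` is [fraction_folded()]: a two-state van't Hoff
#' transition between linear folded and unfolded baselines.  `Tm` is
#' initialized from [tm_from_derivative()] (falling back to the
#' temperature of steepest signal change), baselines from straight-line
#' fits to the outer 15% of points on each side.
#'
#' The free energy at the reference temperature follows from the
#' mid-point convention `dS = dH / Tm`:
#' `dG(T_ref) = dH * (1 - T_ref / Tm)` (temperatures in Kelvin); it is
#' negative when the folded form is favored at `T_ref`.
#'
#' @param curve A [melt_curve()] spanning the transition, ideally with
#'   signal plateaus on both sides.
#' @param molecularity Strands in the folded species (default 1,
#'   intramolecular).
#' @param t_ref Reference temperature in degrees Celsius for `dG_ref`
#'   (default 0).
#' @param start Optional named list overriding starting values
#'   (`tm` in deg C, `dH` in kJ/mol).
#' @return An object of class `two_state_fit`: a list with `tm` (deg C),
#'   `dH`, `dS` (kJ/mol/K), `dG_ref`, `t_ref`, `baselines`
#'   (named `b_f`, `m_f`, `b_u`, `m_u`), `molecularity`, `sigma`
#'   (residual RMS), `cov` (parameter covariance), `in_range` (FALSE, with
#'   a warning, when the fitted Tm lies outside the measured temperature
#'   range), and `curve`.
#' @examples
#' cv <- simulate_melt(tm = 60, dH = -200, noise = 0.01, seed = 7)
#' fit <- fit_two_state(cv)
#' fit$tm
#' @export
fit_two_state <- function(curve, molecularity = 1, t_ref = 0, start = NULL) {
  stopifnot(inherits(curve, "melt_curve"))
  if (nrow(curve) < 10L) stop("need at least 10 points")
  tc <- curve$temperature
  tk <- tc + C_TO_K
  s <- curve$signal

  tm0 <- start$tm %||%
    tryCatch(tm_from_derivative(curve),
             error = function(e) tc[which.max(abs(diff(s)))])
  dh0 <- start$dH %||% -200
  k <- max(3L, ceiling(0.15 * length(tc)))
  lo <- seq_len(k)
  hi <- seq.int(length(tc) - k + 1L, length(tc))
  cf <- stats::coef(stats::lm(s[lo] ~ tc[lo]))
  cu <- stats::coef(stats::lm(s[hi] ~ tc[hi]))

  dat <- data.frame(tk = tk, tc = tc, s = s)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ (b_f + m_f * tc) * fraction_folded(tk, tm_K, dH, molecularity) +
          (b_u + m_u * tc) * (1 - fraction_folded(tk, tm_K, dH, molecularity)),
      data = dat,
      start = list(tm_K = tm0 + C_TO_K, dH = dh0,
                   b_f = cf[[1]], m_f = cf[[2]], b_u = cu[[1]], m_u = cu[[2]]),
      lower = c(tm_K = 200, dH = -3000, b_f = -Inf, m_f = -Inf,
                b_u = -Inf, m_u = -Inf),
      upper = c(tm_K = 500, dH = -0.1, b_f = Inf, m_f = Inf,
                b_u = Inf, m_u = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop("two-state fit did not converge: ", conditionMessage(e),
           "\n  initial Tm = ", signif(tm0, 4), " degC, dH = ", dh0, " kJ/mol")
    }
  )

  p <- stats::coef(fit)
  tm_K <- p[["tm_K"]]
  dH <- p[["dH"]]
  in_range <- tm_K - C_TO_K >= tc[1] && tm_K - C_TO_K <= tc[length(tc)]
  if (!in_range) {
    warning("fitted Tm lies outside the measured temperature range")
  }
  dG_ref <- dH * (1 - (t_ref + C_TO_K) / tm_K)

  structure(
    list(tm = tm_K - C_TO_K, dH = dH, dS = dH / tm_K,
         dG_ref = dG_ref, t_ref = t_ref,
         baselines = c(b_f = p[["b_f"]], m_f = p[["m_f"]],
                       b_u = p[["b_u"]], m_u = p[["m_u"]]),
         molecularity = molecularity,
         sigma = stats::sigma(fit),
         cov = tryCatch(stats::vcov(fit), error = function(e) NULL),
         in_range = in_range,
         curve = curve),
    class = "two_state_fit"
  )
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Two-state melting fit\n")
  cat(sprintf("  Tm      : %.2f degC\n", x$tm))
  cat(sprintf("  dH      : %.1f kJ/mol (van't Hoff)\n", x$dH))
  cat(sprintf("  dS      : %.4f kJ/mol/K\n", x$dS))
  cat(sprintf("  dG(%g C): %.2f kJ/mol\n", x$t_ref, x$dG_ref))
  cat(sprintf("  baselines: folded %.3g + %.3g T, unfolded %.3g + %.3g T\n",
              x$baselines[["b_f"]], x$baselines[["m_f"]],
              x$baselines[["b_u"]], x$baselines[["m_u"]]))
  cat(sprintf("  residual RMS: %.4g; molecularity %d%s\n", x$sigma,
              x$molecularity,
              if (!x$in_range) "; WARNING: Tm outside measured range" else ""))
  invisible(x)
}

#' Predicted signal of a two-state fit
#'
#' @param object A `two_state_fit`.
#' @param temperature Temperatures in degrees Celsius (defaults to the
#'   fitted curve's grid).
#' @param ... Unused.
#' @return Numeric vector of model signal values.
#' @export
predict.two_state_fit <- function(object, temperature = NULL, ...) {
  tc <- temperature %||% object$curve$temperature
  th <- fraction_folded(tc + C_TO_K, object$tm + C_TO_K, object$dH,
                        object$molecularity)
  b <- object$baselines
  (b[["b_f"]] + b[["m_f"]] * tc) * th + (b[["b_u"]] + b[["m_u"]] * tc) * (1 - th)
}

#' Write a two-state fit report
#'
#' Writes the fitted parameters as JSON and, optionally, the observed and
#' fitted curve as TSV.
#'
#' @param fit A `two_state_fit`.
#' @param json_path Output JSON path.
#' @param tsv_path Optional TSV path for the per-temperature table.
#' @return `json_path`, invisibly.
#' @export
write_fit_report <- function(fit, json_path, tsv_path = NULL) {
  rep_ <- list(tm_C = fit$tm, dH_kJ_mol = fit$dH, dS_kJ_mol_K = fit$dS,
               dG_ref_kJ_mol = fit$dG_ref, t_ref_C = fit$t_ref,
               baselines = as.list(fit$baselines),
               molecularity = fit$molecularity,
               residual_rms = fit$sigma, tm_in_range = fit$in_range)
  jsonlite::write_json(rep_, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    tab <- data.frame(temperature = fit$curve$temperature,
                      signal = fit$curve$signal,
                      fitted = predict(fit))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
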