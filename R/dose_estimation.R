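#' Invert a linear-quadratic calibration curve
#'
#' Solves Y(D) = c + alpha*D + beta*D^2 = y for the absorbed dose. Yields
#' at or below the background c map to 0 Gy; otherwise the positive root
#' D = (-alpha + sqrt(alpha^2 + 4 beta (y - c))) / (2 beta) is returned
#' (or (y - c)/alpha for a purely linear curve).
#'
#' @param curve A [calibration_curve()] with `beta > 0`, or `beta = 0` and
#'   `alpha > 0`.
#' @param yield Observed yield(s) per cell, >= 0.
#' @return Dose(s) in Gy.
#' @export
#' @examples
#' crv <- calibration_curve(0.008, 0.088, 0.095)
#' invert_curve(crv, 22 / 50)  # ~1.72 Gy
invert_curve <- function(curve, yield) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(is.na(yield)) || any(yield < 0)) {
    stop("yield must be non-negative", call. = FALSE)
  }
  if (curve$beta < 0) stop("unsupported curve: beta < 0", call. = FALSE)
  if (curve$beta == 0 && curve$alpha == 0) {
    stop("curve is non-invertible: alpha = beta = 0", call. = FALSE)
  }
  excess <- pmax(yield - curve$c, 0)
  if (curve$beta == 0) {
    excess / curve$alpha
  } else {
    (-curve$alpha + sqrt(curve$alpha^2 + 4 * curve$beta * excess)) /
      (2 * curve$beta)
  }
}

#' Exact (Garwood) Poisson confidence limits for a count
#'
#' Two-sided equal-tailed exact limits for the mean of a Poisson variable
#' observed as the count X, from chi-square quantiles:
#' lower = qchisq(a/2, 2X)/2 (0 when X = 0) and
#' upper = qchisq(1 - a/2, 2X + 2)/2, with a = 1 - confidence. These are
#' the limits whose Poisson tail probabilities beyond the observation
#' equal a/2 on each side.
#'
#' @param x Observed count, a non-negative integer (vectorized).
#' @param confidence Coverage, in (0, 1); default 0.95.
#' @return A data.frame with columns `x`, `lower`, `upper`, `confidence`.
#' @export
#' @examples
#' exact_poisson_limits(22)  # 13.79 - 33.31
exact_poisson_limits <- function(x, confidence = 0.95) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop("x must be a non-negative integer count", call. = FALSE)
  }
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  a <- 1 - confidence
  lower <- ifelse(x == 0, 0, stats::qchisq(a / 2, 2 * x) / 2)
  upper <- stats::qchisq(1 - a / 2, 2 * x + 2) / 2
  data.frame(x = as.integer(x), lower = lower, upper = upper,
             confidence = confidence)
}

#' Estimate an absorbed dose from an aberration count
#'
#' Point estimate by inverting the calibration curve at the observed yield
#' X/N. Confidence limits (default method `"exact"`) are obtained by
#' putting exact Garwood limits on the raw count X, converting them to
#' yields over the N scored cells, and pushing each through the inverse
#' curve; because the inverse curve is monotone this preserves the exact
#' count-scale coverage. Curve-coefficient uncertainty is deliberately not
#' folded in, so the interval reflects scoring (Poisson) error only.
#' Method `"delta"` instead reports a first-order standard error
#' se(D) = se(Y) / (alpha + 2 beta D) with se(Y) = sqrt(X)/N and a normal
#' interval clipped at 0; it is offered for comparison and is generally
#' anti-conservative at small counts.
#'
#' @param curve A [calibration_curve()].
#' @param count Observed aberration count X (non-negative integer).
#' @param cells Number of cells scored N (>= 1).
#' @param confidence Interval coverage, default 0.95.
#' @param method `"exact"` (Garwood limits on the count) or `"delta"`.
#' @return An object of class `dose_estimate` with fields `dose`, `lcl`,
#'   `ucl`, `confidence`, `method`, `count`, `cells`, `yield`, `se` (delta
#'   method only) and `curve`.
#' @export
#' @examples
#' crv <- calibration_curve(0.008, 0.088, 0.095)
#' estimate_dose(crv, count = 22, cells = 50)
estimate_dose <- function(curve, count, cells, confidence = 0.95,
                          method = c("exact", "delta")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "calibration_curve"))
  if (length(count) != 1L || length(cells) != 1L) {
    stop("count and cells must be scalars", call. = FALSE)
  }
  if (is.na(cells) || cells < 1 || cells != floor(cells)) {
    stop("cells must be a positive integer", call. = FALSE)
  }
  if (is.na(count) || count < 0 || count != floor(count)) {
    stop("count must be a non-negative integer", call. = FALSE)
  }
  y <- count / cells
  dose <- invert_curve(curve, y)
  se <- NA_real_
  if (method == "exact") {
    lim <- exact_poisson_limits(count, confidence)
    lcl <- invert_curve(curve, lim$lower / cells)
    ucl <- invert_curve(curve, lim$upper / cells)
  } else {
    se_y <- sqrt(count) / cells
    slope <- curve$alpha + 2 * curve$beta * dose
    se <- if (slope > 0) se_y / slope else NA_real_
    z <- stats::qnorm(1 - (1 - confidence) / 2)
    lcl <- max(0, dose - z * se)
    ucl <- dose + z * se
  }
  structure(list(dose = dose, lcl = lcl, ucl = ucl, confidence = confidence,
                 method = method, count = as.integer(count),
                 cells = as.integer(cells), yield = y, se = se,
                 curve = curve),
            class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf(
    "<dose_estimate> %.2f Gy (%.2f-%.2f, %g%% CI, %s)\n  %d aberrations in %d cells (yield %.3f/cell)\n",
    x$dose, x$lcl, x$ucl, 100 * x$confidence, x$method, x$count, x$cells,
    x$yield))
  invisible(x)
}

#' Triage-mode scoring truncation
#'
#' Emergency triage scoring stops early: cells are scored in order until
#' either `max_cells` cells have been examined or the cumulative dicentric
#' count reaches `max_dicentrics` (classically "50 cells or 30
#' dicentrics"), whichever comes first.
#'
#' @param cells A per-cell score table in scoring order.
#' @param max_cells Cell cap, default 50.
#' @param max_dicentrics Cumulative dicentric-equivalents cap, default 30.
#' @return The shortest prefix of `cells` reaching either cap (all cells
#'   if neither is reached).
#' @export
triage_truncate <- function(cells, max_cells = 50, max_dicentrics = 30) {
  cells <- validate_cells(cells)
  if (nrow(cells) == 0L) return(cells)
  cum <- cumsum(cells$dicentric_equivalents)
  hit <- which(cum >= max_dicentrics)
  n_dic <- if (length(hit)) hit[1] else nrow(cells)
  n <- min(nrow(cells), max_cells, n_dic)
  cells[seq_len(n), , drop = FALSE]
}
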