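#' Linear-quadratic calibration curve
#'
#' The standard dose-response model for aberration yields after acute
#' photon exposure: Y(D) = c + alpha * D + beta * D^2, with Y the expected
#' aberrations per cell, D the absorbed dose in Gy, c the background yield,
#' alpha the one-track and beta the two-track coefficient.
#'
#' @param c,alpha,beta Coefficients (per cell, per cell/Gy, per cell/Gy^2);
#'   all must be >= 0.
#' @param se Named or positional numeric vector of length 3 with the
#'   standard errors of (c, alpha, beta); `NA` where unknown.
#' @param cov Optional 3x3 covariance matrix of the coefficients.
#' @param aberration_class Which aberration class the curve calibrates.
#' @param source Free-text provenance of the curve.
#' @param fit Optional fit metadata list (filled by [fit_lq_poisson()]).
#' @return An object of class `calibration_curve`.
#' @export
#' @examples
#' calibration_curve(0.008, 0.088, 0.095, se = c(0.004, 0.022, 0.009))
calibration_curve <- function(c, alpha, beta, se = c(NA, NA, NA), cov = NULL,
                              aberration_class = NA_character_,
                              source = NA_character_, fit = NULL) {
  coefs <- c(c = c, alpha = alpha, beta = beta)
  if (anyNA(coefs) || any(coefs < 0)) {
    stop("coefficients c, alpha, beta must be non-negative numbers",
         call. = FALSE)
  }
  se <- stats::setNames(as.numeric(se), c("c", "alpha", "beta"))
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (!all(dim(cov) == c(3L, 3L))) stop("cov must be 3x3", call. = FALSE)
    dimnames(cov) <- list(names(coefs), names(coefs))
  }
  structure(list(c = unname(c), alpha = unname(alpha), beta = unname(beta),
                 se = se, cov = cov, aberration_class = aberration_class,
                 source = source, fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  fmt <- function(v, s) {
    if (is.na(s)) sprintf("%.4g", v) else sprintf("%.4g +/- %.2g", v, s)
  }
  cat(sprintf("<calibration_curve> Y(D) = %s + %s D + %s D^2  [%s]\n",
              fmt(x$c, x$se["c"]), fmt(x$alpha, x$se["alpha"]),
              fmt(x$beta, x$se["beta"]),
              if (is.na(x$aberration_class)) "unspecified class"
              else x$aberration_class))
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted: %d doses, loglik %.4f, %s in %d iterations\n",
                length(x$fit$doses), x$fit$loglik,
                if (x$fit$converged) "converged" else "NOT converged",
                x$fit$iterations))
  }
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param curve A [calibration_curve()].
#' @param dose Vector of doses in Gy, all >= 0.
#' @return Expected yield per cell, `c + alpha*D + beta*D^2`.
#' @export
#' @examples
#' crv <- calibration_curve(0.008, 0.088, 0.095)
#' evaluate_curve(crv, c(0, 2))
evaluate_curve <- function(curve, dose) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(is.na(dose)) || any(dose < 0)) {
    stop("dose must be non-negative", call. = FALSE)
  }
  curve$c + curve$alpha * dose + curve$beta * dose^2
}

#' Read / write a calibration curve as JSON
#'
#' The on-disk form is a JSON object with fields `aberration_class, c,
#' alpha, beta, se_c, se_alpha, se_beta`, optional `cov` (3x3), `dose_unit`
#' and `source`.
#'
#' @param path File path.
#' @return `read_curve()` returns a [calibration_curve()];
#'   `write_curve()` returns `path` invisibly.
#' @export
read_curve <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  calibration_curve(as.numeric(j$c), as.numeric(j$alpha), as.numeric(j$beta),
                    se = c(num_or_na(j$se_c), num_or_na(j$se_alpha),
                           num_or_na(j$se_beta)),
                    cov = if (!is.null(j$cov)) matrix(unlist(j$cov), 3, 3),
                    aberration_class = if (is.null(j$aberration_class))
                      NA_character_ else j$aberration_class,
                    source = if (is.null(j$source)) NA_character_ else j$source)
}

#' @rdname read_curve
#' @param curve A [calibration_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  obj <- list(aberration_class = curve$aberration_class, c = curve$c,
              alpha = curve$alpha, beta = curve$beta,
              se_c = curve$se[["c"]], se_alpha = curve$se[["alpha"]],
              se_beta = curve$se[["beta"]], dose_unit = "Gy",
              source = curve$source)
  if (!is.null(curve$cov)) obj$cov <- apply(curve$cov, 1, as.list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

# Extract the per-dose sufficient statistics (D, N, X) for fitting.
.lq_design <- function(data, class, dose_range = NULL) {
  if (inherits(data, "score_sheet")) {
    d <- data.frame(dose = sheet_doses(data),
                    n = vapply(data$points, n_cells, 1L),
                    x = vapply(data$points, class_total, 1L, class = class))
  } else if (is.data.frame(data)) {
    nm <- names(data)
    pick <- function(...) {
      cand <- c(...)
      hit <- cand[cand %in% nm]
      if (!length(hit)) stop("fit data needs a column among: ",
                             paste(cand, collapse = ", "), call. = FALSE)
      data[[hit[1]]]
    }
    d <- data.frame(dose = pick("dose_gy", "dose"),
                    n = pick("n_cells", "cells_scored", "cells", "n"),
                    x = if (class %in% nm) data[[class]] else
                      pick("total", "count", "x"))
  } else {
    stop("data must be a score_sheet or a data.frame", call. = FALSE)
  }
  if (anyNA(d$x)) stop("class totals unavailable at some doses", call. = FALSE)
  if (!is.null(dose_range)) {
    d <- d[d$dose >= dose_range[1] & d$dose <= dose_range[2], , drop = FALSE]
  }
  d
}

.lq_loglik <- function(theta, D, N, X) {
  lam <- theta[1] + theta[2] * D + theta[3] * D^2
  if (any(lam < 0) || any(lam == 0 & X > 0)) return(-Inf)
  pos <- X > 0
  sum(X[pos] * log(N[pos] * lam[pos])) - sum(N * lam)
}

.lq_grad_info <- function(theta, D, N, X) {
  Z <- cbind(1, D, D^2)
  lam <- as.vector(Z %*% theta)
  pos <- X > 0
  r <- ifelse(pos, X / lam, 0) - N
  g <- as.vector(t(Z) %*% r)
  w <- ifelse(pos, X / lam^2, 0)
  H <- t(Z * w) %*% Z
  list(g = g, H = H, lam = lam)
}

#' Fit a linear-quadratic curve by Poisson maximum likelihood
#'
#' Fits Y(D) = c + alpha*D + beta*D^2 to per-dose aberration totals, with
#' per-dose counts X_i treated as Poisson with mean N_i * Y(D_i). The
#' aggregated totals are sufficient under this model, so per-cell data are
#' not needed. Maximization is by Newton iteration on the log-likelihood
#' with coefficients projected to be non-negative, started from an
#' unweighted least-squares fit of the yields; standard errors come from
#' the inverse observed information at the optimum. A coefficient that
#' converges onto the zero boundary is flagged and given no standard error,
#' since the information-matrix approximation fails there.
#'
#' @param data A [score_sheet()] or a data.frame with columns
#'   `dose_gy`/`dose`, `n_cells` (or `cells_scored`) and `total` (or a
#'   column named after `class`).
#' @param class Aberration class to fit.
#' @param fix_c,fix_alpha Fix the background (or the linear) coefficient at
#'   zero instead of estimating it.
#' @param dose_range Optional `c(min, max)` restriction on the doses used.
#' @param max_iter,rel_tol,grad_tol Newton stopping controls: maximum
#'   iterations, relative log-likelihood change, and gradient-norm
#'   threshold (scaled internally by the total aberration count, the
#'   natural size of the score equations).
#' @return A [calibration_curve()] whose `fit` field records the doses
#'   used, log-likelihood, iterations, final gradient norm, convergence
#'   flag, per-coefficient boundary flags and the number of free
#'   parameters.
#' @export
#' @examples
#' pts <- data.frame(dose_gy = c(0, 1, 2, 4), n_cells = 1000,
#'                   total = c(10, 62, 196, 610))
#' fit_lq_poisson(pts)
fit_lq_poisson <- function(data, class = "dicentric_equivalents",
                           fix_c = FALSE, fix_alpha = FALSE,
                           dose_range = NULL, max_iter = 200,
                           rel_tol = 1e-10, grad_tol = 1e-8) {
  class <- .match_class(class)
  d <- .lq_design(data, class, dose_range)
  D <- d$dose; N <- d$n; X <- d$x
  free <- c(!fix_c, !fix_alpha, TRUE)
  if (length(D) < sum(free)) {
    stop("need at least as many dose points as free coefficients",
         call. = FALSE)
  }
  if (all(X == 0)) {
    stop("degenerate fit: all aberration totals are zero", call. = FALSE)
  }

  # start from unweighted least squares on the yields, clipped to >= 0
  Y <- X / N
  Zf <- cbind(1, D, D^2)[, free, drop = FALSE]
  ls <- tryCatch(stats::lm.fit(Zf, Y)$coefficients, error = function(e) NULL)
  theta <- c(0, 0, 0)
  theta[free] <- if (is.null(ls) || anyNA(ls)) 1e-3 else pmax(ls, 1e-6)

  ll <- .lq_loglik(theta, D, N, X)
  if (!is.finite(ll)) { theta[free] <- 1e-3; ll <- .lq_loglik(theta, D, N, X) }
  # tolerances scale with the total count: both the score equations and the
  # attainable log-likelihood resolution grow with sum(X)
  g_scale <- 1 + sum(X)
  converged <- FALSE
  iter <- 0
  gnorm <- Inf
  repeat {
    iter <- iter + 1
    gi <- .lq_grad_info(theta, D, N, X)
    # active set: fixed coefficients, plus free ones pinned at the zero
    # boundary with the gradient pointing outward; the projected gradient
    # zeroes those components
    active <- !free | (theta <= 0 & gi$g < 0)
    gproj <- gi$g
    gproj[active] <- 0
    gnorm <- sqrt(sum(gproj^2))
    if (gnorm < grad_tol * g_scale) { converged <- TRUE; break }
    work <- !active
    Hf <- gi$H[work, work, drop = FALSE]
    step <- tryCatch(solve(Hf, gi$g[work]), error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(Hf + diag(1e-8, nrow(Hf)), gi$g[work])
    }
    t <- 1
    improved <- FALSE
    while (t >= 1e-10) {
      cand <- theta
      cand[work] <- pmax(theta[work] + t * step, 0)
      ll_new <- .lq_loglik(cand, D, N, X)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12 * max(1, abs(ll))) {
        improved <- TRUE
        rel_change <- abs(ll_new - ll) / max(1, abs(ll))
        theta <- cand
        ll <- ll_new
        if (rel_change < rel_tol) converged <- TRUE
        break
      }
      t <- t / 2
    }
    if (!improved || converged || iter >= max_iter) break
  }
  if (!converged) {
    stop(sprintf(paste0("LQ fit did not converge in %d iterations ",
                        "(gradient norm %.3g, loglik %.6f)"),
                 iter, gnorm, ll), call. = FALSE)
  }

  gi <- .lq_grad_info(theta, D, N, X)
  boundary <- free & theta <= 0
  interior <- free & !boundary
  se <- c(NA_real_, NA_real_, NA_real_)
  cov <- matrix(0, 3, 3)
  if (any(interior)) {
    Vi <- tryCatch(solve(gi$H[interior, interior, drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(Vi)) {
      cov[interior, interior] <- Vi
      se[interior] <- sqrt(diag(Vi))
    }
  }
  calibration_curve(theta[1], theta[2], theta[3], se = se, cov = cov,
                    aberration_class = class,
                    source = "fit_lq_poisson",
                    fit = list(doses = D, n_cells = N, totals = X,
                               loglik = ll, iterations = iter,
                               gradient_norm = gnorm, converged = converged,
                               fixed = stats::setNames(!free,
                                                       c("c", "alpha", "beta")),
                               boundary = stats::setNames(boundary,
                                                          c("c", "alpha", "beta")),
                               n_free = sum(interior)))
}

#' Poisson deviance goodness of fit for a calibration curve
#'
#' @param curve A fitted (or external) [calibration_curve()].
#' @param data Dose points, as accepted by [fit_lq_poisson()].
#' @param class Aberration class.
#' @return List with `deviance`, `df` and `p_value`. Degrees of freedom are
#'   the number of dose points minus the number of free coefficients (3
#'   unless the curve's fit metadata says otherwise); `df <= 0` yields `NA`
#'   deviance-test results.
#' @export
goodness_of_fit <- function(curve, data, class = "dicentric_equivalents") {
  stopifnot(inherits(curve, "calibration_curve"))
  class <- .match_class(class)
  d <- .lq_design(data, class)
  mu <- d$n * evaluate_curve(curve, d$dose)
  x <- d$x
  term <- ifelse(x > 0, x * log(x / mu) - (x - mu), mu)
  dev <- 2 * sum(term)
  n_free <- if (!is.null(curve$fit)) curve$fit$n_free else 3L
  df <- nrow(d) - n_free
  list(deviance = dev, df = df,
       p_value = if (df > 0) stats::pchisq(dev, df, lower.tail = FALSE)
       else NA_real_)
}
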