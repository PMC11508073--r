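#' Yield and dispersion statistics for a per-cell count vector
#'
#' Core computation behind the classical score-table columns: mean yield
#' with empirical standard error, variance-to-mean dispersion index with
#' its standard error, and the Papworth U statistic for under- or
#' overdispersion relative to Poisson. Written in terms of the sufficient
#' quantities of a count distribution (N cells, total X, sum of squared
#' counts), so per-cell data and aggregated distributions give identical
#' results.
#'
#' With N cells, total count X and yield Y = X/N:
#' \itemize{
#'   \item sample variance s2 = (sum k^2 n_k - X^2/N) / (N - 1)
#'   \item se(Y) = sqrt(s2 / N)
#'   \item dispersion index VM = s2 / Y, expected 1 under Poisson
#'   \item se(VM) = sqrt(2 (1 - 1/X) / (N - 1))
#'   \item U = (VM - 1) / se(VM), approximately standard normal under
#'     Poisson scoring
#' }
#' VM, se(VM) and U are undefined (NA) when Y = 0 or X < 2.
#'
#' @param n_cells Number of cells N (>= 2).
#' @param total Total aberration count X.
#' @param sum_sq Sum of squared per-cell counts.
#' @return Named list with `yield`, `se_yield`, `s2`, `dispersion`,
#'   `se_dispersion`, `u`.
#' @export
#' @examples
#' # 154 cells carrying 19 dicentrics as {0:136, 1:17, 2:1}
#' dispersion_stats(154, 19, 17 * 1 + 1 * 4)
dispersion_stats <- function(n_cells, total, sum_sq) {
  if (n_cells < 2) stop("dispersion statistics need at least 2 cells",
                        call. = FALSE)
  y <- total / n_cells
  s2 <- (sum_sq - total^2 / n_cells) / (n_cells - 1)
  out <- list(yield = y, se_yield = sqrt(s2 / n_cells), s2 = s2,
              dispersion = NA_real_, se_dispersion = NA_real_, u = NA_real_)
  if (total >= 2 && y > 0) {
    vm <- s2 / y
    se_vm <- sqrt(2 * (1 - 1 / total) / (n_cells - 1))
    out$dispersion <- vm
    out$se_dispersion <- se_vm
    out$u <- (vm - 1) / se_vm
  }
  out
}

.dist_moments <- function(dist) {
  k <- as.integer(names(dist))
  n_k <- as.integer(dist)
  list(n = sum(n_k), total = sum(k * n_k), sum_sq = sum(k^2 * n_k))
}

#' Summarize one dose point of a score sheet
#'
#' Computes the derived columns of a classical score table (yield +/- SE,
#' Var/Mean +/- SE, U) for one aberration class at one dose, from the
#' point's count distribution.
#'
#' @param point A [dose_point()] carrying per-cell records or a stored
#'   distribution for `class`, with at least 2 cells.
#' @param class One of [aberration_classes()].
#' @return One-row `data.frame` with columns `dose_gy`, `n_cells`, `total`,
#'   `yield`, `se_yield`, `dispersion`, `se_dispersion`, `u`. Dispersion
#'   columns are `NA` when the yield is 0 or the total is below 2.
#' @export
summarize_dose_point <- function(point, class = "dicentric_equivalents") {
  class <- .match_class(class)
  if (!inherits(point, "dose_point")) stop("point must be a dose_point",
                                           call. = FALSE)
  dist <- class_distribution(point, class)
  if (is.null(dist)) {
    stop("distribution unavailable for ", class, " at ", point$dose, " Gy",
         call. = FALSE)
  }
  m <- .dist_moments(dist)
  st <- dispersion_stats(m$n, m$total, m$sum_sq)
  data.frame(dose_gy = point$dose, n_cells = m$n, total = m$total,
             yield = st$yield, se_yield = st$se_yield,
             dispersion = st$dispersion, se_dispersion = st$se_dispersion,
             u = st$u)
}

#' Summarize every dose point of a score sheet
#'
#' One row per dose, ordered by dose. Dose points whose distribution is
#' unavailable for the requested class (totals-only data) are kept in the
#' output with `NA` statistics and an explanatory `note`, so a single bad
#' dose point does not abort the summary.
#'
#' @param sheet A [score_sheet()].
#' @param class One of [aberration_classes()].
#' @return A `data.frame` with the columns of [summarize_dose_point()] plus
#'   `note`.
#' @export
summarize_sheet <- function(sheet, class = "dicentric_equivalents") {
  class <- .match_class(class)
  if (!inherits(sheet, "score_sheet")) stop("sheet must be a score_sheet",
                                            call. = FALSE)
  rows <- lapply(sheet$points, function(p) {
    res <- tryCatch(summarize_dose_point(p, class), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(dose_gy = p$dose, n_cells = p$n_cells,
                 total = class_total(p, class), yield = NA_real_,
                 se_yield = NA_real_, dispersion = NA_real_,
                 se_dispersion = NA_real_, u = NA_real_,
                 note = conditionMessage(res))
    } else {
      res$note <- ""
      res
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$dose_gy), , drop = FALSE]
}
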