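#' Recompute the published dispersion table from the bundled distributions
#'
#' Reruns [summarize_sheet()] on the bundled G2-PCC dicentric series and
#' lines the computed yield, Var/Mean and U columns up against the values
#' printed in the source study (2-decimal printing), flagging each cell
#' that agrees within `tolerance`.
#'
#' @param tolerance Absolute agreement tolerance; the default 0.02 reflects
#'   2-decimal printing.
#' @return data.frame with computed and published columns and logical
#'   `pass_*` flags for the 13 irradiated doses.
#' @export
reproduce_dispersion_table <- function(tolerance = 0.02) {
  computed <- summarize_sheet(dicentric_dose_response(),
                              "dicentric_equivalents")
  published <- published_dispersion_stats()
  m <- merge(computed, published, by = "dose_gy",
             suffixes = c("_computed", "_published"))
  m <- m[order(m$dose_gy), ]
  m$pass_yield <- abs(m$yield_computed - m$yield_published) <= tolerance
  m$pass_dispersion <-
    abs(m$dispersion_computed - m$dispersion_published) <= tolerance
  m$pass_u <- abs(m$u_computed - m$u_published) <= tolerance
  rownames(m) <- NULL
  m
}

#' Recompute the published dose estimates from the bundled triage counts
#'
#' Pushes every bundled triage-mode dicentric count through
#' [estimate_dose()] with the bundled FISH dicentric calibration curve
#' (exact Garwood limits) and compares the point estimate and both 95%
#' limits with the printed values. Rows with zero delivered dose are
#' reported but not pass/fail checked: the printed zero-dose entries do
#' not follow the count-limit construction (one prints its estimate as its
#' own upper limit) and carry no dosimetric content.
#'
#' @param tolerance Absolute agreement tolerance in Gy, default 0.02.
#' @return data.frame with one row per (condition, dose), computed and
#'   published estimates/limits, and `pass` flags (`NA` for 0 Gy rows).
#' @export
reproduce_dose_estimates <- function(tolerance = 0.02) {
  counts <- triage_dicentric_counts()
  published <- published_dose_estimates()
  curve <- reference_curve("fish_dicentric")
  published$dose_gy <- published$exposure_gy
  m <- merge(counts, published[c("condition", "dose_gy", "estimate_gy",
                                 "lcl_gy", "ucl_gy")],
             by.x = c("condition", "dose_gy"),
             by.y = c("condition", "dose_gy"))
  est <- lapply(seq_len(nrow(m)), function(i) {
    e <- estimate_dose(curve, m$dicentrics[i], m$cells_scored[i])
    data.frame(estimate_computed = e$dose, lcl_computed = e$lcl,
               ucl_computed = e$ucl)
  })
  out <- cbind(m, do.call(rbind, est))
  check <- out$dose_gy > 0
  out$pass_estimate <- ifelse(check,
                              abs(out$estimate_computed - out$estimate_gy) <= tolerance, NA)
  out$pass_lcl <- ifelse(check, abs(out$lcl_computed - out$lcl_gy) <= tolerance,
                         NA)
  out$pass_ucl <- ifelse(check, abs(out$ucl_computed - out$ucl_gy) <= tolerance,
                         NA)
  out[order(out$condition, out$dose_gy), ]
}

#' Per-donor correlation of total-aberration yields between preparations
#'
#' For each donor in a spectrum design, computes the Pearson correlation
#' between the metaphase and G2-PCC total-aberration yields over the
#' shared dose grid.
#'
#' @param design A [spectrum_design()]; defaults to the bundled
#'   preparation-comparison counts.
#' @return Named numeric vector of correlations, one per donor.
#' @export
yield_correlation_by_donor <- function(design = prep_comparison_counts()) {
  design <- spectrum_design(as.data.frame(design))
  design$total <- rowSums(design[aberration_classes()])
  design$yield <- design$total / design$cells_scored
  vapply(split(design, design$donor), function(d) {
    a <- d[d$g2 == 0, ]; b <- d[d$g2 == 1, ]
    a <- a[order(a$dose_gy), ]; b <- b[order(b$dose_gy), ]
    if (!identical(a$dose_gy, b$dose_gy)) {
      stop("preparations disagree on the dose grid", call. = FALSE)
    }
    yield_correlation(a$yield, b$yield)
  }, 1)
}

#' Rerun the whole desk-scale reproduction
#'
#' Bundles [reproduce_dispersion_table()], [reproduce_dose_estimates()]
#' and [yield_correlation_by_donor()] into one report with an overall
#' pass flag.
#'
#' @param tolerance Absolute agreement tolerance (statistics and Gy).
#' @return An object of class `reproduction_report`: list with
#'   `dispersion`, `dose_estimates`, `yield_correlations` and `all_pass`.
#' @export
reproduce_study <- function(tolerance = 0.02) {
  disp <- reproduce_dispersion_table(tolerance)
  est <- reproduce_dose_estimates(tolerance)
  corr <- yield_correlation_by_donor()
  all_pass <- all(disp$pass_yield, disp$pass_dispersion, disp$pass_u) &&
    all(est$pass_estimate, est$pass_lcl, est$pass_ucl, na.rm = TRUE) &&
    all(corr >= 0.99)
  structure(list(dispersion = disp, dose_estimates = est,
                 yield_correlations = corr, all_pass = all_pass,
                 tolerance = tolerance),
            class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat(sprintf("<reproduction_report> tolerance %.3g: %s\n", x$tolerance,
              if (x$all_pass) "all checks pass" else "CHECKS FAILED"))
  cat(sprintf("  dispersion table: %d/%d cells within tolerance\n",
              sum(x$dispersion$pass_yield, x$dispersion$pass_dispersion,
                  x$dispersion$pass_u),
              3L * nrow(x$dispersion)))
  checked <- !is.na(x$dose_estimates$pass_estimate)
  cat(sprintf("  dose estimates: %d/%d cells within tolerance\n",
              sum(x$dose_estimates$pass_estimate[checked],
                  x$dose_estimates$pass_lcl[checked],
                  x$dose_estimates$pass_ucl[checked]),
              3L * sum(checked)))
  cat("  total-yield correlations:",
      paste(names(x$yield_correlations),
            sprintf("%.4f", x$yield_correlations), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}
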