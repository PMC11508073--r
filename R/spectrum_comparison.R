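#' Design table for an aberration-spectrum comparison
#'
#' One row per (dose x donor x preparation) observation, carrying the six
#' aggregated category counts. Per-cell co-occurrence of categories is not
#' needed: the multinomial model conditions on the total aberrations per
#' observation.
#'
#' @param data A data.frame with columns `dose_gy`, `donor`, either
#'   `preparation` (`"G2_PCC"`/`"METAPHASE"`) or a 0/1 `g2` indicator, and
#'   the six columns of [aberration_classes()].
#' @return The validated data.frame with a `g2` indicator column (0 for
#'   metaphase, 1 for G2-PCC), class `spectrum_design`.
#' @export
spectrum_design <- function(data) {
  if (!is.data.frame(data)) stop("data must be a data.frame", call. = FALSE)
  need <- c("dose_gy", "donor", aberration_classes())
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("design is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"g2" %in% names(data)) {
    if (!"preparation" %in% names(data)) {
      stop("design needs a g2 indicator or a preparation column",
           call. = FALSE)
    }
    data$g2 <- as.integer(data$preparation == "G2_PCC")
  }
  if (!all(data$g2 %in% c(0, 1))) {
    stop("g2 indicator must be 0 (metaphase) or 1 (G2-PCC)", call. = FALSE)
  }
  for (cl in aberration_classes()) {
    data[[cl]] <- .check_count_vector(data[[cl]], cl)
  }
  class(data) <- c("spectrum_design", "data.frame")
  data
}

#' Build a spectrum design from score sheets
#'
#' Aggregates each sheet's per-dose class totals into one design row per
#' dose, tagging rows with the sheet's donor and preparation.
#'
#' @param sheets A list of [score_sheet()] objects.
#' @return A [spectrum_design()].
#' @export
spectrum_design_from_sheets <- function(sheets) {
  if (inherits(sheets, "score_sheet")) sheets <- list(sheets)
  rows <- lapply(sheets, function(sh) {
    do.call(rbind, lapply(sh$points, function(p) {
      tot <- vapply(aberration_classes(), function(cl) {
        v <- class_total(p, cl)
        if (is.na(v)) 0L else v
      }, 1L)
      data.frame(dose_gy = p$dose, donor = sh$donor,
                 preparation = sh$preparation, cells_scored = p$n_cells,
                 as.list(tot), stringsAsFactors = FALSE)
    }))
  })
  spectrum_design(do.call(rbind, rows))
}

#' Fit a multinomial dose-response model to aberration spectra
#'
#' Models the category composition of the aberration spectrum as a
#' baseline-category (multinomial logit) regression. For each non-reference
#' category k the log odds against the reference category are
#' `a_k + donor_k + b_k * D^2 + c_k * D^2 * G2`, where G2 is the 0/1
#' preparation indicator; dose enters through its square only, the
#' two-track term that dominates aberration induction over the dose ranges
#' compared here. The interaction coefficients `c_k` carry the question of
#' interest: does the spectrum shift between metaphase chromosomes and
#' G2-PCCs as dose grows? Wald z tests are reported per coefficient.
#'
#' Fitting is delegated to [nnet::multinom()]; coefficients, standard
#' errors and the multinomial log-likelihood kernel are extracted from the
#' converged fit.
#'
#' @param design A [spectrum_design()] with at least two doses and both
#'   preparation levels.
#' @param reference Reference category, fixed at zero coefficients; the
#'   default is compound fragments, typically the largest class.
#' @return An object of class `spectrum_fit`: a list with `coefficients`
#'   (data.frame: category, term, estimate, se, z, p), `interaction`
#'   (the `c_k` rows), `loglik`, `fitted_probabilities` (matrix, rows =
#'   design rows), `reference`, `categories` and the underlying `nnet` fit.
#' @export
fit_spectrum_model <- function(design, reference = "compound_fragments") {
  design <- spectrum_design(as.data.frame(design))
  reference <- .match_class(reference)
  if (length(unique(design$dose_gy)) < 2 || length(unique(design$g2)) < 2) {
    stop("interaction fit needs >= 2 doses and both preparation levels",
         call. = FALSE)
  }
  cats <- c(reference, setdiff(aberration_classes(), reference))
  counts <- as.matrix(design[cats])
  empty <- colSums(counts) == 0
  if (any(empty)) {
    if (empty[1]) stop("reference category has no events", call. = FALSE)
    warning("dropping empty categories: ",
            paste(cats[empty], collapse = ", "), call. = FALSE)
    cats <- cats[!empty]
    counts <- counts[, !empty, drop = FALSE]
  }
  if (ncol(counts) < 2) stop("need at least two non-empty categories",
                             call. = FALSE)
  df <- data.frame(dsq = design$dose_gy^2, g2 = design$g2,
                   donor = factor(design$donor))
  form <- if (nlevels(df$donor) > 1) counts ~ donor + dsq + dsq:g2 else
    counts ~ dsq + dsq:g2
  fit <- nnet::multinom(form, data = df, trace = FALSE, maxit = 1000,
                        reltol = 1e-12)
  if (fit$convergence != 0) {
    stop("multinomial fit did not converge (nnet convergence code ",
         fit$convergence, ")", call. = FALSE)
  }
  cf <- stats::coef(fit)
  se <- summary(fit)$standard.errors
  if (is.null(dim(cf))) {  # two categories: coef() drops to a vector
    cf <- matrix(cf, nrow = 1, dimnames = list(cats[2], names(cf)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(cf))
  }
  coefs <- data.frame(
    category = rep(rownames(cf), ncol(cf)),
    term = rep(colnames(cf), each = nrow(cf)),
    estimate = as.vector(cf), se = as.vector(se))
  coefs$z <- coefs$estimate / coefs$se
  coefs$p <- 2 * stats::pnorm(-abs(coefs$z))
  probs <- stats::fitted(fit)
  if (is.null(dim(probs))) probs <- cbind(1 - probs, probs)
  colnames(probs) <- cats
  ll <- sum(counts[counts > 0] * log(probs[counts > 0]))
  structure(list(coefficients = coefs,
                 interaction = coefs[coefs$term == "dsq:g2", , drop = FALSE],
                 loglik = ll, fitted_probabilities = probs,
                 reference = cats[1], categories = cats, nnet_fit = fit),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("<spectrum_fit> multinomial logit, reference = %s, loglik %.3f\n",
              x$reference, x$loglik))
  cat("dose^2 x G2 interaction:\n")
  print(x$interaction, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Wald test for a single coefficient
#'
#' @param estimate Coefficient estimate.
#' @param se Its standard error, > 0.
#' @return List with `z = estimate/se` and the two-sided normal `p_value`.
#' @export
#' @examples
#' wald_test(2.5, 1.0)
wald_test <- function(estimate, se) {
  if (!is.numeric(se) || anyNA(se) || any(se <= 0)) {
    stop("se must be positive", call. = FALSE)
  }
  z <- estimate / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Pearson correlation of per-dose yields
#'
#' Compares the dose response of two scoring arms (e.g. metaphase vs
#' G2-PCC total-aberration yields over a shared dose grid).
#'
#' @param yields_a,yields_b Equal-length numeric vectors (>= 3 doses).
#' @return Pearson r, or `NA` (with a warning) when either vector has zero
#'   variance.
#' @export
yield_correlation <- function(yields_a, yields_b) {
  if (length(yields_a) != length(yields_b)) {
    stop("yield vectors must have equal length", call. = FALSE)
  }
  if (length(yields_a) < 3) stop("need at least 3 doses", call. = FALSE)
  if (stats::sd(yields_a) == 0 || stats::sd(yields_b) == 0) {
    warning("zero variance in a yield vector; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(yields_a, yields_b)
}
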