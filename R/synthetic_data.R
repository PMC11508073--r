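#' Configuration for a simulated score sheet
#'
#' Describes the generative model the downstream statistics assume: each
#' aberration class has a linear-quadratic mean yield per dose, and
#' per-cell counts are drawn independently per class (co-occurrence
#' between classes is not modelled). Dispersion options:
#' \describe{
#'   \item{`poisson`}{counts ~ Poisson(lambda_class(D)); the reference
#'     model for uniform whole-body photon exposure.}
#'   \item{`neg_binomial`}{gamma-mixed Poisson with shape `nb_size`
#'     (smaller = more overdispersed), emulating heterogeneous scoring.}
#'   \item{`partial_body`}{each cell is irradiated with probability
#'     `fraction_irradiated` (mean lambda(D)) or unexposed (mean c), a
#'     two-component mixture that produces zero-inflated, overdispersed
#'     counts. No cell-death weighting is applied.}
#' }
#'
#' @param curves A [calibration_curve()] (taken to describe dicentric
#'   equivalents) or a named list mapping aberration classes to curves;
#'   classes without a curve are simulated as all-zero.
#' @param doses Dose grid in Gy.
#' @param cells_per_dose Cells scored per dose; scalar or one per dose,
#'   all >= 1.
#' @param dispersion `"poisson"`, `"neg_binomial"` or `"partial_body"`.
#' @param nb_size Negative-binomial shape (required for `neg_binomial`).
#' @param fraction_irradiated Irradiated fraction in (0, 1] (required for
#'   `partial_body`).
#' @param seed Integer RNG seed; mandatory, recorded in the sheet.
#' @param sample_id,preparation,culture_hours,donor Sheet metadata.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(curves, doses, cells_per_dose,
                              dispersion = c("poisson", "neg_binomial",
                                             "partial_body"),
                              nb_size = NULL, fraction_irradiated = NULL,
                              seed, sample_id = "sim",
                              preparation = c("G2_PCC", "METAPHASE"),
                              culture_hours = 48, donor = "sim_donor") {
  dispersion <- match.arg(dispersion)
  preparation <- match.arg(preparation)
  if (inherits(curves, "calibration_curve")) {
    curves <- list(dicentric_equivalents = curves)
  }
  if (!length(curves) || is.null(names(curves)) ||
      !all(names(curves) %in% aberration_classes()) ||
      !all(vapply(curves, inherits, TRUE, "calibration_curve"))) {
    stop("curves must be calibration_curve objects named by aberration class",
         call. = FALSE)
  }
  if (!length(doses) || anyNA(doses) || any(doses < 0)) {
    stop("doses must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(doses)) stop("doses must be unique", call. = FALSE)
  cells_per_dose <- rep_len(cells_per_dose, length(doses))
  if (anyNA(cells_per_dose) || any(cells_per_dose < 1) ||
      any(cells_per_dose != floor(cells_per_dose))) {
    stop("cells_per_dose must be positive integers", call. = FALSE)
  }
  if (dispersion == "neg_binomial" &&
      (is.null(nb_size) || is.na(nb_size) || nb_size <= 0)) {
    stop("neg_binomial dispersion requires nb_size > 0", call. = FALSE)
  }
  if (dispersion == "partial_body" &&
      (is.null(fraction_irradiated) || is.na(fraction_irradiated) ||
       fraction_irradiated <= 0 || fraction_irradiated > 1)) {
    stop("partial_body dispersion requires fraction_irradiated in (0, 1]",
         call. = FALSE)
  }
  if (missing(seed) || is.null(seed) || is.na(seed) ||
      seed != floor(seed)) {
    stop("a stochastic run requires an integer seed", call. = FALSE)
  }
  structure(list(curves = curves, doses = as.numeric(doses),
                 cells_per_dose = as.integer(cells_per_dose),
                 dispersion = dispersion, nb_size = nb_size,
                 fraction_irradiated = fraction_irradiated,
                 seed = as.integer(seed), sample_id = sample_id,
                 preparation = preparation, culture_hours = culture_hours,
                 donor = donor),
            class = "simulation_config")
}

.draw_counts <- function(config, lambda, background, n) {
  switch(config$dispersion,
         poisson = stats::rpois(n, lambda),
         neg_binomial = stats::rnbinom(n, mu = lambda, size = config$nb_size),
         partial_body = {
           irradiated <- stats::rbinom(n, 1, config$fraction_irradiated) == 1
           mu <- ifelse(irradiated, lambda, background)
           stats::rpois(n, mu)
         })
}

#' Simulate a score sheet
#'
#' Draws per-cell aberration counts for every dose in the configuration,
#' independently per aberration class, under the configured dispersion
#' model. The RNG (Mersenne-Twister) is seeded from `config$seed` at the
#' start, so identical configurations yield identical sheets.
#'
#' @param config A [simulation_config()].
#' @return A [score_sheet()]; the seed and RNG kind are attached as
#'   attributes `seed` and `rng_kind`.
#' @export
#' @examples
#' crv <- calibration_curve(0, 0.021, 0.387)
#' sim <- simulate_score_sheet(simulation_config(crv, doses = c(0, 1, 2),
#'                                               cells_per_dose = 50, seed = 1))
simulate_score_sheet <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister")
  points <- lapply(seq_along(config$doses), function(i) {
    d <- config$doses[i]
    n <- config$cells_per_dose[i]
    cols <- lapply(aberration_classes(), function(cl) {
      crv <- config$curves[[cl]]
      if (is.null(crv)) return(integer(n))
      .draw_counts(config, evaluate_curve(crv, d), crv$c, n)
    })
    names(cols) <- aberration_classes()
    cells <- data.frame(cell_id = sprintf("d%g_c%04d", d, seq_len(n)), cols,
                        stringsAsFactors = FALSE)
    dose_point(d, cells = cells)
  })
  sheet <- score_sheet(points, sample_id = config$sample_id,
                       preparation = config$preparation,
                       culture_hours = config$culture_hours,
                       donor = config$donor)
  attr(sheet, "seed") <- config$seed
  attr(sheet, "rng_kind") <- "Mersenne-Twister"
  sheet
}

#' Simulate a multi-arm comparison study
#'
#' Generates one score sheet per configuration (e.g. two preparations x
#' two donors over a shared dose grid) and assembles them into a spectrum
#' design ready for [fit_spectrum_model()]. Under identical per-arm
#' parameters the preparation effect is null by construction.
#'
#' @param configs List of [simulation_config()] objects; all must share
#'   the same dose grid and carry distinct (donor, preparation) pairs.
#' @return List with `sheets` (the simulated [score_sheet()]s) and
#'   `design` (a [spectrum_design()] of aggregated counts).
#' @export
simulate_study <- function(configs) {
  if (!length(configs) ||
      !all(vapply(configs, inherits, TRUE, "simulation_config"))) {
    stop("configs must be a list of simulation_config objects", call. = FALSE)
  }
  doses <- lapply(configs, function(cf) sort(cf$doses))
  if (length(configs) > 1 &&
      !all(vapply(doses[-1], identical, TRUE, doses[[1]]))) {
    stop("all arms must share the same dose grid", call. = FALSE)
  }
  arms <- vapply(configs, function(cf) paste(cf$donor, cf$preparation), "")
  if (anyDuplicated(arms)) {
    stop("each (donor, preparation) arm must appear once", call. = FALSE)
  }
  sheets <- lapply(configs, simulate_score_sheet)
  list(sheets = sheets, design = spectrum_design_from_sheets(sheets))
}
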