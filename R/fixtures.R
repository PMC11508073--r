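#' Bundled study data
#'
#' The package ships, as plain-text fixtures, the per-dose scoring data of
#' an X-ray dose-response study of unstable chromosome aberrations in
#' FISH-stained human lymphocytes, covering calyculin A-induced G2-PCCs
#' over 0-20 Gy and a head-to-head comparison with colcemid-arrested
#' metaphases in two donors (0-7.5 Gy). These loaders return the data in
#' the package's containers so every analysis step can be rerun from them.
#'
#' \describe{
#'   \item{`dicentric_dose_response()`}{[score_sheet()] of the 14-dose
#'     G2-PCC series (0-20 Gy) with full per-dose dicentric count
#'     distributions; multicentrics are already collapsed to dicentric
#'     equivalents.}
#'   \item{`ring_dose_response()`}{[score_sheet()] of the same series with
#'     centric/acentric ring totals only (no distributions were recorded,
#'     so dispersion statistics report as unavailable).}
#'   \item{`prep_comparison_counts()`}{[spectrum_design()] of aggregated
#'     six-category counts, metaphase vs G2-PCC, two donors, six doses.}
#'   \item{`triage_dicentric_counts()`}{data.frame of dicentric totals
#'     scored in triage mode under three culture conditions (calyculin A
#'     36 h and 48 h, colcemid 48 h) at 0/1/2/4 Gy.}
#'   \item{`published_dose_estimates()`}{data.frame of the dose estimates
#'     and 95% limits as printed in the source study, for comparison. The
#'     printed delivered-dose label of the highest row is "3" although the
#'     exposures were 4 Gy; both are kept (`delivered_label_gy`,
#'     `exposure_gy`) rather than silently correcting the label.}
#'   \item{`published_dispersion_stats()`}{data.frame of the printed
#'     yield/dispersion/U columns for the 13 irradiated doses of the
#'     G2-PCC dicentric series, for comparison.}
#' }
#'
#' @return See each entry above.
#' @name study_fixtures
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "pccdose")
  if (path == "") stop("missing bundled fixture: ", file, call. = FALSE)
  path
}

#' @rdname study_fixtures
#' @export
dicentric_dose_response <- function() {
  read_score_sheet(.extdata("g2pcc_dicentric_distributions.csv"),
                   format = "distribution_csv",
                   sample_id = "g2pcc_doseresponse", preparation = "G2_PCC",
                   culture_hours = 48, donor = "donor_F1")
}

#' @rdname study_fixtures
#' @export
ring_dose_response <- function() {
  df <- utils::read.csv(.extdata("g2pcc_ring_totals.csv"))
  points <- lapply(seq_len(nrow(df)), function(i) {
    dose_point(df$dose_gy[i], n_cells = df$cells_scored[i],
               totals = c(centric_rings = df$centric_rings[i],
                          acentric_rings = df$acentric_rings[i]))
  })
  score_sheet(points, sample_id = "g2pcc_rings", preparation = "G2_PCC",
              culture_hours = 48, donor = "donor_F1")
}

#' @rdname study_fixtures
#' @export
prep_comparison_counts <- function() {
  spectrum_design(utils::read.csv(.extdata("prep_comparison_counts.csv"),
                                  stringsAsFactors = FALSE))
}

#' @rdname study_fixtures
#' @export
triage_dicentric_counts <- function() {
  utils::read.csv(.extdata("triage_dicentric_counts.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname study_fixtures
#' @export
published_dose_estimates <- function() {
  utils::read.csv(.extdata("published_dose_estimates.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname study_fixtures
#' @export
published_dispersion_stats <- function() {
  utils::read.csv(.extdata("published_dispersion_stats.csv"))
}

#' Bundled reference calibration curves
#'
#' Three externally determined linear-quadratic curves shipped as JSON
#' fixtures:
#' \describe{
#'   \item{`fish_dicentric`}{the laboratory's FISH dicentric calibration
#'     Y = 0.008 + 0.088 D + 0.095 D^2, the curve used for the bundled
#'     dose estimates.}
#'   \item{`cabas_dicentric`, `cabas_ring`}{coefficients reported from
#'     CABAS regressions of the G2-PCC series. Their fitting protocol and
#'     dose range were not recorded and they are inconsistent with a
#'     full-range LQ fit of the bundled data, so they are provided as
#'     reference metadata only, never as fitting targets.}
#' }
#'
#' @param name Which curve to load.
#' @return A [calibration_curve()].
#' @export
reference_curve <- function(name = c("fish_dicentric", "cabas_dicentric",
                                     "cabas_ring")) {
  name <- match.arg(name)
  read_curve(.extdata(paste0(name, "_curve.json")))
}
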