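#' Aberration categories scored on a FISH-stained cell
#'
#' The six unstable-aberration categories distinguishable with combined
#' centromere/telomere PNA probes: dicentric equivalents (multicentrics
#' collapsed to C-1 dicentrics), rings split by presence of a centromeric
#' signal, and acentric fragments split by telomeric signal at both ends
#' (compound), one end (terminal) or neither (interstitial).
#'
#' @return Character vector of the six category column names, in canonical
#'   order.
#' @export
#' @examples
#' aberration_classes()
aberration_classes <- function() {
  c("dicentric_equivalents", "centric_rings", "acentric_rings",
    "compound_fragments", "terminal_fragments", "interstitial_fragments")
}

.match_class <- function(class) {
  match.arg(class, aberration_classes())
}

.check_count_vector <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop(sprintf("%s must be non-negative integers", what), call. = FALSE)
  }
  as.integer(x)
}

#' Build a table of per-cell aberration scores
#'
#' One row per scored cell, one column per aberration category; this is the
#' canonical per-cell representation from which distributions and totals are
#' derived. Arguments are recycled to a common length.
#'
#' @param dicentric_equivalents,centric_rings,acentric_rings,compound_fragments,terminal_fragments,interstitial_fragments
#'   Non-negative integer counts per cell.
#' @param cell_id Optional cell identifiers; defaults to `cell_1 ... cell_n`.
#' @return A `data.frame` with a `cell_id` column and the six category
#'   columns, validated.
#' @export
#' @examples
#' cell_records(dicentric_equivalents = c(0, 1, 2))
cell_records <- function(dicentric_equivalents = 0L, centric_rings = 0L,
                         acentric_rings = 0L, compound_fragments = 0L,
                         terminal_fragments = 0L, interstitial_fragments = 0L,
                         cell_id = NULL) {
  counts <- list(dicentric_equivalents = dicentric_equivalents,
                 centric_rings = centric_rings,
                 acentric_rings = acentric_rings,
                 compound_fragments = compound_fragments,
                 terminal_fragments = terminal_fragments,
                 interstitial_fragments = interstitial_fragments)
  n <- max(vapply(counts, length, 1L), length(cell_id))
  counts <- lapply(counts, function(x) rep_len(x, n))
  if (is.null(cell_id)) cell_id <- paste0("cell_", seq_len(n))
  df <- data.frame(cell_id = as.character(cell_id), counts,
                   stringsAsFactors = FALSE)
  validate_cells(df)
}

#' Validate a per-cell score table
#'
#' @param cells A data.frame carrying a `cell_id` column and the six columns
#'   of [aberration_classes()].
#' @return The validated data.frame, with count columns coerced to integer.
#' @export
validate_cells <- function(cells) {
  if (!is.data.frame(cells)) stop("cells must be a data.frame", call. = FALSE)
  missing <- setdiff(aberration_classes(), names(cells))
  if (length(missing)) {
    stop("cells is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"cell_id" %in% names(cells)) {
    cells$cell_id <- paste0("cell_", seq_len(nrow(cells)))
  }
  for (cl in aberration_classes()) {
    cells[[cl]] <- .check_count_vector(cells[[cl]], paste0("column ", cl))
  }
  cells
}

#' Total aberrations per cell
#'
#' @param cells A validated per-cell score table.
#' @return Integer vector, the row sums over the six categories.
#' @export
total_aberrations <- function(cells) {
  cells <- validate_cells(cells)
  as.integer(rowSums(cells[aberration_classes()]))
}

#' Dicentric equivalents contributed by multicentric chromosomes
#'
#' A chromosome with C centromeres (C >= 2) is scored as C - 1 dicentric
#' equivalents, so a tricentric counts as two dicentrics and a plain
#' dicentric as one.
#'
#' @param n_centromeres Integer vector of centromere counts, one per
#'   multicentric event; every element must be >= 2.
#' @return The total number of dicentric equivalents, an integer.
#' @export
#' @examples
#' dicentric_equivalents(3)        # one tricentric -> 2
#' dicentric_equivalents(c(5, 2))  # pentacentric + dicentric -> 5
dicentric_equivalents <- function(n_centromeres) {
  if (length(n_centromeres) == 0L) return(0L)
  n <- .check_count_vector(n_centromeres, "n_centromeres")
  if (any(n < 2L)) {
    stop("every multicentric event must have at least 2 centromeres",
         call. = FALSE)
  }
  sum(n - 1L)
}

#' Aggregate per-cell counts into a count distribution
#'
#' Collapses a per-cell score table into the classical score-sheet
#' distribution for one aberration category: how many cells carried 0, 1,
#' 2, ... aberrations of that class.
#'
#' @param cells A per-cell score table.
#' @param class One of [aberration_classes()].
#' @return Named integer vector; names are the counts `0 ... max`, values
#'   the number of cells. Values sum to the number of cells and
#'   `sum(count * n_cells)` equals the class total.
#' @export
#' @examples
#' aggregate_distribution(cell_records(dicentric_equivalents = c(0, 0, 1, 2)),
#'                        "dicentric_equivalents")
aggregate_distribution <- function(cells, class) {
  cells <- validate_cells(cells)
  class <- .match_class(class)
  if (nrow(cells) == 0L) stop("cells must be nonempty", call. = FALSE)
  x <- cells[[class]]
  k <- 0:max(x)
  dist <- vapply(k, function(v) sum(x == v), 1L)
  names(dist) <- k
  dist
}

.validate_distribution <- function(dist, n_cells, class) {
  if (is.null(names(dist)) || anyNA(suppressWarnings(as.integer(names(dist))))) {
    stop("distribution for ", class, " must be named by integer counts",
         call. = FALSE)
  }
  k <- as.integer(names(dist))
  n_k <- .check_count_vector(unname(dist), paste0("distribution of ", class))
  if (any(k < 0)) stop("distribution counts must be >= 0", call. = FALSE)
  if (anyDuplicated(k)) stop("duplicated count in distribution", call. = FALSE)
  if (sum(n_k) != n_cells) {
    stop(sprintf("distribution for %s sums to %d cells but n_cells is %d",
                 class, sum(n_k), n_cells), call. = FALSE)
  }
  o <- order(k)
  stats::setNames(n_k[o], k[o])
}

#' One dose level of a score sheet
#'
#' A dose point holds the cells scored at one absorbed dose, in whichever
#' of three progressively coarser representations the source data support:
#' the full per-cell table, per-class count distributions, or bare class
#' totals. Statistics that need a finer representation than is present
#' report it as unavailable rather than imputing.
#'
#' @param dose Absorbed dose in Gy, a single number >= 0.
#' @param cells Optional per-cell score table (canonical representation).
#' @param distributions Optional named list, class -> named integer vector
#'   (count -> number of cells).
#' @param totals Optional named integer vector of per-class totals.
#' @param n_cells Number of cells scored; required unless `cells` is given.
#' @return An object of class `dose_point`.
#' @export
#' @examples
#' dose_point(0.5, n_cells = 154,
#'            distributions = list(dicentric_equivalents = c(`0` = 136, `1` = 17, `2` = 1)))
dose_point <- function(dose, cells = NULL, distributions = NULL,
                       totals = NULL, n_cells = NULL) {
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("dose must be a single non-negative number (Gy)", call. = FALSE)
  }
  if (!is.null(cells)) {
    cells <- validate_cells(cells)
    if (nrow(cells) == 0L) stop("dose point has no cells", call. = FALSE)
    if (!is.null(n_cells) && n_cells != nrow(cells)) {
      stop("n_cells disagrees with the number of cell records", call. = FALSE)
    }
    n_cells <- nrow(cells)
    derived <- vapply(cells[aberration_classes()], sum, 1L)
    if (!is.null(totals)) {
      for (cl in names(totals)) {
        if (totals[[cl]] != derived[[cl]]) {
          stop("totals disagree with the cell records for ", cl, call. = FALSE)
        }
      }
    }
    totals <- derived
  } else {
    if (is.null(n_cells) || n_cells < 1 || n_cells != floor(n_cells)) {
      stop("n_cells must be a positive integer when no cells are given",
           call. = FALSE)
    }
    n_cells <- as.integer(n_cells)
    tot <- if (is.null(totals)) integer() else totals
    if (!is.null(distributions)) {
      bad <- setdiff(names(distributions), aberration_classes())
      if (length(bad)) stop("unknown aberration class: ", bad[1], call. = FALSE)
      distributions <- mapply(.validate_distribution, distributions,
                              class = names(distributions),
                              MoreArgs = list(n_cells = n_cells),
                              SIMPLIFY = FALSE)
      for (cl in names(distributions)) {
        d <- distributions[[cl]]
        x <- sum(as.integer(names(d)) * d)
        if (cl %in% names(tot) && tot[[cl]] != x) {
          stop("totals disagree with the distribution for ", cl, call. = FALSE)
        }
        tot[[cl]] <- x
      }
    }
    if (length(tot)) {
      bad <- setdiff(names(tot), aberration_classes())
      if (length(bad)) stop("unknown aberration class: ", bad[1], call. = FALSE)
      totals <- stats::setNames(
        .check_count_vector(unlist(tot), "totals"), names(tot))
    } else {
      stop("a dose point needs cells, distributions or totals", call. = FALSE)
    }
  }
  structure(list(dose = as.numeric(dose), n_cells = n_cells, cells = cells,
                 distributions = distributions, totals = totals),
            class = "dose_point")
}

#' @export
print.dose_point <- function(x, ...) {
  cat(sprintf("<dose_point> %g Gy, %d cells; ", x$dose, x$n_cells))
  cat(if (!is.null(x$cells)) "per-cell" else
    if (!is.null(x$distributions)) "distribution" else "totals-only", "\n")
  tot <- x$totals[x$totals > 0]
  if (length(tot)) {
    cat("  totals:", paste(names(tot), tot, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cells scored at a dose point
#' @param point A `dose_point`.
#' @return Integer.
#' @export
n_cells <- function(point) point$n_cells

#' Total aberration count of one class at a dose point
#'
#' @param point A `dose_point`.
#' @param class One of [aberration_classes()].
#' @return Integer total, or `NA` if the class was not scored.
#' @export
class_total <- function(point, class) {
  class <- .match_class(class)
  if (class %in% names(point$totals)) point$totals[[class]] else NA_integer_
}

#' Count distribution of one class at a dose point
#'
#' Derived from the per-cell table when present, otherwise taken from a
#' stored distribution; `NULL` when only totals are available.
#'
#' @inheritParams class_total
#' @return Named integer vector (count -> cells) or `NULL`.
#' @export
class_distribution <- function(point, class) {
  class <- .match_class(class)
  if (!is.null(point$cells)) return(aggregate_distribution(point$cells, class))
  if (!is.null(point$distributions) && class %in% names(point$distributions)) {
    return(point$distributions[[class]])
  }
  NULL
}

#' A scored sample: dose points plus sample metadata
#'
#' @param points List of [dose_point()] objects with unique doses.
#' @param sample_id Sample label.
#' @param preparation `"G2_PCC"` (calyculin A-induced prematurely condensed
#'   chromosomes) or `"METAPHASE"` (colcemid-arrested).
#' @param culture_hours Lymphocyte culture time before harvest, hours.
#' @param donor Donor label.
#' @return An object of class `score_sheet`; points are stored sorted by
#'   dose.
#' @export
score_sheet <- function(points, sample_id = NA_character_,
                        preparation = c("G2_PCC", "METAPHASE"),
                        culture_hours = NA_real_, donor = NA_character_) {
  preparation <- match.arg(preparation)
  if (inherits(points, "dose_point")) points <- list(points)
  if (!length(points) || !all(vapply(points, inherits, TRUE, "dose_point"))) {
    stop("points must be a nonempty list of dose_point objects", call. = FALSE)
  }
  doses <- vapply(points, function(p) p$dose, 1)
  if (anyDuplicated(doses)) {
    stop("dose values must be unique within a score sheet", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 preparation = preparation,
                 culture_hours = as.numeric(culture_hours),
                 donor = as.character(donor),
                 points = points[order(doses)]),
            class = "score_sheet")
}

#' @export
print.score_sheet <- function(x, ...) {
  cat(sprintf("<score_sheet> sample %s (%s, donor %s, %g h culture)\n",
              x$sample_id, x$preparation, x$donor, x$culture_hours))
  cat(sprintf("  %d dose points: %s Gy\n", length(x$points),
              paste(vapply(x$points, function(p) format(p$dose), ""),
                    collapse = ", ")))
  invisible(x)
}

#' Doses of a score sheet
#' @param sheet A `score_sheet`.
#' @return Numeric vector of doses in Gy, ascending.
#' @export
sheet_doses <- function(sheet) vapply(sheet$points, function(p) p$dose, 1)

# ---- readers / writers -----------------------------------------------------

.per_cell_header <- function() {
  c("sample_id", "preparation", "culture_hours", "donor", "dose_gy",
    "cell_id", aberration_classes())
}

#' Read a score sheet from CSV
#'
#' Two dialects are supported. `per_cell_csv` has one row per scored cell
#' with columns `sample_id, preparation, culture_hours, donor, dose_gy,
#' cell_id` and the six category columns. `distribution_csv` is the long
#' form of an aggregated score table, with columns `dose_gy, cells_scored,
#' aberration_class, count, n_cells`.
#'
#' @param path File path.
#' @param format `"per_cell_csv"` or `"distribution_csv"`.
#' @param sample_id,preparation,culture_hours,donor Sample metadata for the
#'   distribution dialect, which does not carry it.
#' @return A [score_sheet()].
#' @export
read_score_sheet <- function(path, format = c("per_cell_csv", "distribution_csv"),
                             sample_id = NA_character_, preparation = "G2_PCC",
                             culture_hours = NA_real_, donor = NA_character_) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "per_cell_csv") {
    missing <- setdiff(.per_cell_header(), names(df))
    if (length(missing)) {
      stop("per-cell sheet is missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (nrow(df) == 0L) stop("score sheet has no cells", call. = FALSE)
    for (meta in c("sample_id", "preparation", "culture_hours", "donor")) {
      if (length(unique(df[[meta]])) != 1L) {
        stop("inconsistent ", meta, " within one sheet", call. = FALSE)
      }
    }
    for (cl in aberration_classes()) {
      bad <- which(is.na(df[[cl]]) | df[[cl]] < 0 | df[[cl]] != floor(df[[cl]]))
      if (length(bad)) {
        stop(sprintf("malformed count in column %s, data row %d", cl, bad[1]),
             call. = FALSE)
      }
    }
    points <- lapply(split(df, df$dose_gy), function(chunk) {
      dose_point(chunk$dose_gy[1],
                 cells = chunk[c("cell_id", aberration_classes())])
    })
    score_sheet(unname(points), sample_id = df$sample_id[1],
                preparation = df$preparation[1],
                culture_hours = df$culture_hours[1], donor = df$donor[1])
  } else {
    need <- c("dose_gy", "cells_scored", "aberration_class", "count", "n_cells")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("distribution sheet is missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (nrow(df) == 0L) stop("score sheet has no rows", call. = FALSE)
    bad <- which(is.na(df$n_cells) | df$n_cells < 0 | is.na(df$count) |
                   df$count < 0)
    if (length(bad)) {
      stop("malformed or negative count in data row ", bad[1], call. = FALSE)
    }
    points <- lapply(split(df, df$dose_gy), function(chunk) {
      n <- unique(chunk$cells_scored)
      if (length(n) != 1L) {
        stop("inconsistent cells_scored at dose ", chunk$dose_gy[1],
             call. = FALSE)
      }
      dists <- lapply(split(chunk, chunk$aberration_class), function(d) {
        # zero-padded: cells with unlisted counts are not assumed
        stats::setNames(as.integer(d$n_cells), d$count)
      })
      dose_point(chunk$dose_gy[1], n_cells = n, distributions = dists)
    })
    score_sheet(unname(points), sample_id = sample_id,
                preparation = preparation, culture_hours = culture_hours,
                donor = donor)
  }
}

#' Write a score sheet to CSV
#'
#' Inverse of [read_score_sheet()]; writing then reading a valid sheet
#' reproduces it. The per-cell dialect requires every dose point to carry
#' per-cell records; the distribution dialect requires a distribution
#' (stored or derivable) for `class`.
#'
#' @param sheet A [score_sheet()].
#' @param path Output file path.
#' @param format `"per_cell_csv"` or `"distribution_csv"`.
#' @param class Aberration class written in the distribution dialect.
#' @return `path`, invisibly.
#' @export
write_score_sheet <- function(sheet, path,
                              format = c("per_cell_csv", "distribution_csv"),
                              class = "dicentric_equivalents") {
  format <- match.arg(format)
  if (format == "per_cell_csv") {
    rows <- lapply(sheet$points, function(p) {
      if (is.null(p$cells)) {
        stop("dose point at ", p$dose,
             " Gy has no per-cell records; cannot write per_cell_csv",
             call. = FALSE)
      }
      data.frame(sample_id = sheet$sample_id, preparation = sheet$preparation,
                 culture_hours = sheet$culture_hours, donor = sheet$donor,
                 dose_gy = p$dose, p$cells[c("cell_id", aberration_classes())],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)[, .per_cell_header()]
  } else {
    class <- .match_class(class)
    rows <- lapply(sheet$points, function(p) {
      d <- class_distribution(p, class)
      if (is.null(d)) {
        stop("dose point at ", p$dose, " Gy has no distribution for ", class,
             call. = FALSE)
      }
      d <- d[d > 0 | as.integer(names(d)) == 0L]
      data.frame(dose_gy = p$dose, cells_scored = p$n_cells,
                 aberration_class = class, count = as.integer(names(d)),
                 n_cells = as.integer(d), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
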