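test_that("multicentrics collapse to centromeres-minus-one dicentric equivalents", {
  expect_identical(dicentric_equivalents(3), 2L)      # one tricentric
  expect_identical(dicentric_equivalents(2), 1L)      # a plain dicentric
  expect_identical(dicentric_equivalents(c(5, 2)), 5L)
  expect_identical(dicentric_equivalents(integer()), 0L)
  expect_error(dicentric_equivalents(1), "at least 2 centromeres")
  expect_error(dicentric_equivalents(c(3, 0)), "at least 2 centromeres")
  expect_error(dicentric_equivalents(2.5), "integer")
})

test_that("aggregation to a count distribution conserves cells and totals", {
  cells <- cell_records(dicentric_equivalents = c(rep(0, 136), rep(1, 17), 2))
  dist <- aggregate_distribution(cells, "dicentric_equivalents")
  expect_identical(dist, c(`0` = 136L, `1` = 17L, `2` = 1L))

  all_zero <- cell_records(dicentric_equivalents = rep(0, 40))
  expect_identical(aggregate_distribution(all_zero, "dicentric_equivalents"),
                   c(`0` = 40L))

  set.seed(101)
  for (i in 1:20) {
    x <- rpois(sample(5:200, 1), runif(1, 0, 4))
    cells <- cell_records(centric_rings = x)
    d <- aggregate_distribution(cells, "centric_rings")
    expect_identical(sum(d), length(x))
    expect_identical(sum(as.integer(names(d)) * d), sum(x))
  }
})

test_that("dose points validate their representations against each other", {
  expect_error(dose_point(-1, n_cells = 10,
                          totals = c(dicentric_equivalents = 1)),
               "non-negative")
  expect_error(dose_point(1, cells = cell_records(dicentric_equivalents = 1)[0, ]),
               "no cells")
  expect_error(dose_point(1, n_cells = 0,
                          totals = c(dicentric_equivalents = 0)),
               "positive integer")
  # distribution must account for every scored cell
  expect_error(dose_point(1, n_cells = 100, distributions =
                            list(dicentric_equivalents = c(`0` = 90, `1` = 5))),
               "sums to 95 cells")
  # totals must agree with a coexisting distribution
  expect_error(dose_point(1, n_cells = 10,
                          distributions = list(dicentric_equivalents = c(`0` = 8, `1` = 2)),
                          totals = c(dicentric_equivalents = 5)),
               "disagree")
  # and with per-cell records
  expect_error(dose_point(1, cells = cell_records(dicentric_equivalents = c(1, 1)),
                          totals = c(dicentric_equivalents = 3)),
               "disagree")
})

test_that("bundled dose-response series reproduces its printed cell and aberration totals", {
  sheet <- dicentric_dose_response()
  expect_length(sheet$points, 14)
  s <- summarize_sheet(sheet, "dicentric_equivalents")
  expect_identical(s$n_cells[s$dose_gy == 0.5], 154L)
  expect_identical(s$total[s$dose_gy == 0.5], 19L)
  expect_identical(s$n_cells[s$dose_gy == 20], 49L)
  expect_identical(s$total[s$dose_gy == 20], 674L)
  expect_identical(sum(s$n_cells), 1646L)
  # conservation: totals from the distribution match sum(k * n_k) per dose
  for (p in sheet$points) {
    d <- class_distribution(p, "dicentric_equivalents")
    expect_identical(sum(as.integer(d)), p$n_cells)
    expect_identical(sum(as.integer(names(d)) * as.integer(d)),
                     class_total(p, "dicentric_equivalents"))
  }
})

test_that("score sheets round-trip through both CSV dialects", {
  cfg <- simulation_config(fish_curve(), doses = c(0, 1, 2.5),
                           cells_per_dose = 50, seed = 11,
                           sample_id = "rt", donor = "donor_X",
                           culture_hours = 48)
  sheet <- simulate_score_sheet(cfg)

  per_cell <- withr::local_tempfile(fileext = ".csv")
  write_score_sheet(sheet, per_cell, "per_cell_csv")
  back <- read_score_sheet(per_cell, "per_cell_csv")
  expect_identical(sheet_doses(back), sheet_doses(sheet))
  expect_identical(back$sample_id, sheet$sample_id)
  for (i in seq_along(sheet$points)) {
    a <- sheet$points[[i]]$cells
    b <- back$points[[i]]$cells
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }

  dist_csv <- withr::local_tempfile(fileext = ".csv")
  write_score_sheet(sheet, dist_csv, "distribution_csv",
                    class = "dicentric_equivalents")
  back2 <- read_score_sheet(dist_csv, "distribution_csv")
  for (i in seq_along(sheet$points)) {
    orig <- class_distribution(sheet$points[[i]], "dicentric_equivalents")
    got <- class_distribution(back2$points[[i]], "dicentric_equivalents")
    expect_identical(got[got > 0], orig[orig > 0])
  }

  # and the bundled distribution sheet is itself write/read stable
  ref <- dicentric_dose_response()
  f <- withr::local_tempfile(fileext = ".csv")
  write_score_sheet(ref, f, "distribution_csv")
  again <- read_score_sheet(f, "distribution_csv")
  expect_equal(vapply(again$points, class_total, 1L, "dicentric_equivalents"),
               vapply(ref$points, class_total, 1L, "dicentric_equivalents"))
})

test_that("malformed sheets are rejected with the offending location", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dose_gy,cells_scored,aberration_class,count,n_cells",
               "1,100,dicentric_equivalents,0,90",
               "1,100,dicentric_equivalents,1,-10"), f)
  expect_error(read_score_sheet(f, "distribution_csv"), "row 2")

  writeLines(c("dose_gy,cells_scored,aberration_class,count,n_cells",
               "1,100,dicentric_equivalents,0,90",
               "1,90,dicentric_equivalents,1,10"), f)
  expect_error(read_score_sheet(f, "distribution_csv"),
               "inconsistent cells_scored")

  # unique doses enforced at the sheet level
  p1 <- dose_point(1, n_cells = 5, totals = c(dicentric_equivalents = 1))
  expect_error(score_sheet(list(p1, p1)), "unique")
})
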