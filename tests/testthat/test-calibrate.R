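test_that("group boundaries follow the mean -/+ sd definitions", {
  # published 10-min labor moments: 77780.06 - 68137.81 = 9642.25
  gl <- group_stats(c(77780.06 - 68137.81 / sqrt(2),
                      77780.06 + 68137.81 / sqrt(2)), "labor")
  expect_equal(gl$mlpi, 77780.06, tolerance = 1e-9)
  expect_equal(gl$sdlpi, 68137.81, tolerance = 1e-9)
  expect_equal(gl$boundary, 9642.25, tolerance = 1e-6)
  # published 12-min non-labor moments: 6248.59 + 3222.90 = 9471.49
  gn <- group_stats(c(6248.59 - 3222.90 / sqrt(2),
                      6248.59 + 3222.90 / sqrt(2)), "non_labor")
  expect_equal(gn$boundary, 9471.49, tolerance = 1e-6)
  # degenerate spread: boundary collapses onto the constant
  const <- group_stats(rep(5, 4), "labor")
  expect_equal(const$sdlpi, 0)
  expect_equal(const$boundary, 5)
  expect_error(group_stats(1, "labor"), "at least 2")
})

test_that("the central range value is the boundary gap, linear in the labor mean", {
  gl <- function(m, s, ctx) group_stats(c(m - s / sqrt(2),
                                          m + s / sqrt(2)), ctx)
  labor <- gl(102674.63, 99319.32, "labor")
  nonlabor <- gl(6248.59, 3222.90, "non_labor")
  expect_equal(central_range_value(labor, nonlabor), -6116.18,
               tolerance = 1e-6)
  expect_error(central_range_value(nonlabor, labor), "context")
  same <- group_stats(rep(3, 3), "labor")
  same_nl <- group_stats(rep(3, 3), "non_labor")
  expect_equal(central_range_value(same, same_nl), 0)
  shifted <- gl(102674.63 + 250, 99319.32, "labor")
  expect_equal(central_range_value(shifted, nonlabor),
               -6116.18 + 250, tolerance = 1e-6)
})

test_that("window selection over the published moments picks the 10-min window", {
  sel <- select_window(published_window_moments())
  expect_identical(sel$chosen, 10)
  expect_equal(sel$crv, 1690.49, tolerance = 0.02)
  tab <- sel$table
  expect_equal(tab$msl[tab$window_min == 10], 9642.25, tolerance = 1e-6)
  expect_equal(tab$msl[tab$window_min == 12], 3355.31, tolerance = 1e-6)
  expect_equal(tab$msnl[tab$window_min == 12], 9471.49, tolerance = 1e-6)
  expect_equal(tab$crv[tab$window_min == 12], -6116.18, tolerance = 1e-6)
  # cells with +/-0.01 printing inconsistencies, checked at 0.02
  expect_equal(tab$msnl[tab$window_min == 8], 5332.18, tolerance = 0.02)
  expect_equal(tab$msl[tab$window_min == 14], 5221.60, tolerance = 0.02)
  # permutation invariance and tie-break toward the shorter window
  perm <- published_window_moments()[c(3, 1, 4, 2), ]
  expect_identical(select_window(perm)$chosen, 10)
  tie <- data.frame(window_min = c(12, 8), labor_mean = c(10, 10),
                    labor_sd = c(1, 1), nonlabor_mean = c(2, 2),
                    nonlabor_sd = c(1, 1))
  expect_identical(select_window(tie)$chosen, 8)
  expect_error(select_window(tie[0, ]), "no candidate")
})

test_that("the three-sigma threshold reproduces the published value and scales", {
  m <- 4807.18; s <- 3144.58
  pool <- c(m - s / sqrt(2), m + s / sqrt(2))
  expect_equal(lpi_threshold(pool), 14240.92, tolerance = 1e-9)
  expect_equal(tckg_from_moments(m, s), 14240.92)
  expect_equal(lpi_threshold(rep(9, 5)), 9)
  set.seed(3)
  v <- stats::rgamma(50, 2, 0.001)
  expect_equal(lpi_threshold(3 * v), 3 * lpi_threshold(v))
  expect_error(lpi_threshold(1), "at least 2")
})

test_that("the threshold recovers generating moments from a large window pool", {
  set.seed(12)
  mu <- 4800; sig <- 3100
  pool <- stats::rnorm(1000, mu, sig)
  expect_lt(abs(lpi_threshold(pool) - (mu + 3 * sig)) / (mu + 3 * sig), 0.05)
})

test_that("detection-to-birth offsets average as expected", {
  t0 <- as.POSIXct("2024-02-01 06:00:00", tz = "UTC")
  off <- mean_offset(c(t0, t0 + 3600), c(t0 + 3600, t0 + 2 * 3600))
  expect_equal(off$mdv, 60)
  same <- mean_offset(c(t0, t0), c(t0, t0))
  expect_equal(same$mdv, 0)
  expect_equal(same$sd, 0)
  # offsets of 60 and 120 min: mean 90, sd ~42.43
  off2 <- mean_offset(c(t0, t0), c(t0 + 60 * 60, t0 + 120 * 60))
  expect_equal(off2$mdv, 90)
  expect_equal(off2$sd, 42.43, tolerance = 1e-3)
  expect_warning(mean_offset(t0 + 60, t0), "after")
  expect_error(mean_offset(as.POSIXct(character(0)),
                           as.POSIXct(character(0))), "pairs")
})

test_that("normality and mean-difference validation behaves on known groups", {
  set.seed(8)
  a <- stats::rnorm(17, 0, 1)
  b <- stats::rnorm(17, 10, 1)
  v <- validate_groups(b, a)
  expect_true(v$significant)
  expect_lt(v$t$p.value, 1e-3)
  expect_true(v$normal)
  ident <- validate_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(ident$t$statistic), 0)
  expect_error(validate_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("herd calibration separates labor from non-labor and survives a round-trip", {
  herd <- small_herd()
  ds <- clean_samples(build_dataset(herd, make_label_intervals(herd),
                                    balance = TRUE, seed = 4L))
  clf <- train_labor_classifier(ds, "tree", seed = 4L)
  cal <- calibrate_herd(herd, clf, k = 20L)
  expect_s3_class(cal, "calibration")
  expect_true(cal$window_min %in% c(8, 10, 12, 14))
  expect_gt(cal$tckg, 0)
  expect_gt(cal$selection$crv, 0)  # labor clearly separates in simulation
  path <- withr::local_tempfile(fileext = ".dcf")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$window_min, cal$window_min)
  expect_equal(back$tckg, cal$tckg, tolerance = 1e-6)
})
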