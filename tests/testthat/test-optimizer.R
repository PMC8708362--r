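test_that("optimal diameter matches a fine brute-force grid scan", {
  cases <- list(list(x = 0, f = 500e3), list(x = 1, f = 100e3),
                list(x = 0.4, f = 250e3))
  for (cs in cases) {
    p <- material_properties(cs$x)
    bf <- oracle_argmax(p$K, p$Ms, p$rho, H = 20e3, f = cs$f, step = 1e-12)
    opt <- find_optimal_diameter(cs$x, 20e3, cs$f)
    expect_lt(abs(opt$D_M - bf$D), 2e-12)           # |dD| <= 2e-3 nm
    expect_equal(opt$PsM, bf$Ps, tolerance = 1e-6)
  }
})

test_that("reported optimum re-evaluates exactly through the loss-power model", {
  opt <- find_optimal_diameter(0.2, 20e3, 250e3)
  expect_identical(opt$PsM,
                   specific_loss_power(0.2, opt$D_M, 20e3, 250e3)$Ps)
  expect_false(opt$boundary)
  expect_gt(opt$D_M, 1e-9); expect_lt(opt$D_M, 20e-9)
  td <- tidy(opt)
  expect_equal(td$D_M, opt$D_M)
  expect_equal(glance(opt)$D_M_nm, opt$D_M * 1e9)
})

test_that("loss-power peak is sharp: +/-30% in diameter halves the power", {
  for (xv in anchor_x) {
    opt <- find_optimal_diameter(xv, 20e3, 500e3)
    side <- specific_loss_power(xv, opt$D_M * c(0.7, 1.3), 20e3, 500e3)$Ps
    expect_true(all(side < 0.5 * opt$PsM))
  }
})

test_that("maximum power grows with frequency at every composition", {
  tab <- psm_vs_x(anchor_x, H = 20e3, f = c(100e3, 250e3, 500e3))
  ordered <- tab |>
    dplyr::arrange(x, f) |>
    dplyr::group_by(x) |>
    dplyr::summarise(inc = all(diff(PsM) > 0), .groups = "drop")
  expect_true(all(ordered$inc))
  # and the composition minimum sits at x = 0.8 for each frequency
  mins <- tab |>
    dplyr::group_by(f) |>
    dplyr::slice(which.min(PsM))
  expect_true(all(mins$x == 0.8))
})

test_that("optimal diameter shrinks with frequency", {
  dm <- dm_vs_frequency(c(0, 0.2, 1), f = c(100e3, 250e3, 500e3), H = 20e3)
  dec <- dm |>
    dplyr::arrange(x, f) |>
    dplyr::group_by(x) |>
    dplyr::summarise(dec = all(diff(D_M) < 0), .groups = "drop")
  expect_true(all(dec$dec))
  # the single-cell value is the scalar optimizer's
  one <- dm[dm$x == 1 & dm$f == 250e3, ]
  expect_equal(one$D_M, find_optimal_diameter(1, 20e3, 250e3)$D_M)
})

test_that("surface grid agrees with scalar evaluation and flags bad grids", {
  surf <- ps_surface(0, D = 16.1e-9, f = 500e3, H = 20e3)
  expect_identical(nrow(surf), 1L)
  expect_equal(surf$Ps, specific_loss_power(0, 16.1e-9, 20e3, 500e3)$Ps)
  full <- ps_surface(0, D = seq(10, 20, 0.5) * 1e-9,
                     f = c(100e3, 250e3, 500e3), H = 20e3)
  expect_identical(nrow(full), 21L * 3L)
  # surface max increases with frequency
  mx <- tapply(full$Ps, full$f, max)
  expect_true(all(diff(mx) > 0))
  expect_error(ps_surface(0, D = numeric(0), f = 500e3, H = 20e3),
               class = "ferroheat_domain_error")
  expect_error(ps_surface(0, D = c(2e-9, 1e-9), f = 500e3, H = 20e3),
               class = "ferroheat_domain_error")
})

test_that("degenerate objectives and boundary optima are reported", {
  expect_error(find_optimal_diameter(0, H = 0, f = 500e3),
               "no interior maximum",
               class = "ferroheat_flat_objective_error")
  expect_error(find_optimal_diameter(0, H = 20e3, f = 0),
               class = "ferroheat_flat_objective_error")
  # peak for magnetite at 500 kHz lies near 16 nm; a 1-12 nm window clips it
  expect_warning(
    opt <- find_optimal_diameter(0, 20e3, 500e3, D_range = c(1e-9, 12e-9)),
    "boundary")
  expect_true(opt$boundary)
  expect_equal(opt$D_M, 12e-9)
})
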