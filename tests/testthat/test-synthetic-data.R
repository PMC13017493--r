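test_that("MAD layout places checks per the design and is reproducible", {
  lay <- generate_layout(9, block_shape = c(5, 5), seed = 42)
  expect_equal(nrow(lay), 225)
  expect_equal(sum(lay$role == "check1"), 9)

  # primary check at the central cell (2,2) of every 5x5 block
  c1 <- lay[lay$role == "check1", ]
  expect_true(all(c1$row %% 5 == 2 & c1$col %% 5 == 2))

  # each secondary check exactly once per block, never central
  for (r in c("check2a", "check2b")) {
    sec <- lay[lay$role == r, ]
    expect_equal(sort(sec$block), 1:9)
    expect_false(any(sec$row %% 5 == 2 & sec$col %% 5 == 2))
  }

  expect_false(any(duplicated(lay[, c("block", "row", "col")])))
  expect_setequal(unique(lay$role), c("test", "check1", "check2a", "check2b"))

  expect_identical(lay, generate_layout(9, block_shape = c(5, 5), seed = 42))
  expect_error(generate_layout(2, block_shape = c(4, 5)), "odd")
  expect_silent(generate_layout(1, seed = 1))
})

test_that("simulated trials follow the additive row/column model", {
  lay <- generate_layout(9, field_cols = 3, seed = 7)
  genos <- unique(lay$genotype)

  flat <- trial_truth(setNames(rep(0, length(genos)), genos), grand_mean = 10)
  expect_true(all(simulate_trial(lay, flat)$value == 10))

  # additivity: genotype effect 5 plus the top block-row effect -1 gives 4
  tr <- trial_truth(setNames(rep(5, length(genos)), genos),
                    row_effects = c(-1, 0, 1), col_effects = c(0, 0, 0))
  tab <- simulate_trial(lay, tr)
  expect_true(all(tab$value[tab$block_row == 0] == 4))
  expect_true(all(tab$value[tab$block_row == 2] == 6))

  bad <- trial_truth(c(P_check1 = 1), grand_mean = 0)
  expect_error(simulate_trial(lay, bad), "NIL_001")
})

test_that("primary-check sample mean concentrates around the trial mean", {
  lay <- generate_layout(10, field_cols = 5, seed = 3)
  genos <- unique(lay$genotype)
  truth <- trial_truth(setNames(rep(0, length(genos)), genos),
                       grand_mean = 10, noise_sd = 0.5)
  tab <- simulate_trial(lay, truth, seed = 11)
  c1 <- tab$value[tab$role == "check1"]
  se <- 0.5 / sqrt(length(c1))
  expect_lt(abs(mean(c1) - 10), 3 * se)
})

test_that("time-course simulation evaluates the stated families", {
  lay <- generate_layout(1, seed = 1)
  days <- seq(25, 95, length.out = 10)
  cp <- curve_params("logistic", asymptote = 100, midpoint = 38, rate = 0.25)
  sim <- simulate_timecourse(lay, cp, days, trait = "CC", seed = 5)

  expect_equal(nrow(sim$series), 25 * 10)
  expect_equal(sum(sim$series$plot_id == sim$series$plot_id[1]), 10)
  expect_equal(eval_curve(cp, 38), 50) # sigmoid midpoint is half the asymptote

  sim2 <- simulate_timecourse(lay, cp, days, trait = "CC", seed = 5)
  expect_identical(sim$series, sim2$series)

  expect_error(simulate_timecourse(lay, cp, numeric(0)), "non-empty")
  expect_error(simulate_timecourse(lay, cp, c(30, 30, 40)), "increasing")

  rpd <- curve_params("rise-plateau-decline", asymptote = 0.9, midpoint = 45,
                      rate = 0.25, decline_onset_day = 80, decline_rate = 0.03)
  expect_equal(eval_curve(rpd, 90), eval_curve(curve_params("logistic",
    asymptote = 0.9, midpoint = 45, rate = 0.25), 90) - 0.03 * 10)
})

test_that("synthetic plot images hit the requested coverage with separable classes", {
  all_soil <- simulate_plot_image(0, c(20, 20), seed = 1)
  expect_false(any(all_soil$mask))

  im <- simulate_plot_image(0.635, c(100, 100), seed = 2)
  expect_equal(sum(im$mask), 6350)
  expect_equal(dim(im$image), c(100, 100, 4))
  expect_true(all(im$image >= 0 & im$image <= 1))

  exg <- excess_green(im$image)
  expect_true(all(exg[im$mask] > 0))   # vegetation pixels green-dominant
  expect_true(all(exg[!im$mask] <= 0)) # soil pixels not
  nd <- ndvi(im$image)
  expect_true(all(nd[im$mask] > 0.3) && all(nd[!im$mask] < 0))

  expect_error(simulate_plot_image(0.5, c(0, 10)), "positive")
  expect_error(simulate_plot_image(1.2), "coverage_fraction")
})

test_that("point clouds fill the requested box at the requested density", {
  cl <- simulate_point_cloud(c(2, 1), 0.5, 1e4, seed = 9)
  expect_equal(nrow(cl), round(1e4 * 2 * 1 * 0.5))
  expect_true(all(cl$x >= 0 & cl$x <= 2))
  expect_true(all(cl$y >= 0 & cl$y <= 1))
  expect_true(all(cl$z >= 0 & cl$z <= 0.5))
  expect_equal(attr(cl, "area_m2"), 2)

  expect_equal(nrow(simulate_point_cloud(c(1, 1), 0, 100)), 0)
  expect_error(simulate_point_cloud(c(1, 1), 1, 0), "positive")
})

test_that("simulated A-Ci curves follow the FvCB forward model", {
  curve <- simulate_aci_curve(vcmax = 100, j = 180, rd = 1.5)
  expect_equal(nrow(curve), 14)
  expect_equal(curve$ci, aci_setpoints())

  # at the compensation point net assimilation equals -Rd
  gs <- bernacchi_kinetics()$gamma_star25
  at_gs <- simulate_aci_curve(vcmax = 100, j = 180, rd = 1.5,
                              ci_setpoints = gs)
  expect_equal(at_gs$a, -1.5, tolerance = 1e-12)

  expect_error(simulate_aci_curve(100, 180, 1.5, ci_setpoints = c(400, -5)),
               "positive")
  expect_identical(simulate_aci_curve(100, 180, 1.5, noise_sd = 0.5, seed = 3),
                   simulate_aci_curve(100, 180, 1.5, noise_sd = 0.5, seed = 3))
})

test_that("leaf-ratio generator is a bimodal mixture with the stated means", {
  lr <- simulate_leaf_ratio(4000, seed = 21)
  broad <- lr$leaf_ratio[lr$leaf_shape == "broad"]
  narrow <- lr$leaf_ratio[lr$leaf_shape == "narrow"]
  expect_lt(abs(mean(broad) - 1.3), 3 * 0.15 / sqrt(length(broad)))
  expect_lt(abs(mean(narrow) - 2.4), 3 * 0.15 / sqrt(length(narrow)))
  expect_identical(lr, simulate_leaf_ratio(4000, seed = 21))
})
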