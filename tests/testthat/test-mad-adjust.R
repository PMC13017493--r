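test_that("a spatially flat primary check leaves Method I an identity", {
  tab <- random_small_trial(1)
  tab$value[tab$role == "check1"] <- 10
  adj <- method1_adjust(tab)
  expect_equal(adj$value_adj, adj$value)
  fit <- attr(adj, "fit")
  expect_equal(fit$grand_mean, 10)
})

test_that("Method I cancels additive block-grid gradients exactly", {
  lay <- generate_layout(9, field_cols = 3, seed = 2)
  genos <- unique(lay$genotype)
  truth <- trial_truth(
    setNames(rnorm(length(genos)), genos),
    row_effects = c(-1, 0.5, 0.5), col_effects = c(2, -1, -1),
    grand_mean = 10
  )
  tab <- simulate_trial(lay, truth)
  adj <- method1_adjust(tab)
  # every adjusted value collapses to grand mean + genotype effect
  expected <- 10 + unname(truth$genotype_effects[adj$genotype])
  expect_equal(adj$value_adj, expected, tolerance = 1e-12)

  # replicated genotypes (checks) have zero variance after adjustment
  reps <- tapply(adj$value_adj, adj$genotype, var)
  expect_lt(max(reps[!is.na(reps)]), 1e-18)
})

test_that("a single block-row field reduces Method I to column centering", {
  lay <- generate_layout(5, field_cols = 5, seed = 3)
  genos <- unique(lay$genotype)
  truth <- trial_truth(setNames(rep(0, length(genos)), genos),
                       col_effects = c(2, 1, 0, -1, -2), grand_mean = 10)
  tab <- simulate_trial(lay, truth)
  adj <- method1_adjust(tab)
  fit <- attr(adj, "fit")
  expect_equal(nrow(fit$row_means), 1)     # R_i constant
  expect_equal(length(unique(fit$col_means$c)), 5) # C_j varies
  expect_equal(adj$value_adj, rep(10, nrow(adj)), tolerance = 1e-12)
})

test_that("Method III recovers an exact linear check relationship", {
  # check1_b = 2 * check2avg_b + 1 across 5 blocks
  lay <- generate_layout(5, field_cols = 5, seed = 4)
  tab <- lay
  tab$value <- 0
  for (b in 1:5) {
    tab$value[tab$block == b & tab$role == "check2a"] <- b - 0.5
    tab$value[tab$block == b & tab$role == "check2b"] <- b + 0.5
    tab$value[tab$block == b & tab$role == "check1"] <- 2 * b + 1
  }
  adj <- method3_adjust(tab)
  fit <- attr(adj, "fit")
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_equal(fit$alpha, 1, tolerance = 1e-12)

  # per-block reference with perfectly agreeing checks: identity
  tab2 <- tab
  for (b in 1:5) {
    tab2$value[tab2$block == b & tab2$role %in% c("check2a", "check2b")] <- b
    tab2$value[tab2$block == b & tab2$role == "check1"] <- b
  }
  adj2 <- method3_adjust(tab2, check2_reference = "block")
  expect_equal(attr(adj2, "fit")$beta, 1, tolerance = 1e-12)
  expect_equal(attr(adj2, "fit")$alpha, 0, tolerance = 1e-12)
  expect_equal(adj2$value_adj, adj2$value, tolerance = 1e-12)

  # constant secondary-check averages leave the slope undefined
  tab3 <- tab
  tab3$value[startsWith(tab3$role, "check2")] <- 5
  expect_error(method3_adjust(tab3), class = "canopytrial_method3_unavailable")
  expect_error(method3_adjust(tab[tab$block <= 2, ]),
               class = "canopytrial_method3_unavailable")
})

test_that("intra-whole-plot error matches the pooled-deviation formula", {
  mk <- function(roles, blocks, values) {
    tibble::tibble(block = blocks, block_row = 0, block_col = blocks,
                   role = roles, value = values)
  }
  # check A {1,2,3} (SS 2), check B {2,4} (SS 2): (2+2)/(2*3)
  tab <- mk(c("check1", "check2a", "check2a", "check2a", "check2b", "check2b"),
            c(1, 1, 2, 3, 1, 2), c(0, 1, 2, 3, 2, 4))
  expect_equal(iwp_error(tab), 4 / 6, tolerance = 1e-12)

  # both checks constant: zero error
  tabc <- mk(c("check1", "check2a", "check2a", "check2b", "check2b"),
             c(1, 1, 2, 1, 2), c(0, 7, 7, 3, 3))
  expect_equal(iwp_error(tabc), 0)

  # one block per check: no degrees of freedom
  tab1 <- mk(c("check1", "check2a", "check2b"), c(1, 1, 1), c(0, 1, 2))
  expect_error(iwp_error(tab1), "too few blocks")
})

test_that("relative efficiency is the 100-scale error ratio with edge conventions", {
  expect_equal(relative_efficiency(0.5, 0.5), 100)
  expect_equal(relative_efficiency(0.6667, 0.33335), 200, tolerance = 1e-4)
  expect_lt(relative_efficiency(1, 2), 100)
  expect_equal(relative_efficiency(0, 0), 100)
  expect_warning(re <- relative_efficiency(1, 0), "infinite")
  expect_identical(re, Inf)
})

test_that("the three-rule criterion is reproduced on constructed RE pairs", {
  expect_equal(choose_adjustment_method(95, 80), "none")
  expect_equal(choose_adjustment_method(99.9, 99.9), "none")
  expect_equal(choose_adjustment_method(90, 130), "method3")
  expect_equal(choose_adjustment_method(130, 90), "method1")
  expect_equal(choose_adjustment_method(140, 120), "method1")
  expect_equal(choose_adjustment_method(120, 140), "method3")
  expect_equal(choose_adjustment_method(120, 120), "method1") # tie
  expect_equal(choose_adjustment_method(95, NA), "none")
  expect_equal(choose_adjustment_method(130, NA), "method1")
})

test_that("adjustments and IWP error match brute-force recomputation", {
  for (seed in 1:15) {
    tab <- random_small_trial(seed)
    m1 <- method1_adjust(tab)
    expect_equal(m1$value_adj, oracle_method1(tab), tolerance = 1e-9)
    m3 <- method3_adjust(tab)
    o3 <- oracle_method3(tab)
    expect_equal(m3$value_adj, o3$adjusted, tolerance = 1e-9)
    expect_equal(attr(m3, "fit")$beta, o3$beta, tolerance = 1e-9)
    expect_equal(iwp_error(tab), oracle_iwp(tab), tolerance = 1e-9)
    expect_equal(iwp_error(m1, "value_adj"), oracle_iwp(m1, "value_adj"),
                 tolerance = 1e-9)
  }
})

test_that("relative efficiency is invariant to trait rescaling", {
  tab <- random_small_trial(99)
  dec <- select_adjustment(tab)
  tab2 <- dplyr::mutate(tab, value = value * 3.7)
  dec2 <- select_adjustment(tab2)
  expect_equal(dec2$re, dec$re, tolerance = 1e-9)
  expect_identical(dec2$chosen, dec$chosen)
})

test_that("Method I preserves the mean on a balanced flat-check field", {
  tab <- random_small_trial(5, noise_sd = 0.4, gradient_sd = 0)
  tab$value[tab$role == "check1"] <- 12 # all row/col means equal mu
  adj <- method1_adjust(tab)
  expect_equal(mean(adj$value_adj), mean(adj$value), tolerance = 1e-12)
})

test_that("multi-stratum trials are adjusted independently per stratum", {
  t1 <- random_small_trial(31)
  t2 <- random_small_trial(32)
  t2$location <- "EF"
  both <- dplyr::bind_rows(t1, t2)
  res <- adjust_trial(both)
  expect_equal(nrow(res$decisions), 2)
  expect_equal(nrow(res$table), nrow(both))

  solo <- select_adjustment(t1)
  in_res <- res$table[res$table$location == "SF", ]
  expect_equal(sort(in_res$value_adj), sort(solo$table$value_adj),
               tolerance = 1e-12)
  expect_true(all(c("re_method1", "re_method3", "chosen") %in%
                    names(res$decisions)))
})
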