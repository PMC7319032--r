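# Linkage of lateralization to behavior.

test_that("Holm correction reproduces step-down arithmetic", {
  # sorted (0.01, 0.03, 0.04) x (3, 2, 1) = (0.03, 0.06, 0.04),
  # monotone max -> (0.03, 0.06, 0.06)
  expect_equal(holm_correct(c(0.01, 0.04, 0.03))$adjusted, c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(0.2)$adjusted, 0.2)
  expect_equal(holm_correct(rep(1, 4))$adjusted, rep(1, 4))
  expect_error(holm_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  # never exceeds Bonferroni, never below raw
  set.seed(1)
  p <- runif(6)
  hc <- holm_correct(p)
  expect_true(all(hc$adjusted <= pmin(1, length(p) * p) + 1e-12))
  expect_true(all(hc$adjusted >= p))
})

# trials table with group labels, identical generating parameters everywhere
grouped_trials_fixture <- function(n_participants = 4, n_per_cell = 40,
                                   kappa = c(cued = 18, `non-cued` = 18),
                                   seed = 2) {
  set.seed(seed)
  groups <- c("consistent-strong", "consistent-moderate",
              "inconsistent-moderate", "inconsistent-strong")
  do.call(rbind, lapply(seq_len(n_participants), function(pid) {
    do.call(rbind, lapply(c("cued", "non-cued"), function(cn) {
      do.call(rbind, lapply(groups, function(g) {
        data.frame(participant_id = pid, condition = cn, group = g,
                   signed_error = rmixture(n_per_cell, kappa[[cn]], 0.4, 0.02))
      }))
    }))
  }))
}

test_that("fit_by_group fits every cell and flags small ones", {
  tr <- grouped_trials_fixture()
  gf <- fit_by_group(tr, min_trials = 30)
  expect_equal(nrow(gf), 4 * 2 * 4)
  expect_true(all(!gf$flagged))
  expect_true(all(is.finite(gf$kappa)))
  # a below-threshold cell is flagged but still fitted
  idx <- which(tr$participant_id == 1 & tr$group == "consistent-strong" &
                 tr$condition == "cued")
  gf2 <- fit_by_group(tr[-idx[1:15], ], min_trials = 30)
  small_row <- gf2[gf2$participant_id == 1 & gf2$lat_group == "consistent-strong" &
                     gf2$cue == "cued", ]
  expect_true(small_row$flagged)
  expect_equal(small_row$n_trials, 25)
  expect_true(is.finite(small_row$kappa))
})

test_that("collapsing the grouping reproduces per-condition fits", {
  tr <- grouped_trials_fixture(n_participants = 2, n_per_cell = 30)
  tr_all <- tr
  tr_all$group <- "all"
  gf <- fit_by_group(tr_all, min_trials = 30)
  bf <- fit_behavior(tr)
  ord_g <- order(gf$participant_id, gf$cue)
  ord_b <- order(bf$participant_id, bf$condition)
  expect_equal(gf$kappa[ord_g], bf$kappa[ord_b], tolerance = 1e-6)
  expect_equal(gf$g[ord_g], bf$g[ord_b], tolerance = 1e-6)
})

test_that("mixed model reduces to the paired t-test for a 2-level design", {
  set.seed(4)
  n <- 12
  fits <- data.frame(participant_id = rep(1:n, 2),
                     cue = rep(c("cued", "non-cued"), each = n),
                     kappa = c(rnorm(n, 20, 3), rnorm(n, 16, 3)))
  fits$lat_group <- "all" # single level: model falls back to cue only
  mm <- mixed_model_interface(fits, parameters = "kappa")
  tt <- t.test(fits$kappa[fits$cue == "cued"], fits$kappa[fits$cue == "non-cued"],
               paired = TRUE)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$p, tt$p.value, tolerance = 1e-6)
  expect_equal(mm$F, unname(tt$statistic)^2, tolerance = 1e-6)
})

test_that("mixed model rejects degenerate input", {
  tr <- grouped_trials_fixture(n_participants = 3, n_per_cell = 30)
  gf <- fit_by_group(tr)
  gf$kappa <- 5
  expect_error(mixed_model_interface(gf, parameters = "kappa"), "constant")
  one_cue <- gf[gf$cue == "cued", ]
  one_cue$kappa <- rnorm(nrow(one_cue), 20)
  expect_error(mixed_model_interface(one_cue, parameters = "kappa"),
               "both cue conditions")
})

test_that("factorial mixed model returns Holm-corrected effects per parameter", {
  tr <- grouped_trials_fixture(n_participants = 6, n_per_cell = 40,
                               kappa = c(cued = 22, `non-cued` = 15), seed = 6)
  gf <- fit_by_group(tr)
  mm <- mixed_model_interface(gf)
  expect_setequal(unique(mm$parameter), c("kappa", "g", "mu"))
  expect_setequal(unique(mm$effect),
                  c("cue", "lateralization", "cue x lateralization"))
  expect_true(all(mm$p_holm >= mm$p - 1e-12))
  # the built-in cue effect on kappa is detected
  expect_lt(mm$p_holm[mm$parameter == "kappa" & mm$effect == "cue"], 0.05)
})

test_that("accuracy-benefit correlation behaves on closed-form cases", {
  acc <- seq(0.5, 0.9, length.out = 10)
  expect_equal(accuracy_benefit_correlation(acc, 2 * acc)$r, 1, tolerance = 1e-12)
  r_neg <- accuracy_benefit_correlation(acc, -3 * acc + rnorm(10, 0, 1e-6))$r
  expect_lt(r_neg, 0)
  expect_error(accuracy_benefit_correlation(acc[1:3], acc[1:3]), "at least 5")
  expect_error(accuracy_benefit_correlation(rep(0.5, 10), 2 * acc), "zero variance")
})
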