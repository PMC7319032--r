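# Single-trial template-correlation classification.

test_that("template is the left minus right mean topography", {
  topo <- rbind(matrix(1, 3, 4), matrix(-1, 3, 4))
  sides <- rep(c("left", "right"), each = 3)
  expect_equal(compute_template(topo, sides), rep(2, 4))
  expect_equal(compute_template(rbind(topo, topo), rep(sides, 2)), rep(2, 4))
  expect_error(compute_template(matrix(rnorm(8), 2, 4), c("left", "left")),
               "both cue sides")
})

test_that("trial correlations behave as Pearson correlations", {
  set.seed(1)
  tmpl <- rnorm(16)
  topo <- rbind(tmpl, -tmpl, 2 * tmpl + 5)
  r <- correlate_trials(topo, tmpl)
  expect_equal(r, c(1, -1, 1), tolerance = 1e-12)
  expect_error(correlate_trials(topo, rep(1, 16)), "constant")
  expect_warning(r2 <- correlate_trials(rbind(tmpl, rep(0, 16)), tmpl), "constant")
  expect_true(is.na(r2[2]))
})

test_that("AUC equals the Mann-Whitney U statistic identity", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (i in 1:5) {
    r <- rnorm(60)
    sides <- sample(c("left", "right"), 60, replace = TRUE,
                    prob = c(0.5, 0.5))
    if (length(unique(sides)) < 2) next
    roc <- roc_optimal_cutoff(r, sides)
    w <- wilcox.test(r[sides == "left"], r[sides == "right"], exact = FALSE)
    u_auc <- unname(w$statistic) / (sum(sides == "left") * sum(sides == "right"))
    expect_equal(roc$auc, u_auc, tolerance = 1e-10)
    # second independent route
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = sides, predictor = r, levels = c("right", "left"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc$auc, proc_auc, tolerance = 1e-10)
  }
})

test_that("perfect separation gives AUC 1 and accuracy 1 at the cutoff", {
  r <- c(rnorm(20, 3, 0.2), rnorm(20, -3, 0.2))
  sides <- rep(c("left", "right"), each = 20)
  roc <- roc_optimal_cutoff(r, sides)
  expect_equal(roc$auc, 1)
  cls <- classify_trials(r, roc$cutoff, sides)
  expect_equal(cls$accuracy, 1)
  expect_true(all(cls$consistency == "consistent"))
})

test_that("degenerate identical correlations are flagged with AUC 1/2", {
  roc <- roc_optimal_cutoff(rep(0.3, 20), rep(c("left", "right"), 10))
  expect_equal(roc$auc, 0.5)
  expect_true(roc$degenerate)
  expect_error(roc_optimal_cutoff(rnorm(5), rep("left", 5)), "both classes")
})

test_that("permutation p-value follows the corrected formula at the extremes", {
  expect_equal(retrolat:::perm_p(0, 1000), 1 / 1001)
  expect_equal(retrolat:::perm_p(1000, 1000), 1)
  expect_equal(retrolat:::perm_p(500, 1000), 501 / 1001)
  # perfectly separated data: no permutation can exceed accuracy 1
  set.seed(3)
  r <- c(rnorm(24, 2, 0.1), rnorm(24, -2, 0.1))
  sides <- rep(c("left", "right"), each = 24)
  pv <- permutation_pvalue(1, r, sides, n_tot = 1000, seed = 4)
  expect_equal(pv$p, 1 / 1001)
  expect_equal(pv$n_k, 0)
})

test_that("label-independent correlations give chance-level classification", {
  set.seed(5)
  r <- rnorm(1000)
  sides <- sample(rep(c("left", "right"), 500))
  roc <- roc_optimal_cutoff(r, sides)
  cls <- classify_trials(r, roc$cutoff, sides)
  # cutoff optimization keeps accuracy at or above 0.5 by construction,
  # but not significantly above the permutation null
  expect_gte(cls$accuracy, 0.5)
  pv <- permutation_pvalue(cls$accuracy, r, sides, n_tot = 200, seed = 6)
  expect_gt(pv$p, 0.05)
})

test_that("classification is invariant to side relabeling and positive scaling", {
  set.seed(7)
  n <- 40
  topo <- matrix(rnorm(n * 12), n, 12)
  sides <- rep(c("left", "right"), n / 2)
  topo[sides == "left", 1:4] <- topo[sides == "left", 1:4] + 1
  c0 <- classify_lateralization(topo, sides, n_perm = 150, seed = 8)
  # global left/right relabeling: template and correlations negate,
  # accuracy and p unchanged
  flipped <- ifelse(sides == "left", "right", "left")
  c1 <- classify_lateralization(topo, flipped, n_perm = 150, seed = 8)
  expect_equal(c1$template, -c0$template, tolerance = 1e-12)
  expect_equal(c1$trial_r, -c0$trial_r, tolerance = 1e-12)
  expect_equal(c1$accuracy, c0$accuracy)
  expect_equal(c1$p, c0$p)
  # positive scaling changes nothing downstream of the correlations
  c2 <- classify_lateralization(5 * topo, sides, n_perm = 150, seed = 8)
  expect_equal(c2$trial_r, c0$trial_r, tolerance = 1e-12)
  expect_equal(c2$accuracy, c0$accuracy)
  expect_equal(c2$predicted_side, c0$predicted_side)
  expect_equal(c2$p, c0$p)
})

test_that("four-way grouping splits each consistency set at its median", {
  set.seed(9)
  r <- runif(100, -1, 1) # distinct |r| almost surely
  cons <- rep("consistent", 100)
  g <- group_trials(r, cons)
  expect_equal(sum(g$strength == "strong"), 50)
  expect_equal(sum(g$strength == "moderate"), 50)
  # ties at the median are strong
  g_tie <- group_trials(rep(0.4, 10), rep("inconsistent", 10))
  expect_true(all(g_tie$strength == "strong"))
  expect_true(all(g_tie$group == "inconsistent-strong"))
  # groups partition all classified trials
  mixed <- group_trials(r, sample(c("consistent", "inconsistent"), 100, TRUE))
  expect_equal(sum(table(mixed$group)), 100)
  expect_true(all(names(table(mixed$group)) %in%
                  c("consistent-strong", "consistent-moderate",
                    "inconsistent-strong", "inconsistent-moderate")))
})

test_that("leave-one-out mode removes the self-inclusion bias direction", {
  set.seed(10)
  topo <- matrix(rnorm(30 * 8), 30, 8)
  sides <- rep(c("left", "right"), 15)
  c_in <- classify_lateralization(topo, sides, n_perm = 0)
  c_loo <- classify_lateralization(topo, sides, n_perm = 0, leave_one_out = TRUE)
  # with pure noise, the self-included template inflates |r| on average
  expect_gt(mean(c_in$trial_r * ifelse(sides == "left", 1, -1)),
            mean(c_loo$trial_r * ifelse(sides == "left", 1, -1)))
})
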