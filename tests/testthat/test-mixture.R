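# Maximum-likelihood mixture fitting.

test_that("fit_mixture recovers generating parameters", {
  set.seed(101)
  x <- rmixture(576, kappa = 20, mu = 0.5, g = 0.02)
  f <- fit_mixture(x)
  expect_s3_class(f, "mixture_fit")
  expect_true(f$converged)
  expect_equal(f$kappa, 20, tolerance = 0.25)
  expect_equal(f$g, 0.02, tolerance = 0.05)
  expect_lt(abs(f$mu - 0.5), 3)
  # MLE dominance: fitted loglik beats the generating parameters
  ll_gen <- sum(mixture_pdf(x, 20, 0.5, 0.02, log = TRUE))
  expect_gte(f$loglik, ll_gen)
})

test_that("fit on uniform errors collapses to the guessing boundary", {
  set.seed(7)
  f <- fit_mixture(runif(576, -180, 180))
  expect_gte(f$g, 0.9)
  expect_true("kappa_unidentifiable" %in% f$boundary)
})

test_that("fit rejects too-few trials", {
  expect_error(fit_mixture(numeric(0)), "at least")
  expect_error(fit_mixture(rnorm(10)), "at least")
})

test_that("fit is invariant to 360-degree wrapping of the input", {
  set.seed(21)
  x <- rmixture(200, kappa = 10, mu = -3, g = 0.1)
  f1 <- fit_mixture(x)
  f2 <- fit_mixture(x + 360 * sample(c(-2, 0, 1, 3), 200, replace = TRUE))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("simulator is the exact inverse of the density (likelihood dominance)", {
  set.seed(31)
  kappa <- 20; mu <- 5; g <- 0.1
  x <- rmixture(10000, kappa, mu, g)
  ll_true <- mean(mixture_pdf(x, kappa, mu, g, log = TRUE))
  perturbed <- rbind(
    c(kappa * 0.5, mu, g), c(kappa * 1.5, mu, g),
    c(kappa, mu, min(1, g + 0.2)), c(kappa, mu, max(0, g - 0.2)),
    c(kappa, mu + 10, g), c(kappa, mu - 10, g)
  )
  for (i in seq_len(nrow(perturbed))) {
    p <- perturbed[i, ]
    # skip perturbations identical to the truth (g - 0.2 clipped at 0 is not)
    if (all(p == c(kappa, mu, g))) next
    expect_gt(ll_true, mean(mixture_pdf(x, p[1], p[2], p[3], log = TRUE)))
  }
})

test_that("mixture_fit methods are coherent", {
  set.seed(41)
  f <- fit_mixture(rmixture(300, 15, 0, 0.05))
  expect_named(coef(f), c("kappa", "mu", "g"))
  expect_equal(as.numeric(logLik(f)), f$loglik)
  expect_length(simulate(f, nsim = 50, seed = 1), 50)
  # simulate with a seed is reproducible and does not disturb the global RNG
  s1 <- simulate(f, nsim = 20, seed = 9)
  s2 <- simulate(f, nsim = 20, seed = 9)
  expect_identical(s1, s2)
  dens <- predict(f, c(-10, 0, 10))
  expect_true(all(dens > 0))
  expect_output(print(f), "kappa")
})

test_that("condition_contrast handles identical fits and degenerate input", {
  fits <- data.frame(participant_id = rep(1:5, 2),
                     condition = rep(c("cued", "non-cued"), each = 5),
                     kappa = rep(20, 10), mu = rep(0.4, 10), g = rep(0.02, 10))
  ct <- condition_contrast(fits)
  expect_equal(ct$mean_diff, rep(0, 3))
  expect_equal(ct$p, rep(1, 3))
  one <- fits[fits$participant_id == 1, ]
  expect_error(condition_contrast(one), "at least 2")
  expect_error(condition_contrast(fits[-1, ]), "both conditions")
})

test_that("cued precision advantage is detected across replicate studies", {
  # positive control: kappa 20 vs 15, 39 participants, modest trials per cell
  n_sig <- 0
  for (rep_i in 1:20) {
    set.seed(500 + rep_i)
    fits <- do.call(rbind, lapply(1:39, function(pid) {
      data.frame(participant_id = pid,
                 condition = c("cued", "non-cued"),
                 kappa = c(fit_mixture(rmixture(144, 20, 0.5, 0.02))$kappa,
                           fit_mixture(rmixture(144, 15, 0.5, 0.02))$kappa),
                 mu = 0, g = 0)
    }))
    ct <- condition_contrast(fits)
    k <- ct[ct$parameter == "kappa", ]
    if (k$mean_diff > 0 && k$p_holm < 0.05) n_sig <- n_sig + 1
  }
  expect_gte(n_sig, 18)
})
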