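# Maximum-likelihood fitting of the bias-extended standard mixture model.

#' Fit the standard mixture model with bias to signed errors
#'
#' Fits the three-parameter mixture of a von Mises memory component
#' (concentration `kappa`, bias `mu` in degrees toward the distractor) and a
#' uniform guessing component (probability `g`) to a vector of signed response
#' errors, by maximum likelihood. The negative log-likelihood is minimized with
#' bounded quasi-Newton (`L-BFGS-B`) from a fixed grid of start values; the
#' best converged start is returned.
#'
#' Input errors are wrapped into (-180, 180] first, so the fit is invariant to
#' adding multiples of 360 to any error. Parameter bounds are
#' `kappa` in (1e-3, 200], `g` in [0, 1], `mu` in [-180, 180]; estimates on a
#' bound are flagged in `$boundary`.
#'
#' @param errors numeric vector of signed errors in degrees.
#' @param min_n minimum number of errors required for a fit (default 20).
#' @param kappa_max upper bound for the concentration parameter.
#' @param n_starts number of multi-start initializations (default 8, drawn
#'   deterministically from a kappa x g x mu grid).
#' @return an object of class `"mixture_fit"`: a list with elements
#'   `kappa`, `mu`, `g`, `loglik`, `n`, `converged`, `n_starts_used`,
#'   `boundary` (character vector of parameters on a bound), and `errors`.
#' @examples
#' set.seed(1)
#' x <- c(rvonmises_deg(500, mu = 2, kappa = 15), runif(20, -180, 180))
#' fit <- fit_mixture(x)
#' coef(fit)
#' @seealso [mixture_pdf()], [condition_contrast()]
#' @export
fit_mixture <- function(errors, min_n = 20, kappa_max = 200, n_starts = 8) {
  errors <- errors[!is.na(errors)]
  if (length(errors) < min_n) {
    stop(sprintf("fit_mixture(): %d errors supplied, need at least %d", length(errors), min_n))
  }
  x <- wrap180(errors)

  negll <- function(p) {
    -sum(mixture_pdf(x, kappa = p[1], mu = p[2], g = p[3], log = TRUE))
  }

  lower <- c(1e-3, -180, 0)
  upper <- c(kappa_max, 180, 1)
  starts <- expand.grid(kappa = c(2, 10, 40), g = c(0.05, 0.3), mu = 0)
  starts <- rbind(starts, data.frame(kappa = 10, g = 0.05, mu = c(-10, 10)))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]

  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    n_used <- n_used + 1L
    opt <- tryCatch(
      stats::optim(
        par = c(starts$kappa[i], starts$mu[i], starts$g[i]),
        fn = negll, method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 1e2, maxit = 500,
                       parscale = c(10, 10, 0.1))
      ),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
  }
  if (is.null(best)) {
    return(structure(
      list(kappa = NA_real_, mu = NA_real_, g = NA_real_, loglik = NA_real_,
           n = length(x), converged = FALSE, n_starts_used = n_used,
           boundary = character(0), errors = x),
      class = "mixture_fit"
    ))
  }

  # polish: refitting from the optimum must not improve loglik materially
  polish <- stats::optim(best$par, negll, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(factr = 1e2, maxit = 500,
                                        parscale = c(10, 10, 0.1)))
  if (polish$value < best$value) best <- polish

  p <- best$par
  # Unidentifiable ridge: for near-uniform data only the product (1-g)*kappa
  # is determined and g is arbitrary along it. If BIC prefers the zero-
  # parameter pure-guessing model, report the canonical boundary solution
  # (g = 1, kappa at its lower bound, flagged) instead of an arbitrary ridge
  # point.
  ll_unif <- -length(x) * log(360)
  if ((-best$value - ll_unif) < 1.5 * log(length(x))) {
    return(structure(
      list(kappa = lower[1], mu = 0, g = 1, loglik = ll_unif,
           n = length(x), converged = TRUE, n_starts_used = n_used,
           boundary = c("kappa_unidentifiable", "g_max"), errors = x),
      class = "mixture_fit"
    ))
  }
  boundary <- character(0)
  if (p[1] >= kappa_max - 1e-6) boundary <- c(boundary, "kappa_max")
  if (p[1] <= 1e-3 + 1e-9) boundary <- c(boundary, "kappa_min")
  if (p[3] >= 1 - 1e-9) boundary <- c(boundary, "g_max")

  structure(
    list(kappa = p[1], mu = wrap180(p[2]), g = p[3], loglik = -best$value,
         n = length(x), converged = best$convergence == 0,
         n_starts_used = n_used, boundary = boundary, errors = x),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Standard mixture model with bias (von Mises + uniform)\n")
  cat(sprintf("  n = %d trials, log-likelihood = %.3f%s\n", x$n, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  kappa = %.3f   mu = %+.3f deg   g = %.4f\n", x$kappa, x$mu, x$g))
  if (length(x$boundary)) {
    cat("  boundary:", paste(x$boundary, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  c(kappa = object$kappa, mu = object$mu, g = object$g)
}

#' @export
logLik.mixture_fit <- function(object, ...) {
  structure(object$loglik, df = 3, nobs = object$n, class = "logLik")
}

#' @export
summary.mixture_fit <- function(object, ...) {
  sd_deg <- if (object$kappa > 0) sqrt(1 / object$kappa) * 180 / pi else Inf
  structure(list(fit = object, circ_sd_deg = sd_deg), class = "summary.mixture_fit")
}

#' @export
print.summary.mixture_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  approx. circular SD of memory component: %.2f deg\n", x$circ_sd_deg))
  invisible(x)
}

#' Simulate signed errors from a fitted mixture model
#'
#' @param object a `mixture_fit`.
#' @param nsim number of errors to draw.
#' @param seed optional integer seed (global RNG state is restored).
#' @param ... unused.
#' @return numeric vector of signed errors in degrees.
#' @export
simulate.mixture_fit <- function(object, nsim = object$n, seed = NULL, ...) {
  draw <- function() rmixture(nsim, kappa = object$kappa, mu = object$mu, g = object$g)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Model density at given errors
#'
#' @param object a `mixture_fit`.
#' @param x signed errors in degrees at which to evaluate the fitted density.
#' @param ... unused.
#' @return density per degree under the fitted parameters.
#' @export
predict.mixture_fit <- function(object, x = seq(-180, 180, by = 1), ...) {
  mixture_pdf(x, kappa = object$kappa, mu = object$mu, g = object$g)
}

#' @export
plot.mixture_fit <- function(x, breaks = 36, main = "Mixture model fit", ...) {
  graphics::hist(x$errors, breaks = breaks, freq = FALSE,
                 xlab = "signed error (deg, + toward distractor)", main = main, ...)
  grid_x <- seq(-180, 180, by = 0.5)
  graphics::lines(grid_x, predict(x, grid_x), lwd = 2)
  invisible(x)
}

#' Per-participant mixture fits from a trial table
#'
#' Convenience wrapper fitting [fit_mixture()] to the signed errors of every
#' participant x condition cell of a trial table.
#'
#' @param trials a trial table (data frame) with columns `participant_id`,
#'   `condition` and `signed_error`.
#' @param min_n minimum trials per cell, passed to [fit_mixture()].
#' @return data frame with one row per participant x condition:
#'   `participant_id`, `condition`, `kappa`, `mu`, `g`, `loglik`, `n_trials`,
#'   `converged`.
#' @export
fit_behavior <- function(trials, min_n = 20) {
  stopifnot(all(c("participant_id", "condition", "signed_error") %in% names(trials)))
  cells <- unique(trials[, c("participant_id", "condition")])
  cells <- cells[order(cells$participant_id, cells$condition), , drop = FALSE]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$participant_id == cells$participant_id[i] &
      trials$condition == cells$condition[i]
    f <- fit_mixture(trials$signed_error[sel], min_n = min_n)
    data.frame(participant_id = cells$participant_id[i],
               condition = cells$condition[i],
               kappa = f$kappa, mu = f$mu, g = f$g, loglik = f$loglik,
               n_trials = f$n, converged = f$converged)
  })
  do.call(rbind, out)
}

#' Paired contrast of mixture parameters between conditions
#'
#' Compares each mixture parameter (`kappa`, `mu`, `g`) between two conditions
#' across participants with two-tailed paired t-tests, Holm-corrected across
#' the three parameters.
#'
#' @param fits data frame of per-participant fits as returned by
#'   [fit_behavior()] (columns `participant_id`, `condition`, `kappa`, `mu`,
#'   `g`).
#' @param conditions length-2 character vector; the contrast is
#'   `conditions[1] - conditions[2]`.
#' @return data frame with one row per parameter: mean difference, 95%
#'   confidence bounds, `t`, `df`, raw `p` and Holm-adjusted `p_holm`.
#' @export
condition_contrast <- function(fits, conditions = c("cued", "non-cued")) {
  stopifnot(length(conditions) == 2)
  a <- fits[fits$condition == conditions[1], ]
  b <- fits[fits$condition == conditions[2], ]
  ids <- intersect(a$participant_id, b$participant_id)
  if (!setequal(a$participant_id, b$participant_id) ||
      length(ids) != nrow(a) || length(ids) != nrow(b)) {
    stop("condition_contrast(): every participant must be fitted in both conditions exactly once")
  }
  if (length(ids) < 2) {
    stop("condition_contrast(): need at least 2 participants for a paired t-test")
  }
  a <- a[match(ids, a$participant_id), ]
  b <- b[match(ids, b$participant_id), ]
  rows <- lapply(c("kappa", "mu", "g"), function(par) {
    d <- a[[par]] - b[[par]]
    if (stats::sd(d) == 0) {
      # identical estimates in both conditions: difference is exactly zero
      return(data.frame(parameter = par, mean_diff = mean(d),
                        ci_lower = mean(d), ci_upper = mean(d),
                        t = 0, df = length(d) - 1, p = 1))
    }
    tt <- stats::t.test(a[[par]], b[[par]], paired = TRUE)
    data.frame(parameter = par, mean_diff = unname(tt$estimate),
               ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_correct(out$p)$adjusted
  out
}
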