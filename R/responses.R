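# Behavioral response simulation: the generative inverse of the mixture model.

#' Simulate continuous-report responses for a trial table
#'
#' Draws a response orientation for every trial from the bias-extended
#' standard mixture model: with probability `g` the response is uniform on the
#' circle (a guess); otherwise it is the target orientation plus a von Mises
#' error with concentration `kappa` and mean `mu`, where positive `mu` points
#' from the target toward the distractor. The `signed_error` column is filled
#' with [signed_error()] applied to the simulated responses.
#'
#' If the trial table carries a `kappa_mult` column (written by
#' [simulate_eeg()] when `behavior_coupling > 0`), each trial's effective
#' concentration is `kappa * kappa_mult`, coupling response precision to the
#' trial's realized lateralization.
#'
#' @param trials trial table from [generate_design()].
#' @param params named list mapping each condition present in `trials` to a
#'   list with elements `kappa`, `mu`, `g`.
#' @param seed integer seed.
#' @return the trial table with `response_orientation` and `signed_error`
#'   filled in.
#' @examples
#' tr <- generate_design(design_spec(n_participants = 1, n_cued_trials = 48,
#'                                   n_uncued_trials = 48, seed = 1))
#' pars <- list(cued = list(kappa = 20, mu = 0.4, g = 0.02),
#'              `non-cued` = list(kappa = 15, mu = 0.4, g = 0.03))
#' tr <- simulate_responses(tr, pars, seed = 2)
#' @export
simulate_responses <- function(trials, params, seed = 1L) {
  conds <- unique(trials$condition)
  missing <- setdiff(conds, names(params))
  if (length(missing)) {
    stop("simulate_responses(): no parameters for condition(s): ",
         paste(missing, collapse = ", "))
  }
  for (cn in conds) {
    p <- params[[cn]]
    stopifnot(p$kappa > 0, p$g >= 0, p$g <= 1)
  }
  kmult <- if ("kappa_mult" %in% names(trials)) trials$kappa_mult else rep(1, nrow(trials))

  with_seed(seed, {
    resp <- numeric(nrow(trials))
    for (cn in conds) {
      sel <- which(trials$condition == cn)
      p <- params[[cn]]
      guess <- stats::runif(length(sel)) < p$g
      # direction from target toward distractor: +1 counterclockwise, -1 clockwise
      dir <- sign(circ_diff(trials$distractor_orientation[sel],
                            trials$target_orientation[sel]))
      err_toward <- numeric(length(sel))
      ng <- sum(!guess)
      if (ng > 0) {
        km <- kmult[sel][!guess]
        if (all(km == km[1])) {
          err_toward[!guess] <- rvonmises_deg(ng, mu = p$mu, kappa = p$kappa * km[1])
        } else {
          err_toward[!guess] <- vapply(km, function(k) {
            rvonmises_deg(1, mu = p$mu, kappa = p$kappa * k)
          }, numeric(1))
        }
      }
      r <- trials$target_orientation[sel] + dir * err_toward
      r[guess] <- stats::runif(sum(guess), 0, 360)
      resp[sel] <- r %% 360
      resp[sel][resp[sel] == 0] <- 360
    }
    trials$response_orientation <- resp
    trials$signed_error <- signed_error(trials$response_orientation,
                                        trials$target_orientation,
                                        trials$distractor_orientation)
    trials
  })
}
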