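# Linking lateralization to behavior: grouped mixture fits, Holm correction,
# mixed-model interface, and between-participant correlation.

#' Holm (step-down Bonferroni) correction
#'
#' Thin, validated wrapper around `stats::p.adjust(method = "holm")` that
#' returns the raw values, the adjusted values (monotone, capped at 1) and
#' the family size.
#'
#' @param pvalues numeric p-values in \[0, 1\]; names are carried through.
#' @return an object of class `"pvalue_set"`: list with `raw`, `adjusted`,
#'   `m`, `labels`.
#' @examples
#' holm_correct(c(0.01, 0.04, 0.03))$adjusted # 0.03 0.06 0.06
#' @export
holm_correct <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("holm_correct(): p-values must lie in [0, 1]")
  }
  structure(list(raw = pvalues,
                 adjusted = stats::p.adjust(pvalues, method = "holm"),
                 m = length(pvalues),
                 labels = names(pvalues)),
            class = "pvalue_set")
}

#' @export
print.pvalue_set <- function(x, ...) {
  df <- data.frame(raw = x$raw, holm = x$adjusted)
  if (!is.null(x$labels)) rownames(df) <- x$labels
  cat(sprintf("Holm-corrected p-values (m = %d)\n", x$m))
  print(df)
  invisible(x)
}

#' Mixture fits per participant x cue x lateralization group
#'
#' Fits the standard mixture model to the signed errors of every
#' participant x condition x group cell. Cells with fewer than `min_trials`
#' trials are flagged (`flagged = TRUE`) but still fitted when they meet the
#' absolute fitting minimum `fit_min`; smaller cells get `NA` estimates and
#' remain in the table rather than being silently dropped.
#'
#' @param trials trial table with columns `participant_id`, `condition`,
#'   `signed_error`, and `group` (from [group_trials()]).
#' @param min_trials flagging threshold per cell (default 30).
#' @param fit_min absolute minimum trials for attempting a fit (default 20).
#' @return data frame with one row per cell: `participant_id`, `cue`,
#'   `lat_group`, `kappa`, `mu`, `g`, `loglik`, `n_trials`, `converged`,
#'   `flagged`.
#' @export
fit_by_group <- function(trials, min_trials = 30, fit_min = 20) {
  needed <- c("participant_id", "condition", "signed_error", "group")
  stopifnot(all(needed %in% names(trials)))
  trials <- trials[!is.na(trials$group) & !is.na(trials$signed_error), ]
  if (!nrow(trials)) stop("fit_by_group(): no trials with group labels and errors")
  cells <- unique(trials[, c("participant_id", "condition", "group")])
  cells <- cells[order(cells$participant_id, cells$condition, cells$group), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$participant_id == cells$participant_id[i] &
      trials$condition == cells$condition[i] &
      trials$group == cells$group[i]
    x <- trials$signed_error[sel]
    base <- data.frame(participant_id = cells$participant_id[i],
                       cue = cells$condition[i], lat_group = cells$group[i],
                       kappa = NA_real_, mu = NA_real_, g = NA_real_,
                       loglik = NA_real_, n_trials = length(x),
                       converged = FALSE, flagged = length(x) < min_trials)
    if (length(x) >= fit_min) {
      f <- fit_mixture(x, min_n = fit_min)
      base$kappa <- f$kappa; base$mu <- f$mu; base$g <- f$g
      base$loglik <- f$loglik; base$converged <- f$converged
    }
    base
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$kappa))) stop("fit_by_group(): no cell reached the fitting minimum")
  out
}

#' Mixed-model analysis of grouped mixture parameters
#'
#' For each mixture parameter, builds the long-format response table from a
#' grouped fit table and fits a linear mixed model with a random intercept
#' per participant through `lme4`/`lmerTest`: either the factorial design
#' `parameter ~ cue * lat_group + (1 | participant)` or, with a continuous
#' per-participant lateralization measure, `parameter ~ cue * accuracy +
#' (1 | participant)`. F-tests use Kenward-Roger degrees of freedom when
#' `pbkrtest` is installed (Satterthwaite otherwise, with a message), and
#' p-values are Holm-corrected across the effects within each parameter.
#'
#' @param fits grouped fit table from [fit_by_group()], or per-participant
#'   fits from [fit_behavior()] when `accuracy` is supplied.
#' @param accuracy optional named numeric vector of per-participant
#'   classification accuracies (continuous lateralization predictor). Names
#'   must match `participant_id`.
#' @param parameters which mixture parameters to analyze.
#' @return data frame with columns `parameter`, `effect`, `F`, `df1`, `df2`,
#'   `p`, `p_holm`.
#' @export
mixed_model_interface <- function(fits, accuracy = NULL,
                                  parameters = c("kappa", "g", "mu")) {
  if (!"cue" %in% names(fits) && "condition" %in% names(fits)) {
    fits$cue <- fits$condition
  }
  continuous <- !is.null(accuracy)
  if (continuous) {
    fits$lat <- accuracy[as.character(fits$participant_id)]
    if (anyNA(fits$lat)) stop("mixed_model_interface(): accuracy missing for some participants")
  } else {
    if (!"lat_group" %in% names(fits)) stop("mixed_model_interface(): need lat_group or accuracy")
    fits$lat <- factor(fits$lat_group)
  }
  fits$cue <- factor(fits$cue)
  if (nlevels(fits$cue) < 2) stop("mixed_model_interface(): need both cue conditions")
  ddf <- if (requireNamespace("pbkrtest", quietly = TRUE)) "Kenward-Roger" else {
    message("mixed_model_interface(): pbkrtest unavailable, using Satterthwaite df")
    "Satterthwaite"
  }
  # single-level lateralization collapses to a cue-only model (the paired
  # cue contrast), keeping the interface usable for reduced designs
  drop_lat <- !continuous && nlevels(factor(fits$lat)) < 2
  form <- if (drop_lat) value ~ cue + (1 | participant_id) else
    value ~ cue * lat + (1 | participant_id)
  out <- lapply(parameters, function(par) {
    d <- fits[!is.na(fits[[par]]), c("participant_id", "cue", "lat", par)]
    names(d)[4] <- "value"
    if (stats::sd(d$value) == 0) stop(sprintf("mixed_model_interface(): response '%s' is constant", par))
    m <- tryCatch(
      lmerTest::lmer(form, data = d,
                     control = lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4))),
      error = function(e) stop(sprintf("mixed_model_interface(): model for '%s' failed: %s",
                                       par, conditionMessage(e)))
    )
    an <- stats::anova(m, ddf = ddf)
    eff <- rownames(an)
    data.frame(parameter = par,
               effect = sub("cue:lat", "cue x lateralization",
                            sub("^lat$", "lateralization", eff)),
               F = an[["F value"]], df1 = an$NumDF, df2 = an$DenDF,
               p = an[["Pr(>F)"]])
  })
  out <- do.call(rbind, out)
  out$p_holm <- NA_real_
  for (par in unique(out$parameter)) {
    sel <- out$parameter == par
    out$p_holm[sel] <- holm_correct(out$p[sel])$adjusted
  }
  rownames(out) <- NULL
  out
}

#' Correlation between lateralization and the behavioral benefit
#'
#' Pearson correlation (two-tailed) between a per-participant lateralization
#' measure (e.g., classification accuracy or the conventional ipsi-contra
#' index) and the per-participant behavioral retro-cue benefit (cued minus
#' non-cued difference of a mixture parameter).
#'
#' @param accuracy numeric per-participant lateralization measure.
#' @param benefit numeric per-participant benefit, same length and order.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
accuracy_benefit_correlation <- function(accuracy, benefit) {
  stopifnot(length(accuracy) == length(benefit))
  if (length(accuracy) < 5) stop("accuracy_benefit_correlation(): need at least 5 participants")
  if (stats::sd(accuracy) == 0 || stats::sd(benefit) == 0) {
    stop("accuracy_benefit_correlation(): zero variance in an input vector")
  }
  ct <- stats::cor.test(accuracy, benefit)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(accuracy))
}
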