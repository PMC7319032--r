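# Reduced-scale replica study used by the end-to-end linkage checks.
#
# Study conditions: 12 participants, 288 cued + 96 non-cued trials each,
# 16 channels at 64 Hz, 4 dB mean contralateral alpha suppression with 4 dB
# per-trial spread (so single-trial lateralization genuinely varies between
# reversed and strong, and every consistency x strength cell stays above the
# fitting minimum), behavior kappa 20 (cued) / 14.6 (non-cued), mu = 0.41,
# g = 0.02. With coupling > 0 the realized per-trial lateralization
# multiplies the effective kappa on cued trials.
linkage_study <- function(coupling, seed) {
  n_p <- 12
  behavior <- list(cued = list(kappa = 20, mu = 0.41, g = 0.02),
                   `non-cued` = list(kappa = 14.6, mu = 0.41, g = 0.02))
  spec <- design_spec(n_participants = n_p, n_cued_trials = 288,
                      n_uncued_trials = 96, block_size = 32, seed = seed)
  trials <- generate_design(spec)
  mo <- generate_montage(16)
  grouped <- vector("list", n_p)
  acc <- numeric(n_p)
  for (pid in seq_len(n_p)) {
    tr <- trials[trials$participant_id == pid, ]
    cfg <- eeg_sim_config(sfreq = 64, epoch_start = -0.2, epoch_end = 2.2,
                          cue_onset = 1.0, lateralization_db = 4,
                          lateralization_trial_sd = 4,
                          behavior_coupling = coupling,
                          seed = child_seed(seed, 100 + pid))
    sim <- simulate_topographies(tr, mo, cfg)
    tr <- simulate_responses(sim$trials, behavior,
                             seed = child_seed(seed, 200 + pid))
    cued <- tr$condition == "cued"
    cl <- classify_lateralization(sim$topo[cued, , drop = FALSE],
                                  tr$cue_side[cued], n_perm = 0)
    r_unc <- correlate_trials(sim$topo[!cued, , drop = FALSE], cl$template)
    cls_unc <- classify_trials(r_unc, cl$cutoff, tr$probed_side[!cued])
    g_unc <- group_trials(r_unc, cls_unc$consistency)
    tr$group <- NA_character_
    tr$group[cued] <- cl$grouping$group
    tr$group[!cued] <- g_unc$group
    grouped[[pid]] <- tr
    acc[pid] <- cl$accuracy
  }
  trials <- do.call(rbind, grouped)
  gf <- fit_by_group(trials, min_trials = 30, fit_min = 20)
  mm <- mixed_model_interface(gf)
  list(grouped_fits = gf, linkage = mm, accuracy = acc)
}

# Holm-significant lateralization effects (main effect or interaction).
lat_effects <- function(mm, parameter = NULL, alpha = 0.05) {
  sel <- mm$effect %in% c("lateralization", "cue x lateralization")
  if (!is.null(parameter)) sel <- sel & mm$parameter == parameter
  any(mm$p_holm[sel] <= alpha)
}
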