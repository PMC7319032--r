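# End-to-end orchestration, configuration, validation and plain-text IO.

#' Write / read a trial table as CSV
#'
#' @param trials trial table data frame.
#' @param path file path.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   the data frame.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Validate a trial table
#'
#' Checks the structural invariants of a trial table: required columns,
#' unique trial ids per participant, cue side consistency with condition,
#' orientation ranges and pairwise difference bounds, 50/50 cue side balance,
#' and agreement of stored signed errors with [signed_error()].
#'
#' @param trials trial table data frame.
#' @param orientation_min_diff,orientation_max_diff pairwise difference
#'   bounds in degrees (NULL skips the check).
#' @return data frame of violations (zero rows when valid) with columns
#'   `check` and `detail`.
#' @export
validate_trial_table <- function(trials, orientation_min_diff = NULL,
                                 orientation_max_diff = NULL) {
  v <- list()
  bad <- function(check, detail) data.frame(check = check, detail = detail)
  required <- c("participant_id", "condition", "cue_side", "probed_side",
                "target_orientation", "distractor_orientation")
  miss <- setdiff(required, names(trials))
  if (length(miss)) {
    return(bad("columns", paste("missing:", paste(miss, collapse = ", "))))
  }
  if ("trial_id" %in% names(trials)) {
    dup <- tapply(trials$trial_id, trials$participant_id, anyDuplicated)
    if (any(unlist(dup) > 0)) v <- c(v, list(bad("trial_id", "duplicate trial_id within participant")))
  }
  wrong_cue <- xor(trials$condition == "non-cued", trials$cue_side == "none")
  if (any(wrong_cue)) {
    v <- c(v, list(bad("cue_side", sprintf("%d rows violate cue_side = none iff non-cued", sum(wrong_cue)))))
  }
  oris <- c(trials$target_orientation, trials$distractor_orientation)
  if (any(oris < 1 | oris > 360, na.rm = TRUE)) {
    v <- c(v, list(bad("orientation", "orientations outside [1, 360]")))
  }
  if (!is.null(orientation_min_diff)) {
    d <- circ_dist(trials$target_orientation, trials$distractor_orientation)
    out <- d < orientation_min_diff | d > orientation_max_diff
    if (any(out)) v <- c(v, list(bad("orientation_diff", sprintf("%d rows outside difference bounds", sum(out)))))
  }
  cued <- trials[trials$condition == "cued", ]
  if (nrow(cued)) {
    bal <- tapply(cued$cue_side == "left", cued$participant_id, mean)
    if (any(abs(unlist(bal) - 0.5) > 1e-9)) {
      v <- c(v, list(bad("cue_balance", "cued trials not split 50/50 by side for some participant")))
    }
  }
  if ("signed_error" %in% names(trials) && any(!is.na(trials$signed_error))) {
    sel <- !is.na(trials$signed_error)
    expect <- signed_error(trials$response_orientation[sel],
                           trials$target_orientation[sel],
                           trials$distractor_orientation[sel])
    if (any(abs(expect - trials$signed_error[sel]) > 1e-6)) {
      v <- c(v, list(bad("signed_error", "stored signed_error disagrees with recomputation")))
    }
  }
  if (length(v)) do.call(rbind, v) else data.frame(check = character(0), detail = character(0))
}

#' Validate a montage object
#'
#' @param montage a `montage`.
#' @return data frame of violations (zero rows when valid).
#' @export
validate_montage <- function(montage) {
  v <- list()
  bad <- function(check, detail) data.frame(check = check, detail = detail)
  lateral <- setdiff(montage$channel_names, montage$midline_channels)
  paired <- c(montage$mirror_pairs$left, montage$mirror_pairs$right)
  if (!setequal(lateral, paired) || anyDuplicated(paired)) {
    v <- c(v, list(bad("mirror_pairs", "lateral channels not in exactly one mirror pair")))
  }
  if (!isSymmetric(montage$adjacency)) v <- c(v, list(bad("adjacency", "not symmetric")))
  if (any(diag(montage$adjacency))) v <- c(v, list(bad("adjacency", "self-links present")))
  if (min(rowSums(montage$adjacency)) < 2) v <- c(v, list(bad("adjacency", "channel with fewer than 2 neighbors")))
  norms <- sqrt(rowSums(montage$positions^2))
  if (any(abs(norms - 1) > 1e-6)) v <- c(v, list(bad("positions", "positions not on the unit sphere")))
  if (length(v)) do.call(rbind, v) else data.frame(check = character(0), detail = character(0))
}

#' Validate an epoch array
#'
#' @param epochs an `epoch_array`.
#' @return data frame of violations (zero rows when valid).
#' @export
validate_epochs <- function(epochs) {
  v <- list()
  bad <- function(check, detail) data.frame(check = check, detail = detail)
  if (is.null(epochs$sfreq) || !is.finite(epochs$sfreq)) {
    v <- c(v, list(bad("sfreq", "sampling rate attribute missing")))
  }
  d <- dim(epochs$data)
  if (length(d) != 3) v <- c(v, list(bad("shape", "data is not trials x channels x time")))
  if (length(epochs$channels) != d[2]) v <- c(v, list(bad("channels", "channel names do not match data")))
  if (length(epochs$times) != d[3]) v <- c(v, list(bad("times", "time axis does not match data")))
  if (!is.null(epochs$trial_info) && nrow(epochs$trial_info) != d[1]) {
    v <- c(v, list(bad("trial_info", "trial metadata not row-aligned with data")))
  }
  if (length(v)) do.call(rbind, v) else data.frame(check = character(0), detail = character(0))
}

#' Validate files on disk
#'
#' Reads trial table CSVs and montage TSVs and reports invariant violations
#' per file.
#'
#' @param paths named list with optional elements `trials` (CSV paths) and
#'   `montage` (TSV paths).
#' @return data frame with columns `file`, `check`, `detail`.
#' @export
validate_files <- function(paths) {
  out <- list()
  for (p in paths$trials %||% character(0)) {
    if (!file.exists(p)) stop("validate_files(): unreadable file: ", p)
    rep <- validate_trial_table(read_trial_table(p))
    if (nrow(rep)) out <- c(out, list(cbind(file = p, rep)))
  }
  for (p in paths$montage %||% character(0)) {
    if (!file.exists(p)) stop("validate_files(): unreadable file: ", p)
    rep <- validate_montage(read_montage(p))
    if (nrow(rep)) out <- c(out, list(cbind(file = p, rep)))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(file = character(0), check = character(0), detail = character(0))
}

#' Pipeline configuration
#'
#' Assembles and validates the parameters of every stage of the replica
#' pipeline. The default is a desk-scale study (10 participants, 200 cued +
#' 100 non-cued trials, 32 channels, 256 Hz) with the full study design
#' available via `paper_scale = TRUE` (39 participants, 576 + 288 trials, 64
#' channels, 512 Hz).
#'
#' @param n_participants,n_cued_trials,n_uncued_trials,block_size design
#'   sizes (trial counts per participant).
#' @param n_channels montage size.
#' @param sfreq,epoch_start,epoch_end,cue_onset timing of simulated epochs.
#' @param lateralization_db,behavior_coupling generator effect sizes.
#' @param behavior_params condition -> mixture parameters for response
#'   generation.
#' @param band alpha analysis band, Hz.
#' @param tfr_freqs wavelet frequency grid; `NULL` uses the full default grid
#'   (30 log-spaced bins, 2-40 Hz). Restricting it to the analysis band cuts
#'   runtime when only band-averaged power feeds the downstream stages.
#' @param n_perm_cluster,n_perm_classifier permutation counts.
#' @param paper_scale use the full study dimensions.
#' @param seed global seed; per-stage child seeds derive from it.
#' @param out_dir output directory for stage artifacts (`NULL` keeps results
#'   in memory only).
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_participants = 10,
                            n_cued_trials = 200, n_uncued_trials = 100,
                            block_size = 50,
                            n_channels = 32,
                            sfreq = 256, epoch_start = -0.6, epoch_end = 3.0,
                            cue_onset = 1.5,
                            lateralization_db = 6, behavior_coupling = 0,
                            behavior_params = list(
                              cued = list(kappa = 20, mu = 0.41, g = 0.01),
                              `non-cued` = list(kappa = 14.6, mu = 0.41, g = 0.02)),
                            band = c(7, 14), tfr_freqs = NULL,
                            n_perm_cluster = 1000, n_perm_classifier = 1000,
                            paper_scale = FALSE, seed = 1L, out_dir = NULL) {
  if (paper_scale) {
    n_participants <- 39; n_cued_trials <- 576; n_uncued_trials <- 288
    block_size <- 48; n_channels <- 64; sfreq <- 512
    epoch_start <- -1.0; epoch_end <- 4.5; cue_onset <- 1.5
  }
  cfg <- list(n_participants = n_participants, n_cued_trials = n_cued_trials,
              n_uncued_trials = n_uncued_trials, block_size = block_size,
              n_channels = n_channels, sfreq = sfreq,
              epoch_start = epoch_start, epoch_end = epoch_end,
              cue_onset = cue_onset, lateralization_db = lateralization_db,
              behavior_coupling = behavior_coupling,
              behavior_params = behavior_params, band = band,
              tfr_freqs = tfr_freqs,
              n_perm_cluster = n_perm_cluster,
              n_perm_classifier = n_perm_classifier,
              seed = as.integer(seed), out_dir = out_dir)
  # validate against stage preconditions before any stage runs
  validate_design_spec(design_spec(n_participants = n_participants,
                                   n_cued_trials = n_cued_trials,
                                   n_uncued_trials = n_uncued_trials,
                                   block_size = block_size, seed = seed))
  if (n_channels < 8 || n_channels %% 2 != 0) stop("pipeline_config: invalid n_channels")
  eeg_sim_config(sfreq = sfreq, epoch_start = epoch_start,
                 epoch_end = epoch_end, cue_onset = cue_onset,
                 lateralization_db = lateralization_db,
                 behavior_coupling = behavior_coupling, seed = seed)
  for (cn in c("cued", "non-cued")) {
    p <- cfg$behavior_params[[cn]]
    if (is.null(p)) stop("pipeline_config: behavior_params must cover both conditions")
    stopifnot(p$kappa > 0, p$g >= 0, p$g <= 1)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys are arguments of
#' [pipeline_config()] (with `behavior_params` as nested maps) and builds a
#' validated configuration.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$band)) y$band <- as.numeric(y$band)
  do.call(pipeline_config, y)
}

#' Run the full replica pipeline
#'
#' Executes the complete analysis chain on synthetic data: design generation,
#' EEG simulation, response simulation (coupled to realized lateralization
#' when configured), per-participant behavioral fits and the cued vs non-cued
#' contrast, time-frequency decomposition with single-trial dB baseline,
#' cluster-based permutation test of ipsi vs contra alpha power, single-trial
#' template classification with permutation inference, four-way trial
#' grouping, grouped mixture fits, and the mixed-model linkage analysis. Each
#' stage draws from a child seed derived from the global seed; the manifest
#' records all child seeds, stage outputs and (when written to disk) MD5
#' checksums, so a rerun with the same configuration reproduces every output.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `"pipeline_result"`: list with elements
#'   `trials`, `montage`, `behavior_fits`, `behavior_contrast`,
#'   `cluster_test`, `classification` (per participant), `accuracy` (per
#'   participant), `grouped_fits`, `linkage`, `linkage_continuous`,
#'   `association` (accuracy vs kappa benefit), `sig_window`,
#'   `used_fallback_window`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(design = child_seed(config$seed, 1),
                eeg = child_seed(config$seed, 2),
                responses = child_seed(config$seed, 3),
                cluster = child_seed(config$seed, 4),
                classifier = child_seed(config$seed, 5))
  log_msg <- function(...) message(sprintf(...))

  spec <- design_spec(n_participants = config$n_participants,
                      n_cued_trials = config$n_cued_trials,
                      n_uncued_trials = config$n_uncued_trials,
                      block_size = config$block_size, seed = seeds$design)
  log_msg("stage design: %d participants x %d trials", config$n_participants,
          config$n_cued_trials + config$n_uncued_trials)
  trials <- generate_design(spec)
  montage <- generate_montage(config$n_channels)

  baseline_window <- config$cue_onset + c(-0.5, 0)
  analysis_window <- c(config$cue_onset, min(config$epoch_end - 0.2, config$cue_onset + 1.5))

  log_msg("stage eeg+tfr: %d channels @ %g Hz", config$n_channels, config$sfreq)
  per_participant <- vector("list", config$n_participants)
  trials_out <- list()
  for (pid in seq_len(config$n_participants)) {
    tr <- trials[trials$participant_id == pid, ]
    cfg_eeg <- eeg_sim_config(sfreq = config$sfreq,
                              epoch_start = config$epoch_start,
                              epoch_end = config$epoch_end,
                              cue_onset = config$cue_onset,
                              lateralization_db = config$lateralization_db,
                              behavior_coupling = config$behavior_coupling,
                              seed = child_seed(seeds$eeg, pid))
    ep <- simulate_eeg(tr, montage, cfg_eeg)
    tr <- simulate_responses(ep$trial_info, config$behavior_params,
                             seed = child_seed(seeds$responses, pid))
    tfr <- morlet_tfr(ep, freqs = config$tfr_freqs %||% tfr_default_freqs())
    tfr <- db_baseline(tfr, baseline_window)
    alpha <- band_average(tfr, config$band)
    cued <- tr$condition == "cued"
    # the sample-level contrast runs on the cue -> probe interval only
    times_a <- attr(alpha, "times")
    ti_an <- which(times_a >= analysis_window[1] & times_a <= analysis_window[2])
    per_participant[[pid]] <- list(
      trials = tr,
      alpha = alpha,
      ic = make_ipsi_contra(alpha[cued, , ti_an, drop = FALSE], tr[cued, ],
                            montage, times = times_a[ti_an])
    )
    trials_out[[pid]] <- tr
  }
  trials <- do.call(rbind, trials_out)

  log_msg("stage behavior: mixture fits per participant x condition")
  behavior_fits <- fit_behavior(trials)
  behavior_contrast <- condition_contrast(behavior_fits)

  log_msg("stage cbpt: %d permutations", config$n_perm_cluster)
  ct <- cluster_permutation_test(lapply(per_participant, `[[`, "ic"),
                                 site_adjacency(montage),
                                 n_perm = config$n_perm_cluster,
                                 seed = seeds$cluster)
  used_fallback <- is.null(ct$sig_window)
  sig_window <- if (used_fallback) {
    log_msg("stage cbpt: no significant cluster; using fallback post-cue window")
    default_sig_window(config$cue_onset)
  } else ct$sig_window

  log_msg("stage classify: %d permutations per participant", config$n_perm_classifier)
  classification <- vector("list", config$n_participants)
  grouped_trials <- list()
  for (pid in seq_len(config$n_participants)) {
    pp <- per_participant[[pid]]
    topo_win <- c(max(sig_window[1], min(attr(pp$alpha, "times"))),
                  min(sig_window[2], max(attr(pp$alpha, "times"))))
    ti <- which(attr(pp$alpha, "times") >= topo_win[1] & attr(pp$alpha, "times") <= topo_win[2])
    topo <- rowMeans(pp$alpha[, , ti, drop = FALSE], dims = 2)
    colnames(topo) <- attr(pp$alpha, "channels")
    sides <- ifelse(pp$trials$condition == "cued", pp$trials$cue_side,
                    pp$trials$probed_side)
    cued <- pp$trials$condition == "cued"
    cl <- classify_lateralization(topo[cued, , drop = FALSE], sides[cued],
                                  n_perm = config$n_perm_classifier,
                                  seed = child_seed(seeds$classifier, pid))
    # non-cued trials are scored against the same template/cutoff via probed side
    r_unc <- correlate_trials(topo[!cued, , drop = FALSE], cl$template)
    cls_unc <- classify_trials(r_unc, cl$cutoff, sides[!cued])
    tr <- pp$trials
    tr$trial_r <- NA_real_; tr$consistency <- NA_character_; tr$group <- NA_character_
    tr$trial_r[cued] <- cl$trial_r
    tr$consistency[cued] <- cl$consistency
    tr$group[cued] <- cl$grouping$group
    tr$trial_r[!cued] <- r_unc
    tr$consistency[!cued] <- cls_unc$consistency
    g_unc <- group_trials(r_unc, cls_unc$consistency)
    tr$group[!cued] <- g_unc$group
    grouped_trials[[pid]] <- tr
    classification[[pid]] <- cl
  }
  trials <- do.call(rbind, grouped_trials)
  accuracy <- vapply(classification, `[[`, numeric(1), "accuracy")
  names(accuracy) <- as.character(seq_len(config$n_participants))

  log_msg("stage link: grouped fits and mixed models")
  grouped_fits <- fit_by_group(trials)
  linkage <- mixed_model_interface(grouped_fits)
  linkage_cont <- mixed_model_interface(behavior_fits, accuracy = accuracy)
  benefit <- behavior_fits$kappa[behavior_fits$condition == "cued"] -
    behavior_fits$kappa[behavior_fits$condition == "non-cued"]
  association <- if (config$n_participants >= 5) {
    accuracy_benefit_correlation(accuracy, benefit)
  } else NULL

  manifest <- list(config = unclass(config), seeds = seeds,
                   stages = c("design", "eeg", "responses", "behavior",
                              "tfr", "cbpt", "classify", "link"),
                   n_trials = nrow(trials),
                   sig_window = sig_window, used_fallback_window = used_fallback,
                   checksums = list())
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(trials = file.path(config$out_dir, "trials.csv"),
               montage = file.path(config$out_dir, "montage.tsv"),
               behavior_fits = file.path(config$out_dir, "behavior_fits.csv"),
               grouped_fits = file.path(config$out_dir, "grouped_fits.csv"),
               linkage = file.path(config$out_dir, "linkage.csv"))
    write_trial_table(trials, paths["trials"])
    write_montage(montage, paths["montage"])
    utils::write.csv(behavior_fits, paths["behavior_fits"], row.names = FALSE)
    utils::write.csv(grouped_fits, paths["grouped_fits"], row.names = FALSE)
    utils::write.csv(linkage, paths["linkage"], row.names = FALSE)
    manifest$checksums <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(trials = trials, montage = montage,
                 behavior_fits = behavior_fits,
                 behavior_contrast = behavior_contrast,
                 cluster_test = ct, classification = classification,
                 accuracy = accuracy, grouped_fits = grouped_fits,
                 linkage = linkage, linkage_continuous = linkage_cont,
                 association = association, sig_window = sig_window,
                 used_fallback_window = used_fallback, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Replica pipeline result\n")
  cat(sprintf("  %d participants, %d trials\n",
              length(x$classification), nrow(x$trials)))
  cat(sprintf("  behavior: delta kappa = %.2f (p_holm = %.3g)\n",
              x$behavior_contrast$mean_diff[x$behavior_contrast$parameter == "kappa"],
              x$behavior_contrast$p_holm[x$behavior_contrast$parameter == "kappa"]))
  ncl <- length(x$cluster_test$clusters)
  cat(sprintf("  cbpt: %d cluster(s)%s\n", ncl,
              if (x$used_fallback_window) ", fallback window used" else ""))
  cat(sprintf("  classification accuracy: mean %.3f (range %.3f-%.3f)\n",
              mean(x$accuracy), min(x$accuracy), max(x$accuracy)))
  lat <- x$linkage[x$linkage$effect != "cue", ]
  cat(sprintf("  linkage: min Holm p over lateralization effects = %.3g\n",
              min(lat$p_holm)))
  invisible(x)
}
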