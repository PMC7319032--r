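# Ipsi/contra pairing over mirror electrodes and the cluster-based
# permutation test on site x time data.

#' Build ipsi/contra power series from mirror pairs
#'
#' For every mirror electrode pair, labels the member contralateral to the
#' cued side as "contra" and the other as "ipsi", per trial, then averages
#' over trials: on a left-cued trial the right-hemisphere member is contra;
#' on a right-cued trial assignments flip. Midline channels have no
#' contralateral partner and are excluded. Non-cued trials are only usable
#' with `use_probed_side = TRUE`, which sides them by the to-be-probed
#' hemifield.
#'
#' @param topotime array trials x channels x time of dB alpha power (from
#'   [band_average()]), with channels named as in `montage`.
#' @param trials trial table rows aligned with the first dimension of
#'   `topotime`.
#' @param montage the `montage` the channels belong to.
#' @param use_probed_side allow non-cued trials by falling back to
#'   `probed_side`.
#' @param times time axis in seconds for the third dimension (defaults to the
#'   `times` attribute left by [band_average()], or sample indices).
#' @return an object of class `"ipsi_contra"`: list with `contra` and `ipsi`
#'   (matrices sites x time), `site_labels` (the left-hemisphere pair member
#'   names), `times`, and `n_trials`.
#' @export
make_ipsi_contra <- function(topotime, trials, montage, use_probed_side = FALSE,
                             times = NULL) {
  stopifnot(inherits(montage, "montage"))
  channels <- dimnames(topotime)[[2]] %||% attr(topotime, "channels")
  times <- times %||% attr(topotime, "times") %||% seq_len(dim(topotime)[3])
  if (is.null(channels)) stop("make_ipsi_contra(): topotime carries no channel names")
  if (nrow(trials) != dim(topotime)[1]) {
    stop("make_ipsi_contra(): trials and topotime disagree on trial count")
  }
  side <- ifelse(trials$condition == "cued", trials$cue_side,
                 if (use_probed_side) trials$probed_side else "none")
  if (any(side == "none")) {
    stop("make_ipsi_contra(): non-cued trials present; set use_probed_side = TRUE to side them by the probed hemifield")
  }
  pairs <- montage$mirror_pairs
  li <- match(pairs$left, channels)
  ri <- match(pairs$right, channels)
  if (anyNA(li) || anyNA(ri)) {
    stop("make_ipsi_contra(): montage mirror pairs not found among data channels")
  }
  n_t <- dim(topotime)[3]
  left_trials <- side == "left"
  contra <- matrix(0, nrow(pairs), n_t)
  ipsi <- matrix(0, nrow(pairs), n_t)
  for (s in seq_len(nrow(pairs))) {
    l_series <- topotime[, li[s], , drop = FALSE]
    r_series <- topotime[, ri[s], , drop = FALSE]
    dim(l_series) <- c(dim(topotime)[1], n_t)
    dim(r_series) <- c(dim(topotime)[1], n_t)
    # left-cued: contra = right channel; right-cued: contra = left channel
    contra[s, ] <- colMeans(rbind(r_series[left_trials, , drop = FALSE],
                                  l_series[!left_trials, , drop = FALSE]))
    ipsi[s, ] <- colMeans(rbind(l_series[left_trials, , drop = FALSE],
                                r_series[!left_trials, , drop = FALSE]))
  }
  rownames(contra) <- rownames(ipsi) <- pairs$left
  structure(list(contra = contra, ipsi = ipsi, site_labels = pairs$left,
                 times = times, n_trials = nrow(trials)),
            class = "ipsi_contra")
}

#' Site adjacency for mirror-pair sites
#'
#' Adjacency between mirror-pair sites is the montage adjacency of their
#' left-hemisphere members.
#'
#' @param montage a `montage`.
#' @return symmetric logical matrix over sites (left pair members).
#' @export
site_adjacency <- function(montage) {
  idx <- match(montage$mirror_pairs$left, montage$channel_names)
  adj <- montage$adjacency[idx, idx, drop = FALSE]
  dimnames(adj) <- list(montage$mirror_pairs$left, montage$mirror_pairs$left)
  adj
}

# Connected components among suprathreshold samples of one sign on the
# site x time grid: samples are linked across consecutive time points at the
# same site, and across spatially adjacent sites at the same time point.
find_clusters <- function(mask, adjacency) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  n <- nrow(idx)
  key <- (idx[, 2] - 1) * nrow(mask) + idx[, 1]
  lookup <- integer(length(mask)); lookup[key] <- seq_len(n)
  labels <- integer(n)
  cl <- 0L
  for (start in seq_len(n)) {
    if (labels[start]) next
    cl <- cl + 1L
    queue <- start
    labels[start] <- cl
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      s <- idx[cur, 1]; t <- idx[cur, 2]
      nb_keys <- integer(0)
      if (t > 1) nb_keys <- c(nb_keys, (t - 2) * nrow(mask) + s)
      if (t < ncol(mask)) nb_keys <- c(nb_keys, t * nrow(mask) + s)
      nb_sites <- which(adjacency[s, ])
      if (length(nb_sites)) nb_keys <- c(nb_keys, (t - 1) * nrow(mask) + nb_sites)
      nb <- lookup[nb_keys]
      nb <- nb[nb > 0]
      nb <- nb[labels[nb] == 0]
      if (length(nb)) {
        labels[nb] <- cl
        queue <- c(queue, nb)
      }
    }
  }
  lapply(seq_len(cl), function(k) idx[labels == k, , drop = FALSE])
}

# Minimum-neighbour spatial-extent rule: prune time slices whose member sites
# do not include a spatially connected group of >= min_nb sites, then
# re-extract connected components.
apply_min_neighbors <- function(clusters, adjacency, min_nb, n_sites, n_times) {
  if (min_nb <= 1) return(clusters)
  out <- list()
  for (cl in clusters) {
    keep <- rep(TRUE, nrow(cl))
    for (t in unique(cl[, 2])) {
      sites <- cl[cl[, 2] == t, 1]
      # largest mutually adjacent group at this slice
      best <- max(vapply(sites, function(s) 1L + sum(adjacency[s, sites]), integer(1)))
      if (length(sites) < min_nb || best < min_nb) keep[cl[, 2] == t] <- FALSE
    }
    if (!any(keep)) next
    sub <- matrix(FALSE, n_sites, n_times)
    sub[cl[keep, , drop = FALSE]] <- TRUE
    out <- c(out, find_clusters(sub, adjacency))
  }
  out
}

# Max |t_sum| over clusters for one t-map (helper for permutations).
max_cluster_stat <- function(tmap, t_crit, adjacency, min_nb) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > t_crit
    if (!any(mask)) next
    cls <- find_clusters(mask, adjacency)
    cls <- apply_min_neighbors(cls, adjacency, min_nb, nrow(tmap), ncol(tmap))
    if (length(cls)) {
      sums <- vapply(cls, function(ix) sum(tmap[ix]), numeric(1))
      best <- max(best, max(abs(sums)))
    }
  }
  best
}

#' Cluster-based permutation test on ipsi/contra data
#'
#' Tests contra minus ipsi power across participants with a paired t-test at
#' every site x time sample, thresholds two-tailed at `sample_alpha`, groups
#' suprathreshold samples of equal sign into spatio-temporally connected
#' clusters (spatial links from `adjacency`, temporal links between
#' consecutive samples), discards clusters failing the minimum-neighbour
#' spatial-extent rule, and scores each cluster by the sum of its t-values
#' (`t_sum`). The null distribution is the maximum |t_sum| under random
#' within-participant ipsi/contra swaps (sign flips of each participant's
#' difference). Cluster p-values use the +1-corrected Monte-Carlo formula
#' `p = (#\{null >= |t_sum|\} + 1) / (n_perm + 1)`; with `n_perm = "all"` the
#' complete set of 2^n sign patterns is enumerated and `p` is the exact
#' fraction `#\{null >= |t_sum|\} / 2^n`. Clusters with `p <= alpha` are
#' declared significant (two-tailed control via the max-|t_sum| null).
#'
#' @param data list of `ipsi_contra` objects, one per participant, sharing
#'   sites and times.
#' @param adjacency symmetric logical site adjacency (see [site_adjacency()]).
#' @param n_perm number of random permutations (default 1000), or `"all"` for
#'   exhaustive enumeration (feasible for small samples).
#' @param sample_alpha two-tailed sample-level threshold (default 0.05).
#' @param min_neighbor_channels minimum number of spatially adjacent sites a
#'   cluster must span at each time slice (default 2; 1 disables the rule).
#' @param alpha cluster-level significance threshold (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @return an object of class `"cluster_test"`: list with `t_map`,
#'   `threshold_mask`, `clusters` (each with `members`, `t_sum`, `sign`,
#'   `p`), `null_max`, `sig_window`, `sig_sites`, `times`, `site_labels`,
#'   `n_participants`, `n_perm`.
#' @export
cluster_permutation_test <- function(data, adjacency, n_perm = 1000,
                                     sample_alpha = 0.05,
                                     min_neighbor_channels = 2,
                                     alpha = 0.05, seed = 1L) {
  stopifnot(length(data) >= 4)
  exhaustive <- identical(n_perm, "all")
  if (!exhaustive && n_perm < 100) warning("cluster_permutation_test(): n_perm < 100 gives a coarse p-value")
  n <- length(data)
  sites <- data[[1]]$site_labels
  times <- data[[1]]$times
  n_s <- nrow(data[[1]]$contra); n_t <- ncol(data[[1]]$contra)

  # participant x sample matrix of contra - ipsi differences
  D <- t(vapply(data, function(d) as.vector(d$contra - d$ipsi), numeric(n_s * n_t)))

  t_from_signs <- function(signs_mat) {
    # rows = permutations; exploits sign-flip invariance of the sum of squares
    mns <- signs_mat %*% D / n
    ss <- matrix(colSums(D^2), nrow(signs_mat), ncol(D), byrow = TRUE)
    vr <- (ss - n * mns^2) / (n - 1)
    tm <- mns / sqrt(vr / n)
    tm[!is.finite(tm)] <- 0 # zero-variance samples get t = 0
    tm
  }

  t_obs <- t_from_signs(matrix(1, 1, n))
  zero_var <- apply(D, 2, stats::sd) == 0
  if (any(zero_var)) {
    warning(sprintf("cluster_permutation_test(): %d zero-variance sample(s) set to t = 0",
                    sum(zero_var)))
  }
  tmap <- matrix(t_obs, n_s, n_t, dimnames = list(sites, NULL))
  t_crit <- stats::qt(1 - sample_alpha / 2, df = n - 1)

  threshold_mask <- abs(tmap) > t_crit
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > t_crit
    if (!any(mask)) next
    cls <- find_clusters(mask, adjacency)
    cls <- apply_min_neighbors(cls, adjacency, min_neighbor_channels, n_s, n_t)
    for (cl in cls) {
      clusters <- c(clusters, list(list(members = cl, t_sum = sum(tmap[cl]), sign = sgn)))
    }
  }

  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    signs <- with_seed(seed,
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  }
  tperm <- t_from_signs(signs)
  null_max <- vapply(seq_len(nrow(signs)), function(p) {
    max_cluster_stat(matrix(tperm[p, ], n_s, n_t), t_crit, adjacency,
                     min_neighbor_channels)
  }, numeric(1))

  for (k in seq_along(clusters)) {
    ts <- abs(clusters[[k]]$t_sum)
    clusters[[k]]$p <- if (exhaustive) {
      sum(null_max >= ts) / length(null_max)
    } else {
      (sum(null_max >= ts) + 1) / (length(null_max) + 1)
    }
  }

  sig <- Filter(function(cl) cl$p <= alpha, clusters)
  sig_window <- NULL; sig_sites <- character(0)
  if (length(sig)) {
    win <- Reduce(rbind, lapply(sig, function(cl) cl$members))
    sig_window <- range(times[win[, 2]])
    sig_sites <- sort(unique(sites[win[, 1]]))
  }

  structure(list(t_map = tmap, threshold_mask = threshold_mask,
                 clusters = clusters, null_max = null_max,
                 sig_window = sig_window, sig_sites = sig_sites,
                 times = times, site_labels = sites,
                 n_participants = n, n_perm = nrow(signs),
                 sample_alpha = sample_alpha, alpha = alpha,
                 min_neighbor_channels = min_neighbor_channels),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster-based permutation test: %d participants, %d sites x %d samples, %d permutations\n",
              x$n_participants, nrow(x$t_map), ncol(x$t_map), x$n_perm))
  if (!length(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (cl in x$clusters) {
      cat(sprintf("  cluster: t_sum = %9.2f (%s), %3d samples, p = %.4g%s\n",
                  cl$t_sum, if (cl$sign > 0) "+" else "-", nrow(cl$members),
                  cl$p, if (cl$p <= x$alpha) " *" else ""))
    }
  }
  if (!is.null(x$sig_window)) {
    cat(sprintf("  significant window: [%.3f, %.3f] s over %d sites\n",
                x$sig_window[1], x$sig_window[2], length(x$sig_sites)))
  }
  invisible(x)
}

#' Conventional lateralization index
#'
#' The classic scalar summary of alpha lateralization: mean ipsilateral minus
#' contralateral dB power over the significant sites and window, one value
#' per participant (positive = contralateral desynchronization).
#'
#' @param data list of `ipsi_contra` objects (one per participant).
#' @param sig_sites non-empty character vector of site labels.
#' @param sig_window length-2 numeric window in seconds (defaults to the full
#'   time range of the data).
#' @return numeric vector, one index per participant.
#' @export
conventional_lateralization_index <- function(data, sig_sites, sig_window = NULL) {
  if (!length(sig_sites)) stop("conventional_lateralization_index(): empty site set")
  vapply(data, function(d) {
    si <- match(sig_sites, d$site_labels)
    if (anyNA(si)) stop("conventional_lateralization_index(): unknown site label")
    ti <- if (is.null(sig_window)) seq_along(d$times) else
      which(d$times >= sig_window[1] & d$times <= sig_window[2])
    mean(d$ipsi[si, ti] - d$contra[si, ti])
  }, numeric(1))
}

#' Fallback analysis window
#'
#' When no cluster reaches significance, downstream stages may fall back to
#' the canonical post-cue window in which retro-cue induced lateralization is
#' typically most pronounced: 300 to 1070 ms after cue onset.
#'
#' @param cue_onset cue time in seconds on the epoch time axis.
#' @return length-2 numeric window in seconds.
#' @export
default_sig_window <- function(cue_onset = 0) cue_onset + c(0.300, 1.070)
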