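# Independent oracles used to cross-check the package implementations.

# Brute-force cluster-based permutation test with exhaustive sign-flip
# enumeration. Independent route: per-sample t-tests via stats::t.test and
# connected components via igraph.
oracle_cbpt <- function(diff_list, adjacency, sample_alpha = 0.05) {
  arr <- simplify2array(diff_list) # sites x times x participants
  n <- dim(arr)[3]
  t_crit <- qt(1 - sample_alpha / 2, n - 1)
  tmap_of <- function(a) {
    apply(a, c(1, 2), function(v) {
      if (stats::sd(v) == 0) 0 else unname(stats::t.test(v)$statistic)
    })
  }
  clusters_of <- function(tm) {
    out <- list()
    for (sgn in c(1, -1)) {
      mask <- (sgn * tm) > t_crit
      if (!any(mask)) next
      idx <- which(mask, arr.ind = TRUE)
      m <- nrow(idx)
      edges <- c()
      if (m > 1) {
        for (a in 1:(m - 1)) for (b in (a + 1):m) {
          same_site <- idx[a, 1] == idx[b, 1] && abs(idx[a, 2] - idx[b, 2]) == 1
          same_time <- idx[a, 2] == idx[b, 2] && adjacency[idx[a, 1], idx[b, 1]]
          if (same_site || same_time) edges <- c(edges, a, b)
        }
      }
      g <- igraph::make_empty_graph(n = m, directed = FALSE)
      if (length(edges)) g <- igraph::add_edges(g, edges)
      comp <- igraph::components(g)$membership
      for (k in unique(comp)) {
        out <- c(out, list(sum(tm[idx[comp == k, , drop = FALSE]])))
      }
    }
    unlist(out)
  }
  t_obs <- tmap_of(arr)
  obs_sums <- clusters_of(t_obs)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- apply(signs, 1, function(s) {
    flipped <- sweep(arr, 3, s, `*`)
    cs <- clusters_of(tmap_of(flipped))
    if (length(cs)) max(abs(cs)) else 0
  })
  list(t_map = t_obs, t_sums = obs_sums,
       p = vapply(obs_sums, function(ts) mean(null_max >= abs(ts)), numeric(1)),
       null_max = null_max)
}

# Wrap site x time difference matrices as the ipsi_contra structures the
# package's test consumes (contra - ipsi = D, split symmetrically).
as_ipsi_contra <- function(D, times = seq_len(ncol(D))) {
  structure(list(contra = D / 2, ipsi = -D / 2,
                 site_labels = rownames(D) %||% paste0("S", seq_len(nrow(D))),
                 times = times, n_trials = 1L),
            class = "ipsi_contra")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
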