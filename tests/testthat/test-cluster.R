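# Ipsi/contra pairing and the cluster-based permutation test.

# minimal topotime array: trials x channels x time with channel dimnames
topo_array <- function(mat_list, channels) {
  arr <- array(NA_real_, dim = c(length(mat_list), length(channels),
                                 ncol(mat_list[[1]])))
  for (i in seq_along(mat_list)) arr[i, , ] <- mat_list[[i]]
  dimnames(arr) <- list(NULL, channels, NULL)
  arr
}

chain_adjacency <- function(n) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj
}

test_that("contra/ipsi assignment follows the cued side", {
  mo <- generate_montage(8)
  ch <- mo$channel_names
  n_t <- 4
  # channel values = channel index, constant over time
  base <- matrix(seq_along(ch), length(ch), n_t)
  trials <- data.frame(condition = "cued", cue_side = c("left", "right"),
                       probed_side = c("left", "right"))
  arr <- topo_array(list(base, base), ch)
  ic_l <- make_ipsi_contra(arr[1, , , drop = FALSE], trials[1, , drop = FALSE], mo)
  l1 <- mo$mirror_pairs$left[1]; r1 <- mo$mirror_pairs$right[1]
  expect_equal(unname(ic_l$contra[1, ]), rep(match(r1, ch), n_t))
  expect_equal(unname(ic_l$ipsi[1, ]), rep(match(l1, ch), n_t))
  ic_r <- make_ipsi_contra(arr[2, , , drop = FALSE], trials[2, , drop = FALSE], mo)
  expect_equal(unname(ic_r$contra[1, ]), rep(match(l1, ch), n_t))
  expect_equal(unname(ic_r$ipsi[1, ]), rep(match(r1, ch), n_t))
  # mirror-symmetric data gives an exactly zero contrast
  sym <- base
  for (k in seq_len(nrow(mo$mirror_pairs))) {
    li <- match(mo$mirror_pairs$left[k], ch)
    ri <- match(mo$mirror_pairs$right[k], ch)
    sym[ri, ] <- sym[li, ]
  }
  ic_s <- make_ipsi_contra(topo_array(list(sym, sym), ch), trials, mo)
  expect_true(all(ic_s$contra - ic_s$ipsi == 0))
  # non-cued trials require the probed-side fallback
  nc <- data.frame(condition = "non-cued", cue_side = "none", probed_side = "left")
  expect_error(make_ipsi_contra(arr[1, , , drop = FALSE], nc, mo), "use_probed_side")
  ic_nc <- make_ipsi_contra(arr[1, , , drop = FALSE], nc, mo, use_probed_side = TRUE)
  expect_equal(unname(ic_nc$contra[1, 1]), match(r1, ch))
})

test_that("identical contra and ipsi produce no clusters", {
  set.seed(2)
  datas <- lapply(1:5, function(i) {
    x <- matrix(rnorm(4 * 6), 4, 6)
    structure(list(contra = x, ipsi = x, site_labels = paste0("S", 1:4),
                   times = 1:6, n_trials = 10L), class = "ipsi_contra")
  })
  expect_warning(
    ct <- cluster_permutation_test(datas, chain_adjacency(4), n_perm = 120,
                                   seed = 1),
    "zero-variance")
  expect_false(any(ct$threshold_mask))
  expect_length(ct$clusters, 0)
  expect_null(ct$sig_window)
})

test_that("exhaustive sign-flip enumeration matches the independent oracle", {
  skip_if_not_installed("igraph")
  set.seed(40)
  adj <- chain_adjacency(4)
  # effect confined to sites 2-3, late time points, plus noise
  diffs <- lapply(1:6, function(i) {
    D <- matrix(rnorm(4 * 5, 0, 1), 4, 5)
    D[2:3, 3:5] <- D[2:3, 3:5] - 2.2
    rownames(D) <- paste0("S", 1:4)
    D
  })
  res <- cluster_permutation_test(lapply(diffs, as_ipsi_contra), adj,
                                  n_perm = "all", min_neighbor_channels = 1)
  oracle <- oracle_cbpt(diffs, adj)
  expect_equal(res$t_map, oracle$t_map, tolerance = 1e-10)
  expect_setequal(round(vapply(res$clusters, `[[`, numeric(1), "t_sum"), 8),
                  round(oracle$t_sums, 8))
  # p-values agree cluster by cluster
  imp <- vapply(res$clusters, `[[`, numeric(1), "p")[
    order(vapply(res$clusters, `[[`, numeric(1), "t_sum"))]
  orc <- oracle$p[order(oracle$t_sums)]
  expect_equal(imp, orc, tolerance = 1e-12)
})

test_that("global sign flip exchanges positive and negative clusters", {
  set.seed(41)
  diffs <- lapply(1:6, function(i) {
    D <- matrix(rnorm(4 * 5), 4, 5); D[1:2, 1:3] <- D[1:2, 1:3] + 2.5; D
  })
  adj <- chain_adjacency(4)
  r1 <- cluster_permutation_test(lapply(diffs, as_ipsi_contra), adj,
                                 n_perm = 200, seed = 7)
  r2 <- cluster_permutation_test(lapply(diffs, function(D) as_ipsi_contra(-D)),
                                 adj, n_perm = 200, seed = 7)
  s1 <- sort(vapply(r1$clusters, `[[`, numeric(1), "t_sum"))
  s2 <- sort(-vapply(r2$clusters, `[[`, numeric(1), "t_sum"))
  expect_equal(s1, s2, tolerance = 1e-10)
  p1 <- vapply(r1$clusters, `[[`, numeric(1), "p")
  p2 <- vapply(r2$clusters, `[[`, numeric(1), "p")
  expect_equal(sort(p1), sort(p2), tolerance = 1e-12)
})

test_that("permutation distribution is invariant to site relabeling", {
  set.seed(42)
  diffs <- lapply(1:8, function(i) matrix(rnorm(5 * 6), 5, 6))
  adj <- chain_adjacency(5)
  perm <- c(3, 1, 5, 2, 4)
  r1 <- cluster_permutation_test(lapply(diffs, as_ipsi_contra), adj,
                                 n_perm = 150, seed = 3)
  r2 <- cluster_permutation_test(lapply(diffs, function(D) as_ipsi_contra(D[perm, ])),
                                 adj[perm, perm], n_perm = 150, seed = 3)
  expect_equal(r1$null_max, r2$null_max, tolerance = 1e-10)
  expect_equal(sort(vapply(r1$clusters, `[[`, numeric(1), "p")),
               sort(vapply(r2$clusters, `[[`, numeric(1), "p")))
})

test_that("doubling the permutation count moves p by less than 3 MC errors", {
  set.seed(43)
  diffs <- lapply(1:8, function(i) {
    D <- matrix(rnorm(4 * 8), 4, 8); D[2:3, 4:7] <- D[2:3, 4:7] - 1.4; D
  })
  adj <- chain_adjacency(4)
  ics <- lapply(diffs, as_ipsi_contra)
  r1 <- cluster_permutation_test(ics, adj, n_perm = 400, seed = 11)
  r2 <- cluster_permutation_test(ics, adj, n_perm = 800, seed = 12)
  p1 <- min(vapply(r1$clusters, `[[`, numeric(1), "p"))
  p2 <- min(vapply(r2$clusters, `[[`, numeric(1), "p"))
  se <- sqrt(p1 * (1 - p1) / 400 + p2 * (1 - p2) / 800)
  expect_lt(abs(p1 - p2), 3 * max(se, 1 / 400))
})

test_that("conventional lateralization index recovers uniform offsets", {
  x <- matrix(rnorm(4 * 6), 4, 6)
  mk <- function(contra, ipsi) {
    structure(list(contra = contra, ipsi = ipsi, site_labels = paste0("S", 1:4),
                   times = seq(0, 1, length.out = 6), n_trials = 5L),
              class = "ipsi_contra")
  }
  expect_equal(conventional_lateralization_index(list(mk(x, x)), paste0("S", 1:4)), 0)
  expect_equal(conventional_lateralization_index(list(mk(x - 2, x)), paste0("S", 1:2)), 2)
  expect_error(conventional_lateralization_index(list(mk(x, x)), character(0)), "empty")
})
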