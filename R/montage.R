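# Synthetic equidistant EEG montage: symmetric rings on the upper head sphere.

#' Generate a symmetric equidistant montage
#'
#' Places `n_channels` electrodes on the unit sphere in concentric rings
#' around the vertex, extending slightly below the equator over posterior
#' areas, with exact mirror symmetry about the sagittal plane. Each ring
#' contains one front-midline and one back-midline channel; all remaining
#' channels form left/right mirror pairs. The spatial adjacency relation marks
#' channels closer than 1.3 times the median nearest-neighbour distance as
#' neighbours (the threshold is widened until every channel has at least two).
#'
#' Coordinates: x = right, y = anterior, z = up; all positions unit-norm.
#'
#' @param n_channels even number of channels, at least 8. Default 64.
#' @return an object of class `"montage"`: list with `channel_names`,
#'   `positions` (n x 3 matrix), `mirror_pairs` (data frame with columns
#'   `left`, `right`), `midline_channels`, and `adjacency` (symmetric logical
#'   matrix without self-links).
#' @examples
#' m <- generate_montage(32)
#' nrow(m$mirror_pairs)
#' @export
generate_montage <- function(n_channels = 64) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 8) stop("generate_montage(): need at least 8 channels")
  if (n_channels %% 2 != 0) {
    stop("generate_montage(): n_channels must be even (lateral channels come in mirror pairs)")
  }

  n_rings <- max(2L, as.integer(round(sqrt(n_channels) / 2)))
  theta_max <- 100 * pi / 180 # extend below the equator over occipital sites
  theta <- seq_len(n_rings) * theta_max / n_rings

  # allocate even per-ring counts (>= 4) proportional to ring circumference
  w <- sin(theta) / sum(sin(theta))
  m <- pmax(4L, 2L * as.integer(round(w * n_channels / 2)))
  excess <- sum(m) - n_channels
  k <- n_rings
  while (excess != 0) {
    step <- if (excess > 0) -2L else 2L
    if (m[k] + step >= 4L) {
      m[k] <- m[k] + step
      excess <- excess + step
    }
    k <- if (k == 1L) n_rings else k - 1L
  }

  pos <- matrix(NA_real_, 0, 3)
  name <- character(0)
  is_mid <- logical(0)
  ring_id <- integer(0)
  for (r in seq_len(n_rings)) {
    phi <- (90 + (seq_len(m[r]) - 1) * 360 / m[r]) * pi / 180
    ring_pos <- cbind(sin(theta[r]) * cos(phi),
                      sin(theta[r]) * sin(phi),
                      cos(theta[r]))
    mid <- abs(ring_pos[, 1]) < 1e-9
    lab <- character(m[r])
    lab[mid] <- sprintf("Z%d%s", r, ifelse(ring_pos[mid, 2] > 0, "F", "B"))
    side <- ifelse(ring_pos[, 1] > 0, "R", "L")
    lat_idx <- cumsum(!mid)
    lab[!mid] <- sprintf("%s%d_%d", side[!mid], r, lat_idx[!mid])
    pos <- rbind(pos, ring_pos)
    name <- c(name, lab)
    is_mid <- c(is_mid, mid)
    ring_id <- c(ring_id, rep(r, m[r]))
  }
  rownames(pos) <- name
  colnames(pos) <- c("x", "y", "z")

  # mirror pairs: match each left channel to the channel at (-x, y, z)
  left_idx <- which(!is_mid & pos[, 1] < 0)
  pair_left <- character(0)
  pair_right <- character(0)
  for (i in left_idx) {
    target <- c(-pos[i, 1], pos[i, 2], pos[i, 3])
    d <- colSums((t(pos) - target)^2)
    j <- which.min(d)
    if (d[j] > 1e-12) stop("generate_montage(): internal mirror matching failure")
    pair_left <- c(pair_left, name[i])
    pair_right <- c(pair_right, name[j])
  }

  # rename laterals so pair k is (Lk, Rk) in a stable posterior-to-anterior order
  ord <- order(pos[pair_left, "y"], pos[pair_left, "z"])
  pair_left <- pair_left[ord]
  pair_right <- pair_right[ord]
  new_name <- name
  for (k in seq_along(pair_left)) {
    new_name[name == pair_left[k]] <- sprintf("L%02d", k)
    new_name[name == pair_right[k]] <- sprintf("R%02d", k)
  }
  mid_names <- name[is_mid]
  for (k in seq_along(mid_names)) {
    new_name[name == mid_names[k]] <- sprintf("Z%02d", k)
  }
  rownames(pos) <- new_name
  mirror_pairs <- data.frame(left = sprintf("L%02d", seq_along(pair_left)),
                             right = sprintf("R%02d", seq_along(pair_right)))

  adjacency <- build_adjacency(pos)

  structure(list(channel_names = new_name,
                 positions = pos,
                 mirror_pairs = mirror_pairs,
                 midline_channels = new_name[is_mid],
                 adjacency = adjacency),
            class = "montage")
}

# Distance-threshold adjacency: neighbours within 1.3 x median nearest-neighbour
# distance; the threshold grows by 10% until every channel has >= 2 neighbours
# and the neighbourhood graph is connected (as on a physical cap).
build_adjacency <- function(pos) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  thr <- 1.3 * stats::median(apply(d, 1, min))
  repeat {
    adj <- d <= thr
    if (min(rowSums(adj)) >= 2 && graph_connected(adj)) break
    thr <- thr * 1.1
  }
  diag(adj) <- FALSE
  adj
}

graph_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    nb <- which(adj[cur, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("Montage: %d channels (%d mirror pairs, %d midline)\n",
              length(x$channel_names), nrow(x$mirror_pairs),
              length(x$midline_channels)))
  cat(sprintf("  adjacency: median degree %d\n",
              as.integer(stats::median(rowSums(x$adjacency)))))
  invisible(x)
}

#' Write / read a montage as TSV
#'
#' Plain-text interchange: columns `name`, `x`, `y`, `z`, `mirror_of` (empty
#' for midline channels) and `is_midline`. The adjacency relation is rebuilt
#' from positions on read.
#'
#' @param montage a `montage` object.
#' @param path file path.
#' @return `write_montage` returns `path` invisibly; `read_montage` returns a
#'   `montage`.
#' @export
write_montage <- function(montage, path) {
  mirror_of <- rep("", length(montage$channel_names))
  mirror_of[match(montage$mirror_pairs$left, montage$channel_names)] <- montage$mirror_pairs$right
  mirror_of[match(montage$mirror_pairs$right, montage$channel_names)] <- montage$mirror_pairs$left
  df <- data.frame(name = montage$channel_names,
                   x = montage$positions[, 1],
                   y = montage$positions[, 2],
                   z = montage$positions[, 3],
                   mirror_of = mirror_of,
                   is_midline = montage$channel_names %in% montage$midline_channels)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  rownames(pos) <- df$name
  lefts <- df$name[!df$is_midline & df$x < 0]
  mirror_pairs <- data.frame(left = lefts,
                             right = df$mirror_of[match(lefts, df$name)])
  structure(list(channel_names = df$name,
                 positions = pos,
                 mirror_pairs = mirror_pairs,
                 midline_channels = df$name[df$is_midline],
                 adjacency = build_adjacency(pos)),
            class = "montage")
}
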