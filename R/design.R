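# Experiment design generation: trial structure, blocks, stimulus orientations.

#' Specify an experiment design
#'
#' Collects the design constants of a retro-cue study with two lateralized
#' oriented items per trial: per-participant trial counts for the cued and
#' non-cued conditions, block size, and the orientation sampling constraints
#' (minimum/maximum pairwise difference, exclusion zone around the cardinal
#' axes). Defaults reproduce the full study design: 576 cued + 288 non-cued
#' trials per participant in blocks of 48, orientation differences between 10
#' and 120 degrees, and a +-5 degree cardinal exclusion.
#'
#' @param n_participants number of participants.
#' @param n_cued_trials cued trials per participant (divisible by `block_size`).
#' @param n_uncued_trials non-cued trials per participant (divisible by
#'   `block_size`).
#' @param block_size trials per homogeneous block.
#' @param orientation_min_diff minimum circular target-distractor difference,
#'   degrees.
#' @param orientation_max_diff maximum circular target-distractor difference,
#'   degrees.
#' @param cardinal_exclusion_halfwidth half-width in degrees of the exclusion
#'   zone around 0/90/180/270 degrees.
#' @param seed integer seed; the design is deterministic given the seed.
#' @return an object of class `"design_spec"` (a validated list).
#' @export
design_spec <- function(n_participants = 39,
                        n_cued_trials = 576,
                        n_uncued_trials = 288,
                        block_size = 48,
                        orientation_min_diff = 10,
                        orientation_max_diff = 120,
                        cardinal_exclusion_halfwidth = 5,
                        seed = 1L) {
  spec <- list(n_participants = as.integer(n_participants),
               n_cued_trials = as.integer(n_cued_trials),
               n_uncued_trials = as.integer(n_uncued_trials),
               block_size = as.integer(block_size),
               orientation_min_diff = orientation_min_diff,
               orientation_max_diff = orientation_max_diff,
               cardinal_exclusion_halfwidth = cardinal_exclusion_halfwidth,
               seed = as.integer(seed))
  validate_design_spec(spec)
  structure(spec, class = "design_spec")
}

validate_design_spec <- function(spec) {
  with(spec, {
    if (n_participants < 1) stop("design_spec: n_participants must be >= 1")
    if (n_cued_trials %% block_size != 0 || n_uncued_trials %% block_size != 0) {
      stop("design_spec: trial counts must be divisible by block_size")
    }
    if (!(orientation_min_diff > 0 && orientation_min_diff < orientation_max_diff &&
          orientation_max_diff <= 180)) {
      stop("design_spec: need 0 < orientation_min_diff < orientation_max_diff <= 180")
    }
    if (cardinal_exclusion_halfwidth < 0) {
      stop("design_spec: cardinal_exclusion_halfwidth must be >= 0")
    }
    if (cardinal_exclusion_halfwidth >= 45) {
      stop("design_spec: cardinal exclusion zones cover the whole circle")
    }
  })
  invisible(spec)
}

# TRUE for integer orientations (1..360) outside the cardinal exclusion zones.
orientation_admissible <- function(theta, halfwidth) {
  if (halfwidth <= 0) return(rep(TRUE, length(theta)))
  d <- pmin(circ_dist(theta, 0), circ_dist(theta, 90),
            circ_dist(theta, 180), circ_dist(theta, 270))
  d > halfwidth
}

# Rejection-sample one admissible (target, distractor) orientation pair.
sample_orientation_pair <- function(spec, max_reject = 1e4) {
  for (i in seq_len(max_reject)) {
    pair <- sample.int(360, 2, replace = TRUE)
    if (!all(orientation_admissible(pair, spec$cardinal_exclusion_halfwidth))) next
    d <- circ_dist(pair[1], pair[2])
    if (d >= spec$orientation_min_diff && d <= spec$orientation_max_diff) return(pair)
  }
  stop("generate_design(): orientation constraints unsatisfiable (rejection cap reached)")
}

#' Generate a trial table from a design specification
#'
#' Produces one row per trial for every participant: block structure
#' (homogeneous cued / non-cued blocks in randomized order, split over two
#' sessions), cue side (balanced 50/50 over cued trials, pseudo-randomized),
#' probed side (equal to the cue side on cued trials, balanced 50/50 on
#' non-cued trials), and target/distractor orientations drawn uniformly from
#' the admissible set (pairwise difference within bounds, cardinal axes
#' excluded). Responses are not filled in; see [simulate_responses()].
#'
#' @param spec a [design_spec()].
#' @return a data frame (trial table) with columns `participant_id`, `session`,
#'   `block`, `trial_id`, `condition` ("cued"/"non-cued"), `cue_side`
#'   ("left"/"right"/"none"), `probed_side`, `target_orientation`,
#'   `distractor_orientation`, `response_orientation` (NA), `signed_error`
#'   (NA). Deterministic given `spec$seed`.
#' @examples
#' head(generate_design(design_spec(n_participants = 1, seed = 7)))
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  validate_design_spec(spec)
  with_seed(spec$seed, {
    per_participant <- lapply(seq_len(spec$n_participants), function(pid) {
      n_cb <- spec$n_cued_trials / spec$block_size
      n_ub <- spec$n_uncued_trials / spec$block_size
      block_cond <- sample(rep(c("cued", "non-cued"), c(n_cb, n_ub)))
      n_blocks <- length(block_cond)
      session <- rep(1:2, length.out = 0)
      # split blocks over two sessions as evenly as possible, first half = session 1
      session_of_block <- rep(1L, n_blocks)
      session_of_block[seq_len(n_blocks) > ceiling(n_blocks / 2)] <- 2L

      # balanced pseudo-random sides within condition
      side_pool <- list(
        cued = sample(rep(c("left", "right"), spec$n_cued_trials / 2)),
        `non-cued` = sample(rep(c("left", "right"), spec$n_uncued_trials / 2))
      )
      used <- c(cued = 0L, `non-cued` = 0L)

      rows <- vector("list", n_blocks)
      trial_counter <- 0L
      for (b in seq_len(n_blocks)) {
        cond <- block_cond[b]
        idx <- used[[cond]] + seq_len(spec$block_size)
        used[[cond]] <- used[[cond]] + spec$block_size
        sides <- side_pool[[cond]][idx]
        ori <- t(vapply(seq_len(spec$block_size),
                        function(i) sample_orientation_pair(spec), integer(2)))
        rows[[b]] <- data.frame(
          participant_id = pid,
          session = session_of_block[b],
          block = b,
          trial_id = trial_counter + seq_len(spec$block_size),
          condition = cond,
          cue_side = if (cond == "cued") sides else "none",
          probed_side = sides,
          target_orientation = ori[, 1],
          distractor_orientation = ori[, 2],
          response_orientation = NA_real_,
          signed_error = NA_real_
        )
        trial_counter <- trial_counter + spec$block_size
      }
      do.call(rbind, rows)
    })
    out <- do.call(rbind, per_participant)
    rownames(out) <- NULL
    out
  })
}
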