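#' Specify a latent functional-connectivity state
#'
#' A latent state is a target correlation structure for the ROI signals:
#' blocks of ROIs (emulating resting-state networks) share a within-block
#' correlation, distinct blocks share a weaker between-block correlation, and
#' a global `strength_scale` multiplies all off-diagonal correlations.  The
#' "abnormal" state used by the cohort generator has lower strength, a
#' flatter block contrast and a per-epoch random strength jitter, which
#' plants the decreased connectivity strength and increased connectivity
#' variability that the downstream state analysis is designed to detect.
#'
#' @param label `"normal"` or `"abnormal"`.
#' @param within_block_corr target correlation inside a block, in (-1, 1).
#' @param between_block_corr target correlation across blocks, in (-1, 1).
#' @param strength_scale multiplier applied to all off-diagonal correlations.
#' @param noise_sd standard deviation of i.i.d. observation noise added on
#'   top of the latent signal (the latent signal has unit variance).
#' @param jitter_band length-2 numeric: per-epoch strength multipliers are
#'   drawn uniformly from this interval. `c(1, 1)` disables jitter.
#' @return An object of class `state_spec`.
#' @export
state_spec <- function(label = c("normal", "abnormal"),
                       within_block_corr = 0.5,
                       between_block_corr = 0.1,
                       strength_scale = 1,
                       noise_sd = 0.2,
                       jitter_band = c(1, 1)) {
  label <- match.arg(label)
  stopifnot(
    abs(within_block_corr) < 1, abs(between_block_corr) < 1,
    is.numeric(strength_scale), length(strength_scale) == 1L,
    noise_sd >= 0,
    length(jitter_band) == 2L, jitter_band[1] <= jitter_band[2],
    jitter_band[1] >= 0
  )
  structure(
    list(label = label,
         within_block_corr = within_block_corr,
         between_block_corr = between_block_corr,
         strength_scale = strength_scale,
         noise_sd = noise_sd,
         jitter_band = jitter_band),
    class = "state_spec"
  )
}

#' Specify a synthetic cohort
#'
#' Defines the study conditions emulated by the generator: two groups of
#' subjects (healthy-control-like and decline-like) whose ROI time series
#' switch, on epochs aligned to the sliding-window stride, between a normal
#' and an abnormal latent covariance state.  The decline-like group dwells in
#' the abnormal state with higher probability.  Defaults mirror the imaging
#' protocol the pipeline targets: 488 volumes at TR 0.8 s with the first 8
#' volumes discarded downstream, and 20-volume (16 s) epochs matching the
#' default window stride.
#'
#' @param n_hc,n_scd subjects per group.
#' @param scales integer vector of parcellation scales (ROI counts); each
#'   scale gets its own time series sharing the subject's latent sequence.
#' @param n_volumes volumes per scan.
#' @param tr_seconds sampling interval.
#' @param epoch_volumes latent-state epoch length, in volumes.
#' @param burnin_volumes leading volumes generated from the first epoch's
#'   state (discarded by the windowing stage).
#' @param dwell_abnormal_hc,dwell_abnormal_scd per-epoch probability of the
#'   abnormal state in each group; the decline group must dwell at least as
#'   often.
#' @param normal_state,abnormal_state `state_spec` objects.
#' @param n_blocks number of RSN-like blocks.
#' @param score_intercept,score_slope,score_noise_sd synthetic psychometric
#'   score model: `score = intercept + slope * abnormal_dwell_fraction +
#'   N(0, noise)`; the default slope is negative so higher abnormal dwell
#'   maps to worse scores.
#' @param seed integer seed controlling every random draw.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 60, n_scd = 60,
                        scales = c(100L, 200L, 300L),
                        n_volumes = 488L, tr_seconds = 0.8,
                        epoch_volumes = 20L, burnin_volumes = 8L,
                        dwell_abnormal_hc = 0.2, dwell_abnormal_scd = 0.7,
                        normal_state = state_spec("normal"),
                        abnormal_state = state_spec(
                          "abnormal",
                          within_block_corr = 0.30,
                          between_block_corr = 0.15,
                          strength_scale = 0.8,
                          jitter_band = c(0.55, 1.45)),
                        n_blocks = 7L,
                        score_intercept = 100, score_slope = -30,
                        score_noise_sd = 2,
                        seed = 1L) {
  stopifnot(
    n_hc >= 1, n_scd >= 1, all(scales >= n_blocks),
    n_volumes > burnin_volumes + epoch_volumes,
    dwell_abnormal_hc >= 0, dwell_abnormal_hc <= 1,
    dwell_abnormal_scd >= 0, dwell_abnormal_scd <= 1,
    inherits(normal_state, "state_spec"),
    inherits(abnormal_state, "state_spec")
  )
  if (dwell_abnormal_scd < dwell_abnormal_hc)
    stop("dwell_abnormal_scd must be >= dwell_abnormal_hc (planted group effect)")
  structure(
    list(n_hc = as.integer(n_hc), n_scd = as.integer(n_scd),
         scales = as.integer(scales),
         n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
         epoch_volumes = as.integer(epoch_volumes),
         burnin_volumes = as.integer(burnin_volumes),
         dwell_abnormal_hc = dwell_abnormal_hc,
         dwell_abnormal_scd = dwell_abnormal_scd,
         normal_state = normal_state, abnormal_state = abnormal_state,
         n_blocks = as.integer(n_blocks),
         score_intercept = score_intercept, score_slope = score_slope,
         score_noise_sd = score_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Assign ROIs to contiguous, balanced blocks
#'
#' Splits `R` ROIs into `n_blocks` blocks whose sizes differ by at most one,
#' emulating the preservation of the seven canonical resting-state networks
#' across parcellation scales.  Blocks are contiguous in ROI index; the seed
#' only randomizes which blocks receive the extra ROI when `R` is not a
#' multiple of `n_blocks`.
#'
#' @param R number of ROIs.
#' @param n_blocks number of blocks (default 7).
#' @param seed integer seed.
#' @return integer vector of length `R` with block ids in `1:n_blocks`.
#' @export
make_block_partition <- function(R, n_blocks = 7L, seed = 1L) {
  R <- as.integer(R); n_blocks <- as.integer(n_blocks)
  if (R < n_blocks) stop("R must be at least n_blocks")
  base <- R %/% n_blocks
  extra <- R %% n_blocks
  sizes <- rep(base, n_blocks)
  if (extra > 0) {
    idx <- with_local_seed(seed, sample.int(n_blocks, extra))
    sizes[idx] <- sizes[idx] + 1L
  }
  rep(seq_len(n_blocks), times = sizes)
}

#' Hemisphere/RSN membership table for a synthetic parcellation
#'
#' Pairs each ROI of a block partition with a hemisphere (alternating L/R
#' within block) and one of the seven canonical RSN labels, in the format
#' expected by [read_membership()] and [rsn_proportions()].
#'
#' @param partition block assignment from [make_block_partition()].
#' @return data.frame with columns `roi_id`, `hemisphere`, `rsn`.
#' @export
synthetic_membership <- function(partition) {
  stopifnot(max(partition) <= length(rsn_labels()))
  hemi <- unlist(lapply(split(seq_along(partition), partition), function(ix) {
    rep_len(c("L", "R"), length(ix))
  }), use.names = FALSE)
  hemi_full <- character(length(partition))
  hemi_full[order(unlist(split(seq_along(partition), partition),
                         use.names = FALSE))] <- hemi
  data.frame(
    roi_id = paste0("ROI", seq_along(partition)),
    hemisphere = hemi_full,
    rsn = rsn_labels()[partition],
    stringsAsFactors = FALSE
  )
}

#' Canonical resting-state network labels
#' @return character vector of the 7 RSN acronyms.
#' @export
rsn_labels <- function() {
  c("DMN", "ECN", "LIM", "SAN", "DAN", "SM", "VIS")
}

#' Latent-state correlation matrix
#'
#' Builds the block-structured correlation matrix implied by a `state_spec`:
#' unit diagonal, `within_block_corr * strength_scale` inside blocks and
#' `between_block_corr * strength_scale` across blocks.  If the result is not
#' positive definite it is repaired by diagonal loading and the epsilon used
#' is recorded in the `"loading"` attribute.
#'
#' @param spec a [state_spec()].
#' @param partition block assignment from [make_block_partition()].
#' @param strength_multiplier extra multiplier on off-diagonals (the
#'   per-epoch jitter); default 1.
#' @return R x R correlation matrix, attribute `"loading"` if repaired.
#' @export
state_covariance <- function(spec, partition, strength_multiplier = 1) {
  stopifnot(inherits(spec, "state_spec"))
  R <- length(partition)
  same <- outer(partition, partition, "==")
  C <- matrix(spec$between_block_corr, R, R)
  C[same] <- spec$within_block_corr
  C <- C * spec$strength_scale * strength_multiplier
  diag(C) <- 1
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) {
    eps <- 1e-8 - ev_min
    C <- C + diag(eps, R)
    ev2 <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev2 <= 0) stop("state covariance not positive definite after loading")
    attr(C, "loading") <- eps
  }
  C
}

# Run expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one subject's multiscale ROI time series
#'
#' Samples a latent normal/abnormal state per epoch from the group's dwell
#' probability, then draws each epoch's signal from a zero-mean multivariate
#' Gaussian with that state's covariance (plus observation noise).  All
#' scales share the latent sequence; each scale has its own noise stream.
#' Identical `(cohort, class_label, seed)` gives identical output.
#'
#' @param cohort a [cohort_spec()].
#' @param class_label `"HC"` or `"SCD"`.
#' @param seed integer seed for this subject.
#' @param subject_id optional id string.
#' @return list with `timeseries` (named list of [roi_timeseries()] per
#'   scale), `states` (integer vector, 1 = abnormal, per epoch), and
#'   `abnormal_fraction`.
#' @export
simulate_subject <- function(cohort, class_label = c("HC", "SCD"), seed,
                             subject_id = "synthetic") {
  stopifnot(inherits(cohort, "cohort_spec"))
  class_label <- match.arg(class_label)
  dwell <- if (class_label == "SCD") cohort$dwell_abnormal_scd else cohort$dwell_abnormal_hc
  n_body <- cohort$n_volumes - cohort$burnin_volumes
  n_epochs <- ceiling(n_body / cohort$epoch_volumes)

  with_local_seed(seed, {
    states <- as.integer(stats::runif(n_epochs) < dwell)
    jitters <- vapply(states, function(s) {
      band <- if (s == 1L) cohort$abnormal_state$jitter_band else cohort$normal_state$jitter_band
      stats::runif(1, band[1], band[2])
    }, numeric(1))

    ts_list <- lapply(cohort$scales, function(R) {
      partition <- make_block_partition(R, cohort$n_blocks, seed = cohort$seed)
      # cache cholesky per (state, jitter): normal state usually unjittered
      chol_cache <- new.env(parent = emptyenv())
      get_chol <- function(s, jit) {
        key <- sprintf("%d_%.12g", s, jit)
        if (is.null(chol_cache[[key]])) {
          sp <- if (s == 1L) cohort$abnormal_state else cohort$normal_state
          chol_cache[[key]] <- chol(state_covariance(sp, partition, jit))
        }
        chol_cache[[key]]
      }
      draw_epoch <- function(n, s, jit) {
        sp <- if (s == 1L) cohort$abnormal_state else cohort$normal_state
        X <- matrix(stats::rnorm(n * R), n, R) %*% get_chol(s, jit)
        if (sp$noise_sd > 0) X <- X + matrix(stats::rnorm(n * R, sd = sp$noise_sd), n, R)
        X
      }
      blocks <- vector("list", n_epochs + 1L)
      blocks[[1L]] <- draw_epoch(cohort$burnin_volumes, states[1L], jitters[1L])
      remaining <- n_body
      for (e in seq_len(n_epochs)) {
        n_e <- min(cohort$epoch_volumes, remaining)
        blocks[[e + 1L]] <- draw_epoch(n_e, states[e], jitters[e])
        remaining <- remaining - n_e
      }
      roi_timeseries(do.call(rbind, blocks), tr_seconds = cohort$tr_seconds,
                     subject_id = subject_id)
    })
    names(ts_list) <- paste0("scale", cohort$scales)
    list(timeseries = ts_list, states = states,
         abnormal_fraction = mean(states))
  })
}

#' Generate a full synthetic cohort
#'
#' Simulates `n_hc + n_scd` subjects at every scale, with per-subject latent
#' ground truth and a synthetic psychometric score that decreases (by
#' default) with the realized abnormal dwell fraction, so the planted
#' brain-behaviour association is recoverable by [psychometric_association()].
#'
#' @param cohort a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `subjects` (table of
#'   id, group, label, score, abnormal_fraction), `timeseries`
#'   (`timeseries[[scale]][[subject]]`), `states` (per-subject epoch
#'   sequences), `partitions` and `membership` per scale, and the `spec`.
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n_hc + cohort$n_scd
  groups <- rep(c("HC", "SCD"), c(cohort$n_hc, cohort$n_scd))
  ids <- sprintf("sub%03d", seq_len(n))
  sub_seeds <- with_local_seed(cohort$seed, sample.int(.Machine$integer.max - 1L, n))
  sims <- lapply(seq_len(n), function(i) {
    simulate_subject(cohort, groups[i], seed = sub_seeds[i], subject_id = ids[i])
  })
  frac <- vapply(sims, `[[`, numeric(1), "abnormal_fraction")
  scores <- with_local_seed(cohort$seed + 1L,
    cohort$score_intercept + cohort$score_slope * frac +
      stats::rnorm(n, sd = cohort$score_noise_sd))
  partitions <- lapply(cohort$scales, make_block_partition,
                       n_blocks = cohort$n_blocks, seed = cohort$seed)
  names(partitions) <- paste0("scale", cohort$scales)
  timeseries <- lapply(names(partitions), function(sc) {
    lapply(sims, function(s) s$timeseries[[sc]])
  })
  names(timeseries) <- names(partitions)
  structure(
    list(subjects = data.frame(subject_id = ids, group = groups,
                               label = as.integer(groups == "SCD"),
                               score = scores, abnormal_fraction = frac,
                               stringsAsFactors = FALSE),
         timeseries = timeseries,
         states = lapply(sims, `[[`, "states"),
         partitions = partitions,
         membership = lapply(partitions, synthetic_membership),
         spec = cohort),
    class = "synthetic_cohort"
  )
}

#' Ground-truth abnormality fraction per sliding window
#'
#' Maps a subject's per-epoch latent states onto sliding windows: each
#' window's value is the fraction of its volumes generated under the
#' abnormal state.  A window is conventionally called abnormal when the
#' fraction exceeds 0.5.
#'
#' @param states per-epoch latent sequence from [simulate_subject()].
#' @param cohort the [cohort_spec()] used.
#' @param window a [window_spec()]; its `drop_initial_volumes` must equal the
#'   cohort's `burnin_volumes`.
#' @return numeric vector of length T of abnormal-volume fractions.
#' @export
window_ground_truth <- function(states, cohort, window = window_spec()) {
  w_vol <- volumes_from_seconds(window$window_seconds, cohort$tr_seconds)
  s_vol <- volumes_from_seconds(window$stride_seconds, cohort$tr_seconds)
  n_body <- cohort$n_volumes - cohort$burnin_volumes
  per_vol <- rep(states, each = cohort$epoch_volumes)[seq_len(n_body)]
  T_n <- count_windows(n_body, window, cohort$tr_seconds)
  vapply(seq_len(T_n), function(t) {
    mean(per_vol[(t - 1L) * s_vol + seq_len(w_vol)])
  }, numeric(1))
}
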