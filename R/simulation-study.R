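#' End-to-end simulation study on a planted synthetic cohort
#'
#' Runs the full pipeline the package implements on one seeded synthetic
#' cohort: multiscale dFCN construction, 5-fold cross-validated single-scale
#' G-L-A classification, multiscale fusion (majority voting, nested weighted
#' voting and nested feature fusion), permutation significance, and the
#' attention-driven state analysis (state labeling against planted ground
#' truth, edge-wise strength/variability comparisons, modularity and global
#' efficiency of thresholded states, transition properties and their
#' association with the synthetic psychometric score).
#'
#' Fusion heads are trained per fold on training-fold subjects only, using
#' the fold model's frozen outputs, and applied to the held-out fold.
#'
#' @param seed master seed; every random draw derives from it.
#' @param scales parcellation scales to simulate.
#' @param n_hc,n_scd group sizes.
#' @param dwell_hc,dwell_scd per-epoch abnormal-state probabilities.
#' @param epochs training epochs per fold model.
#' @param d,a model widths (see [gla_config()]).
#' @param gate_activation LSTM gate nonlinearity used for training.
#' @param k cross-validation folds.
#' @param n_metric_states states sampled per group and scale for the
#'   network-metric comparison.
#' @param n_perm permutations for the majority-vote significance test.
#' @param edge_scale scale (index into `scales`) at which the edge-wise
#'   comparison is run.
#' @param verbose print progress.
#' @return a list of results; see the individual components' names.
#' @export
run_simulation_study <- function(seed = 1L,
                                 scales = c(100L, 200L, 300L),
                                 n_hc = 60L, n_scd = 60L,
                                 dwell_hc = 0.2, dwell_scd = 0.7,
                                 epochs = 15L, d = 8L, a = 4L,
                                 gate_activation = "sigmoid",
                                 k = 5L, n_metric_states = 60L,
                                 n_perm = 1000L, edge_scale = 1L,
                                 verbose = TRUE) {
  t_start <- Sys.time()
  say <- function(...) if (verbose)
    message(sprintf("[%6.1fs] ", as.numeric(Sys.time() - t_start, units = "secs")),
            sprintf(...))
  spec <- cohort_spec(n_hc = n_hc, n_scd = n_scd, scales = scales,
                      dwell_abnormal_hc = dwell_hc,
                      dwell_abnormal_scd = dwell_scd, seed = seed)
  say("generating cohort (%d subjects, scales %s)...",
      n_hc + n_scd, paste(scales, collapse = "/"))
  cohort <- generate_cohort(spec)
  labels <- cohort$subjects$label
  n <- length(labels)
  wspec <- window_spec()
  gt_frac <- do.call(rbind, lapply(cohort$states, window_ground_truth,
                                   cohort = spec, window = wspec))
  gt_abnormal <- gt_frac > 0.5
  folds <- make_folds(labels, k = k, seed = seed + 17L)

  per_scale <- list()
  for (si in seq_along(scales)) {
    sc <- scales[si]
    sc_name <- paste0("scale", sc)
    say("scale %d: building dFCNs...", sc)
    dfcns <- lapply(cohort$timeseries[[sc_name]], build_dfcn, spec = wspec)
    cohort$timeseries[[sc_name]] <- NULL
    cfg <- train_config(epochs = epochs,
                        model = gla_config(d = d, a = a,
                                           gate_activation = gate_activation),
                        seed = seed + 100L * si)
    say("scale %d: %d-fold cross-validation (%d epochs)...", sc, k, epochs)
    cv <- crossval_single_scale(dfcns, labels, cfg, folds = folds)
    say("scale %d: CV AUROC %.3f", sc, cv$metrics$auroc)

    z <- normalize_attention(cv$attention)
    st_labels <- label_states(z)

    # network metrics on a seeded subsample of labeled states
    flat_lab <- as.integer(st_labels)
    pick <- function(lab_val, m) {
      ix <- which(flat_lab == lab_val)
      if (length(ix) > m)
        ix <- with_local_seed(seed + 7L * si + lab_val,
                              sample(ix, m))
      ix
    }
    get_state <- function(ix) {
      sub <- (ix - 1L) %% n + 1L
      win <- (ix - 1L) %/% n + 1L
      dfcns[[sub]]$A[, , win]
    }
    metric_of <- function(ix) {
      A <- threshold_fc(get_state(ix), 0)
      Q <- tryCatch(modularity_partition(A)$Q, error = function(e) NA_real_)
      c(efficiency = global_efficiency(A), modularity = Q)
    }
    say("scale %d: network metrics on labeled states...", sc)
    ix_norm <- pick(0L, n_metric_states)
    ix_scd <- pick(1L, n_metric_states)
    mn <- vapply(ix_norm, metric_of, numeric(2))
    ms <- vapply(ix_scd, metric_of, numeric(2))

    edge_res <- NULL
    if (si == edge_scale) {
      say("scale %d: edge-wise strength/variability comparison...", sc)
      all_states <- lapply(seq_len(n * dfcns[[1]]$T), get_state)
      edge_res <- edge_comparison(all_states[flat_lab == 0L],
                                  all_states[flat_lab == 1L])
      rm(all_states)
    }

    per_scale[[sc_name]] <- list(
      scale = sc, T = dfcns[[1]]$T,
      cv_metrics = cv$metrics,
      fold_auroc = vapply(cv$fold_metrics, `[[`, numeric(1), "auroc"),
      probabilities = cv$probabilities, decisions = cv$decisions,
      fold_probs = cv$fold_probs, fold_features = cv$fold_features,
      z_attention = z, state_labels = st_labels,
      transition = transition_properties(z),
      efficiency = list(normal = mn["efficiency", ], scd = ms["efficiency", ]),
      modularity = list(normal = mn["modularity", ], scd = ms["modularity", ]),
      edge = edge_res)
    rm(dfcns); gc(FALSE)
  }

  # --- multiscale fusion (frozen base models) -------------------------------
  say("multiscale fusion...")
  D <- vapply(per_scale, `[[`, integer(n), "decisions")
  maj_prob <- rowMeans(D)
  majority <- list(probability = maj_prob,
                   metrics = compute_metrics(labels, maj_prob))

  wv_prob <- numeric(n); ff_prob <- numeric(n)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    Pf <- vapply(per_scale, function(ps) ps$fold_probs[f, ], numeric(n))
    wfit <- train_weighted_vote(Pf[tr, , drop = FALSE], labels[tr],
                                seed = seed + 31L * f)
    wv_prob[te] <- as.numeric(Pf[te, , drop = FALSE] %*% wfit$weights)
    Ff <- do.call(cbind, lapply(per_scale, function(ps) ps$fold_features[[f]]))
    hfit <- train_feature_fusion(Ff[tr, , drop = FALSE], labels[tr],
                                 seed = seed + 57L * f)
    ff_prob[te] <- feature_fusion(hfit, Ff[te, , drop = FALSE])
  }
  weighted <- list(probability = wv_prob,
                   metrics = compute_metrics(labels, wv_prob))
  feature <- list(probability = ff_prob,
                  metrics = compute_metrics(labels, ff_prob))

  perm <- permutation_test(labels, maj_prob, "auroc", n_perm = n_perm,
                           seed = seed + 5L)

  # --- attention / state recovery against planted ground truth --------------
  ps1 <- per_scale[[1]]
  z1 <- ps1$z_attention
  abn <- gt_abnormal
  attention_gap <- mean(z1[abn]) - mean(z1[!abn])
  pred_abn <- ps1$state_labels == 1L
  tpr <- sum(pred_abn & abn) / sum(abn)
  tnr <- sum(!pred_abn & !abn) / sum(!abn)
  balanced_accuracy <- (tpr + tnr) / 2

  # --- group-level characterization -----------------------------------------
  eff_cmp <- state_metric_comparison(lapply(per_scale, `[[`, "efficiency"))
  mod_vals <- lapply(per_scale, function(ps) {
    lapply(ps$modularity, function(v) v[is.finite(v)])
  })
  mod_cmp <- state_metric_comparison(mod_vals)

  tend <- vapply(per_scale, function(ps) ps$transition$tendency, numeric(n))
  tend_tests <- lapply(seq_along(scales), function(si) {
    rs <- rank_sum_columns(matrix(tend[labels == 1, si]),
                           matrix(tend[labels == 0, si]))
    data.frame(scale = scales[si], Z = rs$z, p_greater = rs$p_greater)
  })
  tend_tests <- do.call(rbind, tend_tests)

  tend_df <- as.data.frame(tend)
  names(tend_df) <- paste0("tendency_", names(per_scale))
  assoc <- psychometric_association(tend_df, cohort$subjects$score,
                                    seed = seed + 23L)

  edge <- per_scale[[edge_scale]]$edge
  edge_counts <- vapply(edge, function(e) sum(e$significant), integer(1))

  list(
    spec = spec, labels = labels, folds = folds,
    subjects = cohort$subjects,
    per_scale = lapply(per_scale, function(ps)
      ps[c("scale", "T", "cv_metrics", "fold_auroc", "probabilities",
           "decisions", "transition")]),
    z_attention = lapply(per_scale, `[[`, "z_attention"),
    state_labels = lapply(per_scale, `[[`, "state_labels"),
    gt_window_fraction = gt_frac,
    fusion = list(majority = majority, weighted = weighted,
                  feature = feature),
    permutation = perm[c("observed", "p_value")],
    attention_gap = attention_gap,
    state_balanced_accuracy = balanced_accuracy,
    efficiency_comparison = eff_cmp,
    modularity_comparison = mod_cmp,
    efficiency_values = lapply(per_scale, `[[`, "efficiency"),
    tendency_tests = tend_tests,
    psychometric = assoc,
    edge_counts = edge_counts,
    edge_tables = edge)
}
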