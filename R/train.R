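#' Training configuration
#'
#' Defaults are the published optima: 100 epochs, learning rate 0.01, batch
#' size 30, Adam with weight decay 0.001, weighted cross-entropy with class
#' weights inverse to the training-fold sample ratio.
#'
#' @param epochs,learning_rate,batch_size,weight_decay optimizer settings.
#' @param model a [gla_config()].
#' @param seed integer seed for initialization and batch shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 0.01,
                         batch_size = 30L, weight_decay = 0.001,
                         model = gla_config(), seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, model = model,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a single-scale G-L-A model
#'
#' Minibatch Adam on the weighted cross-entropy; class weights are derived
#' from the supplied (training) labels only.  Aborts if the loss becomes
#' non-finite.
#'
#' @param dfcns list of [build_dfcn()] tensors (one scale).
#' @param labels 0/1 vector (1 = SCD).
#' @param config a [train_config()].
#' @param verbose print per-epoch loss.
#' @return list with `params` (trained [gla_init()] set), `loss_curve`
#'   (per-epoch weighted mean loss) and `class_weights`.
#' @export
train_single_scale <- function(dfcns, labels, config = train_config(),
                               verbose = FALSE) {
  stopifnot(length(dfcns) == length(labels))
  R <- if (inherits(dfcns[[1]], "dfcn_tensor")) dfcns[[1]]$R else dim(dfcns[[1]])[1]
  cw <- class_weights_from_labels(labels)
  params <- gla_init(R, config$model, seed = config$seed)
  kind <- config$model$gate_activation
  st <- adam_state(params)
  n <- length(dfcns)
  pre <- precompute_stacks(dfcns)
  w_subj <- cw[labels + 1L]
  loss_curve <- numeric(config$epochs)
  with_local_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_w <- 0
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        bp <- gla_batch_pass_fast(pre, labels, w_subj, params, idx, kind)
        if (!is.finite(bp$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        upd <- adam_update(params, bp$grads, st, lr = config$learning_rate,
                           weight_decay = config$weight_decay)
        params <- upd$params; st <- upd$state
        ep_loss <- ep_loss + bp$loss * bp$w_sum; ep_w <- ep_w + bp$w_sum
      }
      loss_curve[ep] <- ep_loss / ep_w
      if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, loss_curve[ep]))
    }
  })
  list(params = params, loss_curve = loss_curve, class_weights = cw)
}

#' Predicted SCD probabilities for a set of subjects
#'
#' @param params trained [gla_init()] parameter set.
#' @param dfcns list of dFCN tensors.
#' @return numeric vector of P(SCD).
#' @export
gla_predict <- function(params, dfcns) {
  vapply(dfcns, function(d) gla_forward(d, params)$prob[2L], numeric(1))
}

#' Raw (unnormalized) attention scores for a set of subjects
#'
#' Returns the per-window unnormalized attention `w %*% tanh(V m_t)` whose
#' amplitude indexes how decline-related each window's state is.  Softmax
#' is sign-ambiguous, so by default the sign is fixed per model by
#' correlating subject-mean raw scores with the predicted SCD probability
#' and flipping if the correlation is negative.
#'
#' @param params trained [gla_init()] parameter set.
#' @param dfcns list of dFCN tensors.
#' @param sign_correct fix the sign convention (larger = more SCD-related).
#' @return n x T matrix of raw attention scores; attribute `"sign"` records
#'   the factor applied.
#' @export
gla_attention <- function(params, dfcns, sign_correct = TRUE) {
  fw <- lapply(dfcns, gla_forward, params = params)
  raw <- do.call(rbind, lapply(fw, `[[`, "raw"))
  sgn <- 1
  if (sign_correct) {
    probs <- vapply(fw, function(f) f$prob[2L], numeric(1))
    means <- rowMeans(raw)
    if (stats::sd(means) > 0 && stats::sd(probs) > 0) {
      r <- stats::cor(means, probs)
      if (is.finite(r) && r < 0) sgn <- -1
    }
    raw <- sgn * raw
  }
  attr(raw, "sign") <- sgn
  raw
}

#' Stratified cross-validation fold plan
#'
#' Randomly assigns subjects to `k` folds whose sizes differ by at most one;
#' by default the assignment is stratified by class so every fold contains
#' both classes (plain random assignment available).
#'
#' @param labels 0/1 vector.
#' @param k folds (default 5).
#' @param seed integer seed.
#' @param stratified stratify by class.
#' @return integer vector of fold ids in `1:k`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (n < k) stop("fewer subjects than folds")
  if (stratified && min(table(labels)) < k)
    stop("stratified folds need at least k subjects per class")
  with_local_seed(seed, {
    fold_cycle <- sample.int(k) # random fold order for the size remainder
    folds <- integer(n)
    if (stratified) {
      pos <- 0L
      for (cl in sample(unique(labels))) {
        ix <- sample(which(labels == cl))
        folds[ix] <- fold_cycle[(pos + seq_along(ix) - 1L) %% k + 1L]
        pos <- pos + length(ix)
      }
    } else {
      folds[sample.int(n)] <- fold_cycle[(seq_len(n) - 1L) %% k + 1L]
    }
    folds
  })
}

#' Threshold-free and thresholded classification metrics
#'
#' AUROC by the rank statistic (ties averaged), AUPRC by step integration of
#' the precision-recall curve, sensitivity and specificity at the decision
#' threshold.
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted P(positive).
#' @param threshold decision threshold (default 0.5; positive iff > 0.5).
#' @return list with `auroc`, `auprc`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: need both classes")
  r <- rank(probabilities)
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(probabilities, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  prec <- tp / seq_along(tp)
  rec <- tp / n1
  auprc <- sum(diff(c(0, rec)) * prec)
  pred <- probabilities > threshold
  list(auroc = auroc, auprc = auprc,
       sensitivity = sum(pred & labels == 1) / n1,
       specificity = sum(!pred & labels == 0) / n0)
}

#' Permutation significance of a classification metric
#'
#' Shuffles the ground-truth labels `n_perm` times and recomputes the
#' metric; significance is the probability of the permuted metric reaching
#' the observed one.  The default p-value uses add-one smoothing,
#' `(count + 1) / (n_perm + 1)`, so it is never exactly zero; `smoothed =
#' FALSE` gives the plain fraction.
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted P(positive).
#' @param metric one of `"auroc"`, `"auprc"`, `"sensitivity"`,
#'   `"specificity"`.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param smoothed add-one smoothing for the p-value.
#' @return list with `observed`, `permuted` (length `n_perm`), `p_value`.
#' @export
permutation_test <- function(labels, probabilities, metric = "auroc",
                             n_perm = 1000L, seed = 1L, smoothed = TRUE) {
  stopifnot(n_perm >= 1)
  obs <- compute_metrics(labels, probabilities)[[metric]]
  perm <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      compute_metrics(sample(labels), probabilities)[[metric]]
    }, numeric(1))
  })
  cnt <- sum(perm >= obs)
  p <- if (smoothed) (cnt + 1) / (n_perm + 1) else cnt / n_perm
  list(observed = obs, permuted = perm, p_value = p)
}

#' 5-fold cross-validation of a single-scale G-L-A model
#'
#' Trains one model per fold on the other folds and predicts the held-out
#' fold; class weights are computed per training fold.  Also records each
#' fold model's raw attention over all subjects, as required by the
#' attention z-scoring of the state analysis.
#'
#' @param dfcns list of dFCN tensors (one scale).
#' @param labels 0/1 vector.
#' @param config a [train_config()].
#' @param k folds.
#' @param folds optional precomputed fold plan (from [make_folds()]).
#' @param seed seed for the fold plan and per-fold training seeds.
#' @return list with `probabilities` (out-of-fold P(SCD)), `decisions`,
#'   `folds`, `models` (per fold), `attention` (per-fold n x T raw
#'   attention, sign-corrected), `fold_probs` (k x n matrix of every fold
#'   model's probabilities for all subjects), `fold_features` (per fold,
#'   n x d pooled attention features), `fold_metrics` (per-fold
#'   [compute_metrics()]), `metrics` (pooled out-of-fold metrics).
#' @export
crossval_single_scale <- function(dfcns, labels, config = train_config(),
                                  k = 5L, folds = NULL, seed = config$seed) {
  n <- length(labels)
  if (is.null(folds)) folds <- make_folds(labels, k = k, seed = seed)
  k <- max(folds)
  probs <- numeric(n)
  models <- vector("list", k)
  attention <- vector("list", k)
  fold_probs <- matrix(0, k, n)
  fold_features <- vector("list", k)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    cfg <- config; cfg$seed <- config$seed + f
    fit <- train_single_scale(dfcns[tr], labels[tr], cfg)
    models[[f]] <- fit
    fw <- lapply(dfcns, gla_forward, params = fit$params)
    fold_probs[f, ] <- vapply(fw, function(x) x$prob[2L], numeric(1))
    fold_features[[f]] <- do.call(rbind, lapply(fw, `[[`, "h_att"))
    raw <- do.call(rbind, lapply(fw, `[[`, "raw"))
    sgn <- 1
    if (stats::sd(rowMeans(raw)) > 0 && stats::sd(fold_probs[f, ]) > 0) {
      r <- stats::cor(rowMeans(raw), fold_probs[f, ])
      if (is.finite(r) && r < 0) sgn <- -1
    }
    attention[[f]] <- structure(sgn * raw, sign = sgn)
    probs[te] <- fold_probs[f, te]
    fold_metrics[[f]] <- compute_metrics(labels[te], probs[te])
  }
  list(probabilities = probs, decisions = as.integer(probs > 0.5),
       folds = folds, models = models, attention = attention,
       fold_probs = fold_probs, fold_features = fold_features,
       fold_metrics = fold_metrics,
       metrics = compute_metrics(labels, probs))
}

#' Summarize a metric across cross-validation folds
#'
#' Mean, standard deviation and two confidence intervals for per-fold
#' metric values: a normal-approximate interval and a t-based interval
#' (both are reported since the folds are few).
#'
#' @param values per-fold metric values.
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `sd`, `ci_normal`, `ci_t`.
#' @export
fold_summary <- function(values, level = 0.95) {
  k <- length(values)
  if (k < 2) stop("need at least 2 folds to summarize")
  m <- mean(values); s <- stats::sd(values)
  se <- s / sqrt(k)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tq <- stats::qt(1 - (1 - level) / 2, df = k - 1)
  list(mean = m, sd = s,
       ci_normal = c(m - zq * se, m + zq * se),
       ci_t = c(m - tq * se, m + tq * se))
}

#' Predict an external cohort by cross-fold majority vote
#'
#' Each of the `k` fold models votes on every external subject; the subject
#' probability is the fraction of positive votes and the decision is
#' positive when it exceeds 0.5.  Model parameters are not modified.
#'
#' @param fold_models list of trained fits (as in
#'   `crossval_single_scale()$models`).
#' @param dfcns external dFCN tensors (preprocessed independently).
#' @return list with `probability`, `decision`, and the per-model `votes`
#'   matrix.
#' @export
external_predict <- function(fold_models, dfcns) {
  if (length(fold_models) < 1) stop("need at least one fold model")
  votes <- vapply(fold_models, function(m) {
    as.integer(gla_predict(m$params, dfcns) > 0.5)
  }, integer(length(dfcns)))
  votes <- matrix(votes, nrow = length(dfcns))
  prob <- rowMeans(votes)
  list(probability = prob, decision = as.integer(prob > 0.5), votes = votes)
}
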