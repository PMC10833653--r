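#' Majority voting across single-scale models
#'
#' The prediction probability is the ratio of positive votes to voters and
#' the decision is positive when it exceeds 0.5.  With an odd number of
#' voters ties cannot occur; for an even count a tied 0.5 is conservatively
#' negative.
#'
#' @param decisions binary votes (0/1), one per scale model.
#' @param n_voters expected number of voters (default 5; set to
#'   `length(decisions)` for other panel sizes).
#' @return list with `probability` and `decision`.
#' @export
majority_vote <- function(decisions, n_voters = 5L) {
  if (length(decisions) != n_voters)
    stop(sprintf("expected %d votes, got %d", n_voters, length(decisions)))
  if (!all(decisions %in% c(0, 1))) stop("votes must be binary")
  p <- sum(decisions) / n_voters
  list(probability = p, decision = as.integer(p > 0.5))
}

#' Weighted voting across single-scale probabilities
#'
#' Combines the per-scale SCD probabilities.  In `"simplex"` mode the
#' weights are normalized to sum to one and the output is the convex
#' combination (so equal base probabilities pass through unchanged and a
#' one-hot weight reproduces that scale).  In `"affine"` mode the output is
#' `plogis(bias + sum(w * p))`.
#'
#' @param probabilities per-scale probabilities.
#' @param weights per-scale weights (same length).
#' @param mode `"simplex"` or `"affine"`.
#' @param bias intercept for affine mode.
#' @return combined probability in [0, 1].
#' @export
weighted_vote <- function(probabilities, weights, mode = c("simplex", "affine"),
                          bias = 0) {
  mode <- match.arg(mode)
  stopifnot(length(probabilities) == length(weights))
  if (mode == "simplex") {
    w <- weights / sum(weights)
    sum(w * probabilities)
  } else {
    stats::plogis(bias + sum(weights * probabilities))
  }
}

#' Learn weighted-voting weights on frozen base models
#'
#' Trains the combination weights by Adam on the weighted cross-entropy of
#' the convex combination of the frozen base models' probabilities
#' (10 epochs, learning rate 0.001, batch 30 by default).  The base models
#' are not touched: only their probability outputs enter.
#'
#' @param prob_matrix n x n_scales matrix of per-scale P(SCD) on training
#'   subjects.
#' @param labels 0/1 vector.
#' @param epochs,learning_rate,batch_size optimizer settings.
#' @param seed integer seed.
#' @return list with `weights` (simplex), `logits` (unconstrained), and
#'   `loss_curve`.
#' @export
train_weighted_vote <- function(prob_matrix, labels, epochs = 10L,
                                learning_rate = 0.001, batch_size = 30L,
                                seed = 1L) {
  prob_matrix <- as.matrix(prob_matrix)
  n <- nrow(prob_matrix); k <- ncol(prob_matrix)
  cw <- class_weights_from_labels(labels)
  v <- numeric(k)
  m <- numeric(k); s <- numeric(k); step <- 0L
  eps <- 1e-12
  loss_curve <- numeric(epochs)
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_l <- 0; ep_w <- 0
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        w_soft <- exp(v - max(v)); w_soft <- w_soft / sum(w_soft)
        p <- pmin(pmax(as.numeric(prob_matrix[idx, , drop = FALSE] %*% w_soft),
                       eps), 1 - eps)
        y <- labels[idx]
        wt <- cw[y + 1L]
        dp <- ifelse(y == 1, -wt / p, wt / (1 - p)) / sum(wt)
        # d p_i / d v_j through the softmax weights
        dw <- as.numeric(crossprod(prob_matrix[idx, , drop = FALSE], dp))
        gv <- w_soft * (dw - sum(w_soft * dw))
        step <- step + 1L
        m <- 0.9 * m + 0.1 * gv
        s <- 0.999 * s + 0.001 * gv^2
        v <- v - learning_rate * (m / (1 - 0.9^step)) /
          (sqrt(s / (1 - 0.999^step)) + 1e-8)
        li <- ifelse(y == 1, -wt * log(p), -wt * log(1 - p))
        ep_l <- ep_l + sum(li); ep_w <- ep_w + sum(wt)
      }
      loss_curve[ep] <- ep_l / ep_w
    }
  })
  w_soft <- exp(v - max(v)); w_soft <- w_soft / sum(w_soft)
  list(weights = w_soft, logits = v, loss_curve = loss_curve)
}

# --- feature fusion head ----------------------------------------------------

#' Initialize the feature-fusion head
#'
#' Two dense layers with batch normalization after the first, then softmax:
#' the concatenated pooled attention features of the frozen single-scale
#' models enter a hidden layer (BN + ReLU) and a final 2-class layer.
#'
#' @param input_dim concatenated feature width (`n_scales * d`).
#' @param hidden hidden width.
#' @param seed integer seed.
#' @return object of class `fusion_head`.
#' @export
fusion_head_init <- function(input_dim, hidden = 32L, seed = 1L) {
  with_local_seed(seed, {
    structure(list(
      W1 = init_mat(hidden, input_dim, input_dim), b1 = numeric(hidden),
      gamma = rep(1, hidden), beta = numeric(hidden),
      run_mean = numeric(hidden), run_var = rep(1, hidden),
      W2 = init_mat(2, hidden, hidden), b2 = numeric(2),
      hidden = as.integer(hidden), input_dim = as.integer(input_dim)),
      class = "fusion_head")
  })
}

fusion_head_forward <- function(head, X, train = FALSE, bn_eps = 1e-5) {
  Z1 <- X %*% t(head$W1) + matrix(head$b1, nrow(X), head$hidden, byrow = TRUE)
  if (train) {
    mu <- colMeans(Z1)
    va <- colMeans(sweep(Z1, 2, mu)^2)
  } else {
    mu <- head$run_mean; va <- head$run_var
  }
  xhat <- sweep(sweep(Z1, 2, mu), 2, sqrt(va + bn_eps), "/")
  Zb <- sweep(sweep(xhat, 2, head$gamma, "*"), 2, head$beta, "+")
  Hr <- pmax(Zb, 0)
  logits <- Hr %*% t(head$W2) + matrix(head$b2, nrow(X), 2, byrow = TRUE)
  ex <- exp(logits - apply(logits, 1, max))
  P <- ex / rowSums(ex)
  list(P = P, Z1 = Z1, mu = mu, va = va, xhat = xhat, Zb = Zb, Hr = Hr)
}

#' Train the feature-fusion head
#'
#' Adam on the weighted cross-entropy for 10 epochs at learning rate 0.001,
#' batch 30 (defaults as published); batch statistics are used during
#' training and exponential running statistics at prediction time.  Only the
#' head is trainable; base models are frozen upstream.
#'
#' @param features n x input_dim matrix of concatenated `h_ATT` features.
#' @param labels 0/1 vector.
#' @param hidden hidden width.
#' @param epochs,learning_rate,batch_size optimizer settings.
#' @param seed integer seed.
#' @return trained `fusion_head` with `loss_curve` attribute.
#' @export
train_feature_fusion <- function(features, labels, hidden = 32L,
                                 epochs = 10L, learning_rate = 0.001,
                                 batch_size = 30L, seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  head <- fusion_head_init(ncol(X), hidden = hidden, seed = seed)
  cw <- class_weights_from_labels(labels)
  nms <- c("W1", "b1", "gamma", "beta", "W2", "b2")
  m <- lapply(head[nms], function(p) p * 0)
  v <- m; step <- 0L
  bn_eps <- 1e-5; momentum <- 0.9
  loss_curve <- numeric(epochs)
  with_local_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_l <- 0; ep_w <- 0
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        if (length(idx) < 2) next # BN needs a batch
        Xb <- X[idx, , drop = FALSE]
        y <- labels[idx]
        fw <- fusion_head_forward(head, Xb, train = TRUE, bn_eps = bn_eps)
        nb <- length(idx)
        wt <- cw[y + 1L]
        onehot <- matrix(0, nb, 2); onehot[cbind(seq_len(nb), y + 1L)] <- 1
        dlogits <- (fw$P - onehot) * wt / sum(wt)
        g <- list()
        g$W2 <- crossprod(dlogits, fw$Hr)
        g$b2 <- colSums(dlogits)
        dHr <- dlogits %*% head$W2
        dZb <- dHr * (fw$Zb > 0)
        g$gamma <- colSums(dZb * fw$xhat)
        g$beta <- colSums(dZb)
        dxhat <- sweep(dZb, 2, head$gamma, "*")
        istd <- 1 / sqrt(fw$va + bn_eps)
        xc <- sweep(fw$Z1, 2, fw$mu)
        dva <- colSums(dxhat * xc) * (-0.5) * istd^3
        dmu <- colSums(sweep(dxhat, 2, -istd, "*")) + dva * (-2) * colMeans(xc)
        dZ1 <- sweep(dxhat, 2, istd, "*") +
          sweep(xc * (2 / nb), 2, dva, "*") +
          matrix(dmu / nb, nb, head$hidden, byrow = TRUE)
        g$W1 <- crossprod(dZ1, Xb)
        g$b1 <- colSums(dZ1)
        step <- step + 1L
        for (nm in nms) {
          m[[nm]] <- 0.9 * m[[nm]] + 0.1 * g[[nm]]
          v[[nm]] <- 0.999 * v[[nm]] + 0.001 * g[[nm]]^2
          head[[nm]] <- head[[nm]] - learning_rate *
            (m[[nm]] / (1 - 0.9^step)) / (sqrt(v[[nm]] / (1 - 0.999^step)) + 1e-8)
        }
        head$run_mean <- momentum * head$run_mean + (1 - momentum) * fw$mu
        head$run_var <- momentum * head$run_var + (1 - momentum) * fw$va
        p_true <- fw$P[cbind(seq_len(nb), y + 1L)]
        ep_l <- ep_l + sum(wt * -log(pmax(p_true, 1e-12)))
        ep_w <- ep_w + sum(wt)
      }
      loss_curve[ep] <- ep_l / ep_w
    }
  })
  attr(head, "loss_curve") <- loss_curve
  head
}

#' Feature-fusion probabilities
#'
#' @param head trained [train_feature_fusion()] head.
#' @param features n x input_dim matrix.
#' @param train use batch statistics instead of running statistics.
#' @return numeric vector of P(SCD).
#' @export
feature_fusion <- function(head, features, train = FALSE) {
  X <- as.matrix(features)
  if (ncol(X) != head$input_dim)
    stop(sprintf("feature width %d does not match head input %d",
                 ncol(X), head$input_dim))
  fusion_head_forward(head, X, train = train)$P[, 2L]
}
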