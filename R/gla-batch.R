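# Batched forward/backward over subjects for training speed.  Subjects are
# stacked along the row (ROI) dimension: every LSTM equation is elementwise
# or a right-multiplication on the feature dimension, so rows are
# independent and a (B*R) x d matrix steps all B subjects at once.  Produces
# the same gradients as accumulating gla_grad() subject by subject (see the
# equivalence test).

# Per-subject stacked state matrices (T*R x R), the unit of work reused
# across epochs.
precompute_stacks <- function(dfcns) {
  stopifnot(length(dfcns) > 0)
  get_A <- function(d) if (inherits(d, "dfcn_tensor")) d$A else d
  A1 <- get_A(dfcns[[1]])
  R <- dim(A1)[1]; T_n <- dim(A1)[3]
  stacks <- lapply(dfcns, function(d) {
    A <- get_A(d)
    if (!all(dim(A) == c(R, R, T_n)))
      stop("all subjects must share R and T for batched training")
    matrix(aperm(A, c(1, 3, 2)), R * T_n, R)
  })
  list(stacks = stacks, R = R, T_n = T_n)
}

# Compiled batched pass (see src/gla_batch.cpp); same contract as
# gla_batch_pass.  Bias gradients come back as column vectors and are
# flattened here.
gla_batch_pass_fast <- function(pre, labels, weights, params, idx, kind) {
  out <- .gla_batch_pass_cpp(pre$stacks[idx], as.integer(labels[idx]),
                             as.numeric(weights[idx]),
                             params[gla_param_names()],
                             if (kind == "relu") 0L else 1L,
                             pre$R, pre$T_n)
  for (nm in c("b_f", "b_u", "b_c", "b_o", "w_att", "b_cls"))
    out$grads[[nm]] <- as.numeric(out$grads[[nm]])
  out
}

# Weighted-mean batch loss and its gradients for subjects `idx`.
# weights: per-subject loss weights (class weights); the batch loss is
# sum_i w_i * CE_i / sum_i w_i.  Reference R implementation; training uses
# the compiled equivalent.
gla_batch_pass <- function(pre, labels, weights, params, idx, kind) {
  R <- pre$R; T_n <- pre$T_n
  B <- length(idx)
  d <- ncol(params$W_R)
  BR <- B * R
  grp <- rep(seq_len(B), each = R)

  # graph convolution per subject, then reorder to time-major (B*R x d x T)
  XG <- vapply(idx, function(i) pre$stacks[[i]] %*% params$W_R,
               matrix(0, T_n * R, d))              # (T*R) x d x B
  Xtm <- aperm(array(XG, c(R, T_n, d, B)), c(1, 4, 3, 2))
  dim(Xtm) <- c(BR, d, T_n)
  relu_mask <- Xtm > 0
  Xtm <- Xtm * relu_mask

  # fused gate maps: one dgemm for all four gates per step
  ix_f <- seq_len(d); ix_u <- d + ix_f; ix_c <- 2L * d + ix_f; ix_o <- 3L * d + ix_f
  W_all <- cbind(params$W_f, params$W_u, params$W_c, params$W_o)
  U_all <- cbind(params$U_f, params$U_u, params$U_c, params$U_o)
  b_all <- matrix(c(params$b_f, params$b_u, params$b_c, params$b_o),
                  BR, 4L * d, byrow = TRUE)
  H <- matrix(0, BR, d); C <- matrix(0, BR, d)
  steps <- vector("list", T_n)
  Mt <- vector("list", T_n)
  for (t in seq_len(T_n)) {
    X <- matrix(Xtm[, , t], BR, d)
    Z <- X %*% W_all + H %*% U_all + b_all
    zf <- Z[, ix_f]; zu <- Z[, ix_u]; zc <- Z[, ix_c]; zo <- Z[, ix_o]
    f <- gate_act(zf, kind); u <- gate_act(zu, kind); o <- gate_act(zo, kind)
    cc <- tanh(zc)
    C_new <- f * C + u * cc
    tC <- tanh(C_new)
    H_new <- o * tC
    steps[[t]] <- list(zf = zf, zu = zu, zc = zc, zo = zo, f = f, u = u,
                       o = o, cc = cc, C_prev = C, h_prev = H,
                       C = C_new, tC = tC)
    Mt[[t]] <- rowsum(H_new, grp) / R
    H <- H_new; C <- C_new
  }
  if (!all(is.finite(H))) stop("non-finite LSTM state in batched pass")

  # attention
  S <- vector("list", T_n)
  raw <- matrix(0, B, T_n)
  for (t in seq_len(T_n)) {
    S[[t]] <- tanh(Mt[[t]] %*% t(params$V))
    raw[, t] <- S[[t]] %*% params$w_att
  }
  rmax <- apply(raw, 1, max)
  ex <- exp(raw - rmax)
  alpha <- ex / rowSums(ex)
  h_att <- matrix(0, B, d)
  for (t in seq_len(T_n)) h_att <- h_att + alpha[, t] * Mt[[t]]
  logits <- h_att %*% t(params$W_cls) +
    matrix(params$b_cls, B, 2, byrow = TRUE)
  lmax <- apply(logits, 1, max)
  el <- exp(logits - lmax)
  P <- el / rowSums(el)

  y <- labels[idx]
  w <- weights[idx]
  w_sum <- sum(w)
  p_true <- pmax(P[cbind(seq_len(B), y + 1L)], 1e-12)
  loss <- sum(w * -log(p_true)) / w_sum

  # ---- backward ----
  g <- zero_like_params(params)
  onehot <- matrix(0, B, 2); onehot[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (P - onehot) * (w / w_sum)
  g$W_cls <- crossprod(dlogits, h_att)
  g$b_cls <- colSums(dlogits)
  dh_att <- dlogits %*% params$W_cls            # B x d

  dalpha <- matrix(0, B, T_n)
  for (t in seq_len(T_n)) dalpha[, t] <- rowSums(dh_att * Mt[[t]])
  draw <- alpha * (dalpha - rowSums(alpha * dalpha))
  dMt <- vector("list", T_n)
  for (t in seq_len(T_n)) {
    dMt[[t]] <- alpha[, t] * dh_att
    g$w_att <- g$w_att + as.numeric(crossprod(S[[t]], draw[, t]))
    dZs <- (draw[, t] %o% params$w_att) * (1 - S[[t]]^2)
    g$V <- g$V + crossprod(dZs, Mt[[t]])
    dMt[[t]] <- dMt[[t]] + dZs %*% params$V
  }

  dH_next <- matrix(0, BR, d); dC_next <- matrix(0, BR, d)
  dXtm <- array(0, c(BR, d, T_n))
  gW_all <- matrix(0, d, 4L * d); gU_all <- matrix(0, d, 4L * d)
  gb_all <- numeric(4L * d)
  for (t in rev(seq_len(T_n))) {
    st <- steps[[t]]
    dH <- dMt[[t]][grp, , drop = FALSE] / R + dH_next
    do_ <- dH * st$tC
    dC <- dC_next + dH * st$o * (1 - st$tC^2)
    df <- dC * st$C_prev
    du <- dC * st$cc
    dcc <- dC * st$u
    dC_next <- dC * st$f
    dZ <- cbind(df * gate_act_deriv(st$zf, st$f, kind),
                du * gate_act_deriv(st$zu, st$u, kind),
                dcc * (1 - st$cc^2),
                do_ * gate_act_deriv(st$zo, st$o, kind))
    X <- matrix(Xtm[, , t], BR, d)
    gW_all <- gW_all + crossprod(X, dZ)
    gU_all <- gU_all + crossprod(st$h_prev, dZ)
    gb_all <- gb_all + colSums(dZ)
    dXtm[, , t] <- tcrossprod(dZ, W_all)
    dH_next <- tcrossprod(dZ, U_all)
  }
  # fused column order is (f, u, c, o)
  g$W_f <- gW_all[, ix_f]; g$U_f <- gU_all[, ix_f]; g$b_f <- gb_all[ix_f]
  g$W_u <- gW_all[, ix_u]; g$U_u <- gU_all[, ix_u]; g$b_u <- gb_all[ix_u]
  g$W_c <- gW_all[, ix_c]; g$U_c <- gU_all[, ix_c]; g$b_c <- gb_all[ix_c]
  g$W_o <- gW_all[, ix_o]; g$U_o <- gU_all[, ix_o]; g$b_o <- gb_all[ix_o]
  dXtm <- dXtm * relu_mask
  # back to per-subject (T*R x d) and accumulate the graph-kernel gradient
  dXG <- aperm(array(dXtm, c(R, B, d, T_n)), c(1, 4, 3, 2))
  dim(dXG) <- c(R * T_n, d, B)
  for (b in seq_len(B)) {
    g$W_R <- g$W_R + crossprod(pre$stacks[[idx[b]]], dXG[, , b])
  }

  list(loss = loss, w_sum = w_sum, grads = g, prob = P)
}
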