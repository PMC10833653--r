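# Names of learnable arrays in a gla_params list.
gla_param_names <- function() {
  c("W_R", "W_f", "U_f", "b_f", "W_u", "U_u", "b_u",
    "W_c", "U_c", "b_c", "W_o", "U_o", "b_o",
    "V", "w_att", "W_cls", "b_cls")
}

zero_like_params <- function(params) {
  g <- lapply(params[gla_param_names()], function(p) p * 0)
  g
}

#' Analytic gradient of the cross-entropy loss for one subject
#'
#' Backpropagates `-log p[label]` through the classifier, attention pooling,
#' LSTM unrolled over windows, and graph convolution.  Class weighting is a
#' scalar factor and is applied at the batch level by the trainer.
#'
#' @param dfcn a [build_dfcn()] tensor or R x R x T array.
#' @param label 0 (HC) or 1 (SCD).
#' @param params a [gla_init()] parameter set.
#' @return list with `loss` (unweighted cross-entropy), `grads` (named list
#'   matching the parameter arrays) and `prob`.
#' @export
gla_grad <- function(dfcn, label, params) {
  fw <- gla_forward(dfcn, params, keep_cache = TRUE)
  cc <- fw$cache
  R <- cc$R; T_n <- cc$T_n; d <- cc$d
  g <- zero_like_params(params)

  onehot <- c(0, 0); onehot[label + 1L] <- 1
  dlogits <- fw$prob - onehot
  g$W_cls <- dlogits %o% fw$h_att
  g$b_cls <- dlogits
  dh_att <- as.numeric(crossprod(params$W_cls, dlogits))

  M <- cc$M; alpha <- fw$alpha
  dalpha <- as.numeric(M %*% dh_att)
  dM <- alpha %o% dh_att
  draw <- alpha * (dalpha - sum(alpha * dalpha))
  S <- tanh(M %*% t(params$V))
  g$w_att <- as.numeric(crossprod(S, draw))
  dZs <- (draw %o% params$w_att) * (1 - S^2)
  g$V <- crossprod(dZs, M)
  dM <- dM + dZs %*% params$V

  kind <- cc$kind
  dh_next <- matrix(0, R, d); dC_next <- matrix(0, R, d)
  dXstack <- matrix(0, R * T_n, d)
  pool_row <- rep(1 / R, R)
  for (t in rev(seq_len(T_n))) {
    st <- cc$steps[[t]]
    dh <- pool_row %o% dM[t, ] + dh_next
    do_ <- dh * st$tC
    dC <- dC_next + dh * st$o * (1 - st$tC^2)
    C_prev <- if (t > 1) cc$steps[[t - 1]]$C else matrix(0, R, d)
    h_prev <- if (t > 1) cc$steps[[t - 1]]$h else matrix(0, R, d)
    df <- dC * C_prev
    du <- dC * st$cc
    dcc <- dC * st$u
    dC_next <- dC * st$f
    dzf <- df * gate_act_deriv(st$zf, st$f, kind)
    dzu <- du * gate_act_deriv(st$zu, st$u, kind)
    dzo <- do_ * gate_act_deriv(st$zo, st$o, kind)
    dzc <- dcc * (1 - st$cc^2)
    X <- cc$Xstack[(t - 1L) * R + seq_len(R), , drop = FALSE]
    g$W_f <- g$W_f + crossprod(X, dzf)
    g$U_f <- g$U_f + crossprod(h_prev, dzf)
    g$b_f <- g$b_f + colSums(dzf)
    g$W_u <- g$W_u + crossprod(X, dzu)
    g$U_u <- g$U_u + crossprod(h_prev, dzu)
    g$b_u <- g$b_u + colSums(dzu)
    g$W_c <- g$W_c + crossprod(X, dzc)
    g$U_c <- g$U_c + crossprod(h_prev, dzc)
    g$b_c <- g$b_c + colSums(dzc)
    g$W_o <- g$W_o + crossprod(X, dzo)
    g$U_o <- g$U_o + crossprod(h_prev, dzo)
    g$b_o <- g$b_o + colSums(dzo)
    dXstack[(t - 1L) * R + seq_len(R), ] <- dzf %*% t(params$W_f) +
      dzu %*% t(params$W_u) + dzc %*% t(params$W_c) + dzo %*% t(params$W_o)
    dh_next <- dzf %*% t(params$U_f) + dzu %*% t(params$U_u) +
      dzc %*% t(params$U_c) + dzo %*% t(params$U_o)
  }
  dZstack <- dXstack * (cc$Zstack > 0)
  Astack <- matrix(aperm(cc$A, c(1, 3, 2)), R * T_n, R)
  g$W_R <- crossprod(Astack, dZstack)

  list(loss = -log(max(fw$prob[label + 1L], 1e-12)), grads = g, prob = fw$prob)
}

#' Finite-difference gradient (verification utility)
#'
#' Central differences of the per-subject cross-entropy with respect to every
#' parameter element; used to verify [gla_grad()] on small instances.
#'
#' @inheritParams gla_grad
#' @param h step size.
#' @return named list of numeric arrays matching the parameters.
#' @export
gla_numeric_grad <- function(dfcn, label, params, h = 1e-5) {
  loss_at <- function(p) {
    fw <- gla_forward(dfcn, p)
    -log(max(fw$prob[label + 1L], 1e-12))
  }
  g <- zero_like_params(params)
  for (nm in gla_param_names()) {
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      g[[nm]][i] <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    }
  }
  g
}

#' Compare analytic and finite-difference gradients
#'
#' Mixed relative/absolute comparison, `|g_a - g_n| / max(atol, |g_a| +
#' |g_n|)`: elements whose gradients are smaller than `atol` in magnitude
#' are compared absolutely, since central differences carry roundoff noise
#' of order `1e-11` regardless of the gradient's size.
#'
#' @inheritParams gla_numeric_grad
#' @param atol magnitude floor for the relative comparison.
#' @return max error over all parameter elements.
#' @export
gla_gradient_check <- function(dfcn, label, params, h = 1e-5, atol = 1e-6) {
  ga <- gla_grad(dfcn, label, params)$grads
  gn <- gla_numeric_grad(dfcn, label, params, h = h)
  errs <- vapply(gla_param_names(), function(nm) {
    aa <- as.numeric(ga[[nm]]); nn <- as.numeric(gn[[nm]])
    max(abs(aa - nn) / pmax(atol, abs(aa) + abs(nn)))
  }, numeric(1))
  max(errs)
}

# --- Adam optimizer on a gla_params-shaped list -----------------------------

adam_state <- function(params) {
  list(m = zero_like_params(params), v = zero_like_params(params), t = 0L)
}

adam_update <- function(params, grads, state, lr = 0.01,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        weight_decay = 0) {
  state$t <- state$t + 1L
  for (nm in gla_param_names()) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
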