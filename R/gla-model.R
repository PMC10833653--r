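#' G-L-A model configuration
#'
#' Hyperparameters of the single-scale graph-convolution + LSTM + attention
#' classifier.  The printed form of the model applies the ReLU nonlinearity
#' in every gate equation; `gate_activation = "sigmoid"` switches the LSTM
#' gates to conventional logistic gates, which bound the forget/update/output
#' rates in (0, 1) and are numerically tamer over long sequences.  The cell
#' candidate always uses tanh and the graph convolution always uses ReLU.
#'
#' @param d hidden feature width of the graph convolution and LSTM.
#' @param a attention width.
#' @param gate_activation `"relu"` (as printed) or `"sigmoid"`.
#' @return object of class `gla_config`.
#' @export
gla_config <- function(d = 16L, a = 8L,
                       gate_activation = c("relu", "sigmoid")) {
  gate_activation <- match.arg(gate_activation)
  stopifnot(d >= 1, a >= 1)
  structure(list(d = as.integer(d), a = as.integer(a),
                 gate_activation = gate_activation),
            class = "gla_config")
}

# uniform fan-in init: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

#' Initialize G-L-A parameters
#'
#' Uniform fan-in scaled initialization, reproducible under `seed`.  The
#' graph kernel `W_R` maps the R-dimensional connectivity rows to d features;
#' each LSTM gate has a d x d input map, a d x d recurrent map and a
#' d-vector bias acting on the feature dimension (biases broadcast over
#' ROIs); the attention module scores the ROI-pooled d-vector through
#' `w %*% tanh(V m_t)`; the classifier is one dense layer to two logits.
#'
#' @param R parcellation scale (ROI count) the model is bound to.
#' @param config a [gla_config()].
#' @param seed integer seed.
#' @return object of class `gla_params` (a named list of arrays).
#' @export
gla_init <- function(R, config = gla_config(), seed = 1L) {
  d <- config$d; a <- config$a
  with_local_seed(seed, {
    p <- list(
      W_R = init_mat(R, d, R),
      W_f = init_mat(d, d, d), U_f = init_mat(d, d, d), b_f = numeric(d),
      W_u = init_mat(d, d, d), U_u = init_mat(d, d, d), b_u = numeric(d),
      W_c = init_mat(d, d, d), U_c = init_mat(d, d, d), b_c = numeric(d),
      W_o = init_mat(d, d, d), U_o = init_mat(d, d, d), b_o = numeric(d),
      V = init_mat(a, d, d), w_att = stats::runif(a, -1, 1) / sqrt(a),
      W_cls = init_mat(2, d, d), b_cls = numeric(2)
    )
    structure(p, R = R, config = config, seed = seed, class = "gla_params")
  })
}

#' @export
print.gla_params <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<gla_params> R = %d, d = %d, a = %d, gates = %s\n",
              attr(x, "R"), cfg$d, cfg$a, cfg$gate_activation))
  invisible(x)
}

gate_act <- function(z, kind) {
  if (kind == "relu") pmax(z, 0) else 1 / (1 + exp(-z))
}
gate_act_deriv <- function(z, act_z, kind) {
  if (kind == "relu") (z > 0) + 0 else act_z * (1 - act_z)
}

#' Graph convolution of one dFCN state
#'
#' `h_GC = ReLU(A_t %*% W_R)` — the nodal feature matrix is fixed to the
#' identity, so the output carries only the topological feature of the
#' state.  All states of a subject share the same kernel.
#'
#' @param A R x R dFCN state matrix.
#' @param params a [gla_init()] parameter set.
#' @return R x d nonnegative feature matrix.
#' @export
graph_conv <- function(A, params) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be square")
  if (nrow(A) != nrow(params$W_R))
    stop(sprintf("scale mismatch: A is %d x %d but W_R expects R = %d",
                 nrow(A), ncol(A), nrow(params$W_R)))
  pmax(A %*% params$W_R, 0)
}

#' One LSTM step over the feature dimension
#'
#' Forget/update/output rates and the tanh cell candidate are computed from
#' the current graph feature and the previous hidden state; the cell and
#' hidden updates are element-wise.  The initial hidden and cell states are
#' all-zero.
#'
#' @param h_gc R x d graph-convolution output for this window.
#' @param prev list with `h` and `C` (R x d each), e.g.
#'   `lstm_zero_state(R, d)`.
#' @param params a [gla_init()] parameter set.
#' @return list with `h`, `C` (R x d).
#' @export
lstm_step <- function(h_gc, prev, params) {
  kind <- attr(params, "config")$gate_activation
  st <- lstm_step_cached(h_gc, prev, params, kind)
  if (!all(is.finite(st$h)) || !all(is.finite(st$C)))
    stop("non-finite value in LSTM step")
  list(h = st$h, C = st$C)
}

#' @rdname lstm_step
#' @param R,d dimensions of the zero state.
#' @export
lstm_zero_state <- function(R, d) {
  z <- matrix(0, R, d)
  list(h = z, C = z)
}

lstm_step_cached <- function(X, prev, params, kind) {
  bcast <- function(b) matrix(b, nrow(X), length(b), byrow = TRUE)
  zf <- X %*% params$W_f + prev$h %*% params$U_f + bcast(params$b_f)
  zu <- X %*% params$W_u + prev$h %*% params$U_u + bcast(params$b_u)
  zc <- X %*% params$W_c + prev$h %*% params$U_c + bcast(params$b_c)
  zo <- X %*% params$W_o + prev$h %*% params$U_o + bcast(params$b_o)
  f <- gate_act(zf, kind); u <- gate_act(zu, kind); o <- gate_act(zo, kind)
  cc <- tanh(zc)
  C <- f * prev$C + u * cc
  tC <- tanh(C)
  h <- o * tC
  list(zf = zf, zu = zu, zc = zc, zo = zo, f = f, u = u, o = o,
       cc = cc, C = C, tC = tC, h = h)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Temporal attention pooling
#'
#' Each window's hidden state is pooled over the ROI dimension (mean) to a
#' d-vector `m_t`; the unnormalized score is `w %*% tanh(V m_t)`, the
#' normalized weights alpha are its softmax over windows, and the pooled
#' subject feature is `h_ATT = sum_t alpha_t m_t`.
#'
#' @param h_seq list of T hidden-state matrices (R x d), or a T x d matrix
#'   of already-pooled features.
#' @param params a [gla_init()] parameter set.
#' @return list with `h_att` (d-vector), `raw` and `alpha` (length T).
#' @export
attention_pool <- function(h_seq, params) {
  M <- if (is.matrix(h_seq)) h_seq
       else do.call(rbind, lapply(h_seq, colMeans))
  if (nrow(M) < 1) stop("attention needs T >= 1 windows")
  S <- tanh(M %*% t(params$V))            # T x a
  raw <- as.numeric(S %*% params$w_att)   # T
  alpha <- softmax(raw)
  list(h_att = as.numeric(crossprod(M, alpha)), raw = raw, alpha = alpha)
}

#' Classifier head
#'
#' One dense layer then softmax over the two classes (HC, SCD).
#'
#' @param h_att pooled d-vector from [attention_pool()].
#' @param params a [gla_init()] parameter set.
#' @return probability 2-vector (sums to 1), names `c("HC","SCD")`.
#' @export
classify <- function(h_att, params) {
  logits <- as.numeric(params$W_cls %*% h_att + params$b_cls)
  p <- softmax(logits)
  names(p) <- c("HC", "SCD")
  p
}

#' Full G-L-A forward pass for one subject
#'
#' Composition graph convolution -> LSTM over windows -> attention pooling
#' -> classifier, sharing the graph kernel and attention module across all
#' windows of the subject.
#'
#' @param dfcn a [build_dfcn()] tensor (or plain R x R x T array).
#' @param params a [gla_init()] parameter set.
#' @param keep_cache keep intermediates for backpropagation (internal).
#' @return list with `prob` (2-vector), `h_att`, `raw`, `alpha`, and
#'   optionally `cache`.
#' @export
gla_forward <- function(dfcn, params, keep_cache = FALSE) {
  A <- if (inherits(dfcn, "dfcn_tensor")) dfcn$A else dfcn
  stopifnot(length(dim(A)) == 3)
  R <- dim(A)[1]; T_n <- dim(A)[3]
  if (R != nrow(params$W_R))
    stop(sprintf("scale mismatch: dfcn R = %d, model R = %d", R, nrow(params$W_R)))
  d <- ncol(params$W_R)
  kind <- attr(params, "config")$gate_activation

  # stacked graph convolution: (T*R x R) %*% (R x d)
  Astack <- matrix(aperm(A, c(1, 3, 2)), R * T_n, R)
  Zstack <- Astack %*% params$W_R
  Xstack <- pmax(Zstack, 0)

  prev <- lstm_zero_state(R, d)
  steps <- vector("list", T_n)
  M <- matrix(0, T_n, d)
  for (t in seq_len(T_n)) {
    X <- Xstack[(t - 1L) * R + seq_len(R), , drop = FALSE]
    st <- lstm_step_cached(X, prev, params, kind)
    if (!all(is.finite(st$h)))
      stop(sprintf("non-finite LSTM state at window %d", t))
    steps[[t]] <- st
    M[t, ] <- colMeans(st$h)
    prev <- list(h = st$h, C = st$C)
  }
  att <- attention_pool(M, params)
  prob <- classify(att$h_att, params)
  out <- list(prob = prob, h_att = att$h_att, raw = att$raw, alpha = att$alpha)
  if (keep_cache)
    out$cache <- list(A = A, Zstack = Zstack, Xstack = Xstack, steps = steps,
                      M = M, att = att, R = R, T_n = T_n, d = d, kind = kind)
  out
}

#' Weighted cross-entropy loss
#'
#' `-weight[label] * log p[label]`, batch-reduced by the weighted mean
#' (sum of weighted losses over the sum of the applied weights), with the
#' class weights set to the inverse of the class sample ratio in the
#' training set (see [class_weights_from_labels()]).  Probabilities are
#' clamped at `eps` to keep the loss finite.
#'
#' @param prob matrix n x 2 of class probabilities (cols HC, SCD) or a
#'   2-vector for a single subject.
#' @param labels integer vector, 0 = HC, 1 = SCD.
#' @param class_weights positive 2-vector `c(w_HC, w_SCD)`.
#' @param eps clamp for log.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(prob, labels, class_weights = c(1, 1),
                                   eps = 1e-12) {
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1)
  stopifnot(ncol(prob) == 2, all(class_weights > 0),
            length(labels) == nrow(prob))
  p_true <- prob[cbind(seq_len(nrow(prob)), labels + 1L)]
  w <- class_weights[labels + 1L]
  sum(w * -log(pmax(p_true, eps))) / sum(w)
}

#' Class weights as the inverse of the training sample ratio
#'
#' @param labels training labels (0/1).
#' @return 2-vector normalized so a balanced set gives `c(1, 1)`; the weight
#'   ratio between classes is the inverse of the class count ratio.
#' @export
class_weights_from_labels <- function(labels) {
  n <- length(labels); n1 <- sum(labels == 1); n0 <- n - n1
  if (n0 == 0 || n1 == 0) stop("both classes required to derive class weights")
  c(n / (2 * n0), n / (2 * n1))
}
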