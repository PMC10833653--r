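gla_p <- function(R, d = 3L, a = 3L, gates = "sigmoid", seed = 1L) {
  gla_init(R, gla_config(d = d, a = a, gate_activation = gates), seed = seed)
}

test_that("graph convolution is ReLU(A W) with shape checking", {
  p <- gla_p(2, d = 1)
  p$W_R <- matrix(c(1, 2), 2, 1)
  A <- matrix(c(1, .5, .5, 1), 2, 2)
  expect_equal(graph_conv(A, p), matrix(c(2, 2.5), 2, 1))
  p$W_R <- matrix(c(1, -1), 2, 1)
  expect_equal(graph_conv(diag(2), p), matrix(c(1, 0), 2, 1))
  p$W_R <- matrix(0, 2, 1)
  expect_equal(graph_conv(A, p), matrix(0, 2, 1))
  expect_error(graph_conv(diag(3), p), "scale mismatch")
  set.seed(1)
  A_r <- crossprod(matrix(rnorm(4), 2)); A_r <- A_r / max(abs(A_r))
  expect_true(all(graph_conv(A_r, gla_p(2, d = 3)) >= 0))
})

test_that("LSTM step follows the printed gate algebra", {
  p <- gla_p(2, d = 2, gates = "sigmoid")
  for (nm in c("W_f", "U_f", "W_u", "U_u", "W_c", "U_c", "W_o", "U_o"))
    p[[nm]] <- matrix(0, 2, 2)
  p$b_f <- p$b_u <- p$b_c <- p$b_o <- numeric(2)
  z <- lstm_zero_state(2, 2)
  st <- lstm_step(matrix(0, 2, 2), z, p)
  expect_equal(st$C, matrix(0, 2, 2))
  expect_equal(st$h, matrix(0, 2, 2))

  # with only a huge forget bias and prior cell c, the new cell is
  # sigma(b_f) * c ~= c (update gate contributes u * tanh(0) = 0)
  p$b_f <- c(50, 50)
  C0 <- matrix(c(1, -2, 3, 4), 2, 2)
  st2 <- lstm_step(matrix(0, 2, 2), list(h = matrix(0, 2, 2), C = C0), p)
  expect_equal(st2$C, C0, tolerance = 1e-12)

  # relu gates zero out everything at zero pre-activation
  pr <- gla_p(2, d = 2, gates = "relu")
  for (nm in c("W_f", "U_f", "W_u", "U_u", "W_c", "U_c", "W_o", "U_o"))
    pr[[nm]] <- matrix(0, 2, 2)
  pr$b_f <- pr$b_u <- pr$b_c <- pr$b_o <- numeric(2)
  st3 <- lstm_step(matrix(1, 2, 2), list(h = matrix(0, 2, 2), C = C0), pr)
  expect_equal(st3$C, matrix(0, 2, 2))
})

test_that("scalar LSTM step matches an independent evaluator", {
  set.seed(8)
  w <- as.list(stats::setNames(rnorm(12),
        c("wf", "uf", "bf", "wu", "uu", "bu",
          "wc", "uc", "bc", "wo", "uo", "bo")))
  p <- gla_p(1, d = 1, gates = "sigmoid")
  p$W_f <- matrix(w$wf); p$U_f <- matrix(w$uf); p$b_f <- w$bf
  p$W_u <- matrix(w$wu); p$U_u <- matrix(w$uu); p$b_u <- w$bu
  p$W_c <- matrix(w$wc); p$U_c <- matrix(w$uc); p$b_c <- w$bc
  p$W_o <- matrix(w$wo); p$U_o <- matrix(w$uo); p$b_o <- w$bo
  x <- 0.7; h0 <- 0.2; c0 <- -0.4
  got <- lstm_step(matrix(x), list(h = matrix(h0), C = matrix(c0)), p)
  want <- scalar_lstm_step(x, h0, c0, w)
  expect_equal(as.numeric(got$h), want$h, tolerance = 1e-12)
  expect_equal(as.numeric(got$C), want$C, tolerance = 1e-12)
})

test_that("attention pooling normalizes and reduces to closed forms", {
  p <- gla_p(3, d = 2, a = 2)
  M1 <- matrix(c(1, 2), 1, 2)
  att1 <- attention_pool(M1, p)
  expect_equal(att1$alpha, 1)
  expect_equal(att1$h_att, as.numeric(M1))

  M <- matrix(rep(c(1, 2), each = 4), 4, 2)
  att <- attention_pool(M, p)
  expect_equal(att$alpha, rep(0.25, 4))
  expect_equal(sum(att$alpha), 1)

  # raws {0, ln 3} -> alpha {0.25, 0.75}
  expect_equal(dfcnstate:::softmax(c(0, log(3))), c(0.25, 0.75))
})

test_that("classifier is softmax over one dense layer", {
  p <- gla_p(3, d = 2)
  p$W_cls <- matrix(0, 2, 2); p$b_cls <- c(0, 0)
  expect_equal(unname(classify(c(1, -1), p)), c(0.5, 0.5))
  p$b_cls <- c(0, log(9)); p$W_cls <- matrix(0, 2, 2)
  expect_equal(unname(classify(c(1, 1), p)), c(0.1, 0.9))
  p$b_cls <- p$b_cls + 7  # shift invariance
  expect_equal(unname(classify(c(1, 1), p)), c(0.1, 0.9))
})

test_that("forward outputs live on the probability simplex", {
  set.seed(4)
  p <- gla_p(6, d = 3, a = 2, seed = 2)
  for (i in 1:100) {
    A <- array(0, c(6, 6, 3))
    for (t in 1:3) {
      M <- matrix(rnorm(36), 6); M <- (M + t(M)) / 2; diag(M) <- 1
      A[, , t] <- pmax(pmin(M, 1), -1)
    }
    out <- gla_forward(A, p)
    expect_equal(sum(out$prob), 1)
    expect_true(all(out$prob >= 0))
    expect_equal(sum(out$alpha), 1)
    expect_true(all(out$alpha > 0))
  }
})

test_that("forward is pure and order-sensitive through the LSTM", {
  co <- tiny_cohort(seed = 12, R = 12L, n_hc = 1, n_scd = 1)
  dfcn <- build_dfcn(co$timeseries$scale12[[1]])
  p <- gla_p(12, d = 4, a = 3, seed = 6)
  o1 <- gla_forward(dfcn, p)
  o2 <- gla_forward(dfcn, p)
  expect_identical(o1$prob, o2$prob)
  rev_d <- dfcn
  rev_d$A <- dfcn$A[, , rev(seq_len(dfcn$T))]
  o3 <- gla_forward(rev_d, p)
  expect_false(isTRUE(all.equal(o1$prob, o3$prob)))
})

test_that("time-constant input with zero gate parameters gives uniform attention", {
  # relu gates at zero pre-activation keep every hidden state identical,
  # so the softmax over windows is uniform
  p <- gla_p(5, d = 3, a = 2, gates = "relu", seed = 3)
  for (nm in c("W_f", "U_f", "W_u", "U_u", "W_c", "U_c", "W_o", "U_o"))
    p[[nm]] <- matrix(0, 3, 3)
  p$b_f <- p$b_u <- p$b_c <- p$b_o <- numeric(3)
  A1 <- crossprod(matrix(rnorm(25), 5)) / 5
  A <- array(rep(A1, 4), c(5, 5, 4))
  out <- gla_forward(A, p)
  expect_equal(out$alpha, rep(0.25, 4))
})

test_that("weighted cross-entropy applies inverse-ratio class weights", {
  probs <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  expect_equal(weighted_cross_entropy(probs, c(0, 1), c(1, 1)),
               mean(-log(c(0.8, 0.7))))
  # 64 HC : 112 SCD -> weights in inverse ratio
  lab <- rep(c(0L, 1L), c(64, 112))
  cw <- class_weights_from_labels(lab)
  expect_equal(cw[1] / cw[2], 112 / 64)
  expect_lt(weighted_cross_entropy(matrix(c(1e-9, 1 - 1e-9), 1), 1L, cw),
            1e-6)
  expect_error(class_weights_from_labels(rep(1, 5)), "both classes")
})

test_that("analytic gradients match finite differences on a small instance", {
  co <- tiny_cohort(seed = 31, R = 4L, n_hc = 1, n_scd = 1)
  dfcn <- build_dfcn(co$timeseries$scale4[[1]])
  dfcn$A <- dfcn$A[, , 1:3, drop = FALSE]; dfcn$T <- 3L
  p <- gla_p(4, d = 3, a = 3, gates = "sigmoid", seed = 7)
  expect_lt(gla_gradient_check(dfcn, 1L, p), 1e-4)
  expect_lt(gla_gradient_check(dfcn, 0L, p), 1e-4)
  # printed relu-gate variant: correct away from the kinks (looser because
  # central differences can straddle a kink)
  pr <- gla_p(4, d = 3, a = 3, gates = "relu", seed = 7)
  expect_lt(gla_gradient_check(dfcn, 1L, pr), 1e-2)
})

test_that("batched pass equals per-subject gradient accumulation and its compiled port", {
  co <- tiny_cohort(seed = 13, R = 10L, n_hc = 3, n_scd = 3)
  dfcns <- tiny_dfcns(co)
  lab <- co$subjects$label
  pre <- dfcnstate:::precompute_stacks(dfcns)
  cw <- class_weights_from_labels(lab)
  w <- cw[lab + 1]
  idx <- c(1L, 3L, 4L, 6L)
  for (kind in c("sigmoid", "relu")) {
    p <- gla_p(10, d = 4, a = 3, gates = kind, seed = 5)
    bpR <- dfcnstate:::gla_batch_pass(pre, lab, w, p, idx, kind)
    bpC <- dfcnstate:::gla_batch_pass_fast(pre, lab, w, p, idx, kind)
    acc <- dfcnstate:::zero_like_params(p)
    lsum <- 0; wsum <- sum(w[idx])
    for (i in idx) {
      gi <- gla_grad(dfcns[[i]], lab[i], p)
      for (nm in dfcnstate:::gla_param_names())
        acc[[nm]] <- acc[[nm]] + w[i] * gi$grads[[nm]] / wsum
      lsum <- lsum + w[i] * gi$loss / wsum
    }
    expect_equal(bpR$loss, lsum, tolerance = 1e-12)
    expect_equal(bpC$loss, lsum, tolerance = 1e-12)
    for (nm in dfcnstate:::gla_param_names()) {
      expect_equal(bpR$grads[[nm]], unname(acc[[nm]]), tolerance = 1e-10)
      expect_equal(unname(as.matrix(bpC$grads[[nm]]))[, , drop = TRUE],
                   unname(acc[[nm]]), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})
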