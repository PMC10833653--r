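test_that("attention z-scoring uses each model's own moments before averaging", {
  raw1 <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  z1 <- normalize_attention(list(raw1))
  expect_equal(mean(z1), 0)
  expect_equal(stats::sd(z1), 1)
  expect_equal(normalize_attention(list(raw1, raw1)), z1)

  # hand case: 3 windows, 2 models with different scales
  rawA <- matrix(c(0, 1, 2), 1, 3)
  rawB <- matrix(c(10, 30, 20), 1, 3)
  zA <- (rawA - 1) / stats::sd(rawA)
  zB <- (rawB - 20) / stats::sd(rawB)
  expect_equal(normalize_attention(list(rawA, rawB)), (zA + zB) / 2)

  expect_error(normalize_attention(list(matrix(1, 2, 3))), "zero variance")
  expect_error(normalize_attention(list()), "at least one")
})

test_that("state labeling thresholds strictly above zero", {
  z <- matrix(c(-1, 0, 1), 1, 3)
  expect_equal(as.integer(label_states(z)), c(0L, 0L, 1L))
  expect_equal(as.integer(label_states(matrix(c(-2, -0.1), 1))), c(0L, 0L))
  expect_equal(as.integer(label_states(z, threshold = -1.5)), c(1L, 1L, 1L))
  # subject-level grouping variant overrides window attention
  z2 <- matrix(rnorm(6), 2, 3)
  lab <- label_states(z2, by_subject = c(1L, 0L))
  expect_equal(lab, matrix(c(1L, 0L), 2, 3))
})

test_that("vectorized rank-sum tests agree with wilcox.test", {
  set.seed(51)
  X1 <- matrix(rnorm(15 * 6), 15, 6)
  X2 <- matrix(rnorm(12 * 6, mean = 0.8), 12, 6)
  rs <- dfcnstate:::rank_sum_columns(X1, X2)
  for (j in 1:6) {
    ref <- stats::wilcox.test(X1[, j], X2[, j], alternative = "greater",
                              exact = FALSE, correct = FALSE)
    expect_equal(rs$p_greater[j], ref$p.value, tolerance = 1e-10)
    ref2 <- stats::wilcox.test(X1[, j], X2[, j], exact = FALSE,
                               correct = FALSE)
    expect_equal(rs$p_two_sided[j], ref2$p.value, tolerance = 1e-10)
  }
})

test_that("vectorized Levene tests agree with the classical implementation", {
  skip_if_not_installed("car")
  set.seed(52)
  X1 <- matrix(rnorm(20 * 4, sd = 2), 20, 4)
  X2 <- matrix(rnorm(25 * 4, sd = 1), 25, 4)
  lv <- dfcnstate:::levene_columns(X1, X2, center = "mean")
  for (j in 1:4) {
    vals <- c(X1[, j], X2[, j])
    grp <- factor(rep(c("a", "b"), c(20, 25)))
    ref <- car::leveneTest(vals, grp, center = mean)
    expect_equal(lv$p_two_sided[j], ref[1, "Pr(>F)"], tolerance = 1e-10)
    expect_equal(lv$t[j]^2, ref[1, "F value"], tolerance = 1e-10)
  }
})

test_that("edge comparison flags planted block effects in the right direction", {
  set.seed(53)
  R <- 12
  mk_states <- function(n, shift_block = 0, sd_block = 1) {
    lapply(seq_len(n), function(i) {
      A <- matrix(rnorm(R * R, 0.3, 0.1), R, R)
      A[1:4, 1:4] <- rnorm(16, 0.3 + shift_block, 0.1 * sd_block)
      A <- (A + t(A)) / 2; diag(A) <- 1
      A
    })
  }
  normal <- mk_states(150)
  scd <- mk_states(150, shift_block = -0.3, sd_block = 3)
  res <- edge_comparison(normal, scd, alpha = 1e-4)
  dec <- res$strength_decrease
  in_block <- dec$i <= 4 & dec$j <= 4
  expect_true(all(dec$significant[in_block]))
  expect_equal(sum(dec$significant[!in_block]), 0)
  expect_true(all(res$variability_increase$significant[in_block]))
  expect_equal(sum(res$strength_increase$significant), 0)

  # identical groups: nothing survives Bonferroni
  null_res <- edge_comparison(mk_states(60), mk_states(60))
  expect_lte(sum(vapply(null_res, function(e) sum(e$significant),
                        integer(1))), 1)
  expect_error(edge_comparison(normal[1], scd[1]), "at least 2")
})

test_that("RSN proportions count block memberships correctly", {
  part <- make_block_partition(28, 7, seed = 1)
  mem <- synthetic_membership(part)
  E <- 28 * 27 / 2
  idx <- which(upper.tri(matrix(0, 28, 28)), arr.ind = TRUE)
  none <- data.frame(i = idx[, 1], j = idx[, 2], significant = FALSE)
  rp0 <- rsn_proportions(none, mem)
  expect_true(all(rp0$proportion[!is.na(rp0$proportion)] == 0))

  all_sig <- transform(none, significant = TRUE)
  rp1 <- rsn_proportions(all_sig, mem)
  expect_true(all(rp1$proportion[!is.na(rp1$proportion)] == 1))

  set.seed(54)
  some <- transform(none, significant = runif(E) < 0.1)
  rp <- rsn_proportions(some, mem)
  cells <- rp$proportion[!is.na(rp$proportion)]
  expect_lt(abs(stats::weighted.mean(cells,
                                     w = rep(1, length(cells))) - 0.1), 0.12)
  expect_lt(abs(mean(some$significant) - 0.1), 0.03)
  expect_error(rsn_proportions(data.frame(i = 1, j = 99, significant = TRUE),
                               mem), "beyond membership")
})

test_that("metric comparison reports Z, p and FDR per scale", {
  set.seed(55)
  vals <- list(
    s100 = list(normal = rnorm(40, 0.5, 0.05), scd = rnorm(40, 0.4, 0.05)),
    s200 = list(normal = rnorm(40, 0.5, 0.05), scd = rnorm(40, 0.5, 0.05)))
  out <- state_metric_comparison(vals)
  expect_equal(out$scale, c("s100", "s200"))
  expect_lt(out$p[1], 0.001)
  expect_lt(out$Z[1], 0)           # scd below normal
  expect_gt(out$p[2], 0.01)
  expect_equal(out$p_fdr, stats::p.adjust(out$p, "BH"))

  # exact enumeration at n = 2 vs 2: two-sided rank-sum p for complete
  # separation is 1/3 (2 of 6 orderings as extreme)
  tiny <- list(s = list(normal = c(1, 2), scd = c(3, 4)))
  ex <- state_metric_comparison(tiny, method = "exact")
  expect_equal(ex$p, 1 / 3)
})

test_that("transition properties are the mean and unbiased sd of attention", {
  z <- matrix(c(-1, 1, 0, 0), 2, 2, byrow = TRUE)
  tp <- transition_properties(z)
  expect_equal(tp$tendency, c(0, 0))
  expect_equal(tp$variability, c(sqrt(2), 0))
  expect_error(transition_properties(matrix(1, 3, 1)), "T < 2")
})

test_that("psychometric association recovers planted monotone links", {
  x <- 1:12
  up <- data.frame(prop = x)
  perf <- psychometric_association(up, 2 * x + 3, n_boot = 200, seed = 1)
  expect_equal(perf$rho, 1)
  neg <- psychometric_association(up, -x, n_boot = 200, seed = 1)
  expect_equal(neg$rho, -1)
  expect_lt(neg$p, 0.05)
  expect_error(psychometric_association(up, rep(1, 12)), "constant")
  expect_error(psychometric_association(data.frame(p = 1:4), 1:4), "at least 5")

  set.seed(56)
  rhos <- replicate(30, {
    psychometric_association(data.frame(p = rnorm(20)), rnorm(20),
                             n_boot = 50, seed = 2)$rho
  })
  expect_lt(abs(mean(rhos)), 0.15)
})
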