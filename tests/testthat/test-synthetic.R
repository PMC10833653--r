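test_that("block partitions are balanced and validated", {
  expect_equal(make_block_partition(7, 7), 1:7)
  p <- make_block_partition(100, 7, seed = 3)
  sizes <- as.integer(table(p))
  expect_true(all(sizes %in% c(14L, 15L)))
  expect_equal(sum(sizes), 100L)
  expect_error(make_block_partition(6, 7), "at least")
})

test_that("state covariance reproduces the requested block structure", {
  part <- rep(1:2, each = 2)
  s0 <- state_spec(within_block_corr = 0, between_block_corr = 0)
  expect_equal(state_covariance(s0, part), diag(4))

  s1 <- state_spec(within_block_corr = 0.6, between_block_corr = 0.1)
  C <- state_covariance(s1, part)
  expect_equal(diag(C), rep(1, 4))
  expect_equal(C[1, 2], 0.6)
  expect_equal(C[3, 4], 0.6)
  expect_equal(C[1, 3], 0.1)
  expect_equal(C, t(C))

  s_half <- state_spec(within_block_corr = 0.6, between_block_corr = 0.1,
                       strength_scale = 0.5)
  C2 <- state_covariance(s_half, part)
  off <- upper.tri(C)
  expect_equal(C2[off], C[off] / 2)
})

test_that("subject simulation is a pure function of spec and seed", {
  cs <- cohort_spec(n_hc = 2, n_scd = 2, scales = 10L, n_blocks = 5L,
                    seed = 9)
  a <- simulate_subject(cs, "SCD", seed = 123)
  b <- simulate_subject(cs, "SCD", seed = 123)
  expect_identical(a$timeseries$scale10$data, b$timeseries$scale10$data)
  expect_identical(a$states, b$states)

  cs0 <- cohort_spec(n_hc = 2, n_scd = 2, scales = 10L, n_blocks = 5L,
                     dwell_abnormal_hc = 0, dwell_abnormal_scd = 0, seed = 9)
  s0 <- simulate_subject(cs0, "HC", seed = 5)
  expect_true(all(s0$states == 0L))
})

test_that("long simulations recover the planted correlations", {
  cs <- cohort_spec(n_hc = 1, n_scd = 1, scales = 20L, n_volumes = 6008L,
                    dwell_abnormal_hc = 0, dwell_abnormal_scd = 1,
                    normal_state = state_spec(within_block_corr = 0.5,
                                              between_block_corr = 0.1,
                                              noise_sd = 0),
                    seed = 21)
  s <- simulate_subject(cs, "HC", seed = 77)
  part <- make_block_partition(20, 7, seed = cs$seed)
  C_hat <- stats::cor(s$timeseries$scale20$data)
  C_tgt <- state_covariance(cs$normal_state, part)
  expect_lt(max(abs(C_hat - C_tgt)), 0.05)
  # Frobenius error shrinks with series length
  short <- simulate_subject(
    cohort_spec(n_hc = 1, n_scd = 1, scales = 20L, n_volumes = 208L,
                dwell_abnormal_hc = 0, dwell_abnormal_scd = 1,
                normal_state = cs$normal_state, seed = 21),
    "HC", seed = 77)
  err <- function(X) norm(stats::cor(X) - C_tgt, "F")
  expect_lt(err(s$timeseries$scale20$data),
            err(short$timeseries$scale20$data))
})

test_that("cohorts carry labels, planted dwell contrast and scores", {
  cs <- cohort_spec(n_hc = 5, n_scd = 5, scales = 10L, n_blocks = 5L,
                    seed = 4)
  co <- generate_cohort(cs)
  expect_equal(nrow(co$subjects), 10L)
  expect_equal(co$subjects$label, rep(c(0L, 1L), each = 5))
  expect_length(co$timeseries$scale10, 10L)

  big <- generate_cohort(cohort_spec(n_hc = 50, n_scd = 50, scales = 10L,
                                     n_blocks = 5L,
                                     dwell_abnormal_hc = 0.2,
                                     dwell_abnormal_scd = 0.8, seed = 8))
  frac <- big$subjects$abnormal_fraction
  grp <- big$subjects$group
  expect_gt(mean(frac[grp == "SCD"]), mean(frac[grp == "HC"]))
  # binomial expectation: means near the dwell probabilities
  expect_lt(abs(mean(frac[grp == "HC"]) - 0.2), 0.05)
  expect_lt(abs(mean(frac[grp == "SCD"]) - 0.8), 0.05)

  noiseless <- generate_cohort(cohort_spec(n_hc = 10, n_scd = 10,
                                           scales = 10L, n_blocks = 5L,
                                           score_noise_sd = 0, seed = 2))
  r <- stats::cor(noiseless$subjects$score,
                  noiseless$subjects$abnormal_fraction, method = "spearman")
  expect_equal(r, -1)
})

test_that("window ground truth maps epochs onto windows", {
  cs <- cohort_spec(n_hc = 1, n_scd = 1, scales = 10L, n_blocks = 5L, seed = 1)
  states <- rep(c(0L, 1L), 12)  # alternating 20-volume epochs
  gt <- window_ground_truth(states, cs)
  expect_length(gt, 22L)
  # each 60-volume window spans 3 epochs of 20 volumes
  expect_equal(gt[1], mean(rep(states[1:3], each = 20)))
  all_abn <- window_ground_truth(rep(1L, 24), cs)
  expect_true(all(all_abn == 1))
})
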