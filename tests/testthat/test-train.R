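test_that("fold plans are balanced, stratified and reproducible", {
  lab10 <- rep(c(0L, 1L), each = 5)
  f10 <- make_folds(lab10, k = 5, seed = 1)
  expect_equal(as.integer(table(f10)), rep(2L, 5))

  lab176 <- rep(c(0L, 1L), c(64, 112))
  f176 <- make_folds(lab176, k = 5, seed = 2)
  expect_equal(sort(as.integer(table(f176)), decreasing = TRUE),
               c(36L, 35L, 35L, 35L, 35L))
  # stratification: both classes in every fold
  for (f in 1:5) expect_equal(sort(unique(lab176[f176 == f])), c(0L, 1L))

  expect_identical(make_folds(lab176, seed = 7), make_folds(lab176, seed = 7))
  expect_error(make_folds(rep(c(0L, 1L), c(3, 20)), k = 5), "at least")
})

test_that("metrics match closed forms and a brute-force pair count", {
  m <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2))
  expect_equal(m$auroc, 0.75)
  perfect <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$auprc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  reversed <- compute_metrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(reversed$auroc, 0)
  expect_error(compute_metrics(c(1, 1), c(0.5, 0.6)), "both classes")

  set.seed(14)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    lab <- c(0L, 1L, sample(0:1, n - 2, TRUE))
    pr <- round(runif(n), 2)  # ties likely
    expect_equal(compute_metrics(lab, pr)$auroc, pairwise_auroc(lab, pr))
  }
})

test_that("rank AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  lab <- sample(0:1, 40, TRUE, prob = c(0.4, 0.6))
  pr <- runif(40)
  ours <- compute_metrics(lab, pr)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, pr, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("permutation p-values follow the add-one rule and detect extremes", {
  lab <- rep(c(0L, 1L), each = 10)
  pr <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))  # perfect separation
  res <- permutation_test(lab, pr, n_perm = 500, seed = 2)
  expect_equal(res$observed, 1)
  expect_lte(res$p_value, 3 / 501)

  one <- permutation_test(lab, pr, n_perm = 1, seed = 3)
  expect_equal(one$p_value, ifelse(one$permuted >= 1, 1, 0.5))
  raw <- permutation_test(lab, pr, n_perm = 100, seed = 4, smoothed = FALSE)
  expect_equal(raw$p_value, mean(raw$permuted >= raw$observed))
})

test_that("training reduces the weighted loss on separable synthetic data", {
  co <- tiny_cohort(seed = 20, R = 20L, n_hc = 8, n_scd = 8)
  dfcns <- tiny_dfcns(co)
  lab <- co$subjects$label
  cfg <- train_config(epochs = 10, model = gla_config(d = 4, a = 3,
                      gate_activation = "sigmoid"), seed = 3)
  # untrained model starts near maximum entropy
  p0 <- gla_init(20, cfg$model, seed = cfg$seed)
  probs0 <- cbind(1 - gla_predict(p0, dfcns), gla_predict(p0, dfcns))
  expect_lt(abs(weighted_cross_entropy(probs0, lab) - log(2)), 0.1)

  fit <- train_single_scale(dfcns, lab, cfg)
  expect_lt(fit$loss_curve[10], fit$loss_curve[1])
  expect_gt(compute_metrics(lab, gla_predict(fit$params, dfcns))$auroc, 0.95)

  fit2 <- train_single_scale(dfcns, lab, cfg)
  expect_identical(fit$params$W_R, fit2$params$W_R)  # determinism
})

test_that("cross-validation keeps class weights inside the training fold", {
  co <- tiny_cohort(seed = 25, R = 15L, n_hc = 7, n_scd = 9)
  dfcns <- tiny_dfcns(co)
  lab <- co$subjects$label
  cfg <- train_config(epochs = 2, model = gla_config(d = 3, a = 2,
                      gate_activation = "sigmoid"), seed = 5)
  cv <- crossval_single_scale(dfcns, lab, cfg, k = 4, seed = 9)
  expect_length(cv$probabilities, 16)
  expect_true(all(cv$probabilities >= 0 & cv$probabilities <= 1))
  for (f in 1:4) {
    tr_lab <- lab[cv$folds != f]
    expect_equal(cv$models[[f]]$class_weights,
                 class_weights_from_labels(tr_lab))
  }
})

test_that("fold summaries report both normal and t intervals", {
  v <- c(0.8, 0.85, 0.9, 0.75, 0.82)
  fs <- fold_summary(v)
  expect_equal(fs$mean, mean(v))
  expect_equal(fs$sd, sd(v))
  se <- sd(v) / sqrt(5)
  expect_equal(fs$ci_normal, mean(v) + c(-1, 1) * qnorm(0.975) * se)
  expect_equal(fs$ci_t, mean(v) + c(-1, 1) * qt(0.975, 4) * se)
  expect_true(diff(fs$ci_t) > diff(fs$ci_normal))
  expect_error(fold_summary(0.8), "at least 2")
})

test_that("external prediction is a frozen cross-fold majority vote", {
  co <- tiny_cohort(seed = 26, R = 12L, n_hc = 6, n_scd = 6)
  dfcns <- tiny_dfcns(co)
  lab <- co$subjects$label
  cfg <- train_config(epochs = 3, model = gla_config(d = 3, a = 2,
                      gate_activation = "sigmoid"), seed = 2)
  cv <- crossval_single_scale(dfcns, lab, cfg, k = 3, seed = 4)
  ext_co <- tiny_cohort(seed = 27, R = 12L, n_hc = 2, n_scd = 2)
  ext <- tiny_dfcns(ext_co)
  before <- serialize(lapply(cv$models, `[[`, "params"), NULL)
  pr <- external_predict(cv$models, ext)
  after <- serialize(lapply(cv$models, `[[`, "params"), NULL)
  expect_identical(before, after)   # checkpoints untouched
  expect_true(all(pr$probability %in% c(0, 1/3, 2/3, 1)))
  expect_equal(pr$probability,
               rowMeans(vapply(cv$models, function(m)
                 as.integer(gla_predict(m$params, ext) > 0.5),
                 integer(4))))
  expect_error(external_predict(list(), ext), "at least one")
})
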