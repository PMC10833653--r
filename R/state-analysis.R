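#' Cross-fold z-scored attention
#'
#' Each fold model's raw attention scores are first z-scored over all of
#' that model's windows (its own mean and standard deviation) and then
#' averaged across models, making the fold models' arbitrary score scales
#' commensurable.
#'
#' @param attention_list list of n x T raw-attention matrices, one per fold
#'   model (see [gla_attention()]).
#' @return n x T matrix of averaged z-scores.
#' @export
normalize_attention <- function(attention_list) {
  if (length(attention_list) < 1) stop("need at least one model's attention")
  zs <- lapply(attention_list, function(raw) {
    s <- stats::sd(raw)
    if (!is.finite(s) || s == 0)
      stop("attention scores of a model have zero variance")
    (raw - mean(raw)) / s
  })
  Reduce(`+`, zs) / length(zs)
}

#' Label windows as normal or SCD-related
#'
#' The mean attention level (zero after z-scoring) is the intuitive
#' threshold: windows with z-attention strictly above it are labeled
#' SCD-related.
#'
#' A subject-level grouping variant is available for sensitivity analyses:
#' supplying the subjects' diagnoses labels every window of a diagnosed
#' subject as SCD-related, regardless of attention.
#'
#' @param z_attention n x T matrix from [normalize_attention()] (or vector).
#' @param threshold decision threshold (default 0).
#' @param by_subject optional 0/1 diagnosis vector of length n; when given,
#'   window labels are the subject's diagnosis (subject-level grouping).
#' @return integer matrix/vector of labels, 1 = SCD-related, 0 = normal.
#' @export
label_states <- function(z_attention, threshold = 0, by_subject = NULL) {
  if (!is.null(by_subject)) {
    z_attention <- as.matrix(z_attention)
    stopifnot(length(by_subject) == nrow(z_attention),
              all(by_subject %in% c(0, 1)))
    lab <- matrix(as.integer(by_subject), nrow(z_attention),
                  ncol(z_attention))
    return(lab)
  }
  lab <- (z_attention > threshold) + 0L
  storage.mode(lab) <- "integer"
  lab
}

#' Upper-triangle edge values of a stack of FC matrices
#'
#' @param states list of R x R matrices, or an R x R x n array.
#' @return n x E matrix (E = R(R-1)/2), edges in column-major upper-triangle
#'   order; attribute `"edge_index"` holds the (i, j) pairs.
#' @export
edge_matrix <- function(states) {
  if (is.array(states) && length(dim(states)) == 3)
    states <- lapply(seq_len(dim(states)[3]), function(k) states[, , k])
  R <- nrow(states[[1]])
  ut <- upper.tri(states[[1]])
  idx <- which(ut, arr.ind = TRUE)
  M <- do.call(rbind, lapply(states, function(A) A[ut]))
  attr(M, "edge_index") <- idx
  M
}

# Vectorized two-sample Mann-Whitney rank-sum tests over the columns of two
# matrices; tie-corrected normal approximation (no continuity correction).
rank_sum_columns <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2); n <- n1 + n2
  X <- rbind(X1, X2)
  mu <- n1 * n2 / 2
  res <- apply(X, 2, function(x) {
    r <- rank(x)
    U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tie_term <- 0
    if (anyDuplicated(x)) {
      tie <- tabulate(match(x, unique(x)))
      tie_term <- sum(tie^3 - tie) / (n * (n - 1))
    }
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sig2 <= 0) return(c(NA_real_, NA_real_))
    z <- (U1 - mu) / sqrt(sig2)
    c(z, U1)
  })
  z <- res[1, ]
  list(z = z,
       p_greater = stats::pnorm(z, lower.tail = FALSE), # group1 tends larger
       p_less = stats::pnorm(z, lower.tail = TRUE),
       p_two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

# Vectorized classical Levene tests (one per column): two-sample pooled t
# on absolute deviations from the group center.  center = "median" gives the
# Brown-Forsythe variant.
levene_columns <- function(X1, X2, center = c("mean", "median")) {
  center <- match.arg(center)
  cfun <- if (center == "mean") colMeans else function(X) apply(X, 2, stats::median)
  D1 <- abs(sweep(X1, 2, cfun(X1)))
  D2 <- abs(sweep(X2, 2, cfun(X2)))
  n1 <- nrow(D1); n2 <- nrow(D2)
  m1 <- colMeans(D1); m2 <- colMeans(D2)
  v1 <- colSums(sweep(D1, 2, m1)^2)
  v2 <- colSums(sweep(D2, 2, m2)^2)
  df <- n1 + n2 - 2
  sp <- sqrt((v1 + v2) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  t <- (m1 - m2) / se
  t[se == 0] <- NA_real_
  list(t = t, df = df,
       p_greater = stats::pt(t, df, lower.tail = FALSE), # group1 more variable
       p_less = stats::pt(t, df, lower.tail = TRUE),
       p_two_sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Edge-wise comparison of normal and SCD-related states
#'
#' For every upper-triangle edge, one-sided Mann-Whitney rank-sum tests on
#' connectivity strength and one-sided Levene tests on connectivity
#' variability, in both directions, Bonferroni-corrected over the
#' `R(R-1)/2` edges (the family is the edge set of the scale).
#'
#' @param normal_states,scd_states lists of R x R FC matrices (or 3-d
#'   arrays) for the two state groups; at least 2 states each.
#' @param alpha significance level applied to corrected p-values (default
#'   0.0001).
#' @param correction `"bonferroni"` (default) or any [stats::p.adjust()]
#'   method.
#' @param levene_center `"mean"` (classical) or `"median"` (Brown-Forsythe).
#' @return list of four data.frames (`strength_decrease`,
#'   `strength_increase`, `variability_increase`, `variability_decrease`),
#'   each with edge indices, raw and corrected p-values and a `significant`
#'   flag; "decrease"/"increase" describe the SCD-related states relative to
#'   normal.  Constant edges are skipped (NA) and counted in
#'   `attr(, "n_skipped")`.
#' @export
edge_comparison <- function(normal_states, scd_states, alpha = 1e-4,
                            correction = "bonferroni",
                            levene_center = "mean") {
  Xn <- edge_matrix(normal_states)
  Xs <- edge_matrix(scd_states)
  if (nrow(Xn) < 2 || nrow(Xs) < 2)
    stop("need at least 2 states per group")
  if (ncol(Xn) != ncol(Xs)) stop("state matrices have different scales")
  idx <- attr(Xn, "edge_index")
  rs <- rank_sum_columns(Xn, Xs)  # group1 = normal
  lv <- levene_columns(Xs, Xn, center = levene_center) # group1 = scd
  mk <- function(p, stat) {
    p_adj <- stats::p.adjust(p, method = correction)
    data.frame(i = idx[, 1], j = idx[, 2], statistic = stat,
               p = p, p_adj = p_adj,
               significant = !is.na(p_adj) & p_adj < alpha)
  }
  out <- list(
    strength_decrease = mk(rs$p_greater, rs$z),   # normal > scd
    strength_increase = mk(rs$p_less, rs$z),
    variability_increase = mk(lv$p_greater, lv$t), # scd more variable
    variability_decrease = mk(lv$p_less, lv$t)
  )
  attr(out, "n_skipped") <- sum(is.na(rs$z))
  attr(out, "alpha") <- alpha
  out
}

#' Proportions of altered edges per RSN pair
#'
#' Counts the significant edges in every (hemisphere x RSN) block pair and
#' divides by the block's edge count; the lower triangle is omitted since
#' the matrix is symmetric.  Log10 display values use a configurable floor
#' for empty cells.
#'
#' @param sig_edges data.frame with columns `i`, `j`, `significant` (one
#'   direction from [edge_comparison()]).
#' @param membership data.frame with `roi_id`, `hemisphere`, `rsn` covering
#'   all R ROIs (ROI order = matrix order).
#' @param log_floor proportion assigned to empty cells on the log scale.
#' @return list with `proportion` (14 x 14, upper triangle incl. diagonal),
#'   `log10_display`, and `groups`.
#' @export
rsn_proportions <- function(sig_edges, membership, log_floor = 1e-4) {
  labs <- rsn_labels()
  if (!all(membership$rsn %in% labs))
    stop("unknown RSN label in membership")
  groups <- paste(rep(c("L", "R"), each = length(labs)),
                  rep(labs, 2), sep = "-")
  g_of_roi <- paste(membership$hemisphere, membership$rsn, sep = "-")
  if (!all(g_of_roi %in% groups)) stop("hemisphere must be L or R")
  R <- nrow(membership)
  if (max(c(sig_edges$i, sig_edges$j)) > R)
    stop("edge index beyond membership table (unmapped ROI)")
  gi <- match(g_of_roi[sig_edges$i], groups)
  gj <- match(g_of_roi[sig_edges$j], groups)
  a <- pmin(gi, gj); b <- pmax(gi, gj)
  ng <- length(groups)
  tot <- matrix(0, ng, ng); sig <- matrix(0, ng, ng)
  for (e in seq_len(nrow(sig_edges))) {
    tot[a[e], b[e]] <- tot[a[e], b[e]] + 1
    if (isTRUE(sig_edges$significant[e])) sig[a[e], b[e]] <- sig[a[e], b[e]] + 1
  }
  prop <- sig / tot
  prop[tot == 0] <- NA
  prop[lower.tri(prop)] <- NA
  disp <- log10(pmax(prop, log_floor))
  dimnames(prop) <- dimnames(disp) <- list(groups, groups)
  list(proportion = prop, log10_display = disp, groups = groups)
}

#' Compare a network metric between normal and SCD-related states
#'
#' Two-sided Mann-Whitney rank-sum test per scale with Benjamini-Hochberg
#' correction across scales.
#'
#' @param values named list per scale, each a list with `normal` and
#'   `scd` numeric vectors of the metric.
#' @param method `"normal"` (tie-corrected normal approximation, reports Z)
#'   or `"exact"` ([stats::wilcox.test()] exact p where computable).
#' @return data.frame with scale, group medians, Z, p and FDR-corrected p.
#' @export
state_metric_comparison <- function(values, method = c("normal", "exact")) {
  method <- match.arg(method)
  rows <- lapply(names(values), function(sc) {
    x <- values[[sc]]$scd; y <- values[[sc]]$normal
    if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
    if (method == "normal") {
      rs <- rank_sum_columns(matrix(x), matrix(y))
      z <- rs$z; p <- rs$p_two_sided
    } else {
      wt <- stats::wilcox.test(x, y, exact = TRUE)
      p <- wt$p.value
      z <- stats::qnorm(1 - p / 2) * sign(stats::median(x) - stats::median(y))
    }
    data.frame(scale = sc, median_scd = stats::median(x),
               median_normal = stats::median(y), Z = z, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' State-transition properties from attention time series
#'
#' The subject-level mean of the z-scored attention series is the tendency
#' to stay in an SCD-related state; the (unbiased) standard deviation is the
#' transition variability.
#'
#' @param z_attention n x T matrix from [normalize_attention()].
#' @return data.frame with `tendency` and `variability` per subject.
#' @export
transition_properties <- function(z_attention) {
  z_attention <- as.matrix(z_attention)
  if (ncol(z_attention) < 2)
    stop("transition variability undefined for T < 2")
  data.frame(tendency = rowMeans(z_attention),
             variability = apply(z_attention, 1, stats::sd))
}

#' Spearman association between transition properties and psychometrics
#'
#' Spearman correlation with a two-sided bootstrap significance from 1000
#' pair resamples (the p-value is the smoothed two-sided fraction of
#' bootstrap correlations crossing zero), Benjamini-Hochberg corrected
#' within each property family.
#'
#' @param properties data.frame of numeric properties (columns = family
#'   members, e.g. one per scale).
#' @param scores numeric psychometric score vector (same subjects).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return data.frame with property, Spearman `rho`, bootstrap `p`, and
#'   `p_fdr`.
#' @export
psychometric_association <- function(properties, scores, n_boot = 1000L,
                                     seed = 1L) {
  properties <- as.data.frame(properties)
  n <- length(scores)
  if (n < 5) stop("need at least 5 paired observations")
  if (stats::sd(scores) == 0) stop("scores are constant: correlation undefined")
  rows <- lapply(names(properties), function(nm) {
    x <- properties[[nm]]
    if (nrow(properties) != n) stop("properties and scores differ in length")
    rho <- stats::cor(x, scores, method = "spearman")
    boot <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ix <- sample.int(n, replace = TRUE)
        suppressWarnings(stats::cor(x[ix], scores[ix], method = "spearman"))
      }, numeric(1))
    })
    boot <- boot[is.finite(boot)]
    p_neg <- (sum(boot <= 0) + 1) / (length(boot) + 1)
    p_pos <- (sum(boot >= 0) + 1) / (length(boot) + 1)
    data.frame(property = nm, rho = rho,
               p = min(1, 2 * min(p_neg, p_pos)))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}
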