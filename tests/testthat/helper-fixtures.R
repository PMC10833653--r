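# Shared fixtures and independent oracles, generated in code.

# small cohort whose dFCNs are cheap to build
tiny_cohort <- function(seed = 42L, R = 30L, n_hc = 6L, n_scd = 6L) {
  generate_cohort(cohort_spec(n_hc = n_hc, n_scd = n_scd, scales = R,
                              n_blocks = min(7L, R), seed = seed))
}

tiny_dfcns <- function(cohort, scale_name = NULL) {
  if (is.null(scale_name)) scale_name <- names(cohort$timeseries)[1]
  lapply(cohort$timeseries[[scale_name]], build_dfcn)
}

# random symmetric nonnegative weighted graph with zero diagonal
random_graph <- function(n, p_edge = 0.5, weighted = TRUE) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  m <- sum(ut)
  w <- ifelse(stats::runif(m) < p_edge,
              if (weighted) stats::runif(m, 0.1, 1) else 1, 0)
  A[ut] <- w
  A + t(A)
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum modularity over every partition (n small!)
exhaustive_max_q <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(p) newman_q(A, p), numeric(1)))
}

# brute-force AUROC: proportion of positive/negative pairs correctly ordered
pairwise_auroc <- function(labels, probs) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# independently coded scalar LSTM step (d = 1, R = 1) for oracle comparison
scalar_lstm_step <- function(x, h_prev, c_prev, w, act = plogis) {
  f <- act(w$wf * x + w$uf * h_prev + w$bf)
  u <- act(w$wu * x + w$uu * h_prev + w$bu)
  cc <- tanh(w$wc * x + w$uc * h_prev + w$bc)
  o <- act(w$wo * x + w$uo * h_prev + w$bo)
  C <- f * c_prev + u * cc
  list(h = o * tanh(C), C = C)
}
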