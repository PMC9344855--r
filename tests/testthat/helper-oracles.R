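# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately avoid the package's computational paths: the
# triple-loop V-term oracle evaluates the kernel sums by direct nested
# summation with its own kernel formula, and the partial-likelihood oracle
# maximizes the Breslow log partial likelihood by two-stage grid search.

# Gaussian kernel written out independently of coexmi::gaussian_kernel
oracle_gauss <- function(d, h) exp(-d^2 / (2 * h^2)) / (h * sqrt(2 * pi))

# naive triple-loop evaluation of the V-term sums with per-marker
# bandwidths h (KDE bandwidths; the convolution kernel uses sqrt(2) h)
naive_v_terms <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  K <- lapply(seq_len(p), function(k) {
    outer(x[, k], x[, k], function(a, b) oracle_gauss(a - b, sqrt(2) * h[k]))
  })
  VJ <- 0
  for (i in seq_len(n)) for (s in seq_len(n)) {
    pr <- 1
    for (k in seq_len(p)) pr <- pr * K[[k]][i, s]
    VJ <- VJ + pr
  }
  VJ <- VJ / n^2
  VC <- 0
  for (i in seq_len(n)) {
    pr <- 1
    for (k in seq_len(p)) pr <- pr * mean(K[[k]][i, ])
    VC <- VC + pr
  }
  VC <- VC / n
  VM <- 1
  for (k in seq_len(p)) VM <- VM * mean(K[[k]])
  list(V_J = VJ, V_C = VC, V_M = VM)
}

# Breslow log partial likelihood for a single predictor, no ties assumed
breslow_loglik <- function(gamma, time, event, E) {
  lp <- gamma * E
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + lp[i] - log(sum(exp(lp[risk])))
  }
  ll
}

# two-stage grid search maximizer of the Breslow partial likelihood
grid_search_gamma <- function(time, event, E, lo = -50, hi = 50) {
  g1 <- seq(lo, hi, length.out = 2001)
  ll1 <- vapply(g1, breslow_loglik, numeric(1), time, event, E)
  best <- g1[which.max(ll1)]
  step <- g1[2] - g1[1]
  g2 <- seq(best - step, best + step, length.out = 4001)
  ll2 <- vapply(g2, breslow_loglik, numeric(1), time, event, E)
  g2[which.max(ll2)]
}

# the fixed 5-point bivariate dataset used by several estimator checks
fixed5 <- function() {
  matrix(c(0.1, 0.2, 0.5, 0.9, 0.8,
           0.2, 0.1, 0.5, 0.8, 0.9), ncol = 2)
}

# quick in-memory cell table: one tibble row per cell
toy_cells <- function(n_per_subject = 5, subjects = c("a", "b"), seed = 1,
                      p = 2) {
  withr::with_seed(seed, {
    df <- do.call(rbind, lapply(subjects, function(sj) {
      d <- data.frame(subject_id = rep(sj, n_per_subject))
      for (k in seq_len(p)) d[[paste0("M", k)]] <- runif(n_per_subject)
      d
    }))
    as_cell_table(df, markers = paste0("M", seq_len(p)))
  })
}

max_rel_err <- function(a, b) {
  a <- unlist(a[c("V_J", "V_C", "V_M")])
  b <- unlist(b[c("V_J", "V_C", "V_M")])
  max(abs(a - b) / pmax(abs(b), .Machine$double.xmin))
}
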