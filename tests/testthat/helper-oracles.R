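# Independent oracles used by the tests: these deliberately re-derive
# quantities by direct enumeration / brute force, separate from the
# package's implementation paths.

# Wrap a plain matrix (with dimnames) into an expr_matrix quickly.
make_expr <- function(m, units = "log2", cohort = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expression_matrix(m, units = units, cohort = cohort)
}

# Brute-force running-sum enrichment score: walks the ranked list
# position by position accumulating hit/miss increments.
brute_es <- function(metric, hit, p) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric)^p
  nr <- sum(w[hit])
  if (nr == 0) {
    w[] <- 1
    nr <- nh
  }
  ph <- 0; pm <- 0
  dev <- numeric(n)
  for (i in seq_len(n)) {
    if (hit[i]) ph <- ph + w[i] / nr else pm <- pm + 1 / (n - nh)
    dev[i] <- ph - pm
  }
  # same documented tie rule as the package: positive extremum wins a
  # tie in absolute deviation
  if (max(dev) >= -min(dev) - 1e-12) max(dev) else min(dev)
}

# Cox partial log-likelihood for a single covariate, no ties assumed;
# maximized by two-stage grid search to ~1e-5.
cox_partial_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

grid_cox_beta <- function(times, events, x) {
  coarse <- seq(-5, 5, by = 0.01)
  ll <- vapply(coarse, cox_partial_loglik, numeric(1), times, events, x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, cox_partial_loglik, numeric(1), times, events, x)
  fine[which.max(llf)]
}

# Direct observed-minus-expected log-rank tabulation for two groups.
oracle_logrank_2g <- function(times, events, groups) {
  lev <- sort(unique(groups))
  stopifnot(length(lev) == 2L)
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at <- times >= tt
    n <- sum(at)
    n1 <- sum(at & groups == lev[1L])
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & groups == lev[1L])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Minimal assignment data.frame for tests that construct labels directly.
mk_assign <- function(ids, classes, scheme = "X") {
  structure(data.frame(sample_id = ids, scheme = scheme, class = classes,
                       stringsAsFactors = FALSE),
            class = c("subtype_assignment", "data.frame"))
}

# Random ranked-list instances for ES oracle comparisons.
random_es_instance <- function() {
  n <- sample(5:50, 1L)
  metric <- sort(round(rnorm(n), 4), decreasing = TRUE)
  k <- sample(1:min(10, n - 1L), 1L)
  hit <- rep(FALSE, n)
  hit[sample(n, k)] <- TRUE
  ranked <- data.frame(gene = paste0("g", seq_len(n)), metric = metric,
                       stringsAsFactors = FALSE)
  class(ranked) <- c("ranked_genes", "data.frame")
  list(ranked = ranked, hit = hit,
       set = ranked$gene[hit], p = sample(c(0, 1), 1L))
}
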