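# Independent brute-force oracles used to check the analytic implementations.

# BH step-up by enumeration: the adjusted value of p_i is the smallest
# candidate level q at which the step-up procedure rejects i.
oracle_bh <- function(p) {
  m <- length(p)
  cand <- sort(unique(c(pmin(p * m / rep(seq_len(m), each = m), 1), 1)))
  rejected_at <- function(q) {
    ps <- sort(p)
    # 1e-9 guard against float round-trip in q = p*m/k candidates
    k <- suppressWarnings(max(which(ps <= q * seq_len(m) / m + 1e-9)))
    if (!is.finite(k)) return(rep(FALSE, m))
    p <= ps[k]
  }
  vapply(seq_len(m), function(i) {
    min(cand[vapply(cand, function(q) rejected_at(q)[i], logical(1))])
  }, numeric(1))
}

# Breslow partial log-likelihood evaluated on a beta grid (vector-safe)
oracle_cox_grid <- function(x, time, event, betas) {
  ll <- vapply(betas, function(b) {
    out <- 0
    for (u in sort(unique(time[event == 1]))) {
      dead <- time == u & event == 1
      rs <- time >= u
      out <- out + sum(b * x[dead]) - sum(dead) * log(sum(exp(b * x[rs])))
    }
    out
  }, numeric(1))
  betas[which.max(ll)]
}

# O(n^2) silhouette widths for a hard labeling under Euclidean distance
oracle_silhouette <- function(z, labels) {
  z <- as.matrix(z)
  n <- nrow(z)
  d <- as.matrix(stats::dist(z))
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    if (sum(own) == 1) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# Harrell's C by explicit pair enumeration
oracle_harrell <- function(risk, time, event) {
  conc <- disc <- ties <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] < risk[j]) disc <- disc + 1
      else ties <- ties + 1
    }
  }
  (conc + 0.5 * ties) / (conc + disc + ties)
}

# Spearman rho from explicitly averaged ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  stats::cor(avg_rank(x), avg_rank(y))
}

# rank-based AUROC of a score against a binary truth
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# prefixed multimodal feature matrix from a synthetic cohort
cohort_features <- function(co) {
  f <- cbind(co$features_expr, co$features_path)
  colnames(f) <- c(paste0("expr_", colnames(co$features_expr)),
                   paste0("path_", colnames(co$features_path)))
  f
}

# hub-regulator SEM used across the single-cell tests
hub_edges <- function() {
  data.frame(regulator = rep("g1", 5), target = paste0("g", 2:6),
             weight = c(0.6, -0.5, 0.5, 0.6, -0.6))
}
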