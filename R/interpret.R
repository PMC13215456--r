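# Feature-level interpretation of the risk axis: permutation importance on
# Harrell's C through the trained encoder, and cross-modal Spearman maps.

#' Harrell's concordance index
#'
#' Over all usable pairs (shorter observed time has an event and times are
#' unequal), counts pairs where the shorter-lived sample has the higher
#' risk; ties in risk count one half.
#'
#' @param risk numeric risk scores (higher = worse predicted outcome).
#' @param surv survival data.frame (`time`, `event`).
#' @return concordance in \[0, 1\].
#' @export
harrell_c <- function(risk, surv) {
  surv <- as_surv(surv)
  assert(length(risk) == nrow(surv), "risk length must match survival table")
  t_ <- surv$time; e_ <- surv$event
  conc <- disc <- ties <- 0
  for (i in which(e_ == 1)) {
    later <- t_ > t_[i]
    if (!any(later)) next
    dr <- risk[i] - risk[later]
    conc <- conc + sum(dr > 0)
    disc <- disc + sum(dr < 0)
    ties <- ties + sum(dr == 0)
  }
  tot <- conc + disc + ties
  if (tot == 0) abort("no comparable pairs")
  (conc + 0.5 * ties) / tot
}

#' Permutation importance of input features for the risk score
#'
#' Baseline is the Harrell C-index of the risk score (encoder -> selected
#' latent dims -> Cox-weighted sum) against survival. Each feature column
#' is permuted `n_repeats` times (seeded), the table re-encoded and
#' re-scored; the importance is the mean drop in C. A feature that the
#' encoder ignores has importance exactly 0.
#'
#' @param ae_model trained `latent_model`.
#' @param risk_model fitted `risk_model`.
#' @param table samples x features matrix (raw scale, training columns).
#' @param surv survival data.frame aligned to rows.
#' @param n_repeats permutations per feature (>= 3).
#' @param seed integer seed.
#' @return data.frame `feature`, `modality`, `importance`, `rank`, sorted
#'   by decreasing importance; attribute `baseline_c`.
#' @export
permutation_importance <- function(ae_model, risk_model, table, surv,
                                   n_repeats = 5L, seed = 1L) {
  assert(n_repeats >= 3, "n_repeats must be >= 3")
  x <- as.matrix(table)
  surv <- as_surv(surv)
  base_risk <- risk_score(risk_model, encode(ae_model, x))
  if (sd(base_risk) == 0) abort("degenerate risk: constant over samples")
  base_c <- harrell_c(base_risk, surv)

  imp <- with_seed(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(x)), j]
        base_c - harrell_c(risk_score(risk_model, encode(ae_model, xp)), surv)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  out <- data.frame(
    feature = colnames(x),
    modality = ifelse(startsWith(colnames(x), "expr_"), "expr", "path"),
    importance = imp, stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "baseline_c") <- base_c
  attr(out, "n_repeats") <- n_repeats
  out
}

#' Spearman correlation map over selected features
#'
#' Rank-transforms each column (average ties) and computes Pearson
#' correlation on the ranks. Constant columns have undefined correlation
#' and are reported as NA with a warning (diagonal stays 1).
#'
#' @param table samples x features matrix.
#' @param features optional character vector of columns to include.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_map <- function(table, features = NULL) {
  x <- as.matrix(table)
  if (!is.null(features)) {
    assert(all(features %in% colnames(x)), "unknown feature names")
    x <- x[, features, drop = FALSE]
  }
  assert(nrow(x) >= 3, "need at least 3 samples")
  const <- apply(x, 2, function(v) sd(v) == 0)
  rho <- suppressWarnings(cor(x, method = "spearman"))
  if (any(const)) {
    warning(sprintf("constant column(s): %s; correlations set to NA",
                    paste(colnames(x)[const], collapse = ", ")))
    rho[const, ] <- NA; rho[, const] <- NA
  }
  diag(rho) <- 1
  rho
}
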