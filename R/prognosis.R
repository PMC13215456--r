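# Survival screening, Gaussian-mixture subtyping and risk stratification
# of the autoencoder latent space.

# normalize survival input: data.frame with columns time, event
as_surv <- function(surv) {
  if (is.data.frame(surv)) {
    assert(all(c("time", "event") %in% names(surv)),
           "survival table needs columns 'time' and 'event'")
    surv <- data.frame(time = as.numeric(surv$time),
                       event = as.numeric(surv$event),
                       row.names = NULL)
  } else abort("surv must be a data.frame with columns time, event")
  assert(all(is.finite(surv$time)) && all(surv$time > 0), "times must be > 0")
  assert(all(surv$event %in% c(0, 1)), "event must be 0/1")
  surv
}

#' Univariate Cox proportional hazards fit
#'
#' Newton-Raphson maximization of the Breslow-ties partial likelihood for a
#' single covariate, with a Wald test against the standard normal.
#'
#' @param x numeric covariate vector.
#' @param surv data.frame with columns `time` (> 0) and `event` (0/1).
#' @param tol convergence tolerance on `|delta beta|` (default 1e-8).
#' @param max_iter maximum Newton iterations (default 50).
#' @return list with `beta`, `se`, `p`, `iterations`, `loglik`.
#' @export
cox_fit <- function(x, surv, tol = 1e-8, max_iter = 50L) {
  surv <- as_surv(surv)
  x <- as.numeric(x)
  assert(length(x) == nrow(surv), "covariate length must match survival table")
  assert(all(is.finite(x)), "covariate must be finite")
  if (sum(surv$event) < 1) abort("no events: Cox model undefined")
  if (sd(x) == 0) abort("covariate is constant")

  ord <- order(surv$time)
  t_s <- surv$time[ord]; d_s <- surv$event[ord]; x_s <- x[ord]
  # tie blocks: first position of each unique time indexes the full risk set
  first_idx <- which(!duplicated(t_s))
  block <- rep.int(seq_along(first_idx), diff(c(first_idx, length(t_s) + 1L)))
  ev_blocks <- unique(block[d_s == 1])
  d_t <- vapply(ev_blocks, function(b) sum(d_s[block == b]), numeric(1))
  sx_t <- vapply(ev_blocks, function(b) sum(x_s[block == b & d_s == 1]), numeric(1))
  risk_start <- first_idx[ev_blocks]  # risk set = indices >= risk_start

  revcum <- function(v) rev(cumsum(rev(v)))
  beta <- 0
  for (it in seq_len(max_iter)) {
    w <- exp(beta * x_s)
    S0 <- revcum(w)[risk_start]
    S1 <- revcum(w * x_s)[risk_start]
    S2 <- revcum(w * x_s^2)[risk_start]
    U <- sum(sx_t - d_t * S1 / S0)
    I <- sum(d_t * (S2 / S0 - (S1 / S0)^2))
    if (!is.finite(U) || !is.finite(I) || I <= 0)
      abort("non-convergent: monotone partial likelihood (perfect separation)")
    step <- U / I
    beta <- beta + step
    if (abs(beta) > 30)
      abort("non-convergent: monotone partial likelihood (perfect separation)")
    if (abs(step) < tol) break
  }
  if (abs(step) >= tol)
    abort("non-convergent: Newton-Raphson did not converge")
  w <- exp(beta * x_s)
  S0 <- revcum(w)[risk_start]
  S1 <- revcum(w * x_s)[risk_start]
  S2 <- revcum(w * x_s^2)[risk_start]
  I <- sum(d_t * (S2 / S0 - (S1 / S0)^2))
  loglik <- sum(sx_t * beta - d_t * log(S0))
  se <- 1 / sqrt(I)
  list(beta = beta, se = se,
       p = 2 * pnorm(abs(beta / se), lower.tail = FALSE),
       iterations = it, loglik = loglik)
}

#' Screen latent dimensions by univariate Cox regression
#'
#' Each latent dimension is standardized and tested one at a time; a
#' dimension is selected when its Wald p-value falls below `alpha_screen`.
#' If none pass, the single smallest-p dimension is selected with a warning
#' so that downstream risk scoring always has at least one axis.
#'
#' @param latent numeric matrix, samples x latent dimensions.
#' @param surv survival data.frame (`time`, `event`) aligned to rows.
#' @param alpha_screen per-dimension significance threshold (default 0.05).
#' @return data.frame with `dim`, `beta`, `se`, `p`, `selected`, `reason`.
#' @export
screen_latent <- function(latent, surv, alpha_screen = 0.05) {
  latent <- as.matrix(latent)
  surv <- as_surv(surv)
  assert(nrow(latent) == nrow(surv), "latent rows must match survival table")
  if (sum(surv$event) < 10)
    warning("fewer than 10 events: Cox screening will be unstable")

  res <- lapply(seq_len(ncol(latent)), function(j) {
    zj <- latent[, j]
    s <- sd(zj)
    if (s == 0) return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                            reason = "constant dimension"))
    fit <- tryCatch(cox_fit((zj - mean(zj)) / s, surv),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  reason = conditionMessage(fit)))
    list(beta = fit$beta, se = fit$se, p = fit$p, reason = NA_character_)
  })
  out <- data.frame(
    dim = seq_len(ncol(latent)),
    beta = vapply(res, `[[`, numeric(1), "beta"),
    se = vapply(res, `[[`, numeric(1), "se"),
    p = vapply(res, `[[`, numeric(1), "p"),
    reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  out$selected <- !is.na(out$p) & out$p < alpha_screen
  if (!any(out$selected)) {
    if (all(is.na(out$p))) abort("no latent dimension could be fit")
    warning("no dimension passed the screen; keeping the smallest-p dimension")
    out$selected[which.min(out$p)] <- TRUE
  }
  out
}

# squared Mahalanobis-free diagonal Gaussian log-density, n x k
.diag_gauss_logdens <- function(z, means, vars) {
  n <- nrow(z); k <- nrow(means); m <- ncol(z)
  ll <- matrix(0, n, k)
  for (j in seq_len(k)) {
    dif <- sweep(z, 2, means[j, ], "-")
    ll[, j] <- -0.5 * (m * log(2 * pi) + sum(log(vars[j, ])) +
                         rowSums(sweep(dif^2, 2, vars[j, ], "/")))
  }
  ll
}

# k-means++ seeding: rows of z used as initial centers
.kmeanspp <- function(z, k) {
  n <- nrow(z)
  centers <- matrix(NA_real_, k, ncol(z))
  centers[1, ] <- z[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(z, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1L)) {
    pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L, ] <- z[sample.int(n, 1L, prob = pr), ]
    d2 <- pmin(d2, rowSums(sweep(z, 2, centers[j + 1L, ], "-")^2))
  }
  centers
}

#' Gaussian mixture clustering with diagonal covariances
#'
#' EM on a k-component diagonal-covariance Gaussian mixture. Ten seeded
#' k-means++ restarts are run and the fit with the best log-likelihood kept.
#' Per-dimension variances are floored at 1e-6.
#'
#' @param z numeric matrix, samples x dimensions.
#' @param k number of components (>= 2).
#' @param seed integer seed controlling all restarts.
#' @param n_restarts number of k-means++ restarts (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return list with `labels`, `means` (k x m), `vars` (k x m), `weights`,
#'   `loglik`, `responsibilities`.
#' @export
gmm_cluster <- function(z, k, seed, n_restarts = 10L, max_iter = 200L,
                        tol = 1e-8) {
  z <- as.matrix(z)
  assert(is_count_scalar(k), "k must be an integer")
  if (k < 2) abort("k must be >= 2")
  assert(nrow(z) > k, "need more observations than components")
  n <- nrow(z); m <- ncol(z)

  run_em <- function() {
    for (attempt in 1:3) {
      means <- .kmeanspp(z, k)
      vars <- matrix(pmax(apply(z, 2, var), 1e-6), k, m, byrow = TRUE)
      weights <- rep(1 / k, k)
      ll_old <- -Inf
      empty <- FALSE
      for (it in seq_len(max_iter)) {
        ld <- .diag_gauss_logdens(z, means, vars) +
          rep(log(weights), each = n)
        mx <- apply(ld, 1, max)
        r <- exp(ld - mx)
        rs <- rowSums(r)
        ll <- sum(mx + log(rs))
        r <- r / rs
        nk <- colSums(r)
        if (any(nk < 1e-8)) { empty <- TRUE; break }
        weights <- nk / n
        means <- (t(r) %*% z) / nk
        for (j in seq_len(k)) {
          dif <- sweep(z, 2, means[j, ], "-")
          vars[j, ] <- pmax(colSums(r[, j] * dif^2) / nk[j], 1e-6)
        }
        if (is.finite(ll_old) && (ll - ll_old) < tol * (abs(ll_old) + 1)) break
        ll_old <- ll
      }
      if (!empty)
        return(list(means = means, vars = vars, weights = weights,
                    loglik = ll, resp = r))
    }
    abort("empty mixture component after 3 re-initializations")
  }

  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_restarts)) {
      fit <- tryCatch(run_em(), error = function(e) e)
      if (inherits(fit, "error")) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best)) abort("empty mixture component after 3 re-initializations")
    labels <- max.col(best$resp, ties.method = "first")
    list(labels = labels, means = best$means, vars = best$vars,
         weights = best$weights, loglik = best$loglik,
         responsibilities = best$resp)
  })
}

#' Select the number of mixture components by mean silhouette
#'
#' Fits a Gaussian mixture for every k in `k_range` and returns the k whose
#' hard labels maximize the mean silhouette width under Euclidean distance.
#' Ties go to the smaller k; a k whose fit fails (or collapses to a single
#' occupied component) is skipped with a warning.
#'
#' @param z numeric matrix, samples x dimensions.
#' @param k_range candidate component counts (default 2:6).
#' @param seed integer seed (shared across candidates).
#' @return list with `k`, `silhouette` (data.frame k, mean_sil) and `labels`
#'   for the winning k.
#' @export
select_k <- function(z, k_range = 2:6, seed = 1L) {
  z <- as.matrix(z)
  k_range <- sort(unique(as.integer(k_range)))
  assert(nrow(z) >= 3 * max(k_range), "need n >= 3 * max(k_range)")
  dz <- stats::dist(z)
  sils <- rep(NA_real_, length(k_range))
  labs <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- tryCatch(gmm_cluster(z, k, seed), error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("k=%d skipped: %s", k, conditionMessage(fit)))
      next
    }
    if (length(unique(fit$labels)) < 2) {
      warning(sprintf("k=%d skipped: clustering collapsed to one label", k))
      next
    }
    sil <- cluster::silhouette(fit$labels, dz)
    sils[i] <- mean(sil[, "sil_width"])
    labs[[i]] <- fit$labels
  }
  if (all(is.na(sils))) abort("all candidate k failed")
  best <- which.max(sils)  # first maximum = smallest k on ties
  list(k = k_range[best],
       silhouette = data.frame(k = k_range, mean_sil = sils),
       labels = labs[[best]])
}

#' Fit the latent risk model
#'
#' Standardizes the training latent space, screens dimensions by univariate
#' Cox regression, and defines the risk score as the Cox-coefficient-weighted
#' sum of the selected (standardized) dimensions. The stratification cutoff
#' is the median training risk; all statistics (centering, scaling, betas,
#' cutoff) are frozen at fit time so validation data can only be transformed.
#'
#' @param latent training latent matrix, samples x dimensions.
#' @param surv training survival data.frame (`time`, `event`).
#' @param alpha_screen Cox screening threshold (default 0.05).
#' @return object of class `risk_model`.
#' @export
fit_risk_model <- function(latent, surv, alpha_screen = 0.05) {
  latent <- as.matrix(latent)
  surv <- as_surv(surv)
  screen <- screen_latent(latent, surv, alpha_screen)
  sel <- which(screen$selected)
  center <- colMeans(latent)
  scale_ <- apply(latent, 2, sd)
  scale_[scale_ == 0] <- 1
  model <- structure(class = "risk_model", list(
    screen = screen, selected = sel, beta = screen$beta[sel],
    center = center, scale = scale_, alpha_screen = alpha_screen
  ))
  model$risk_train <- risk_score(model, latent)
  model$median_cutoff <- median(model$risk_train)
  model
}

#' Compute the latent risk score
#'
#' @param model a `risk_model` from [fit_risk_model()].
#' @param latent latent matrix with the same number of columns as at fit time.
#' @return numeric risk vector (Cox linear predictor over selected dims).
#' @export
risk_score <- function(model, latent) {
  assert(inherits(model, "risk_model"), "model must be a risk_model")
  latent <- as.matrix(latent)
  assert(ncol(latent) == length(model$center),
         "latent column count differs from the fitted model")
  zs <- sweep(sweep(latent, 2, model$center, "-"), 2, model$scale, "/")
  as.numeric(zs[, model$selected, drop = FALSE] %*% model$beta)
}

#' Stratify risk scores into high/low groups
#'
#' High risk iff `risk > cutoff`; ties at the cutoff go to the low-risk
#' group. Validation cohorts must be stratified with the training median.
#'
#' @param risk numeric risk vector.
#' @param cutoff scalar cutoff (typically `model$median_cutoff`).
#' @return factor with levels `low`, `high`.
#' @export
stratify <- function(risk, cutoff) {
  factor(ifelse(risk > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param surv survival data.frame (`time`, `event`).
#' @return data.frame with one row per unique event/censoring time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival` (right-continuous
#'   step function).
#' @export
km_estimate <- function(surv) {
  surv <- as_surv(surv)
  tt <- sort(unique(surv$time))
  n_risk <- vapply(tt, function(u) sum(surv$time >= u), numeric(1))
  n_event <- vapply(tt, function(u) sum(surv$time == u & surv$event == 1), numeric(1))
  n_censor <- vapply(tt, function(u) sum(surv$time == u & surv$event == 0), numeric(1))
  s <- cumprod(1 - n_event / n_risk)
  data.frame(time = tt, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = s)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic comparing event-time
#' distributions across two groups, referred to a chi-squared distribution
#' with 1 degree of freedom.
#'
#' @param surv survival data.frame (`time`, `event`).
#' @param group two-level grouping vector aligned to rows of `surv`.
#' @return list with `chi2`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(surv, group) {
  surv <- as_surv(surv)
  g <- as.factor(group)
  assert(length(g) == nrow(surv), "group length must match survival table")
  if (nlevels(droplevels(g)) != 2) abort("exactly two non-empty groups required")
  g <- droplevels(g)
  in1 <- g == levels(g)[2]

  ev_times <- sort(unique(surv$time[surv$event == 1]))
  O1 <- E1 <- V <- 0
  O <- c(0, 0)
  for (u in ev_times) {
    at_risk <- surv$time >= u
    n <- sum(at_risk); n1 <- sum(at_risk & in1)
    d <- sum(surv$time == u & surv$event == 1)
    d1 <- sum(surv$time == u & surv$event == 1 & in1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    O <- O + c(d - d1, d1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = setNames(O, levels(g)),
       expected = setNames(c(sum(O) - E1, E1), levels(g)))
}

#' Hazard ratio between two risk groups
#'
#' Cox fit on the group indicator (second level vs first); the 95% CI is
#' `exp(beta +/- 1.96 se)`.
#'
#' @param surv survival data.frame (`time`, `event`).
#' @param group two-level grouping vector (e.g. output of [stratify()]).
#' @return list with `hr`, `ci_low`, `ci_high`, `beta`, `se`, `p`.
#' @export
group_hr <- function(surv, group) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2) abort("exactly two non-empty groups required")
  fit <- cox_fit(as.numeric(g == levels(g)[2]), surv)
  list(hr = exp(fit$beta),
       ci_low = exp(fit$beta - 1.96 * fit$se),
       ci_high = exp(fit$beta + 1.96 * fit$se),
       beta = fit$beta, se = fit$se, p = fit$p)
}
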