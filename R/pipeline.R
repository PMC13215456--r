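#' End-to-end multimodal prognosis pipeline
#'
#' Convenience driver over the module functions: 7:3 train/validation
#' split, autoencoder training on the training partition only, latent
#' encoding of both partitions, Cox screening and risk-model fitting on
#' the training latent space, and stratified survival reporting (log-rank
#' and hazard ratio) for both partitions using training-derived statistics
#' only. Optionally selects the mixture subtype count by silhouette.
#'
#' @param features samples x features matrix (e.g. from [assemble()] or a
#'   synthetic cohort's `cbind` of prefixed blocks).
#' @param surv survival data.frame with `sample`, `time`, `event` columns
#'   (or `time`/`event` aligned to rows of `features`).
#' @param cfg an [ae_config()].
#' @param split_ratio training fraction (default 0.7).
#' @param alpha_screen Cox screening threshold (default 0.05).
#' @param seed integer seed for the split (AE seed lives in `cfg`).
#' @param subtype logical: also run silhouette-selected GMM subtyping on
#'   the selected training latent dims (default FALSE).
#' @return list with `split`, `ae`, `risk_model`, per-partition `latent`,
#'   `risk`, `group`, `logrank`, `hr`, and optionally `subtypes`.
#' @export
run_pipeline <- function(features, surv, cfg = ae_config(),
                         split_ratio = 0.7, alpha_screen = 0.05,
                         seed = 1L, subtype = FALSE) {
  features <- as.matrix(features)
  if ("sample" %in% names(surv)) {
    assert(all(rownames(features) %in% surv$sample),
           "every feature row needs a survival record")
    surv <- surv[match(rownames(features), surv$sample), , drop = FALSE]
  }
  surv <- data.frame(time = surv$time, event = surv$event,
                     row.names = rownames(features))

  sp <- split_cohort(features, ratio = split_ratio, seed = seed)
  tr <- features[sp$train_ids, , drop = FALSE]
  va <- features[sp$validation_ids, , drop = FALSE]
  surv_tr <- surv[sp$train_ids, , drop = FALSE]
  surv_va <- surv[sp$validation_ids, , drop = FALSE]

  ae <- train_autoencoder(tr, cfg)
  z_tr <- encode(ae, tr)
  z_va <- encode(ae, va)

  rm_ <- fit_risk_model(z_tr, surv_tr, alpha_screen)
  risk_tr <- rm_$risk_train
  risk_va <- risk_score(rm_, z_va)
  grp_tr <- stratify(risk_tr, rm_$median_cutoff)
  grp_va <- stratify(risk_va, rm_$median_cutoff)

  res <- list(
    split = sp, ae = ae, risk_model = rm_,
    train = list(latent = z_tr, risk = risk_tr, group = grp_tr,
                 surv = surv_tr,
                 logrank = logrank_test(surv_tr, grp_tr),
                 hr = group_hr(surv_tr, grp_tr)),
    validation = list(latent = z_va, risk = risk_va, group = grp_va,
                      surv = surv_va,
                      logrank = tryCatch(logrank_test(surv_va, grp_va),
                                         error = function(e) NULL),
                      hr = tryCatch(group_hr(surv_va, grp_va),
                                    error = function(e) NULL)))
  if (subtype) {
    zs <- z_tr[, rm_$selected, drop = FALSE]
    res$subtypes <- tryCatch(
      select_k(zs, k_range = 2:min(6, floor(nrow(zs) / 3)), seed = seed),
      error = function(e) NULL)
  }
  res
}
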