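#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control. Adjusted values are monotone in the
#' input order statistics and clipped at 1.
#'
#' @param pvals numeric vector of p-values, all in \[0, 1\].
#' @return numeric vector of BH-adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  assert(is.numeric(pvals) && length(pvals) >= 1L, "pvals must be a non-empty numeric vector")
  assert(!anyNA(pvals), "pvals must not contain NA")
  assert(all(pvals >= 0 & pvals <= 1), "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' PTM-restricted differential expression screen
#'
#' Restricts a log2-scale expression matrix to genes on a user-supplied
#' PTM (post-translational modification) gene list, computes per-gene log2
#' fold changes between two groups and Welch two-sample t-test p-values, and
#' applies BH FDR control across the tested PTM genes. A gene is called
#' significant when `fdr < 0.05` and `|log2fc| > 1`.
#'
#' @param expr numeric matrix, genes x samples, log2-scale normalized values.
#'   Row names are gene IDs, column names sample IDs.
#' @param groups binary group labels (0/1, logical, or 2-level factor), one
#'   per column of `expr`. The fold change is group 1 minus group 0.
#' @param ptm_genes named character vector mapping gene ID to PTM category
#'   (e.g. "ubiquitination"), or a data.frame with columns `gene`, `category`.
#' @param fdr_cut,lfc_cut significance thresholds (defaults 0.05 and 1).
#' @return data.frame with columns `gene`, `log2fc`, `p`, `fdr`,
#'   `ptm_category`, `significant`, one row per tested PTM gene.
#' @export
differential_expression <- function(expr, groups, ptm_genes,
                                    fdr_cut = 0.05, lfc_cut = 1) {
  assert(is.matrix(expr) && is.numeric(expr), "expr must be a numeric matrix")
  assert(!is.null(rownames(expr)), "expr must have gene row names")
  assert(anyDuplicated(rownames(expr)) == 0L, "gene IDs must be unique")
  if (is.data.frame(ptm_genes)) {
    assert(all(c("gene", "category") %in% names(ptm_genes)),
           "ptm_genes data.frame needs columns 'gene' and 'category'")
    ptm_genes <- setNames(as.character(ptm_genes$category),
                          as.character(ptm_genes$gene))
  }
  assert(length(ptm_genes) > 0, "ptm_genes must be nonempty")

  g <- as.integer(as.factor(groups)) - 1L
  assert(length(g) == ncol(expr), "groups length must match sample count")
  assert(all(g %in% c(0L, 1L)), "groups must be binary")
  if (sum(g == 0L) < 2L || sum(g == 1L) < 2L)
    abort("each group needs at least 2 samples")

  keep <- intersect(rownames(expr), names(ptm_genes))
  assert(length(keep) > 0, "no PTM genes found in the expression matrix")
  x <- expr[keep, , drop = FALSE]
  x <- x[complete.cases(x), , drop = FALSE]  # drop genes with any NA

  x0 <- x[, g == 0L, drop = FALSE]
  x1 <- x[, g == 1L, drop = FALSE]
  n0 <- ncol(x0); n1 <- ncol(x1)
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- apply(x0, 1, var); v1 <- apply(x1, 1, var)

  log2fc <- m1 - m0
  se2 <- v0 / n0 + v1 / n1
  tt <- (m1 - m0) / sqrt(se2)
  # Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * pt(abs(tt), df = df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(abs(log2fc[se2 == 0]) > 0, 0, 1)
  fdr <- bh_fdr(p)

  out <- data.frame(
    gene = rownames(x),
    log2fc = unname(log2fc),
    p = unname(p),
    fdr = unname(fdr),
    ptm_category = unname(ptm_genes[rownames(x)]),
    significant = unname(fdr < fdr_cut & abs(log2fc) > lfc_cut),
    stringsAsFactors = FALSE
  )
  out[order(out$fdr, out$p), , drop = FALSE]
}
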