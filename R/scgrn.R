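# Single-cell companion stage: QC, CPM normalization, consensus gene
# regulatory network (GRN) inference by subsampled principal-component
# regression with CP tensor denoising, pseudo-knockout perturbation, and
# manifold-alignment displacement ranking. Adjacency convention: rows are
# regulators, columns are targets.

#' Single-cell quality control
#'
#' Gene filter first: genes detected (count > 0) in fewer than `min_cells`
#' cells are dropped. Cell filters are then applied on the gene-filtered
#' matrix: cells with fewer than `min_genes` or more than `max_genes`
#' detected genes, or with mitochondrial fraction above `max_mito`
#' (strictly), are removed. Mitochondrial genes are identified by a name
#' prefix (default `"MT-"`).
#'
#' @param m genes x cells nonnegative count matrix with dimnames.
#' @param min_cells,min_genes,max_genes,max_mito QC thresholds
#'   (defaults 10, 200, 5000, 0.10).
#' @param mito_prefix mitochondrial gene-name prefix (default "MT-").
#' @return filtered count matrix; attributes `removed_genes` and
#'   `removed_cells` record what was dropped.
#' @export
sc_qc <- function(m, min_cells = 10, min_genes = 200, max_genes = 5000,
                  max_mito = 0.10, mito_prefix = "MT-") {
  m <- as.matrix(m)
  assert(nrow(m) > 0 && ncol(m) > 0, "empty matrix")
  assert(all(m >= 0), "counts must be nonnegative")
  assert(!is.null(rownames(m)) && !is.null(colnames(m)),
         "counts need gene and cell names")

  det_cells <- rowSums(m > 0)
  gene_keep <- det_cells >= min_cells
  removed_genes <- rownames(m)[!gene_keep]
  m2 <- m[gene_keep, , drop = FALSE]

  detected <- colSums(m2 > 0)
  is_mito <- startsWith(rownames(m2), mito_prefix)
  tot <- colSums(m2)
  mito_frac <- if (any(is_mito))
    colSums(m2[is_mito, , drop = FALSE]) / pmax(tot, 1)
  else rep(0, ncol(m2))
  cell_keep <- detected >= min_genes & detected <= max_genes &
    mito_frac <= max_mito
  removed_cells <- colnames(m2)[!cell_keep]
  out <- m2[, cell_keep, drop = FALSE]
  if (ncol(out) == 0) abort("all cells removed by QC")
  attr(out, "removed_genes") <- removed_genes
  attr(out, "removed_cells") <- removed_cells
  out
}

#' Counts-per-million normalization with log1p
#'
#' Scales each cell to one million counts and applies `log1p`.
#'
#' @param m genes x cells count matrix (no zero-total cells).
#' @return genes x cells numeric matrix.
#' @export
cpm_normalize <- function(m) {
  m <- as.matrix(m)
  tot <- colSums(m)
  if (any(tot == 0)) abort("zero column total: run QC first")
  log1p(sweep(m, 2, tot, "/") * 1e6)
}

#' Single-subsample GRN by principal component regression
#'
#' For each target gene i, the top principal components of the remaining
#' genes (cells as observations) are computed; gene i's profile is
#' regressed on the PC scores and the coefficients are back-projected
#' through the loadings to per-regulator weights forming column i of the
#' adjacency. Gene rows are z-scored across cells first; the diagonal is
#' forced to zero.
#'
#' @param x normalized genes x cells matrix (e.g. [cpm_normalize()] output).
#' @param n_pcs number of principal components (default 20; reduced with a
#'   warning when the basis is rank-deficient).
#' @return weighted adjacency matrix (rows regulators, columns targets).
#' @export
pcnet <- function(x, n_pcs = 20L) {
  x <- as.matrix(x)
  G <- nrow(x); n <- ncol(x)
  assert(G >= 3, "need at least 3 genes")
  assert(n > n_pcs, "need more cells than principal components")
  # z-score genes across cells; guard constant genes
  mu <- rowMeans(x); s <- apply(x, 1, sd); s[s == 0] <- 1
  xs <- (x - mu) / s
  p_use <- min(n_pcs, G - 1L, n - 1L)
  if (p_use < n_pcs)
    warning(sprintf("rank-deficient PC basis: using %d PCs", p_use))

  W <- matrix(0, G, G, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(G)) {
    A <- t(xs[-i, , drop = FALSE])            # cells x (G-1)
    sv <- svd(A, nu = p_use, nv = p_use)
    y <- xs[i, ]
    # coefficients on scores S = U D: (S'S)^{-1} S' y = D^{-1} U' y
    b <- crossprod(sv$u, y) / sv$d[seq_len(p_use)]
    W[-i, i] <- sv$v %*% b                     # back-project to genes
  }
  diag(W) <- 0
  W
}

# keep the top fraction q of entries by |w| (off-diagonal), zero the rest
.sparsify_top <- function(W, q) {
  off <- abs(W[row(W) != col(W)])
  if (all(off == 0)) return(W)
  th <- quantile(off, probs = 1 - q, names = FALSE)
  W[abs(W) < th] <- 0
  diag(W) <- 0
  W
}

.khatri_rao <- function(B, C) {
  # column-wise Kronecker: (J*K) x R from B (J x R), C (K x R)
  R <- ncol(B)
  out <- matrix(0, nrow(B) * nrow(C), R)
  for (r in seq_len(R)) out[, r] <- kronecker(C[, r], B[, r])
  out
}

#' CP (CANDECOMP/PARAFAC) decomposition of a 3-way tensor by ALS
#'
#' Seeded random initialization; alternating least squares with column
#' normalization; stops at `max_iter` iterations or when the relative fit
#' change falls below `tol`. Errors out if the reconstruction error
#' increases for five consecutive iterations.
#'
#' @param tens numeric 3-way array.
#' @param rank CP rank.
#' @param seed integer seed for the initialization.
#' @param max_iter,tol iteration cap and relative-change tolerance
#'   (defaults 100, 1e-6).
#' @return list with factor matrices `A`, `B`, `C`, weights `lambda`, the
#'   reconstruction `est`, and `rel_error`.
#' @export
cp_als <- function(tens, rank = 3L, seed = 1L, max_iter = 100L, tol = 1e-6) {
  assert(length(dim(tens)) == 3, "tens must be a 3-way array")
  dims <- dim(tens)
  X1 <- matrix(aperm(tens, c(1, 2, 3)), dims[1], dims[2] * dims[3])
  X2 <- matrix(aperm(tens, c(2, 1, 3)), dims[2], dims[1] * dims[3])
  X3 <- matrix(aperm(tens, c(3, 1, 2)), dims[3], dims[1] * dims[2])
  nrmX <- sqrt(sum(tens^2))
  if (nrmX == 0) nrmX <- 1

  with_seed(seed, {
    A <- matrix(rnorm(dims[1] * rank), dims[1], rank)
    B <- matrix(rnorm(dims[2] * rank), dims[2], rank)
    C <- matrix(rnorm(dims[3] * rank), dims[3], rank)
    err_old <- Inf; bad <- 0L
    for (it in seq_len(max_iter)) {
      A <- X1 %*% .khatri_rao(B, C) %*%
        MASS_ginv(crossprod(B) * crossprod(C))
      A_n <- sqrt(colSums(A^2)); A_n[A_n == 0] <- 1; A <- sweep(A, 2, A_n, "/")
      B <- X2 %*% .khatri_rao(A, C) %*%
        MASS_ginv(crossprod(A) * crossprod(C))
      B_n <- sqrt(colSums(B^2)); B_n[B_n == 0] <- 1; B <- sweep(B, 2, B_n, "/")
      C <- X3 %*% .khatri_rao(A, B) %*%
        MASS_ginv(crossprod(A) * crossprod(B))
      lambda <- sqrt(colSums(C^2)); lambda[lambda == 0] <- 1
      C <- sweep(C, 2, lambda, "/")

      est1 <- sweep(A, 2, lambda, "*") %*% t(.khatri_rao(B, C))
      err <- sqrt(sum((X1 - est1)^2)) / nrmX
      if (err > err_old + 1e-12) bad <- bad + 1L else bad <- 0L
      if (bad >= 5L) abort("CP-ALS divergence: error increased 5 iterations")
      if (is.finite(err_old) && abs(err_old - err) < tol) { err_old <- err; break }
      err_old <- err
    }
    est <- array(sweep(A, 2, lambda, "*") %*% t(.khatri_rao(B, C)), dim = dims)
    list(A = A, B = B, C = C, lambda = lambda, est = est, rel_error = err_old)
  })
}

# Moore-Penrose pseudoinverse (small symmetric matrices)
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Consensus GRN by subsampling and CP tensor denoising
#'
#' Repeatedly subsamples cells, infers one PC-regression network per
#' subsample, keeps the top `top_q` fraction of entries by magnitude in
#' each, stacks the sparsified adjacencies into a G x G x n_nets tensor,
#' denoises it by rank-`cp_rank` CP decomposition, averages the
#' reconstruction over the third mode, and rescales to `max |w| = 1`.
#'
#' @param x normalized genes x cells matrix.
#' @param n_nets number of subsample networks (>= 2, default 10).
#' @param cells_per_net cells per subsample; default `min(500, 70%)`.
#' @param top_q retained fraction of edges per network (default 0.05).
#' @param cp_rank CP rank (default 3).
#' @param n_pcs PCs per network (default 20).
#' @param seed integer seed (subsampling and CP init).
#' @param net_fn network inference function `(x, n_pcs) -> adjacency`
#'   (default [pcnet()]).
#' @return consensus weighted adjacency, zero diagonal, max |w| = 1.
#' @export
consensus_grn <- function(x, n_nets = 10L, cells_per_net = NULL,
                          top_q = 0.05, cp_rank = 3L, n_pcs = 20L,
                          seed = 1L, net_fn = pcnet) {
  x <- as.matrix(x)
  assert(n_nets >= 2, "n_nets must be >= 2")
  n <- ncol(x); G <- nrow(x)
  if (is.null(cells_per_net)) cells_per_net <- min(500L, floor(0.7 * n))
  assert(cells_per_net <= n, "cells_per_net exceeds available cells")

  nets <- with_seed(seed, {
    lapply(seq_len(n_nets), function(k) {
      idx <- sample.int(n, cells_per_net)
      .sparsify_top(net_fn(x[, idx, drop = FALSE], n_pcs), top_q)
    })
  })
  tens <- array(unlist(nets), dim = c(G, G, n_nets))
  fit <- cp_als(tens, rank = cp_rank, seed = seed)
  W <- apply(fit$est, c(1, 2), mean)
  diag(W) <- 0
  mx <- max(abs(W))
  if (mx > 0) W <- W / mx
  dimnames(W) <- dimnames(nets[[1]])
  W
}

#' In-silico (pseudo) knockout of a gene
#'
#' Returns a copy of the network with all outgoing edges of `gene` (its
#' regulator row) set to zero; every other entry is unchanged.
#'
#' @param wt weighted adjacency (rows regulators, columns targets).
#' @param gene gene name (must be a row of `wt`).
#' @return perturbed adjacency.
#' @export
pseudo_ko <- function(wt, gene) {
  assert(is.matrix(wt) && nrow(wt) == ncol(wt), "wt must be square")
  if (!gene %in% rownames(wt)) abort(sprintf("unknown gene '%s'", gene))
  ko <- wt
  ko[gene, ] <- 0
  ko
}

#' Rank genes by manifold-alignment displacement between WT and KO networks
#'
#' Both networks are symmetrized (`(|W| + |W'|)/2`) and coupled through a
#' joint 2G x 2G matrix with identity cross-links of strength
#' `mu = 0.9 * mean(row sums)`. Genes are embedded with the `d_embed`
#' smallest nonzero eigenvectors of the joint graph Laplacian; each gene's
#' displacement is the Euclidean distance between its WT and KO rows.
#' Squared displacements scaled by their mean are referred to a
#' chi-squared(1) upper tail and BH-adjusted; `fdr < 0.05` flags
#' significant perturbation. The knocked-out gene (detected as the row
#' that differs, or given explicitly) is excluded from the ranking.
#'
#' @param wt,ko weighted adjacencies with identical gene order.
#' @param d_embed embedding dimension (default 30, capped at available).
#' @param ko_gene optional name of the knocked-out gene.
#' @param fdr_cut significance threshold (default 0.05).
#' @return data.frame `gene`, `delta`, `p`, `fdr`, `significant`, ordered
#'   by decreasing displacement (KO gene last with NA p/fdr).
#' @export
align_and_rank <- function(wt, ko, d_embed = 30L, ko_gene = NULL,
                           fdr_cut = 0.05) {
  assert(is.matrix(wt) && is.matrix(ko) && all(dim(wt) == dim(ko)),
         "wt and ko must be equal-size square matrices")
  assert(identical(rownames(wt), rownames(ko)), "gene order must match")
  G <- nrow(wt)
  genes <- rownames(wt)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(G))

  if (is.null(ko_gene)) {
    diff_rows <- which(rowSums(wt != ko) > 0)
    if (length(diff_rows) == 1L) ko_gene <- genes[diff_rows]
  }

  A_wt <- (abs(wt) + t(abs(wt))) / 2
  A_ko <- (abs(ko) + t(abs(ko))) / 2
  rs <- c(rowSums(A_wt), rowSums(A_ko))
  # the identity coupling must dominate the graph spectrum (2*mu above the
  # largest Laplacian eigenvalue, bounded by twice the max degree) so that
  # corresponding genes stay pinned and, for identical networks, the
  # retained modes are exactly the shared (zero-displacement) ones
  mu <- max(0.9 * mean(rs), 1.05 * max(rs))
  if (mu <= 0) mu <- 1e-8
  J <- rbind(cbind(A_wt, diag(mu, G)), cbind(diag(mu, G), A_ko))
  deg <- rowSums(J)
  if (any(deg == 0)) {
    warning("disconnected joint graph: adding uniform epsilon coupling")
    J <- J + 1e-8
    diag(J) <- diag(J) - 1e-8
    deg <- rowSums(J)
  }
  L <- diag(deg) - J
  ei <- eigen(L, symmetric = TRUE)
  vals <- rev(ei$values)            # ascending
  vecs <- ei$vectors[, rev(seq_len(2 * G)), drop = FALSE]
  # drop the trivial (zero) modes and the coupling band at >= 2*mu, which
  # holds the anti-aligned pair modes; what remains are the shared
  # structural modes whose two halves move only when the networks differ
  nz <- which(vals > max(vals) * 1e-10 & vals < 2 * mu * (1 - 1e-9))
  if (length(nz) == 0) nz <- which(vals > max(vals) * 1e-10)
  take <- nz[seq_len(min(d_embed, length(nz)))]
  E <- vecs[, take, drop = FALSE]

  delta <- sqrt(rowSums((E[seq_len(G), , drop = FALSE] -
                           E[G + seq_len(G), , drop = FALSE])^2))
  idx <- if (!is.null(ko_gene)) which(genes != ko_gene) else seq_len(G)
  ss <- sum(delta[idx]^2)
  p <- rep(NA_real_, G)
  if (ss < 1e-16) {
    p[idx] <- 1
  } else {
    stat <- delta[idx]^2 * length(idx) / ss
    p[idx] <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  fdr <- rep(NA_real_, G)
  fdr[idx] <- bh_fdr(p[idx])
  out <- data.frame(gene = genes, delta = delta, p = p, fdr = fdr,
                    significant = !is.na(fdr) & fdr < fdr_cut,
                    stringsAsFactors = FALSE)
  out[order(is.na(out$p), -out$delta), , drop = FALSE]
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric upper-tail enrichment of a hit set against
#' user-supplied gene sets within a universe, with BH correction across
#' sets.
#'
#' @param hits character vector of hit genes (subset of `universe`).
#' @param universe character vector of background genes (nonempty).
#' @param sets named list of character vectors (pathway/gene sets).
#' @return data.frame `set`, `n_set`, `n_hits`, `overlap`, `p`, `fdr`.
#' @export
ora <- function(hits, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  hits <- unique(hits)
  assert(all(hits %in% universe), "hits must be a subset of the universe")
  assert(is.list(sets) && length(sets) > 0 && !is.null(names(sets)),
         "sets must be a named list")

  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(s, hits))
    p <- phyper(ov - 1, length(s), length(universe) - length(s),
                length(hits), lower.tail = FALSE)
    data.frame(set = nm, n_set = length(s), n_hits = length(hits),
               overlap = ov, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}
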