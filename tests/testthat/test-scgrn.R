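test_that("QC thresholds sit exactly at the stated cutoffs", {
  # mito fraction: 9.9% kept, 10.0% kept, 10.1% removed (totals 1000)
  counts <- rbind(g1 = rep(300, 3), g2 = rep(300, 3), g3 = c(301, 300, 299),
                  "MT-1" = c(99, 100, 101))
  colnames(counts) <- c("a", "b", "c")
  out <- sc_qc(counts, min_cells = 0, min_genes = 2, max_genes = 5000,
               max_mito = 0.10)
  expect_setequal(colnames(out), c("a", "b"))
  expect_equal(attr(out, "removed_cells"), "c")

  # detected genes: 199 removed, 200 kept
  m <- matrix(1, 250, 2, dimnames = list(sprintf("g%d", 1:250), c("x", "y")))
  m[200:250, 1] <- 0       # cell x detects 199 genes
  out2 <- sc_qc(m, min_cells = 0, min_genes = 200, max_genes = 5000)
  expect_equal(colnames(out2), "y")

  # gene filter: detected in 9 cells removed, 10 kept; applied before cells
  m3 <- matrix(5, 3, 12, dimnames = list(c("g1", "g2", "g3"),
                                         sprintf("c%d", 1:12)))
  m3[1, 1:3] <- 0          # g1 detected in 9 cells
  out3 <- sc_qc(m3, min_cells = 10, min_genes = 1, max_genes = 5000)
  expect_equal(rownames(out3), c("g2", "g3"))
  expect_equal(attr(out3, "removed_genes"), "g1")
})

test_that("QC output is invariant to input row/column order", {
  sc <- make_sc(20, 100, hub_edges(), seed = 41, n_qc_mito = 3,
                n_qc_lowgenes = 3)
  a <- sc_qc(sc$counts, min_cells = 3, min_genes = 10, max_mito = 0.10)
  perm <- withr::with_seed(1, list(r = sample(nrow(sc$counts)),
                                   c = sample(ncol(sc$counts))))
  b <- sc_qc(sc$counts[perm$r, perm$c], min_cells = 3, min_genes = 10,
             max_mito = 0.10)
  expect_setequal(rownames(a), rownames(b))
  expect_setequal(colnames(a), colnames(b))
  expect_equal(a[rownames(b), colnames(b)], b, ignore_attr = TRUE)
})

test_that("CPM normalization identities hold", {
  withr::with_seed(42, m <- matrix(rpois(50, 20), 5, 10))
  dimnames(m) <- list(sprintf("g%d", 1:5), sprintf("c%d", 1:10))
  x <- cpm_normalize(m)
  expect_equal(colSums(expm1(x)), rep(1e6, 10), ignore_attr = TRUE)
  x2 <- cpm_normalize(cbind(m, 2 * m[, 1]))
  expect_equal(unname(x2[, 11]), unname(x[, 1]))
  xe <- cpm_normalize(matrix(3, 4, 2, dimnames = list(letters[1:4], c("a", "b"))))
  expect_equal(xe[, 1], xe[, 2], ignore_attr = TRUE)
  m0 <- m; m0[, 1] <- 0
  expect_error(cpm_normalize(m0), "zero column")
})

test_that("PC-regression networks are near-zero for independent genes", {
  sc <- make_sc(10, 1000, NULL, seed = 43, n_mito = 0)
  W <- pcnet(cpm_normalize(sc$counts), n_pcs = 9)
  off <- row(W) != col(W)
  expect_lt(mean(abs(W[off])), 0.05)
  expect_true(all(diag(W) == 0))
})

test_that("pcnet is equivariant under gene permutation", {
  sc <- make_sc(8, 300, hub_edges(), seed = 44, n_mito = 0)
  x <- cpm_normalize(sc$counts)
  W <- pcnet(x, n_pcs = 7)
  perm <- c(3, 1, 8, 2, 5, 4, 7, 6)
  Wp <- pcnet(x[perm, ], n_pcs = 7)
  expect_equal(Wp, W[perm, perm], tolerance = 1e-6)
})

test_that("a planted SEM is recovered with AUROC > 0.8 by a single network", {
  sc <- make_sc(10, 500, hub_edges(), seed = 45, n_mito = 0)
  W <- pcnet(cpm_normalize(sc$counts), n_pcs = 9)
  truth <- sc$grn_true != 0
  off <- row(W) != col(W)
  expect_gt(auroc(abs(W)[off], truth[off]), 0.8)
})

test_that("CP decomposition: exact rank-1 recovery and identical-slice consensus", {
  withr::with_seed(46, { a <- rnorm(6); b <- rnorm(5); cc <- rnorm(4) })
  tens <- array(outer(outer(a, b), cc), c(6, 5, 4))
  fit <- cp_als(tens, rank = 1, seed = 2)
  expect_lt(fit$rel_error, 1e-6)
  expect_lt(max(abs(fit$est - tens)), 1e-6 * max(abs(tens)))

  # identical low-rank slices: the averaged reconstruction is the slice
  withr::with_seed(47, {
    W <- outer(rnorm(6), rnorm(6)) + outer(rnorm(6), rnorm(6))
  })
  tens2 <- array(rep(W, 5), c(6, 6, 5))
  fit2 <- cp_als(tens2, rank = 3, seed = 3)
  cons <- apply(fit2$est, c(1, 2), mean)
  expect_gt(cor(as.vector(cons), as.vector(W)), 0.999999)
})

test_that("consensus networks are deterministic and properly normalized", {
  sc <- make_sc(10, 400, hub_edges(), seed = 48, n_mito = 0)
  x <- cpm_normalize(sc$counts)
  W1 <- consensus_grn(x, n_nets = 5, cells_per_net = 250, n_pcs = 9, seed = 4)
  W2 <- consensus_grn(x, n_nets = 5, cells_per_net = 250, n_pcs = 9, seed = 4)
  expect_identical(W1, W2)
  expect_equal(max(abs(W1)), 1)
  expect_true(all(diag(W1) == 0))
})

test_that("pseudo-knockout zeroes exactly the outgoing-edge row", {
  withr::with_seed(49, W <- matrix(rnorm(25), 5, 5))
  diag(W) <- 0
  dimnames(W) <- list(paste0("g", 1:5), paste0("g", 1:5))
  ko <- pseudo_ko(W, "g2")
  expect_true(all(ko["g2", ] == 0))
  expect_identical(ko[-2, ], W[-2, ])
  expect_error(pseudo_ko(W, "nope"), "unknown gene")
  # a gene with no outgoing edges: knockout is a no-op
  W0 <- W; W0["g4", ] <- 0
  expect_identical(pseudo_ko(W0, "g4"), W0)
})

test_that("alignment of a network with itself is a zero map", {
  sc <- make_sc(10, 300, hub_edges(), seed = 50, n_mito = 0)
  W <- suppressWarnings(consensus_grn(cpm_normalize(sc$counts), n_nets = 5,
                                      cells_per_net = 200, n_pcs = 9, seed = 5))
  pr <- align_and_rank(W, W)
  expect_lt(max(pr$delta), 1e-8)
  expect_equal(sum(pr$significant), 0)
})

test_that("knocking out a hub ranks its direct targets by displacement", {
  sc <- make_sc(10, 500, hub_edges(), seed = 51, n_mito = 0)
  W <- consensus_grn(cpm_normalize(sc$counts), n_nets = 10,
                     cells_per_net = 350, n_pcs = 9, seed = 6)
  pr <- align_and_rank(W, pseudo_ko(W, "g1"))
  expect_true(is.na(pr$p[pr$gene == "g1"]))
  nk <- pr[pr$gene != "g1", ]
  tgt <- paste0("g", 2:6)
  expect_gt(auroc(nk$delta, nk$gene %in% tgt), 0.8)
  # mean rank of true targets within the top 2*|T| positions
  expect_lte(mean(match(tgt, nk$gene)), 2 * length(tgt))
})

test_that("knockout of an isolated gene perturbs nothing", {
  W <- matrix(0, 6, 6, dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  W[1, 2:4] <- c(0.8, -0.6, 0.5); W[2, 5] <- 0.7
  pr <- align_and_rank(W, pseudo_ko(W, "g6"))
  expect_equal(sum(pr$significant), 0)
})

test_that("hypergeometric enrichment matches the exact tail sum", {
  universe <- sprintf("u%d", 1:20)
  set5 <- universe[1:5]
  hits <- c(universe[1:4], universe[10])
  res <- ora(hits, universe, list(s = set5))
  p_manual <- sum(choose(5, 4:5) * choose(15, 1:0)) / choose(20, 5)
  expect_equal(res$p, p_manual, tolerance = 1e-12)
  expect_equal(res$overlap, 4)

  res0 <- ora(universe[10:12], universe, list(s = universe[1:4]))
  expect_gte(res0$p, 0.5)
  resd <- ora(universe, universe, list(s = universe))
  expect_equal(resd$p, 1)
  expect_error(ora("x", character(0), list(s = "x")), "empty universe")
  expect_error(ora("zz", universe, list(s = set5)), "subset")
})
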