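# Synthetic fixtures with full ground truth: stained slides, survival-linked
# multimodal cohorts, and SEM-generated single-cell counts. All generators
# are pure functions of (arguments, seed).

# default H&E stain matrix (columns: hematoxylin, eosin; rows: R,G,B optical
# density), unit-normalized Ruifrok-style vectors
default_stain_matrix <- function() {
  s <- cbind(h = c(0.650, 0.704, 0.286), e = c(0.072, 0.990, 0.105))
  sweep(s, 2, sqrt(colSums(s^2)), "/")
}

# optical density <-> 8-bit intensity (I0 = 256 with +1 offset)
od_from_rgb <- function(I) -log10((I + 1) / 256)
rgb_from_od <- function(od) {
  I <- 256 * 10^(-od) - 1
  round(pmin(pmax(I, 0), 255))
}

# rasterize one rotated ellipse; returns (row, col) pixel matrix
.ellipse_pixels <- function(cx, cy, a, b, theta, h, w) {
  r_max <- ceiling(max(a, b))
  rows <- max(1, floor(cy - r_max)):min(h, ceiling(cy + r_max))
  cols <- max(1, floor(cx - r_max)):min(w, ceiling(cx + r_max))
  g <- expand.grid(row = rows, col = cols)
  dx <- g$col - cx; dy <- g$row - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  as.matrix(g[u^2 + v^2 <= 1, c("row", "col"), drop = FALSE])
}

#' Generate a synthetic stained slide with ground truth
#'
#' Renders a white-background RGB image with an eosin-tinted tissue region
#' covering approximately `tissue_coverage` of the area and
#' hematoxylin-dark elliptical nuclei at recorded positions. Stains mix
#' linearly in optical-density space through a known stain matrix so that
#' stain unmixing has a recoverable ground truth.
#'
#' @param width,height image dimensions in pixels (>= 64).
#' @param n_nuclei number of nuclei to place (centers always inside tissue).
#' @param tissue_coverage target tissue area fraction in \[0, 1\].
#' @param seed integer seed; regeneration is identical.
#' @param radius_range nucleus semi-major axis range in px (default c(5, 12)).
#' @param stain_matrix 3 x 2 OD-space stain matrix (hematoxylin, eosin);
#'   default [default_stain_matrix()].
#' @return list of class `synthetic_slide` with `image` (H x W x 3, 0-255),
#'   `tissue_mask` (logical H x W), `nuclei` (data.frame cx, cy, radius,
#'   axis_ratio, theta), `stain_matrix_true`.
#' @export
make_slide <- function(width, height, n_nuclei, tissue_coverage, seed,
                       radius_range = c(5, 12),
                       stain_matrix = default_stain_matrix()) {
  assert(width >= 64 && height >= 64, "dimensions must be >= 64 px")
  assert(tissue_coverage >= 0 && tissue_coverage <= 1,
         "tissue_coverage must be in [0, 1]")
  assert(n_nuclei >= 0, "n_nuclei must be >= 0")
  assert(radius_range[1] > 3 && radius_range[2] <= 30,
         "nucleus radii must lie in (3, 30] px")
  if (n_nuclei > 0 && tissue_coverage == 0)
    abort("tissue coverage 0 cannot host nuclei")

  with_seed(seed, {
    h <- height; w <- width
    # tissue blob: quantile-thresholded smoothed noise -> exact area fraction
    if (tissue_coverage == 0) {
      mask <- matrix(FALSE, h, w)
    } else if (tissue_coverage == 1) {
      mask <- matrix(TRUE, h, w)
    } else {
      noise <- matrix(rnorm(h * w), h, w)
      sm <- as.matrix(EBImage::gblur(EBImage::Image(noise),
                                     sigma = min(h, w) / 10))
      mask <- sm <= quantile(sm, tissue_coverage)
    }
    if (n_nuclei > 0 && sum(mask) < n_nuclei * pi * radius_range[2]^2 * 2)
      abort("tissue coverage infeasible for requested nuclei count")

    # place non-touching nuclei with centers inside the tissue mask
    nuclei <- data.frame(cx = numeric(0), cy = numeric(0), radius = numeric(0),
                         axis_ratio = numeric(0), theta = numeric(0))
    if (n_nuclei > 0) {
      mask_idx <- which(mask)  # column-major linear indices
      tries <- 0L
      while (nrow(nuclei) < n_nuclei) {
        tries <- tries + 1L
        if (tries > 300L * n_nuclei)
          abort("tissue coverage infeasible for requested nuclei count")
        pix <- mask_idx[sample.int(length(mask_idx), 1L)]
        cy <- ((pix - 1L) %% h) + 1L
        cx <- ((pix - 1L) %/% h) + 1L
        r <- runif(1, radius_range[1], radius_range[2])
        if (nrow(nuclei) > 0 &&
            any(sqrt((nuclei$cx - cx)^2 + (nuclei$cy - cy)^2) <
                  nuclei$radius + r + 4)) next
        nuclei <- rbind(nuclei, data.frame(
          cx = cx, cy = cy, radius = r,
          axis_ratio = runif(1, 0.65, 1), theta = runif(1, 0, pi)))
      }
    }

    # concentrations: eosin-rich tissue, hematoxylin-dominant nuclei
    c_h <- matrix(0, h, w); c_e <- matrix(0, h, w)
    if (any(mask)) {
      n_t <- sum(mask)
      c_e[mask] <- pmax(0.70 + 0.08 * rnorm(n_t), 0.30)
      c_h[mask] <- pmax(0.30 + 0.04 * rnorm(n_t), 0.15)
    }
    for (i in seq_len(nrow(nuclei))) {
      px <- .ellipse_pixels(nuclei$cx[i], nuclei$cy[i], nuclei$radius[i],
                            nuclei$radius[i] * nuclei$axis_ratio[i],
                            nuclei$theta[i], h, w)
      lin <- px[, 1] + (px[, 2] - 1L) * h
      c_h[lin] <- pmax(0.85 + 0.06 * rnorm(length(lin)), 0.50)
      c_e[lin] <- 0.15
    }

    conc <- rbind(as.vector(c_h), as.vector(c_e))
    od <- stain_matrix %*% conc  # 3 x npix
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- matrix(rgb_from_od(od[ch, ]), h, w)

    structure(class = "synthetic_slide", list(
      image = img, tissue_mask = mask, nuclei = nuclei,
      stain_matrix_true = stain_matrix,
      params = list(width = width, height = height, n_nuclei = n_nuclei,
                    tissue_coverage = tissue_coverage, seed = seed)))
  })
}

#' Generate a survival-linked multimodal cohort
#'
#' Latent factors `z ~ N(0, I)` drive both feature blocks (linear mixing
#' plus Gaussian noise) and proportional-hazards survival: event times are
#' exponential with hazard `h0 * exp(z %*% beta_true)` (baseline
#' `h0 = 0.01`/day) and censoring times are exponential with rate solved
#' numerically so the expected censoring fraction equals `censor_rate`.
#'
#' @param n samples (>= 20).
#' @param k latent factors (>= 1).
#' @param d_expr,d_path number of expression / pathomics features.
#' @param beta_true length-k log-hazard effects (at least one nonzero).
#' @param noise_sd feature noise standard deviation.
#' @param censor_rate target censoring fraction in \[0, 1).
#' @param seed integer seed.
#' @param h0 baseline hazard per day (default 0.01).
#' @return list of class `synthetic_cohort`: `features_expr` (n x d_expr),
#'   `features_path` (n x d_path), `survival` (sample, time, event),
#'   `z_true`, `loadings_expr`, `loadings_path`, `beta_true`, plus params.
#' @export
make_cohort <- function(n, k, d_expr, d_path, beta_true, noise_sd = 0.2,
                        censor_rate = 0.3, seed = 1L, h0 = 0.01) {
  assert(n >= 20, "n must be >= 20")
  assert(k >= 1, "k must be >= 1")
  assert(length(beta_true) == k, "beta_true must have length k")
  assert(any(beta_true != 0), "at least one beta entry must be nonzero")
  if (censor_rate >= 1) abort("censor_rate must be < 1")
  assert(censor_rate >= 0, "censor_rate must be >= 0")

  with_seed(seed, {
    z <- matrix(rnorm(n * k), n, k)
    L_e <- matrix(rnorm(k * d_expr), k, d_expr)
    L_p <- matrix(rnorm(k * d_path), k, d_path)
    fe <- z %*% L_e + noise_sd * matrix(rnorm(n * d_expr), n, d_expr)
    fp <- z %*% L_p + noise_sd * matrix(rnorm(n * d_path), n, d_path)
    samples <- sprintf("S%04d", seq_len(n))
    rownames(fe) <- rownames(fp) <- samples
    colnames(fe) <- sprintf("g%03d", seq_len(d_expr))
    colnames(fp) <- sprintf("f%03d", seq_len(d_path))

    hazard <- h0 * exp(as.numeric(z %*% beta_true))
    t_event <- rexp(n, rate = hazard)
    if (censor_rate == 0) {
      time <- t_event; event <- rep(1, n)
    } else {
      # solve mean_i c/(c + h_i) = censor_rate for the censoring rate c
      f <- function(cc) mean(cc / (cc + hazard)) - censor_rate
      cc <- uniroot(f, lower = 1e-10, upper = 1e6, tol = 1e-12)$root
      t_cens <- rexp(n, rate = cc)
      time <- pmin(t_event, t_cens)
      event <- as.numeric(t_event <= t_cens)
    }
    structure(class = "synthetic_cohort", list(
      features_expr = fe, features_path = fp,
      survival = data.frame(sample = samples, time = time, event = event,
                            stringsAsFactors = FALSE),
      z_true = z, loadings_expr = L_e, loadings_path = L_p,
      beta_true = beta_true,
      params = list(n = n, k = k, d_expr = d_expr, d_path = d_path,
                    noise_sd = noise_sd, censor_rate = censor_rate,
                    seed = seed, h0 = h0)))
  })
}

# edge list (regulator, target, weight) -> weighted adjacency matrix
grn_from_edges <- function(edges, genes) {
  W <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (!is.null(edges) && nrow(edges) > 0) {
    assert(all(c("regulator", "target", "weight") %in% names(edges)),
           "grn_spec needs columns regulator, target, weight")
    reg <- as.character(edges$regulator); tgt <- as.character(edges$target)
    assert(all(reg %in% genes) && all(tgt %in% genes),
           "grn_spec references unknown genes")
    assert(all(reg != tgt), "self-loops are not allowed")
    W[cbind(match(reg, genes), match(tgt, genes))] <- edges$weight
  }
  W
}

#' Generate single-cell counts from a linear structural equation model
#'
#' Steady-state expression per cell is `x = (I - t(W))^-1 eps` with
#' `eps ~ N(0, 1)` and `W` the signed regulator-by-target adjacency built
#' from `grn_spec`. Expression is shifted, exponentiated, scaled by a
#' lognormal(0, 0.3) per-cell library factor, and Poisson-sampled into
#' counts. A block of mitochondrial genes (prefix `MT-`) independent of the
#' network is appended, and QC-violating cells (high mitochondrial fraction,
#' low detected-gene complexity) are planted at recorded indices.
#'
#' @param n_genes number of network genes (named `g1..`).
#' @param n_cells number of cells.
#' @param grn_spec NULL (no edges) or a data.frame with columns `regulator`,
#'   `target`, `weight`; spectral radius of the adjacency must be < 1.
#' @param seed integer seed.
#' @param n_mito number of appended mitochondrial genes (default 4).
#' @param n_qc_mito,n_qc_lowgenes number of planted high-mito /
#'   low-complexity cells (defaults 0).
#' @param base_log_mean baseline log expression shift (default log(5)).
#' @return list of class `synthetic_sc`: `counts` (genes x cells integers,
#'   mito rows last), `grn_true` (network genes only), `mito_fracs`,
#'   `genes_detected`, `qc_mito_cells`, `qc_lowgene_cells`, params.
#' @export
make_sc <- function(n_genes, n_cells, grn_spec = NULL, seed = 1L,
                    n_mito = 4L, n_qc_mito = 0L, n_qc_lowgenes = 0L,
                    base_log_mean = log(5)) {
  assert(n_genes >= 2, "need at least 2 genes")
  assert(n_cells >= 10, "need at least 10 cells")
  genes <- sprintf("g%d", seq_len(n_genes))
  W <- grn_from_edges(grn_spec, genes)
  if (any(W != 0)) {
    rho <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (rho >= 1) abort("GRN spectral radius must be < 1")
  }

  with_seed(seed, {
    eps <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells)
    x <- solve(diag(n_genes) - t(W), eps)
    lib <- exp(rnorm(n_cells, 0, 0.3))
    lambda <- exp(base_log_mean + x) * rep(lib, each = n_genes)
    counts <- matrix(rpois(length(lambda), lambda), n_genes, n_cells)

    mito_genes <- if (n_mito > 0) sprintf("MT-%d", seq_len(n_mito)) else character(0)
    if (n_mito > 0) {
      lam_m <- exp(base_log_mean + matrix(rnorm(n_mito * n_cells, 0, 0.5),
                                          n_mito, n_cells)) *
        rep(lib, each = n_mito) * 0.15
      counts <- rbind(counts, matrix(rpois(length(lam_m), lam_m),
                                     n_mito, n_cells))
    }
    rownames(counts) <- c(genes, mito_genes)
    colnames(counts) <- sprintf("cell%d", seq_len(n_cells))

    viol <- sample.int(n_cells, n_qc_mito + n_qc_lowgenes)
    qc_mito <- sort(head(viol, n_qc_mito))
    qc_low <- sort(tail(viol, n_qc_lowgenes))
    if (n_qc_mito > 0) {
      assert(n_mito > 0, "planting mito violations requires n_mito > 0")
      for (j in qc_mito) {
        tot <- sum(counts[genes, j])
        # push mitochondrial content to ~25% of the cell's UMIs
        target <- ceiling(tot / 3)
        add <- as.vector(stats::rmultinom(1, target, rep(1, n_mito)))
        counts[mito_genes, j] <- counts[mito_genes, j] + add
      }
    }
    if (n_qc_lowgenes > 0) {
      keep_n <- max(2L, round(0.1 * n_genes))
      for (j in qc_low) {
        zero <- sample(seq_len(n_genes), n_genes - keep_n)
        counts[zero, j] <- 0L
        counts[mito_genes, j] <- 0L
      }
    }

    mito_fracs <- if (n_mito > 0)
      colSums(counts[mito_genes, , drop = FALSE]) / pmax(colSums(counts), 1)
    else rep(0, n_cells)
    structure(class = "synthetic_sc", list(
      counts = counts, grn_true = W, mito_fracs = mito_fracs,
      genes_detected = colSums(counts > 0),
      qc_mito_cells = colnames(counts)[qc_mito],
      qc_lowgene_cells = colnames(counts)[qc_low],
      params = list(n_genes = n_genes, n_cells = n_cells, seed = seed,
                    n_mito = n_mito, n_qc_mito = n_qc_mito,
                    n_qc_lowgenes = n_qc_lowgenes)))
  })
}

#' Write synthetic artifacts to disk with sidecar metadata
#'
#' Slides are written as image PNG + mask PNG + nuclei CSV; cohorts as
#' `features.tsv` + `survival.tsv`; single-cell data as MatrixMarket MTX +
#' features/barcodes TSVs. Every artifact gets a `*_meta.json` sidecar with
#' the generator's seed and parameters.
#'
#' @param x a `synthetic_slide`, `synthetic_cohort` or `synthetic_sc`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "synthetic").
#' @return invisibly, the written file paths.
#' @export
write_synthetic <- function(x, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, paste0(prefix, "_", f))
  files <- character(0)
  if (inherits(x, "synthetic_slide")) {
    png::writePNG(x$image / 255, p("image.png"))
    png::writePNG(x$tissue_mask * 1, p("mask.png"))
    write.table(x$nuclei, p("nuclei.csv"), sep = ",", row.names = FALSE)
    files <- c(p("image.png"), p("mask.png"), p("nuclei.csv"))
  } else if (inherits(x, "synthetic_cohort")) {
    feat <- cbind(data.frame(sample = rownames(x$features_expr)),
                  as.data.frame(x$features_expr),
                  as.data.frame(x$features_path))
    write.table(feat, p("features.tsv"), sep = "\t", row.names = FALSE)
    write.table(x$survival, p("survival.tsv"), sep = "\t", row.names = FALSE)
    files <- c(p("features.tsv"), p("survival.tsv"))
  } else if (inherits(x, "synthetic_sc")) {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), p("matrix.mtx"))
    writeLines(rownames(x$counts), p("features.tsv"))
    writeLines(colnames(x$counts), p("barcodes.tsv"))
    files <- c(p("matrix.mtx"), p("features.tsv"), p("barcodes.tsv"))
  } else abort("unknown synthetic artifact")
  jsonlite::write_json(x$params, p("meta.json"), auto_unbox = TRUE)
  invisible(c(files, p("meta.json")))
}
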