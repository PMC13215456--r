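# Slide image -> per-sample pathomics features: non-overlapping tiling,
# Otsu tissue masking, Macenko stain normalization, pooled deep
# convolutional features and curated morphometrics.

.check_rgb <- function(image) {
  assert(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3,
         "image must be an H x W x 3 array")
  assert(all(is.finite(image)), "image must be finite")
}

#' Partition a slide into non-overlapping square tiles
#'
#' Tiles are emitted row-major with 0-based grid indices; right/bottom
#' remainders smaller than a full tile are dropped, so partial edge tiles
#' are never produced.
#'
#' @param image H x W x 3 RGB array (0-255).
#' @param tile_size tile edge length in px (default 512).
#' @return list of tile records: `row`, `col` (0-based), `pixels`
#'   (tile_size x tile_size x 3).
#' @export
tile_slide <- function(image, tile_size = 512L) {
  .check_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < tile_size || w < tile_size)
    abort("image smaller than one tile")
  nr <- h %/% tile_size; nc <- w %/% tile_size
  out <- vector("list", nr * nc)
  i <- 0L
  for (r in seq_len(nr) - 1L) for (cc in seq_len(nc) - 1L) {
    i <- i + 1L
    out[[i]] <- list(
      row = r, col = cc,
      pixels = image[r * tile_size + seq_len(tile_size),
                     cc * tile_size + seq_len(tile_size), , drop = FALSE])
  }
  out
}

#' Otsu-derived tissue mask
#'
#' Converts to luminance, applies Otsu's threshold to the intensity
#' histogram, and marks pixels darker than the threshold as tissue. A
#' constant image has no separable classes and yields an all-false mask
#' with a warning.
#'
#' @param image H x W x 3 RGB array (0-255).
#' @return logical H x W matrix (TRUE = tissue).
#' @export
tissue_mask <- function(image) {
  .check_rgb(image)
  gray <- (0.299 * image[, , 1] + 0.587 * image[, , 2] +
             0.114 * image[, , 3]) / 255
  if (diff(range(gray)) == 0) {
    warning("constant image: no separable classes, mask is all false")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  th <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1), levels = 256)
  gray < th
}

#' Compute tissue fractions and retain informative tiles
#'
#' Each tile's tissue fraction is the masked-pixel share of its area; a
#' tile is retained iff the fraction strictly exceeds `min_fraction`.
#'
#' @param tiles tile list from [tile_slide()].
#' @param mask logical tissue mask with the dimensions of the source slide.
#' @param min_fraction retention threshold (default 0.80, strict).
#' @return the tile list with `tissue_fraction` and `retained` added.
#' @export
filter_tiles <- function(tiles, mask, min_fraction = 0.80) {
  assert(is.matrix(mask), "mask must be a matrix")
  lapply(tiles, function(tl) {
    ts <- dim(tl$pixels)[1]
    assert(tl$row * ts + ts <= nrow(mask) && tl$col * ts + ts <= ncol(mask),
           "mask dimensions do not cover the tile grid")
    sub <- mask[tl$row * ts + seq_len(ts), tl$col * ts + seq_len(ts)]
    tl$tissue_fraction <- mean(sub)
    tl$retained <- tl$tissue_fraction > min_fraction
    tl
  })
}

# hematoxylin = the blue-appearing stain, i.e. the column absorbing more
# strongly in red (larger red-OD component)
.order_stains <- function(s) {
  if (s[1, 1] >= s[1, 2]) s else s[, 2:1]
}

# exact nonnegative least squares for a 2-column design, vectorized over
# pixels: od is 3 x n, s is 3 x 2; returns 2 x n concentrations
.nnls2 <- function(s, od) {
  G <- crossprod(s)           # 2 x 2
  b <- crossprod(s, od)       # 2 x n
  cu <- solve(G, b)           # unconstrained solution
  neg <- cu[1, ] < 0 | cu[2, ] < 0
  if (any(neg)) {
    bn <- b[, neg, drop = FALSE]
    c1 <- pmax(bn[1, ] / G[1, 1], 0)   # stain 1 only
    c2 <- pmax(bn[2, ] / G[2, 2], 0)   # stain 2 only
    odn <- od[, neg, drop = FALSE]
    r1 <- colSums((odn - s[, 1] %o% c1)^2)
    r2 <- colSums((odn - s[, 2] %o% c2)^2)
    use1 <- r1 <= r2
    cu[1, neg] <- ifelse(use1, c1, 0)
    cu[2, neg] <- ifelse(use1, 0, c2)
  }
  cu
}

#' Estimate stain vectors by the Macenko procedure
#'
#' Pixels are mapped to optical density (`-log10((I+1)/256)`); pixels with
#' any channel below `beta_od` are discarded as unstained. The two leading
#' eigenvectors of the OD covariance define a plane; the extreme projection
#' angles at the `alpha_pct` and `100 - alpha_pct` percentiles give the two
#' stain directions. Hematoxylin is identified as the blue-appearing stain
#' (larger red-channel OD). Concentrations come from exact nonnegative
#' least squares; reference maxima are their 99th percentiles.
#'
#' @param image H x W x 3 RGB array (0-255).
#' @param beta_od minimum per-channel OD for a stained pixel (default 0.15).
#' @param alpha_pct extreme-angle percentile (default 1).
#' @return list of class `stain_model` with `stain_matrix` (3 x 2 unit
#'   columns: hematoxylin, eosin) and `max_concentrations` (length 2).
#' @export
estimate_stains <- function(image, beta_od = 0.15, alpha_pct = 1) {
  .check_rgb(image)
  od <- apply(image, 3, function(ch) od_from_rgb(as.vector(ch)))  # n x 3
  keep <- rowSums(od < beta_od) == 0
  if (sum(keep) < 100) abort("insufficient stained tissue")
  odk <- od[keep, , drop = FALSE]

  V <- eigen(stats::cov(odk), symmetric = TRUE)$vectors[, 1:2]
  # orient the plane basis so projections on the first axis are positive,
  # keeping the stain cone contiguous in angle (no atan2 wrap-around)
  proj <- odk %*% V
  if (mean(proj[, 1]) < 0) { V[, 1] <- -V[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  ex <- quantile(phi, c(alpha_pct, 100 - alpha_pct) / 100, names = FALSE)
  dirs <- V %*% rbind(cos(ex), sin(ex))   # 3 x 2
  # orient into the nonnegative OD octant and unit-normalize
  for (j in 1:2) {
    if (sum(dirs[, j]) < 0) dirs[, j] <- -dirs[, j]
    dirs[, j] <- pmax(dirs[, j], 0)
    dirs[, j] <- dirs[, j] / sqrt(sum(dirs[, j]^2))
  }
  s <- .order_stains(dirs)
  conc <- .nnls2(s, t(odk))
  structure(class = "stain_model", list(
    stain_matrix = s,
    max_concentrations = apply(conc, 1, quantile, probs = 0.99, names = FALSE)))
}

#' Normalize a tile to a reference stain model
#'
#' Unmixes the tile under the source model, rescales each stain
#' concentration by the ratio of reference to source maxima, and
#' reconstructs through the reference stain matrix.
#'
#' @param tile H x W x 3 RGB array (0-255).
#' @param source `stain_model` of the tile's slide.
#' @param reference target `stain_model`.
#' @return normalized H x W x 3 uint8-valued array.
#' @export
normalize_tile <- function(tile, source, reference) {
  .check_rgb(tile)
  assert(inherits(source, "stain_model") && inherits(reference, "stain_model"),
         "source and reference must be stain models")
  h <- dim(tile)[1]; w <- dim(tile)[2]
  od <- rbind(od_from_rgb(as.vector(tile[, , 1])),
              od_from_rgb(as.vector(tile[, , 2])),
              od_from_rgb(as.vector(tile[, , 3])))
  conc <- .nnls2(source$stain_matrix, od)
  conc <- conc * (reference$max_concentrations / source$max_concentrations)
  od_new <- reference$stain_matrix %*% conc
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) out[, , ch] <- matrix(rgb_from_od(od_new[ch, ]), h, w)
  out
}

# ---- deep feature backbone -------------------------------------------------

# 3x3 convolution via im2col + GEMM; x is H x W x Cin, wmat (9*Cin) x Cout
.conv3x3 <- function(x, wmat, bias, stride) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  xp <- array(0, dim = c(h + 2, w + 2, cin))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  ho <- (h + 2 - 3) %/% stride + 1L
  wo <- (w + 2 - 3) %/% stride + 1L
  ri <- seq(1L, by = stride, length.out = ho)
  ci <- seq(1L, by = stride, length.out = wo)
  cols <- matrix(0, ho * wo, 9L * cin)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    patch <- xp[ri + di, ci + dj, , drop = FALSE]
    cols[, k + seq_len(cin)] <- matrix(patch, ho * wo, cin)
    k <- k + cin
  }
  y <- cols %*% wmat
  y <- sweep(y, 2, bias, "+")
  array(y, dim = c(ho, wo, ncol(wmat)))
}

relu <- function(x) { x[x < 0] <- 0; x }

#' Seeded tiny residual convolutional backbone
#'
#' A five-stage residual encoder mapping a 224 x 224 x 3 input to a
#' 7 x 7 x C activation grid: stages 1-4 apply a stride-2 3x3 convolution
#' + ReLU followed by a stride-1 3x3 residual block; the final stage is a
#' stride-2 projection to the feature dimension C. Weights are
#' He-initialized from the seed and frozen; the backbone is a fixed
#' random feature extractor satisfying the [deep_features()] contract.
#' The release configuration uses `channels = c(8, 16, 16, 32, 2048)` to
#' match a ResNet-50-style 2048-channel final stage; tests use a
#' 32-channel tail.
#'
#' @param channels per-stage output channel counts (length 5; last entry
#'   is the feature dimension C).
#' @param seed integer seed for weight initialization.
#' @return list of class `conv_backbone`.
#' @export
tiny_backbone <- function(channels = c(8, 16, 16, 32, 32), seed = 1L) {
  assert(length(channels) == 5, "channels must have length 5 (stride-2 stages)")
  with_seed(seed, {
    cin <- 3L
    stages <- vector("list", 5L)
    for (s in 1:5) {
      cout <- channels[s]
      w_down <- matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                       9 * cin, cout)
      w_res <- if (s < 5)
        matrix(rnorm(9 * cout * cout, sd = sqrt(2 / (9 * cout))),
               9 * cout, cout)
      else NULL
      stages[[s]] <- list(w_down = w_down, b_down = rep(0, cout),
                          w_res = w_res, b_res = rep(0, cout))
      cin <- cout
    }
    structure(class = "conv_backbone",
              list(stages = stages, channels = channels, seed = seed))
  })
}

#' Run a backbone forward pass
#'
#' @param backbone a `conv_backbone` (or a plain function of the
#'   standardized 224 x 224 x 3 array).
#' @param x standardized 224 x 224 x 3 array.
#' @return activation array H' x W' x C (7 x 7 x C for a 224 input).
#' @export
backbone_forward <- function(backbone, x) {
  if (is.function(backbone)) return(backbone(x))
  assert(inherits(backbone, "conv_backbone"), "invalid backbone")
  for (st in backbone$stages) {
    x <- relu(.conv3x3(x, st$w_down, st$b_down, stride = 2L))
    if (!is.null(st$w_res))
      x <- x + relu(.conv3x3(x, st$w_res, st$b_res, stride = 1L))
  }
  x
}

#' Pooled deep features for one tile
#'
#' Resizes the tile to 224 x 224, standardizes each channel with
#' ImageNet-style statistics (mean 0.485/0.456/0.406, SD 0.229/0.224/0.225
#' after scaling to \[0,1\]), runs the backbone, and reduces the C x 7 x 7
#' activation tensor to a C-vector by per-channel spatial maximum.
#'
#' @param tile H x W x 3 RGB array (0-255).
#' @param backbone `conv_backbone` or function; must produce a 7 x 7 grid.
#' @return named numeric C-vector (`path_resnet0` ... `path_resnet<C-1>`).
#' @export
deep_features <- function(tile, backbone) {
  .check_rgb(tile)
  img <- EBImage::resize(EBImage::Image(tile / 255, colormode = "Color"),
                         w = 224, h = 224)
  x <- as.array(img)
  mu <- c(0.485, 0.456, 0.406); sdv <- c(0.229, 0.224, 0.225)
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - mu[ch]) / sdv[ch]
  act <- backbone_forward(backbone, x)
  assert(length(dim(act)) == 3, "backbone must return a 3-d activation array")
  if (dim(act)[1] != 7 || dim(act)[2] != 7)
    abort("backbone output grid is not 7 x 7")
  v <- apply(act, 3, max)
  names(v) <- sprintf("path_resnet%d", seq_along(v) - 1L)
  v
}

#' Aggregate tile feature vectors to the slide level
#'
#' Element-wise mean over the retained tiles' deep feature vectors.
#'
#' @param tile_vectors list of equal-length named numeric vectors.
#' @return named numeric vector of the same length.
#' @export
aggregate_slide <- function(tile_vectors) {
  if (length(tile_vectors) == 0) abort("no informative tissue")
  lens <- vapply(tile_vectors, length, integer(1))
  assert(all(lens == lens[1]), "tile vectors must share a length")
  m <- do.call(rbind, tile_vectors)
  colMeans(m)
}

# ---- nuclei segmentation and morphometrics ---------------------------------

#' Segment nuclei on the hematoxylin channel
#'
#' Local-mean adaptive thresholding (box window, additive offset), hole
#' filling, connected components, watershed splitting of touching objects
#' on the distance transform, and an equivalent-diameter gate.
#'
#' @param hema 2-D numeric matrix (hematoxylin concentration or OD; higher
#'   values = more nuclear signal).
#' @param d_min,d_max equivalent-diameter bounds in px (defaults 10, 50).
#' @param window adaptive-threshold box window in px; default `2*d_max + 1`
#'   so the local mean always sees background around a nucleus.
#' @param offset additive threshold offset (default 0.1).
#' @return integer label matrix (0 = background), labels sequential.
#' @export
segment_nuclei <- function(hema, d_min = 10, d_max = 50, window = NULL,
                           offset = 0.1) {
  assert(is.matrix(hema) && all(is.finite(hema)), "channel must be finite")
  if (is.null(window)) window <- 2 * d_max + 1
  half <- max(1L, floor(window / 2))
  half <- min(half, (min(dim(hema)) - 1L) %/% 2L)  # box must fit the image
  bw <- EBImage::thresh(EBImage::Image(hema), w = half, h = half,
                        offset = offset)
  bw <- EBImage::fillHull(bw)
  if (sum(bw) == 0) return(matrix(0L, nrow(hema), ncol(hema)))
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- as.matrix(EBImage::imageData(lab))
  areas <- tabulate(lab[lab > 0])
  eqd <- 2 * sqrt(areas / pi)
  keep <- which(eqd >= d_min & eqd <= d_max)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Expand nuclei into whole-cell regions
#'
#' Distance-limited outward propagation: every background pixel within
#' `max_expand` px (Euclidean) of a nucleus joins the nearest nucleus'
#' label, so cells are disjoint and each contains its nucleus. Ties at
#' exactly equidistant pixels go to the smaller label. The propagation is
#' purely geometric; the `intensity` argument is accepted for interface
#' compatibility and unused.
#'
#' @param nuclei_labels integer label matrix from [segment_nuclei()].
#' @param intensity ignored (geometric propagation).
#' @param max_expand maximum expansion distance in px.
#' @return integer label matrix of secondary (cell) objects.
#' @export
expand_cells <- function(nuclei_labels, intensity = NULL, max_expand = 10) {
  lab <- nuclei_labels
  assert(is.matrix(lab), "labels must be a matrix")
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0 || max_expand <= 0) return(lab)
  best_d <- array(Inf, dim = dim(lab))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (l in ids) {
    # distance of every pixel to the nearest pixel of label l
    dl <- as.matrix(EBImage::distmap(EBImage::Image(1 - (lab == l))))
    upd <- dl < best_d
    best_d[upd] <- dl[upd]
    out[upd] <- l
  }
  out[best_d > max_expand] <- 0L
  out
}

# per-object mean of a channel
.obj_means <- function(lab, channel) {
  ids <- sort(unique(lab[lab > 0]))
  vapply(ids, function(l) mean(channel[lab == l]), numeric(1))
}

# gray-level co-occurrence contrast: 8 levels, 1-px offset, mean of the
# 0/45/90/135 degree directions
.glcm_contrast <- function(channel, levels = 8L) {
  rng <- range(channel)
  if (diff(rng) == 0) return(0)
  q <- pmin(floor((channel - rng[1]) / diff(rng) * levels) + 1L, levels)
  h <- nrow(q); w <- ncol(q)
  pair_contrast <- function(a, b) {
    tab <- table(factor(a, levels = 1:levels), factor(b, levels = 1:levels))
    p <- tab / sum(tab)
    d <- abs(row(p) - col(p))
    sum(p * d^2)
  }
  mean(c(
    pair_contrast(q[, -w], q[, -1]),                 # 0 deg
    pair_contrast(q[-h, -w], q[-1, -1]),             # 45 deg
    pair_contrast(q[-h, ], q[-1, ]),                 # 90 deg
    pair_contrast(q[-h, -1], q[-1, -w])              # 135 deg
  ))
}

# coefficient of variation of mean intensity over 4 concentric object rings
.radial_cv <- function(lab, channel) {
  ids <- sort(unique(lab[lab > 0]))
  cvs <- vapply(ids, function(l) {
    inside <- lab == l
    dm <- as.matrix(EBImage::distmap(EBImage::Image(inside * 1)))
    d <- dm[inside]
    if (max(d) == 0) return(NA_real_)
    ring <- pmin(floor(d / max(d) * 4) + 1L, 4L)
    mns <- tapply(channel[inside], ring, mean)
    if (length(mns) < 2 || mean(mns) == 0) return(NA_real_)
    stats::sd(mns) / mean(mns)
  }, numeric(1))
  mean(cvs, na.rm = TRUE)
}

# solidity = object area / convex hull area (shoelace on hull of pixel
# centers, padded by half-pixel border approximation)
.obj_solidity <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  vapply(ids, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < 4) return(1)
    hull <- grDevices::chull(idx)
    hp <- idx[hull, , drop = FALSE]
    n <- nrow(hp)
    a <- abs(sum(hp[, 1] * hp[c(2:n, 1), 2] - hp[c(2:n, 1), 1] * hp[, 2])) / 2
    # pixel-center hull underestimates the rasterized area; add the border
    per <- sum(sqrt(rowSums((hp - hp[c(2:n, 1), , drop = FALSE])^2)))
    min(nrow(idx) / (a + per / 2 + 1), 1)
  }, numeric(1))
}

#' Curated morphometric descriptors (11 variables)
#'
#' Aggregates intensity, texture, size/shape and intensity-distribution
#' measurements over segmented nuclei (primary objects) and cells
#' (secondary objects) into exactly 11 named values:
#' `nuclei_count`, `mean_nucleus_area`, `sd_nucleus_area`,
#' `mean_nucleus_perimeter`, `mean_nucleus_eccentricity`,
#' `mean_nucleus_solidity`, `mean_hematoxylin_intensity_in_nuclei`,
#' `mean_eosin_intensity_in_cells`, `glcm_contrast_hematoxylin` (8-level,
#' 1-px offset, 4-direction mean), `nuclear_density` (nuclei per 10^4
#' tissue px) and `mean_radial_intensity_cv` (CV of mean hematoxylin over
#' 4 concentric rings). With zero nuclei the count and density are 0 and
#' all object statistics are NA.
#'
#' @param primary nucleus label matrix.
#' @param secondary cell label matrix (e.g. from [expand_cells()]).
#' @param hema,eosin aligned stain channels (numeric matrices).
#' @param tissue logical tissue mask for the density denominator; default
#'   NULL uses pixels with combined stain signal > 0.15.
#' @return named numeric vector of length 11.
#' @export
morphometrics <- function(primary, secondary, hema, eosin, tissue = NULL) {
  assert(all(dim(primary) == dim(hema)) && all(dim(hema) == dim(eosin)),
         "label images and channels must be aligned")
  if (is.null(tissue)) tissue <- (hema + eosin) > 0.15
  n_obj <- length(unique(primary[primary > 0]))
  tissue_px <- sum(tissue)

  if (n_obj == 0) {
    out <- c(nuclei_count = 0, mean_nucleus_area = NA, sd_nucleus_area = NA,
             mean_nucleus_perimeter = NA, mean_nucleus_eccentricity = NA,
             mean_nucleus_solidity = NA,
             mean_hematoxylin_intensity_in_nuclei = NA,
             mean_eosin_intensity_in_cells = NA,
             glcm_contrast_hematoxylin = .glcm_contrast(hema),
             nuclear_density = 0, mean_radial_intensity_cv = NA)
    return(out)
  }

  shp <- EBImage::computeFeatures.shape(primary)
  mom <- EBImage::computeFeatures.moment(primary, hema)
  areas <- shp[, "s.area"]
  out <- c(
    nuclei_count = n_obj,
    mean_nucleus_area = mean(areas),
    sd_nucleus_area = if (n_obj > 1) stats::sd(areas) else NA_real_,
    mean_nucleus_perimeter = mean(shp[, "s.perimeter"]),
    mean_nucleus_eccentricity = mean(mom[, "m.eccentricity"]),
    mean_nucleus_solidity = mean(.obj_solidity(primary)),
    mean_hematoxylin_intensity_in_nuclei = mean(.obj_means(primary, hema)),
    mean_eosin_intensity_in_cells =
      if (any(secondary > 0)) mean(.obj_means(secondary, eosin)) else NA_real_,
    glcm_contrast_hematoxylin = .glcm_contrast(hema),
    nuclear_density = n_obj / (max(tissue_px, 1) / 1e4),
    mean_radial_intensity_cv = .radial_cv(primary, hema)
  )
  out
}

#' Full pathomics feature row for one slide
#'
#' Tiles the slide, masks tissue, filters tiles at the tissue-fraction
#' threshold, optionally Macenko-normalizes retained tiles to a reference,
#' extracts pooled deep features per tile (mean-aggregated over retained
#' tiles), and computes slide-level morphometrics from per-tile nucleus
#' segmentation (mean over retained tiles, NA-aware).
#'
#' @param image H x W x 3 RGB slide (0-255).
#' @param backbone deep feature backbone (see [tiny_backbone()]).
#' @param tile_size tile edge (default 512).
#' @param min_tissue retention threshold (default 0.80).
#' @param reference optional reference `stain_model` for normalization.
#' @param seg_args list of arguments forwarded to [segment_nuclei()].
#' @param max_expand cell expansion radius in px (default 5).
#' @return named numeric vector: `path_resnet*` then the 11 `morph_*`
#'   (prefixed) descriptors, plus attribute `n_tiles_retained`.
#' @export
slide_pathomics <- function(image, backbone, tile_size = 512L,
                            min_tissue = 0.80, reference = NULL,
                            seg_args = list(), max_expand = 5) {
  tiles <- tile_slide(image, tile_size)
  mask <- tissue_mask(image)
  tiles <- filter_tiles(tiles, mask, min_tissue)
  kept <- Filter(function(t) t$retained, tiles)
  if (length(kept) == 0) abort("no informative tissue")

  src <- if (!is.null(reference)) estimate_stains(image) else NULL
  deep <- vector("list", length(kept))
  morph <- matrix(NA_real_, length(kept), 11)
  for (i in seq_along(kept)) {
    px <- kept[[i]]$pixels
    if (!is.null(reference)) px <- normalize_tile(px, src, reference)
    deep[[i]] <- deep_features(px, backbone)
    sm <- if (!is.null(reference)) reference else estimate_stains(image)
    od <- rbind(od_from_rgb(as.vector(px[, , 1])),
                od_from_rgb(as.vector(px[, , 2])),
                od_from_rgb(as.vector(px[, , 3])))
    conc <- .nnls2(sm$stain_matrix, od)
    hch <- matrix(conc[1, ], tile_size, tile_size)
    ech <- matrix(conc[2, ], tile_size, tile_size)
    prim <- do.call(segment_nuclei, c(list(hch), seg_args))
    sec <- expand_cells(prim, max_expand = max_expand)
    morph[i, ] <- morphometrics(prim, sec, hch, ech)
  }
  mv <- colMeans(morph, na.rm = TRUE)
  names(mv) <- paste0("morph_", names(morphometrics(
    matrix(0L, 2, 2), matrix(0L, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))))
  out <- c(aggregate_slide(deep), mv)
  attr(out, "n_tiles_retained") <- length(kept)
  out
}
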