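# disk raster helper: value `v` inside disks on a zero background
disk_channel <- function(h, w, centers, radii, v = 0.8) {
  ch <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    rr <- outer(seq_len(h) - centers[i, 2], rep(1, w)) ^ 2 +
      outer(rep(1, h), seq_len(w) - centers[i, 1]) ^ 2
    ch[rr <= radii[i]^2] <- v
  }
  ch
}

# render an RGB image from concentration fields through a stain matrix
render_od <- function(ch, ce, s) {
  od <- s %*% rbind(as.vector(ch), as.vector(ce))
  img <- array(0, dim = c(nrow(ch), ncol(ch), 3))
  for (k in 1:3)
    img[, , k] <- matrix(round(pmin(pmax(256 * 10^(-od[k, ]) - 1, 0), 255)),
                         nrow(ch), ncol(ch))
  img
}

# concentration scene with mixed and near-pure pixels (pure pixels must
# clear the any-channel OD filter, hence the strong pure-eosin range)
stain_scene <- function(h = 120, w = 200, seed = 1) {
  withr::with_seed(seed, {
    n <- h * w
    type <- sample(1:3, n, replace = TRUE, prob = c(0.6, 0.2, 0.2))
    ch <- ifelse(type == 1, runif(n, 0.3, 1.2),
                 ifelse(type == 2, runif(n, 0.6, 1.2), 0))
    ce <- ifelse(type == 1, runif(n, 0.3, 1.2),
                 ifelse(type == 3, runif(n, 2.1, 2.4), 0))
  })
  list(ch = matrix(ch, h, w), ce = matrix(ce, h, w))
}

angle_deg <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi

test_that("tiling partitions the slide row-major and drops edge remainders", {
  img <- array(runif(1024 * 1024 * 3) * 255, c(1024, 1024, 3))
  tl <- tile_slide(img, 512)
  expect_length(tl, 4)
  expect_equal(vapply(tl, `[[`, numeric(1), "row"), c(0, 0, 1, 1))
  expect_equal(vapply(tl, `[[`, numeric(1), "col"), c(0, 1, 0, 1))
  expect_identical(tl[[4]]$pixels, img[513:1024, 513:1024, , drop = FALSE])

  img2 <- array(0, c(1030, 700, 3))
  expect_length(tile_slide(img2, 512), 2)
  expect_error(tile_slide(array(0, c(100, 600, 3)), 512), "smaller")
})

test_that("Otsu tissue mask separates dark tissue from background", {
  img <- array(255, c(64, 64, 3))
  img[, 1:32, ] <- 0
  m <- tissue_mask(img)
  expect_true(all(m[, 1:32]) && !any(m[, 33:64]))

  expect_warning(m0 <- tissue_mask(array(255, c(32, 32, 3))), "constant")
  expect_equal(mean(m0), 0)

  sl <- make_slide(256, 256, 0, 0.5, seed = 30)
  expect_lt(abs(mean(tissue_mask(sl$image)) - mean(sl$tissue_mask)), 0.05)
})

test_that("tile retention uses a strict tissue-fraction threshold", {
  # 20x20 tiles: integer pixel counts for every 0.01 fraction step
  img <- array(0, c(20, 20 * 101, 3))
  mask <- matrix(FALSE, 20, 20 * 101)
  for (i in 0:100) {
    npix <- 4 * i  # fraction i/100 of 400 px
    if (npix > 0) mask[seq_len(npix) %% 20 + 1,
                       20 * i + (seq_len(npix) - 1) %/% 20 + 1] <- TRUE
  }
  # simpler exact construction: fill column-wise
  mask[] <- FALSE
  for (i in 0:100) {
    npix <- 4 * i
    if (npix > 0) {
      block <- matrix(FALSE, 20, 20)
      block[seq_len(npix)] <- TRUE
      mask[, 20 * i + 1:20] <- block
    }
  }
  tl <- filter_tiles(tile_slide(img, 20), mask, min_fraction = 0.80)
  fr <- vapply(tl, `[[`, numeric(1), "tissue_fraction")
  ret <- vapply(tl, `[[`, logical(1), "retained")
  expect_equal(sort(fr), seq(0, 1, by = 0.01), tolerance = 1e-12)
  expect_equal(max(fr[!ret]), 0.80)         # 0.80 itself is rejected
  expect_equal(min(fr[ret]), 0.81)
  expect_true(all(ret == (fr > 0.80)))
})

test_that("Macenko estimation recovers the true stain vectors within 2 degrees", {
  sc <- stain_scene(seed = 31)
  S <- ptmfuse:::default_stain_matrix()
  img <- render_od(sc$ch, sc$ce, S)
  sm <- estimate_stains(img)
  expect_lt(angle_deg(sm$stain_matrix[, 1], S[, 1]), 2)
  expect_lt(angle_deg(sm$stain_matrix[, 2], S[, 2]), 2)
  expect_true(all(sm$stain_matrix >= 0))
  expect_equal(colSums(sm$stain_matrix^2), c(1, 1), tolerance = 1e-9)
  expect_error(estimate_stains(array(255, c(64, 64, 3))), "insufficient")
})

test_that("unmixing with the generating model reproduces OD within 1%", {
  sc <- stain_scene(seed = 32)
  S <- ptmfuse:::default_stain_matrix()
  od_true <- S %*% rbind(as.vector(sc$ch), as.vector(sc$ce))
  model <- structure(class = "stain_model",
                     list(stain_matrix = S, max_concentrations = c(1, 1)))
  conc <- ptmfuse:::.nnls2(S, od_true)
  od_hat <- S %*% conc
  expect_lt(sqrt(sum((od_hat - od_true)^2)) / sqrt(sum(od_true^2)), 0.01)
})

test_that("stain normalization: identity, idempotence, harmonization", {
  sc <- stain_scene(seed = 33)
  S1 <- ptmfuse:::default_stain_matrix()
  S2 <- cbind(c(0.55, 0.76, 0.35), c(0.10, 0.95, 0.25))
  S2 <- sweep(S2, 2, sqrt(colSums(S2^2)), "/")
  img1 <- render_od(sc$ch, sc$ce, S1)
  img2 <- render_od(sc$ch, sc$ce, S2)
  m1 <- estimate_stains(img1)
  m2 <- estimate_stains(img2)

  id <- normalize_tile(img1, m1, m1)
  expect_lte(mean(abs(id - img1)), 2)

  once <- normalize_tile(img2, m2, m1)
  twice <- normalize_tile(once, estimate_stains(once), m1)
  expect_lte(mean(abs(twice - once)), 2)

  pre <- mean(abs(img1 - img2))
  post <- mean(abs(normalize_tile(img1, m1, m1) - once))
  expect_lt(post * 5, pre)
})

test_that("deep feature pooling takes exact per-channel spatial maxima", {
  withr::with_seed(34, act <- array(runif(7 * 7 * 5), c(7, 7, 5)))
  v <- deep_features(array(128, c(64, 64, 3)), function(x) act)
  expect_equal(unname(v), apply(act, 3, max))
  expect_equal(names(v), sprintf("path_resnet%d", 0:4))
  expect_error(
    deep_features(array(128, c(64, 64, 3)),
                  function(x) array(0, c(8, 8, 5))), "7 x 7")
})

test_that("the seeded backbone is deterministic and has the contract shapes", {
  bb <- tiny_backbone(seed = 35)
  tile <- array(128, c(128, 128, 3))
  v1 <- deep_features(tile, bb)
  v2 <- deep_features(tile, tiny_backbone(seed = 35))
  expect_identical(v1, v2)
  expect_length(v1, 32)
  expect_true(all(is.finite(v1)))
})

test_that("the release-config backbone emits a 2048-element vector", {
  bb <- tiny_backbone(channels = c(8, 16, 16, 32, 2048), seed = 36)
  v <- deep_features(array(100, c(224, 224, 3)), bb)
  expect_length(v, 2048)
  expect_equal(names(v)[2048], "path_resnet2047")
})

test_that("slide aggregation is the tile mean, symmetric, duplication-invariant", {
  withr::with_seed(37, { v <- runif(8); w <- runif(8) })
  names(v) <- names(w) <- sprintf("path_resnet%d", 0:7)
  expect_equal(aggregate_slide(list(v)), v)
  expect_equal(aggregate_slide(list(v, w)), (v + w) / 2)
  expect_equal(aggregate_slide(list(v, w)), aggregate_slide(list(w, v)))
  expect_equal(aggregate_slide(list(v, v)), v)
  expect_error(aggregate_slide(list()), "no informative tissue")
})

test_that("nucleus segmentation finds disks inside the diameter gate", {
  ctr <- cbind(c(40, 120, 200, 60, 180), c(40, 60, 40, 180, 190))
  ch <- disk_channel(240, 240, ctr, radii = rep(10, 5))
  lab <- segment_nuclei(ch, d_min = 10, d_max = 50)
  expect_equal(max(lab), 5)

  small <- disk_channel(100, 100, cbind(50, 50), radii = 3)  # diameter 6
  expect_equal(max(segment_nuclei(small, d_min = 10, d_max = 50)), 0)
  expect_equal(max(segment_nuclei(matrix(0, 50, 50))), 0)
})

test_that("segmentation precision and recall reach 0.9 on non-touching disks", {
  withr::with_seed(38, {
    ctr <- cbind(sample(seq(30, 370, by = 68), 6, replace = FALSE),
                 sample(seq(30, 370, by = 68), 6, replace = FALSE))
    radii <- runif(6, 7, 15)    # diameters 14-30 px
    ch <- disk_channel(400, 400, ctr, radii) + matrix(rnorm(400 * 400, 0, 0.02), 400)
  })
  lab <- segment_nuclei(ch, d_min = 10, d_max = 50)
  ids <- setdiff(unique(as.vector(lab)), 0)
  cent <- t(vapply(ids, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    c(mean(idx[, 2]), mean(idx[, 1]))
  }, numeric(2)))
  matched <- vapply(seq_len(nrow(ctr)), function(i) {
    any(sqrt((cent[, 1] - ctr[i, 1])^2 + (cent[, 2] - ctr[i, 2])^2) < radii[i])
  }, logical(1))
  recall <- mean(matched)
  precision <- sum(matched) / max(nrow(cent), 1)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("cell expansion is nearest-seed, distance-limited, nucleus-preserving", {
  lab <- matrix(0L, 60, 60)
  lab[28:32, 18:22] <- 1L   # two square nuclei 8 px apart edge-to-edge
  lab[28:32, 31:35] <- 2L
  sec <- expand_cells(lab, max_expand = 10)
  # brute-force nearest-seed oracle with the same smaller-label tie rule
  seeds <- which(lab > 0, arr.ind = TRUE)
  sl <- lab[lab > 0]
  oracle <- matrix(0L, 60, 60)
  for (r in 1:60) for (cc in 1:60) {
    d <- sqrt((seeds[, 1] - r)^2 + (seeds[, 2] - cc)^2)
    if (min(d) <= 10) oracle[r, cc] <- sl[which.min(d)]
  }
  expect_identical(sec, oracle)
  expect_true(all(sec[lab > 0] == lab[lab > 0]))

  expect_identical(expand_cells(lab, max_expand = 0), lab)

  one <- matrix(0L, 40, 40); one[18:22, 18:22] <- 1L
  e5 <- expand_cells(one, max_expand = 5)
  dm <- as.matrix(EBImage::distmap(EBImage::Image(1 - (one == 1))))
  expect_true(all(dm[e5 == 1] <= 5))
  expect_true(all(e5[dm <= 5] == 1))
})

test_that("morphometrics returns the 11 curated descriptors with exact conventions", {
  # single disk radius 10
  ch <- disk_channel(100, 100, cbind(50, 50), radii = 10, v = 1)
  lab <- matrix(0L, 100, 100); lab[ch > 0] <- 1L
  mv <- morphometrics(lab, lab, ch, ch * 0.5)
  expect_length(mv, 11)
  expect_equal(unname(mv["nuclei_count"]), 1)
  expect_lt(abs(mv["mean_nucleus_area"] - pi * 100) / (pi * 100), 0.05)
  expect_lte(mv["mean_nucleus_eccentricity"], 0.2)
  expect_gte(mv["mean_nucleus_solidity"], 0.85)

  # 4:1 ellipse is strongly eccentric
  ell <- matrix(0L, 100, 100)
  px <- ptmfuse:::.ellipse_pixels(50, 50, 40, 10, 0, 100, 100)
  ell[px] <- 1L
  mve <- morphometrics(ell, ell, matrix(1, 100, 100), matrix(0, 100, 100))
  expect_gte(mve["mean_nucleus_eccentricity"], 0.9)

  # blank image: count and density 0, object statistics missing
  blank <- matrix(0L, 50, 50)
  mv0 <- morphometrics(blank, blank, matrix(0, 50, 50), matrix(0, 50, 50))
  expect_length(mv0, 11)
  expect_equal(unname(mv0["nuclei_count"]), 0)
  expect_equal(unname(mv0["nuclear_density"]), 0)
  expect_true(is.na(mv0["mean_nucleus_area"]))
})

test_that("the slide-level pathomics row combines pooled deep and morphometric features", {
  sl <- make_slide(256, 256, 6, 1.0, seed = 39)
  bb <- tiny_backbone(seed = 1)
  row <- slide_pathomics(sl$image, bb, tile_size = 128, min_tissue = 0.5,
                         seg_args = list(d_min = 6, d_max = 50))
  expect_length(row, 32 + 11)
  expect_true(all(startsWith(names(row)[1:32], "path_resnet")))
  expect_true(all(startsWith(names(row)[33:43], "morph_")))
  expect_gte(attr(row, "n_tiles_retained"), 1)
})
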