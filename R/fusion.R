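# Joint pathomics + transcriptomics feature table and the denoising
# autoencoder latent representation.

#' Assemble the joint multimodal feature table
#'
#' Inner-joins the expression block (genes x samples, typically restricted
#' to significant PTM DEGs) with the pathomics block (samples x features)
#' on sample ID. Columns are prefixed `expr_` / `path_` so the two
#' modalities can never collide. Z-scoring is deferred to training time.
#'
#' @param expr numeric matrix, genes x samples (log2 scale).
#' @param path numeric matrix or data.frame, samples x pathomics features
#'   (row names = sample IDs, or a `sample` column).
#' @return numeric matrix, samples x (expr + path) features.
#' @export
assemble <- function(expr, path) {
  assert(is.matrix(expr) && !is.null(rownames(expr)) && !is.null(colnames(expr)),
         "expr must be a genes x samples matrix with dimnames")
  if (is.data.frame(path)) {
    if ("sample" %in% names(path)) {
      rownames(path) <- path$sample
      path$sample <- NULL
    }
    path <- as.matrix(path)
  }
  assert(is.matrix(path) && !is.null(rownames(path)),
         "path must be a samples x features matrix with sample row names")
  if (anyDuplicated(colnames(expr)) || anyDuplicated(rownames(path)))
    abort("duplicate sample IDs")
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(path)))
    abort("duplicate feature IDs")

  shared <- intersect(colnames(expr), rownames(path))
  if (length(shared) == 0) abort("zero shared samples between modalities")
  dropped <- setdiff(union(colnames(expr), rownames(path)), shared)
  if (length(dropped) > 0)
    warning(sprintf("%d sample(s) present in only one modality were excluded",
                    length(dropped)))
  e <- t(expr[, shared, drop = FALSE])
  colnames(e) <- paste0("expr_", rownames(expr))
  p <- path[shared, , drop = FALSE]
  pn <- colnames(p)
  colnames(p) <- ifelse(startsWith(pn, "path_"), pn, paste0("path_", pn))
  out <- cbind(e, p)
  assert(!anyNA(out), "assembled table contains missing values")
  out
}

#' Split samples into training and validation sets
#'
#' Deterministic seeded random split; `|train| = round(ratio * n)`.
#'
#' @param table samples x features matrix (row names = sample IDs).
#' @param ratio training fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list with `train_ids` and `validation_ids` (disjoint, covering
#'   all samples).
#' @export
split_cohort <- function(table, ratio = 0.7, seed = 1L) {
  assert(ratio > 0 && ratio < 1, "ratio must be in (0, 1)")
  ids <- rownames(table)
  assert(!is.null(ids), "table must have sample row names")
  n <- length(ids)
  if (n < 10) abort("need at least 10 samples to split")
  n_train <- round(ratio * n)
  tr <- with_seed(seed, sample(ids, n_train))
  list(train_ids = tr, validation_ids = setdiff(ids, tr))
}

#' Autoencoder configuration
#'
#' Release defaults follow the fusion model: encoder hidden sizes
#' 128/64/32 (latent = innermost 32), dropout 0.1 on hidden activations,
#' mini-batch SGD with batch size 64, learning rate 0.001, 150 epochs.
#'
#' @param hidden_sizes encoder stack (mirrored decoder); last = latent dim.
#' @param dropout dropout rate on hidden ReLU activations during training.
#' @param batch_size mini-batch size (full batch when n is smaller).
#' @param learning_rate SGD step size.
#' @param epochs training epochs.
#' @param seed seed for initialization, shuffling and dropout masks.
#' @return list of class `ae_config`.
#' @export
ae_config <- function(hidden_sizes = c(128, 64, 32), dropout = 0.1,
                      batch_size = 64, learning_rate = 0.001,
                      epochs = 150, seed = 1L) {
  assert(all(hidden_sizes > 0) && dropout >= 0 && dropout < 1 &&
           batch_size > 0 && learning_rate > 0 && epochs > 0,
         "all configuration values must be positive (dropout in [0,1))")
  structure(class = "ae_config",
            list(hidden_sizes = as.integer(hidden_sizes), dropout = dropout,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)))
}

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# forward pass through one stack of (weight, bias) layers; ReLU on all but
# the last layer; optional inverted-dropout masks on hidden activations
.ff <- function(x, layers, dropout = 0, cache = FALSE) {
  acts <- list(x)
  masks <- list()
  L <- length(layers)
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% layers[[l]]$w
    z <- sweep(z, 2, layers[[l]]$b, "+")
    if (l < L) {
      z <- relu(z)
      if (dropout > 0) {
        m <- matrix(rbinom(length(z), 1, 1 - dropout), nrow(z)) / (1 - dropout)
        z <- z * m
        masks[[l]] <- m
      }
    }
    acts[[l + 1]] <- z
  }
  if (cache) list(out = acts[[L + 1]], acts = acts, masks = masks)
  else acts[[L + 1]]
}

# backprop through .ff given upstream gradient; returns per-layer grads and
# the gradient wrt the stack input
.bp <- function(fwd, layers, grad_out, dropout = 0) {
  L <- length(layers)
  grads <- vector("list", L)
  g <- grad_out
  for (l in rev(seq_len(L))) {
    a_in <- fwd$acts[[l]]
    grads[[l]] <- list(w = crossprod(a_in, g), b = colSums(g))
    g <- g %*% t(layers[[l]]$w)
    if (l > 1) {
      g <- g * (fwd$acts[[l]] != 0)  # ReLU (+dropout zeros) pass-through
      if (dropout > 0 && length(fwd$masks) >= l - 1 &&
          !is.null(fwd$masks[[l - 1]]))
        g <- g * fwd$masks[[l - 1]]
    }
  }
  list(grads = grads, grad_in = g)
}

#' Train the multimodal autoencoder
#'
#' Symmetric feedforward autoencoder: encoder `d -> 128 -> 64 -> 32` (ReLU
#' hidden layers, linear latent), mirrored linear-output decoder. Inverted
#' dropout is applied to hidden activations during training only. The mean
#' squared reconstruction error is minimized by seeded mini-batch SGD
#' (per-epoch shuffling); columns are z-scored with statistics of the
#' training table, which are stored in the model and reused at encode time.
#'
#' @param table training samples x features matrix (raw scale).
#' @param cfg an [ae_config()].
#' @return list of class `latent_model`: `encoder`, `decoder` (weight
#'   stacks), `loss_trace` (per-epoch mean training MSE), `center`,
#'   `scale`, `columns`, `cfg`.
#' @export
train_autoencoder <- function(table, cfg = ae_config()) {
  x <- as.matrix(table)
  assert(all(is.finite(x)), "table must be finite")
  n <- nrow(x); d <- ncol(x)
  assert(d >= cfg$hidden_sizes[length(cfg$hidden_sizes)],
         "need at least as many features as latent dimensions")
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scl, "/")

  hs <- cfg$hidden_sizes
  enc_dims <- c(d, hs)
  dec_dims <- c(rev(hs), d)

  with_seed(cfg$seed, {
    enc <- lapply(seq_len(length(enc_dims) - 1), function(l)
      list(w = .glorot(enc_dims[l], enc_dims[l + 1]),
           b = rep(0, enc_dims[l + 1])))
    dec <- lapply(seq_len(length(dec_dims) - 1), function(l)
      list(w = .glorot(dec_dims[l], dec_dims[l + 1]),
           b = rep(0, dec_dims[l + 1])))

    bs <- min(cfg$batch_size, n)
    loss_trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        xb <- xs[idx, , drop = FALSE]
        fe <- .ff(xb, enc, cfg$dropout, cache = TRUE)
        fd <- .ff(fe$out, dec, cfg$dropout, cache = TRUE)
        resid <- fd$out - xb
        loss <- mean(resid^2)
        if (!is.finite(loss))
          abort(sprintf("non-finite training loss at epoch %d", ep))
        g_out <- 2 * resid / length(resid)
        bd <- .bp(fd, dec, g_out, cfg$dropout)
        be <- .bp(fe, enc, bd$grad_in, cfg$dropout)
        lr <- cfg$learning_rate
        for (l in seq_along(dec)) {
          dec[[l]]$w <- dec[[l]]$w - lr * bd$grads[[l]]$w
          dec[[l]]$b <- dec[[l]]$b - lr * bd$grads[[l]]$b
        }
        for (l in seq_along(enc)) {
          enc[[l]]$w <- enc[[l]]$w - lr * be$grads[[l]]$w
          enc[[l]]$b <- enc[[l]]$b - lr * be$grads[[l]]$b
        }
        ep_loss <- ep_loss + loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      loss_trace[ep] <- ep_loss / ep_n
    }
    structure(class = "latent_model", list(
      encoder = enc, decoder = dec, loss_trace = loss_trace,
      center = center, scale = scl, columns = colnames(x), cfg = cfg))
  })
}

.check_columns <- function(model, table) {
  cols <- colnames(table)
  missing <- setdiff(model$columns, cols)
  extra <- setdiff(cols, model$columns)
  if (length(missing) > 0 || length(extra) > 0)
    abort(sprintf("column mismatch; missing: [%s]; extra: [%s]",
                  paste(missing, collapse = ", "),
                  paste(extra, collapse = ", ")))
}

#' Encode samples into the latent space
#'
#' Deterministic forward pass (dropout disabled) through the trained
#' encoder, after applying the training z-scoring statistics.
#'
#' @param model a `latent_model` from [train_autoencoder()].
#' @param table samples x features matrix with the training columns.
#' @return latent matrix, samples x latent-dim (`latent1` ...).
#' @export
encode <- function(model, table) {
  assert(inherits(model, "latent_model"), "model must be a latent_model")
  x <- as.matrix(table)
  .check_columns(model, x)
  x <- x[, model$columns, drop = FALSE]
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  z <- .ff(xs, model$encoder, dropout = 0)
  colnames(z) <- sprintf("latent%d", seq_len(ncol(z)))
  rownames(z) <- rownames(table)
  z
}

#' Reconstruct samples through the autoencoder
#'
#' @param model a `latent_model`.
#' @param table samples x features matrix with the training columns.
#' @return reconstruction in the z-scored feature space (same shape as the
#'   z-scored input).
#' @export
reconstruct <- function(model, table) {
  z <- encode(model, table)
  out <- .ff(z, model$decoder, dropout = 0)
  colnames(out) <- model$columns
  rownames(out) <- rownames(table)
  out
}

#' Reconstruction mean squared error on the z-scored scale
#'
#' @param model a `latent_model`.
#' @param table samples x features matrix.
#' @return scalar MSE between the z-scored input and its reconstruction.
#' @export
reconstruction_mse <- function(model, table) {
  x <- as.matrix(table)[, model$columns, drop = FALSE]
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  mean((reconstruct(model, table) - xs)^2)
}
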