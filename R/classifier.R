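#' Training configuration for the reference image classifier
#'
#' @param lr learning rate (> 0). The default of 0.02 is tuned for the
#'   built-in reference network with momentum SGD; external large
#'   networks typically use much smaller rates (e.g. 8e-4).
#' @param bs minibatch size (>= 1).
#' @param epochs number of passes over the training set (>= 0).
#' @param seed integer seed; training is deterministic under a fixed seed
#'   up to floating-point reduction order.
#' @param arch `"small_cnn"` (built-in reference network) or `"external"`
#'   (user-supplied `train_fn` / `predict_fn` hooks).
#' @param input_size square edge length images are downsampled to before
#'   entering the network.
#' @param train_fn,predict_fn hooks for `arch = "external"`.
#' @return an object of class `training_config`.
#' @export
training_config <- function(lr = 0.02, bs = 32, epochs = 60, seed = 1L,
                            arch = c("small_cnn", "external"),
                            input_size = 64, train_fn = NULL,
                            predict_fn = NULL) {
  arch <- match.arg(arch)
  if (lr <= 0) stop("lr must be positive")
  if (bs < 1) stop("bs must be >= 1")
  if (epochs < 0) stop("epochs must be >= 0")
  if (arch == "external" && (is.null(train_fn) || is.null(predict_fn)))
    stop("external arch requires train_fn and predict_fn")
  structure(list(lr = lr, bs = as.integer(bs), epochs = as.integer(epochs),
                 seed = as.integer(seed), arch = arch,
                 input_size = as.integer(input_size),
                 train_fn = train_fn, predict_fn = predict_fn),
            class = "training_config")
}

#' Load manifest images into a pixel matrix
#'
#' Reads each PNG and downsamples to `size x size` by block averaging
#' (nearest-neighbour sampling when the edge is not a multiple of `size`).
#'
#' @param manifest data.frame with columns `path`, `mol_id`, `rx`, `ry`,
#'   `rz` and optionally `label`.
#' @param size target edge length in pixels.
#' @return list with `x` (matrix, one row per image, `size*size*3`
#'   columns), `mol_id`, `rotation` (data.frame), `label`.
#' @export
load_images <- function(manifest, size = 32L) {
  n <- nrow(manifest)
  d <- size * size * 3L
  x <- matrix(0, n, d)
  for (k in seq_len(n)) {
    img <- png::readPNG(manifest$path[k])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
    px <- dim(img)[1L]
    if (px == size) {
      small <- img
    } else if (px %% size == 0L) {
      f <- px %/% size
      a <- array(img, c(f, size, f, size, 3L))
      b <- colMeans(a, dims = 1L)             # (size, f, size, 3)
      small <- colMeans(aperm(b, c(2L, 1L, 3L, 4L)), dims = 1L)
    } else {
      sel <- round(seq(1, px, length.out = size))
      small <- img[sel, sel, , drop = FALSE]
    }
    x[k, ] <- as.vector(small)
  }
  list(x = x, mol_id = manifest$mol_id,
       rotation = manifest[, intersect(c("rx", "ry", "rz"), names(manifest)),
                           drop = FALSE],
       label = if ("label" %in% names(manifest)) manifest$label else NULL)
}

# ---- small reference CNN (pure R, im2col convolutions) ---------------------
# Architecture: conv 5x5x8 / relu / maxpool 2 -> conv 5x5x16 / relu /
# maxpool 2 -> global average pooling -> dense 16 / relu -> dense 1 /
# sigmoid. The global-average-pooling head makes the classifier respond to
# local structural features wherever they appear in the frame (the relevant
# invariance for rotated snapshots of one molecule) and keeps the parameter
# count small enough to train on molecule counts in the tens without
# memorising individual training structures. Sized for CPU minutes; larger
# nets plug in via arch = "external".

.im2col_index <- function(h, w, ch, k) {
  oh <- h - k + 1L; ow <- w - k + 1L
  pos <- expand.grid(i = seq_len(oh), j = seq_len(ow))   # i fastest
  off <- expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L), c = 0:(ch - 1L))
  idx <- matrix(0L, oh * ow, nrow(off))
  for (q in seq_len(nrow(off)))
    idx[, q] <- (off$c[q]) * h * w + (pos$j + off$dj[q] - 1L) * h +
      (pos$i + off$di[q])
  list(idx = idx, oh = oh, ow = ow)
}

.pool_index <- function(oh, ow) {
  ph <- oh %/% 2L; pw <- ow %/% 2L
  pos <- expand.grid(i = seq_len(ph), j = seq_len(pw))
  base <- (2L * pos$j - 2L) * oh + (2L * pos$i - 1L)
  cbind(base, base + 1L, base + oh, base + oh + 1L)
}

# X: (B, P, F) array; returns pooled (B, P/4, F) plus argmax for backprop
.maxpool <- function(X, pidx) {
  B <- dim(X)[1L]; F <- dim(X)[3L]
  P2 <- nrow(pidx)
  out <- array(-Inf, c(B, P2, F))
  arg <- array(1L, c(B, P2, F))
  for (q in 1:4) {
    cand <- X[, pidx[, q], , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- q
  }
  list(out = out, arg = arg)
}

.init_cnn <- function(size, seed) {
  set.seed(seed)
  he <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))
  c1 <- .im2col_index(size, size, 3L, 5L)
  p1 <- .pool_index(c1$oh, c1$ow)
  h2 <- c1$oh %/% 2L; w2 <- c1$ow %/% 2L
  c2 <- .im2col_index(h2, w2, 8L, 5L)
  p2 <- .pool_index(c2$oh, c2$ow)
  # sparse scatter for the conv2 input gradient (im2col transpose)
  qv <- as.vector(c2$idx)
  scat2 <- Matrix::sparseMatrix(i = seq_along(qv), j = qv,
                                x = 1, dims = c(length(qv), h2 * w2 * 8L))
  list(size = size,
       W1 = matrix(he(75, 75 * 8), 75, 8), b1 = numeric(8),
       W2 = matrix(he(200, 200 * 16), 200, 16), b2 = numeric(16),
       W3 = matrix(he(16, 16 * 16), 16, 16), b3 = numeric(16),
       W4 = matrix(he(16, 16), 16, 1), b4 = 0,
       c1 = c1, p1 = p1, h2 = h2, w2 = w2, c2 = c2, p2 = p2,
       scat2 = scat2)
}

.cnn_forward <- function(net, X, keep = FALSE) {
  B <- nrow(X)
  X <- X - 0.5                 # centre pixel intensities
  imcol <- function(Xb, idx) {
    out <- Xb[, as.vector(idx)]       # (B, P*K); b fastest, then (p, k)
    dim(out) <- c(B * nrow(idx), ncol(idx))
    out
  }
  addb <- function(Z, b) Z + rep(b, each = nrow(Z))
  X1 <- imcol(X, net$c1$idx)                       # (B*P1, 75)
  Z1 <- addb(X1 %*% net$W1, net$b1)
  A1 <- pmax(Z1, 0)
  dim(A1) <- c(B, nrow(net$c1$idx), 8L)
  P1 <- .maxpool(A1, net$p1)                       # (B, P1/4, 8)
  Xp1 <- P1$out
  dim(Xp1) <- c(B, length(Xp1) / B)                # (B, h2*w2*8) col-major
  X2 <- imcol(Xp1, net$c2$idx)
  Z2 <- addb(X2 %*% net$W2, net$b2)
  A2 <- pmax(Z2, 0)
  dim(A2) <- c(B, nrow(net$c2$idx), 16L)
  P2 <- .maxpool(A2, net$p2)
  P2n <- dim(P2$out)[2L]
  Gm <- P2$out
  dim(Gm) <- c(B * P2n, 16L)
  G <- rowsum(Gm, rep(seq_len(B), times = P2n)) / P2n  # global average pool
  Z3 <- G %*% net$W3 + rep(net$b3, each = B)
  A3 <- pmax(Z3, 0)
  logit <- drop(A3 %*% net$W4) + net$b4
  p <- 1 / (1 + exp(-logit))
  if (!keep) return(p)
  list(p = p, X1 = X1, Z1 = Z1, P1 = P1, Xp1 = Xp1, X2 = X2, Z2 = Z2,
       P2 = P2, G = G, Z3 = Z3, A3 = A3)
}

.cnn_backward <- function(net, X, y, fw) {
  B <- nrow(X)
  dlogit <- (fw$p - y) / B                          # BCE + sigmoid
  dW4 <- crossprod(fw$A3, dlogit); db4 <- sum(dlogit)
  dA3 <- outer(dlogit, drop(net$W4))
  dZ3 <- dA3 * (fw$Z3 > 0)
  dW3 <- crossprod(fw$G, dZ3); db3 <- colSums(dZ3)
  dG <- tcrossprod(dZ3, net$W3)                     # (B, 16)
  # undo global average pooling, then unpool 2
  P2n <- nrow(net$p2)
  dP2 <- aperm(array(t(dG) / P2n, c(16L, B, P2n)), c(2L, 3L, 1L))
  dA2a <- array(0, c(B, nrow(net$c2$idx), 16L))
  for (q in 1:4) {
    m <- fw$P2$arg == q
    if (any(m)) {
      tgt <- array(0, dim(dP2)); tgt[m] <- dP2[m]
      dA2a[, net$p2[, q], ] <- dA2a[, net$p2[, q], , drop = FALSE] + tgt
    }
  }
  dA2 <- dA2a
  dim(dA2) <- c(B * nrow(net$c2$idx), 16L)
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$X2, dZ2); db2 <- colSums(dZ2)
  dX2 <- tcrossprod(dZ2, net$W2)                    # (B*P, 200)
  # scatter back through im2col of conv2 (precomputed sparse transpose)
  dim(dX2) <- c(B, length(dX2) / B)
  dXp1 <- as.matrix(dX2 %*% net$scat2)
  # unpool 1
  dP1 <- array(dXp1, c(B, nrow(net$p1), 8L))
  dA1a <- array(0, c(B, nrow(net$c1$idx), 8L))
  for (q in 1:4) {
    m <- fw$P1$arg == q
    if (any(m)) {
      tgt <- array(0, dim(dP1)); tgt[m] <- dP1[m]
      dA1a[, net$p1[, q], ] <- dA1a[, net$p1[, q], , drop = FALSE] + tgt
    }
  }
  dA1 <- dA1a
  dim(dA1) <- c(B * nrow(net$c1$idx), 8L)
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$X1, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       W4 = dW4, b4 = db4)
}

#' Train the reference image classifier
#'
#' Trains the built-in small convolutional network (or dispatches to an
#' external hook) with minibatch stochastic gradient descent with momentum
#' on binary cross-entropy, recording per-epoch training loss, validation
#' loss and validation accuracy (at the 0.5 probability cut).
#'
#' @param train_images,val_images image sets from [load_images()]; labels
#'   must contain both classes in the training set.
#' @param config a [training_config()].
#' @return list of class `snap_classifier` with the fitted model and
#'   `history` (data.frame: `epoch`, `loss_tra`, `loss_val`, `acc_val`).
#' @export
train_image_classifier <- function(train_images, val_images,
                                   config = training_config()) {
  if (length(train_images$label) == 0L || length(val_images$label) == 0L)
    stop("training and validation sets must be nonempty")
  ytr <- as.numeric(.as_active(train_images$label))
  yva <- as.numeric(.as_active(val_images$label))
  if (length(unique(ytr)) < 2L)
    stop("training labels contain a single class")
  if (config$arch == "external") {
    model <- config$train_fn(train_images, val_images, config)
    return(structure(list(arch = "external", model = model,
                          predict_fn = config$predict_fn,
                          input_size = config$input_size,
                          history = data.frame()),
                     class = "snap_classifier"))
  }
  size <- config$input_size
  stopifnot(ncol(train_images$x) == size * size * 3L)
  net <- .init_cnn(size, config$seed)
  vel <- lapply(net[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")],
                function(w) w * 0)
  mom <- 0.9
  bce <- function(p, y) -mean(y * log(pmax(p, 1e-12)) +
                                (1 - y) * log(pmax(1 - p, 1e-12)))
  history <- data.frame(epoch = integer(0), loss_tra = numeric(0),
                        loss_val = numeric(0), acc_val = numeric(0))
  n <- nrow(train_images$x)
  if (config$epochs > 0L) {
    for (ep in seq_len(config$epochs)) {
      set.seed(config$seed + ep)
      ord <- sample(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = config$bs)) {
        take <- ord[start:min(start + config$bs - 1L, n)]
        Xb <- train_images$x[take, , drop = FALSE]
        yb <- ytr[take]
        fw <- .cnn_forward(net, Xb, keep = TRUE)
        losses <- c(losses, bce(fw$p, yb))
        gr <- .cnn_backward(net, Xb, yb, fw)
        for (nm in names(gr)) {
          vel[[nm]] <- mom * vel[[nm]] - config$lr * gr[[nm]]
          net[[nm]] <- net[[nm]] + vel[[nm]]
        }
      }
      pva <- .cnn_forward(net, val_images$x)
      history <- rbind(history, data.frame(
        epoch = ep, loss_tra = mean(losses), loss_val = bce(pva, yva),
        acc_val = mean((pva >= 0.5) == yva)))
    }
  }
  structure(list(arch = "small_cnn", net = net, input_size = size,
                 config = config, history = history),
            class = "snap_classifier")
}

#' Predict per-image activity probabilities
#'
#' @param model a `snap_classifier` from [train_image_classifier()].
#' @param images an image set from [load_images()].
#' @param batch forward-pass batch size.
#' @return data.frame (`mol_id`, rotation columns, `probability`), one row
#'   per input image; a pure function of (model, image bytes).
#' @export
predict_images <- function(model, images, batch = 256L) {
  stopifnot(inherits(model, "snap_classifier"))
  n <- nrow(images$x)
  if (n == 0L)
    return(data.frame(mol_id = character(0), probability = numeric(0)))
  if (model$arch == "external") {
    p <- model$predict_fn(model$model, images)
  } else {
    if (ncol(images$x) != model$input_size^2 * 3L)
      stop("image size mismatch: model expects edge ", model$input_size)
    p <- numeric(n)
    for (start in seq(1L, n, by = batch)) {
      take <- start:min(start + batch - 1L, n)
      p[take] <- .cnn_forward(model$net, images$x[take, , drop = FALSE])
    }
  }
  out <- cbind(data.frame(mol_id = images$mol_id,
                          stringsAsFactors = FALSE),
               images$rotation)
  out$probability <- p
  out
}

# ---- descriptor-table tree-ensemble baseline -------------------------------

#' Compute a molecular descriptor table
#'
#' One row per molecule: physicochemical properties from Open Babel
#' (H-bond acceptors/donors, logP, molar refractivity, molecular weight,
#' fluorine count, topological polar surface area) plus the 1024 bits of
#' the FP2 path fingerprint. Columns containing non-finite values are
#' median-imputed; all-missing columns are dropped. Both adjustments are
#' reported in attributes.
#'
#' @param smiles character vector of SMILES.
#' @param mol_ids row identifiers (default: the SMILES).
#' @return numeric matrix (rows = molecules that parsed, named columns),
#'   with attributes `dropped` (failed molecules), `imputed` and
#'   `removed_cols`.
#' @export
compute_descriptors <- function(smiles, mol_ids = smiles) {
  stopifnot(length(smiles) == length(mol_ids))
  if (length(smiles) == 0L) {
    m <- matrix(numeric(0), 0L, 0L)
    attr(m, "dropped") <- character(0)
    return(m)
  }
  ok <- !is.na(canonical_smiles(smiles))
  dropped <- mol_ids[!ok]
  if (!any(ok)) {
    m <- matrix(numeric(0), 0L, 0L)
    attr(m, "dropped") <- dropped
    return(m)
  }
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smiles[ok], mol_ids[ok])))
  props <- ChemmineR::propOB(sdfset)
  num_cols <- names(props)[vapply(props, is.numeric, logical(1L))]
  phys <- as.matrix(props[, num_cols, drop = FALSE])
  fp <- ChemmineR::fingerprintOB(sdfset, "FP2")@fpma
  colnames(fp) <- sprintf("FP2_%04d", seq_len(ncol(fp)))
  m <- cbind(phys, fp)
  rownames(m) <- mol_ids[ok]
  all_bad <- apply(m, 2L, function(v) all(!is.finite(v)))
  removed <- colnames(m)[all_bad]
  m <- m[, !all_bad, drop = FALSE]
  imputed <- character(0)
  for (j in seq_len(ncol(m))) {
    bad <- !is.finite(m[, j])
    if (any(bad)) {
      m[bad, j] <- stats::median(m[!bad, j])
      imputed <- c(imputed, colnames(m)[j])
    }
  }
  attr(m, "dropped") <- dropped
  attr(m, "imputed") <- imputed
  attr(m, "removed_cols") <- removed
  m
}

#' Baseline grid configuration for the tree ensembles
#'
#' `max_features` is mapped to the number of candidate features per split
#' for the random forest (`mtry`) and, for gradient boosting, to the
#' per-tree column subsample fraction `max_features / n_features`; the
#' mapping is recorded in the fitted object's metadata.
#'
#' @param model `"rf"` or `"xgb"`.
#' @param max_depth maximum tree depth (>= 1).
#' @param n_estimators number of trees / boosting rounds (>= 1).
#' @param max_features feature-subsampling size (>= 1).
#' @param seed integer seed.
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(model = c("rf", "xgb"), max_depth = 20,
                            n_estimators = 1000, max_features = 120,
                            seed = 1L) {
  model <- match.arg(model)
  if (max_depth < 1 || n_estimators < 1 || max_features < 1)
    stop("max_depth, n_estimators and max_features must be >= 1")
  structure(list(model = model, max_depth = as.integer(max_depth),
                 n_estimators = as.integer(n_estimators),
                 max_features = as.integer(max_features),
                 seed = as.integer(seed)),
            class = "baseline_config")
}

#' Repeated hold-out evaluation of the descriptor-table baseline
#'
#' For each repeat: a fresh seeded 1:1 train/test split of the rows, a
#' random-forest or gradient-boosting fit with the configured grid values,
#' and the held-out AUC. A degenerate draw (single-class half) is redrawn
#' with the next seed and logged.
#'
#' @param x numeric descriptor matrix from [compute_descriptors()].
#' @param labels character vector (`"active"`/`"inactive"`), parallel to
#'   rows of `x`.
#' @param config a [baseline_config()].
#' @param n_repeats number of independent splits (default 5).
#' @return list with `aucs`, `mean`, `sd`, `config`, `redraws` and
#'   `feature_mapping` metadata.
#' @export
train_tree_baseline <- function(x, labels, config = baseline_config(),
                                n_repeats = 5L) {
  if (nrow(x) < 4L) stop("need at least 4 rows")
  y <- .as_active(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  p <- ncol(x)
  aucs <- numeric(n_repeats)
  redraws <- 0L
  seed_k <- config$seed
  for (r in seq_len(n_repeats)) {
    repeat {
      set.seed(seed_k)
      seed_used <- seed_k
      seed_k <- seed_k + 1L
      tr <- sample(nrow(x), floor(nrow(x) / 2))
      if (length(unique(y[tr])) == 2L && length(unique(y[-tr])) == 2L) break
      redraws <- redraws + 1L
      if (redraws > 25L * n_repeats)
        stop("cannot draw a two-class 1:1 split; class counts too small")
    }
    if (config$model == "rf") {
      df <- data.frame(y = factor(y[tr]), x[tr, , drop = FALSE])
      fit <- ranger::ranger(y ~ ., data = df,
                            num.trees = config$n_estimators,
                            mtry = min(config$max_features, p),
                            max.depth = config$max_depth,
                            probability = TRUE, seed = seed_used,
                            num.threads = 1L)
      prob <- stats::predict(fit, data.frame(x[-tr, , drop = FALSE]))$
        predictions[, "TRUE"]
    } else {
      set.seed(seed_used)
      dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE],
                                  label = as.numeric(y[tr]))
      fit <- xgboost::xgb.train(
        params = list(max_depth = config$max_depth,
                      colsample_bytree = min(1, config$max_features / p),
                      objective = "binary:logistic", nthread = 1L,
                      seed = seed_used),
        data = dtr, nrounds = config$n_estimators, verbose = 0)
      prob <- stats::predict(fit,
                             xgboost::xgb.DMatrix(x[-tr, , drop = FALSE]))
    }
    aucs[r] <- roc_auc(prob,
                       ifelse(y[-tr], "active", "inactive"))$auc
  }
  list(aucs = aucs, mean = mean(aucs), sd = stats::sd(aucs),
       config = config, redraws = redraws,
       feature_mapping = if (config$model == "rf")
         "max_features -> mtry (features per split)" else
           "max_features -> colsample_bytree = max_features / n_features")
}
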