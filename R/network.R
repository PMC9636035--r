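# The classifier stack. One compact convolutional backbone serves both
# deployments: TumorNet (3-class normal/LUAD/LUSC) and TMBNet (binary
# high/low TMB). A gradient-reversed confounder head over slide IDs can be
# attached to the shared representation (adversarial confounder
# suppression). Forward and backward passes are explicit matrix algebra
# (im2col convolution), which keeps every gradient auditable and the whole
# stack trainable on a single CPU at desk scale.

#' Describe a backbone
#'
#' @param architecture backbone family; `"small_cnn"` (one 5x5 stride-2
#'   convolution, ReLU, global average pooling, one hidden dense layer) is
#'   the implemented architecture.
#' @param input_px edge length the network consumes; patches are
#'   area-resampled to this size (default 32).
#' @param n_filters convolution filters (default 12).
#' @param representation_dim width of the penultimate representation that
#'   feeds both heads (default 16).
#' @param layernorm apply layer normalization (per-sample, across
#'   features) to the convolution and dense pre-activations (default
#'   TRUE). Normalization makes the feature and logit scales independent
#'   of the weight initialization, which is what lets the small
#'   learning-rate schedule make progress within a short run; a
#'   per-sample scheme is used because training batches are drawn from a
#'   single slide, so batch statistics would carry (and remove) the
#'   slide-level signal itself.
#' @param pretrained must be `FALSE`; no pretrained weights ship with the
#'   package.
#' @return a `backbone_spec`.
#' @export
backbone_spec <- function(architecture = "small_cnn", input_px = 32L,
                          n_filters = 12L, representation_dim = 16L,
                          layernorm = TRUE, pretrained = FALSE) {
  architecture <- match.arg(architecture)
  if (pretrained)
    stop("no pretrained weights are available for small_cnn", call. = FALSE)
  if (representation_dim < 1L) stop("representation_dim must be > 0", call. = FALSE)
  structure(list(architecture = architecture, input_px = as.integer(input_px),
                 n_filters = as.integer(n_filters),
                 representation_dim = as.integer(representation_dim),
                 layernorm = isTRUE(layernorm),
                 kernel = 5L, stride = 2L, pretrained = FALSE),
            class = "backbone_spec")
}

# --- layer normalization (per row, i.e. per sample/position) --------------
# gamma/beta are per-feature (column) learnable scale and shift.

ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  list(y = sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+"),
       xhat = xhat, sd = sd)
}

ln_backward <- function(dy, cache, gamma) {
  dxhat <- sweep(dy, 2L, gamma, "*")
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) /
    cache$sd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

conv_geometry <- function(spec) {
  S <- spec$input_px; k <- spec$kernel; st <- spec$stride
  ho <- (S - k) %/% st + 1L
  P <- ho * ho
  idx <- matrix(0L, nrow = P, ncol = k * k * 3L)
  p <- 0L
  for (r0 in 0:(ho - 1L)) {
    for (c0 in 0:(ho - 1L)) {
      p <- p + 1L
      o <- 0L
      for (ch in 1:3) {
        for (dc in 0:(k - 1L)) {
          for (dr in 0:(k - 1L)) {
            o <- o + 1L
            idx[p, o] <- (r0 * st + dr + 1L) + (c0 * st + dc) * S +
              (ch - 1L) * S * S
          }
        }
      }
    }
  }
  list(P = P, idx = idx, cols = k * k * 3L)
}

#' Build a classifier with an optional gradient-reversed confounder head
#'
#' The task head and the confounder head consume the same penultimate
#' representation; the confounder branch contains the gradient reversal,
#' so its own linear map descends the confounder cross-entropy while the
#' backbone ascends it. Heads are zero-initialized (an untrained model
#' outputs uniform probabilities); convolution and dense weights use
#' He-scaled draws from the current RNG state.
#'
#' @param spec a [backbone_spec()].
#' @param n_task_classes number of task classes (>= 2).
#' @param n_confounder_classes number of slide IDs; 0 disables the
#'   confounder branch.
#' @param lambda gradient-reversal weight (>= 0).
#' @param task_levels,confounder_levels optional class name vectors.
#' @return an `advcs_model`.
#' @export
build_model <- function(spec, n_task_classes, n_confounder_classes = 0L,
                        lambda = 1, task_levels = NULL,
                        confounder_levels = NULL) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (n_task_classes < 2L) stop("need at least 2 task classes", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  geo <- conv_geometry(spec)
  Fh <- spec$n_filters; R <- spec$representation_dim
  params <- list(
    W1 = matrix(stats::rnorm(geo$cols * Fh, 0, sqrt(2 / geo$cols)), geo$cols, Fh),
    b1 = numeric(Fh),
    W2 = matrix(stats::rnorm(Fh * R, 0, sqrt(2 / Fh)), Fh, R),
    b2 = numeric(R),
    Wt = matrix(0, R, n_task_classes), bt = numeric(n_task_classes))
  if (spec$layernorm) {
    params$gamma1 <- rep(1, Fh); params$beta1 <- numeric(Fh)
    params$gamma2 <- rep(1, R); params$beta2 <- numeric(R)
  }
  if (n_confounder_classes > 0L) {
    params$Wc <- matrix(0, R, n_confounder_classes)
    params$bc <- numeric(n_confounder_classes)
  }
  structure(list(spec = spec, geometry = geo, params = params,
                 n_task_classes = as.integer(n_task_classes),
                 n_confounder_classes = as.integer(n_confounder_classes),
                 lambda = lambda,
                 task_levels = task_levels,
                 confounder_levels = confounder_levels,
                 trained = FALSE, history = NULL, config = NULL),
            class = "advcs_model")
}

#' Gradient reversal: identity forward pass
#'
#' @param x numeric values.
#' @param lambda reversal weight (>= 0); unused on the forward pass.
#' @return `x` unchanged.
#' @seealso [gradient_reverse_backward()]
#' @export
gradient_reverse <- function(x, lambda = 1) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  x
}

#' Gradient reversal: backward pass
#'
#' The gradient propagated upstream is minus `lambda` times the downstream
#' gradient.
#'
#' @param grad downstream gradient.
#' @param lambda reversal weight (>= 0).
#' @return `-lambda * grad`.
#' @export
gradient_reverse_backward <- function(grad, lambda = 1) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  -lambda * grad
}

# Stack a list of 0..255 patch arrays into the n x (S*S*3) matrix the
# backbone consumes (values scaled to 0..1, resized to spec$input_px).
stack_patches <- function(model, patches) {
  S <- model$spec$input_px
  n <- length(patches)
  X <- matrix(0, n, S * S * 3L)
  for (i in seq_len(n)) {
    img <- patches[[i]]
    if (inherits(img, "piter_patch")) img <- img$pixels
    stopifnot_rgb(img, "patch")
    if (dim(img)[1] != S || dim(img)[2] != S) img <- resize_rgb(img, S, S)
    X[i, ] <- as.vector(img) / 255
  }
  X
}

# Full forward pass on a stacked batch matrix. Returns every intermediate
# needed by the backward pass. Layer normalization is per sample, so the
# forward pass is identical in training and evaluation.
model_forward <- function(model, X) {
  n <- nrow(X)
  geo <- model$geometry
  P <- geo$P
  pm <- model$params
  ln <- model$spec$layernorm
  Xc <- X[, as.vector(geo$idx), drop = FALSE]   # n x (P*cols), position-fastest
  dim(Xc) <- c(n * P, geo$cols)
  Z1 <- sweep(Xc %*% pm$W1, 2L, pm$b1, "+")
  ln1 <- NULL
  if (ln) {
    ln1 <- ln_forward(Z1, pm$gamma1, pm$beta1)
    Z1n <- ln1$y
  } else Z1n <- Z1
  A1 <- relu(Z1n)
  g <- rowsum(A1, group = rep.int(seq_len(n), P)) / P
  Z2 <- sweep(g %*% pm$W2, 2L, pm$b2, "+")
  ln2 <- NULL
  if (ln) {
    ln2 <- ln_forward(Z2, pm$gamma2, pm$beta2)
    Z2n <- ln2$y
  } else Z2n <- Z2
  A2 <- relu(Z2n)
  Lt <- sweep(A2 %*% pm$Wt, 2L, pm$bt, "+")
  out <- list(Xc = Xc, Z1 = Z1, Z1n = Z1n, ln1 = ln1, g = g, Z2 = Z2,
              Z2n = Z2n, ln2 = ln2, representation = A2,
              task_logits = Lt, task_probs = softmax_rows(Lt))
  if (model$n_confounder_classes > 0L) {
    # forward through the reversal is the identity
    Ar <- gradient_reverse(A2, model$lambda)
    Lc <- sweep(Ar %*% model$params$Wc, 2L, model$params$bc, "+")
    out$conf_logits <- Lc
    out$conf_probs <- softmax_rows(Lc)
  }
  out
}

#' Cross-entropy and gradients of the adversarial objective on one batch
#'
#' Computes the total loss `CE_task + alpha * CE_conf` and the gradient of
#' every parameter, with the gradient reversal applied where the
#' confounder branch meets the shared representation. Exposed so the
#' backward pass can be verified against finite differences.
#'
#' @param model an `advcs_model`.
#' @param X stacked batch (`n x input_px^2*3`), from `stack_patches`.
#' @param y integer task targets (1-based).
#' @param s integer confounder targets (1-based), or `NULL`.
#' @param alpha confounder loss weight.
#' @param lambda gradient-reversal weight; defaults to the model's.
#' @param project_conflict if TRUE, the reversed confounder gradient at
#'   the representation is projected orthogonal to the task gradient
#'   whenever the two conflict (negative inner product), so adversarial
#'   pressure cannot directly undo task learning.
#' @return list with `losses` (task, conf, total) and `grads`.
#' @export
advcs_gradients <- function(model, X, y, s = NULL, alpha = 0,
                            lambda = model$lambda,
                            project_conflict = FALSE) {
  fw <- model_forward(model, X)
  n <- nrow(X)
  lt <- log_softmax_rows(fw$task_logits)
  loss_task <- -mean(lt[cbind(seq_len(n), y)])
  dLt <- fw$task_probs
  dLt[cbind(seq_len(n), y)] <- dLt[cbind(seq_len(n), y)] - 1
  dLt <- dLt / n
  grads <- list(Wt = crossprod(fw$representation, dLt), bt = colSums(dLt))
  dA2 <- dLt %*% t(model$params$Wt)
  loss_conf <- 0
  if (alpha > 0) {
    if (is.null(s) || model$n_confounder_classes == 0L)
      stop("alpha > 0 requires a confounder branch and targets", call. = FALSE)
    lc <- log_softmax_rows(fw$conf_logits)
    loss_conf <- -mean(lc[cbind(seq_len(n), s)])
    dLc <- fw$conf_probs
    dLc[cbind(seq_len(n), s)] <- dLc[cbind(seq_len(n), s)] - 1
    dLc <- alpha * dLc / n
    grads$Wc <- crossprod(fw$representation, dLc)
    grads$bc <- colSums(dLc)
    # reversal: the backbone ascends the confounder cross-entropy
    rev_grad <- gradient_reverse_backward(dLc %*% t(model$params$Wc), lambda)
    if (project_conflict) {
      ip <- sum(rev_grad * dA2)
      nt <- sum(dA2^2)
      if (ip < 0 && nt > 0) rev_grad <- rev_grad - (ip / nt) * dA2
    }
    dA2 <- dA2 + rev_grad
  }
  dZ2n <- dA2 * (fw$Z2n > 0)
  if (model$spec$layernorm) {
    bb2 <- ln_backward(dZ2n, fw$ln2, model$params$gamma2)
    grads$gamma2 <- bb2$dgamma; grads$beta2 <- bb2$dbeta
    dZ2 <- bb2$dx
  } else dZ2 <- dZ2n
  grads$W2 <- crossprod(fw$g, dZ2)
  grads$b2 <- colSums(dZ2)
  dg <- dZ2 %*% t(model$params$W2)
  P <- model$geometry$P
  dA1 <- dg[rep.int(seq_len(n), P), , drop = FALSE] / P
  dZ1n <- dA1 * (fw$Z1n > 0)
  if (model$spec$layernorm) {
    bb1 <- ln_backward(dZ1n, fw$ln1, model$params$gamma1)
    grads$gamma1 <- bb1$dgamma; grads$beta1 <- bb1$dbeta
    dZ1 <- bb1$dx
  } else dZ1 <- dZ1n
  grads$W1 <- crossprod(fw$Xc, dZ1)
  grads$b1 <- colSums(dZ1)
  list(losses = list(task = loss_task, conf = loss_conf,
                     total = loss_task + alpha * loss_conf),
       grads = grads, forward = fw)
}

#' Predict class probabilities (and representations) for patches
#'
#' Deterministic evaluation-mode forward pass; no augmentation. Patches
#' are processed in batches and results keep input order.
#'
#' @param model an `advcs_model`.
#' @param patches list of RGB arrays or `piter_patch` objects.
#' @param type `"task"` (probability matrix), `"representation"`, or
#'   `"confounder"`.
#' @param batch_size internal batch size.
#' @return matrix with one row per patch.
#' @export
predict_patches <- function(model, patches, type = c("task", "representation",
                                                     "confounder"),
                            batch_size = 128L) {
  type <- match.arg(type)
  stopifnot(inherits(model, "advcs_model"))
  if (type == "confounder" && model$n_confounder_classes == 0L)
    stop("model has no confounder branch", call. = FALSE)
  n <- length(patches)
  if (n == 0L) return(matrix(numeric(0), 0L, 0L))
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    X <- stack_patches(model, patches[idx])
    fw <- model_forward(model, X)
    block <- switch(type, task = fw$task_probs,
                    representation = fw$representation,
                    confounder = fw$conf_probs)
    out <- rbind(out, block)
  }
  rownames(out) <- NULL
  if (type == "task" && !is.null(model$task_levels))
    colnames(out) <- model$task_levels
  out
}

#' Linear probe: how decodable is the slide ID from the representation?
#'
#' Fits a fresh multinomial-logistic probe predicting slide ID from frozen
#' representations, on a per-slide stratified train split, and reports
#' held-out accuracy together with the chance level 1/N. High probe
#' accuracy means the representation still carries the slide-level
#' confounder that adversarial suppression is meant to remove.
#'
#' @param representations numeric matrix (patches x features).
#' @param slide_ids character/factor slide ID per row.
#' @param train_frac fraction of each slide's patches used to fit the
#'   probe (default 0.7).
#' @return list with `accuracy`, `chance`, `n_classes`, `n_test`.
#' @export
probe_confounder <- function(representations, slide_ids, train_frac = 0.7) {
  slide_ids <- as.character(slide_ids)
  stopifnot(nrow(representations) == length(slide_ids))
  tab <- table(slide_ids)
  small <- names(tab)[tab < 2L]
  if (length(small) > 0L) {
    warning(sprintf("excluding %d slide(s) with < 2 patches", length(small)))
    keep <- !(slide_ids %in% small)
    representations <- representations[keep, , drop = FALSE]
    slide_ids <- slide_ids[keep]
  }
  lev <- unique(slide_ids)
  if (length(lev) < 2L)
    stop("need at least 2 slide IDs with >= 2 patches", call. = FALSE)
  train_idx <- unlist(lapply(lev, function(s) {
    i <- which(slide_ids == s)
    i[seq_len(max(1L, floor(train_frac * length(i))))]
  }))
  test_idx <- setdiff(seq_along(slide_ids), train_idx)
  df <- data.frame(representations)
  df$.slide <- factor(slide_ids, levels = lev)
  fit <- nnet::multinom(.slide ~ ., data = df[train_idx, , drop = FALSE],
                        trace = FALSE, maxit = 200L,
                        MaxNWts = (ncol(representations) + 2L) * length(lev) + 10L)
  pred <- predict(fit, newdata = df[test_idx, , drop = FALSE])
  list(accuracy = mean(as.character(pred) == slide_ids[test_idx]),
       chance = 1 / length(lev), n_classes = length(lev),
       n_test = length(test_idx))
}
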