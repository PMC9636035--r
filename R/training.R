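#' Training configuration
#'
#' Defaults follow the optimization recipe used for both network
#' deployments: Adam with a cosine learning-rate schedule decreasing from
#' 6e-4 to 6e-6 over 20 epochs, weight decay 0.01, batches of 32 patches
#' drawn from a single slide, and augmentation by random 90-degree
#' rotations plus horizontal flips with probability 0.5.
#'
#' @param batch_size patches per batch (default 32).
#' @param epochs schedule length (default 20).
#' @param lr_max,lr_min cosine schedule endpoints (defaults 6e-4, 6e-6).
#' @param weight_decay decoupled weight decay on weight matrices
#'   (default 0.01).
#' @param aug_rot90 enable random 90-degree rotations (default TRUE).
#' @param aug_flip_p horizontal-flip probability (default 0.5).
#' @param lambda gradient-reversal weight (default 1).
#' @param lambda_warmup fraction of steps over which lambda ramps linearly
#'   from 0 (default 1: the ramp spans the whole run, so the task is
#'   learned first and invariance pressure grows as it consolidates).
#' @param alpha confounder cross-entropy weight; 0 disables adversarial
#'   confounder suppression (default 0.5).
#' @param conf_head_lr_mult learning-rate multiplier for the confounder
#'   head's own gradient steps between refits (default 0: the head is
#'   held fixed between refits). Adam's per-parameter normalization makes
#'   head updates insensitive to `alpha`, so per-step head training
#'   cannot keep up with the drifting representation at the recipe's
#'   learning rates; the refit mechanism replaces it.
#' @param conf_head_refit_every refit the confounder head to convergence
#'   (multinomial logistic regression on the current representations of
#'   all training patches) every this many epochs (default 1; 0 disables).
#'   Between refits the head keeps taking gradient steps. Solving the
#'   inner maximization well is what makes the reversed gradient point at
#'   the directions that actually encode the confounder; a head trained
#'   only by small SGD steps lags the drifting representation and the
#'   backbone can defeat it without discarding slide information.
#' @param conf_head_decay ridge penalty used when refitting the head
#'   (default 1). Regularization keeps the refit head accurate but soft;
#'   a fully saturated softmax head emits near-zero gradients and the
#'   reversal has nothing to push against, and an unregularized one
#'   starts exploiting the subtle label-carrying features rather than
#'   the high-amplitude slide signature.
#' @param grad_projection if TRUE (default) the reversed confounder
#'   gradient at the representation is projected orthogonal to the task
#'   gradient when the two conflict; adversarial pressure then suppresses
#'   the confounder without directly undoing task learning.
#' @param conf_head_conditional if TRUE the refit residualizes
#'   the representations against the task labels first, so the adversary
#'   targets only label-orthogonal slide signatures. Labels are slide
#'   resolved (every slide has one label), so an unconditional slide-ID
#'   adversary can attack the task signal itself.
#' @param conf_head_refit_batches refit cadence in batches (overrides the
#'   per-epoch cadence when set); frequent refits keep the adversary
#'   current with the drifting representation.
#' @param conf_head_reset_every re-initialize the confounder head (weights
#'   to zero, fresh optimizer state) every this many epochs (default 0 =
#'   never); an alternative, weaker form of adversary refresh.
#' @param batches_per_epoch number of batches that constitute an epoch;
#'   `NULL` (default) uses one pass in expectation, i.e.
#'   `sum(ceiling(patches_per_slide / batch_size))` over training slides.
#'   Because patches are sampled with replacement an epoch is a schedule
#'   unit, not a strict pass; larger values give the optimizer (and the
#'   adversarial minimax) more steps per schedule unit.
#' @param mixed_slide_batches if TRUE, batches mix patches across slides
#'   (ablation mode); default FALSE, one slide per batch.
#' @param seed master seed; sampling, augmentation and initialization use
#'   separate streams derived from it.
#' @return a `training_config`.
#' @export
training_config <- function(batch_size = 32L, epochs = 20L, lr_max = 6e-4,
                            lr_min = 6e-6, weight_decay = 0.01,
                            aug_rot90 = TRUE, aug_flip_p = 0.5,
                            lambda = 1, lambda_warmup = 1, alpha = 0.5,
                            conf_head_lr_mult = 0, conf_head_refit_every = 1L,
                            grad_projection = FALSE,
                            conf_head_decay = 1, conf_head_conditional = FALSE,
                            conf_head_refit_batches = 25L,
                            conf_head_reset_every = 0L,
                            batches_per_epoch = NULL,
                            mixed_slide_batches = FALSE, seed = 1L) {
  if (lr_min >= lr_max) stop("lr_min must be < lr_max", call. = FALSE)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_max = lr_max, lr_min = lr_min,
                 schedule = "cosine", weight_decay = weight_decay,
                 aug_rot90 = aug_rot90, aug_flip_p = aug_flip_p,
                 lambda = lambda, lambda_warmup = lambda_warmup,
                 alpha = alpha, conf_head_lr_mult = conf_head_lr_mult,
                 conf_head_refit_every = as.integer(conf_head_refit_every),
                 grad_projection = isTRUE(grad_projection),
                 conf_head_decay = conf_head_decay,
                 conf_head_conditional = isTRUE(conf_head_conditional),
                 conf_head_refit_batches = if (is.null(conf_head_refit_batches))
                   NULL else as.integer(conf_head_refit_batches),
                 conf_head_reset_every = as.integer(conf_head_reset_every),
                 batches_per_epoch = if (is.null(batches_per_epoch)) NULL
                                     else as.integer(batches_per_epoch),
                 mixed_slide_batches = mixed_slide_batches,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Cross-entropy loss
#'
#' `-log p(target)`, computed stably from logits via log-softmax. Accepts
#' a single sample (vector) or a batch (matrix, one row per sample), with
#' class probabilities or raw logits.
#'
#' @param x probabilities or logits (vector or matrix).
#' @param target 1-based class index (scalar or per-row vector).
#' @param input `"probs"` or `"logits"`.
#' @return mean loss over the batch (nonnegative).
#' @export
cross_entropy <- function(x, target, input = c("probs", "logits")) {
  input <- match.arg(input)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (any(target < 1L) || any(target > ncol(x)))
    stop("target class index out of range", call. = FALSE)
  lp <- if (input == "probs") {
    if (any(x < 0) || any(abs(rowSums(x) - 1) > 1e-6))
      stop("rows of x are not probability vectors", call. = FALSE)
    log_softmax_rows(log(pmax(x, 1e-300)))
  } else log_softmax_rows(x)
  -mean(lp[cbind(seq_len(nrow(lp)), target)])
}

#' Composite adversarial confounder-suppression loss
#'
#' `total = CE_task + alpha * CE_confounder`. The gradient reversal lives
#' inside the confounder branch of the model, so at the loss level the
#' confounder term is a plain weighted cross-entropy: the confounder head
#' descends it while the backbone (through the reversal) ascends it.
#'
#' @param task_probs,task_target task probabilities and 1-based target(s).
#' @param conf_probs,conf_target confounder probabilities and target(s);
#'   required when `alpha > 0`.
#' @param alpha confounder loss weight (>= 0).
#' @return list with `task`, `conf`, `total`.
#' @export
advcs_loss <- function(task_probs, task_target, conf_probs = NULL,
                       conf_target = NULL, alpha = 0) {
  task <- cross_entropy(task_probs, task_target)
  conf <- 0
  if (alpha > 0) {
    if (is.null(conf_probs) || is.null(conf_target))
      stop("alpha > 0 but confounder outputs/targets are missing", call. = FALSE)
    conf <- cross_entropy(conf_probs, conf_target)
  }
  list(task = task, conf = conf, total = task + alpha * conf)
}

#' Cosine learning-rate schedule
#'
#' `lr(t) = lr_min + (lr_max - lr_min) * (1 + cos(pi t)) / 2`, monotone
#' non-increasing from `lr_max` at `t = 0` to `lr_min` at `t = 1`.
#'
#' @param t training progress fraction in `[0, 1]` (vectorized).
#' @param lr_max,lr_min schedule endpoints.
#' @return learning rate(s).
#' @export
cosine_lr <- function(t, lr_max = 6e-4, lr_min = 6e-6) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]", call. = FALSE)
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t))
}

#' Augment a square patch
#'
#' Rotation by k*90 degrees (k uniform on 0..3) followed by a horizontal
#' flip with probability `flip_p`. The pixel multiset is preserved. Draws
#' come from the current RNG state; `rot_k`/`flip` can be forced.
#'
#' @param patch `piter_patch` or RGB array.
#' @param flip_p flip probability (default 0.5).
#' @param rot_k optional forced rotation count (0..3).
#' @param flip optional forced flip (logical).
#' @return augmented patch, same type and shape.
#' @export
augment_patch <- function(patch, flip_p = 0.5, rot_k = NULL, flip = NULL) {
  img <- if (inherits(patch, "piter_patch")) patch$pixels else patch
  stopifnot_rgb(img, "patch")
  d <- dim(img)
  if (d[1] != d[2]) stop("augmentation requires a square patch", call. = FALSE)
  if (is.null(rot_k)) rot_k <- sample.int(4L, 1L) - 1L
  if (is.null(flip)) flip <- stats::runif(1L) < flip_p
  if (rot_k > 0L) {
    for (i in seq_len(rot_k)) {
      img <- aperm(img, c(2, 1, 3))
      img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
    }
  }
  if (flip) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (inherits(patch, "piter_patch")) {
    patch$pixels <- img
    patch
  } else img
}

# Flatten bags into a per-slide table used by the sampler and the trainer.
slide_table <- function(bags) {
  out <- list()
  for (bag in bags) {
    for (sid in names(bag$slides)) {
      ps <- bag$slides[[sid]]
      out[[sid]] <- list(slide_id = sid, patient_id = bag$patient_id,
                         class = bag$class, patches = ps,
                         n = length(ps))
    }
  }
  out
}

#' Sample one training batch
#'
#' Draws `batch_size` patches uniformly with replacement from the tissue
#' patches of a single slide (one slide per batch); every label in the
#' batch is the slide's patient-level TMB class. Slides with zero patches
#' are skipped with a warning.
#'
#' @param bags list of patient bags (see [cohort_bags()]).
#' @param batch_size number of patches (default 32).
#' @param slide_id optional: force a particular slide.
#' @return list with `patches`, `class` (one label per patch), `slide_id`.
#' @export
sample_batch <- function(bags, batch_size = 32L, slide_id = NULL) {
  slides <- slide_table(bags)
  empty <- vapply(slides, function(s) s$n == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("skipping %d slide(s) with zero tissue patches", sum(empty)))
    slides <- slides[!empty]
  }
  if (length(slides) == 0L) stop("no non-empty slides to sample from", call. = FALSE)
  if (is.null(slide_id))
    slide_id <- names(slides)[sample.int(length(slides), 1L)]
  sl <- slides[[slide_id]]
  if (is.null(sl)) stop("unknown or empty slide: ", slide_id, call. = FALSE)
  idx <- sample.int(sl$n, batch_size, replace = TRUE)
  list(patches = sl$patches[idx], class = rep(sl$class, batch_size),
       slide_id = slide_id)
}

# Fit the confounder head to convergence on the current representations:
# multinomial logistic regression of slide ID on the penultimate features.
# When task labels are supplied the representations are first residualized
# against them (per-class means removed), so the head can only exploit
# label-orthogonal directions -- the slide-level nuisance -- and the
# reversed gradient cannot attack the task signal itself. Returns weights
# on the model's logit parameterization (first class as reference gives an
# equivalent softmax up to a constant shift).
fit_confounder_head <- function(model, patches, slide_ids, slide_levels,
                                decay = 0.3, task_labels = NULL) {
  reps <- predict_patches(model, patches, type = "representation")
  if (!is.null(task_labels)) {
    for (lv in unique(task_labels)) {
      rows <- task_labels == lv
      reps[rows, ] <- sweep(reps[rows, , drop = FALSE], 2L,
                            colMeans(reps[rows, , drop = FALSE]))
    }
  }
  df <- data.frame(reps)
  df$.slide <- factor(slide_ids, levels = slide_levels)
  fit <- tryCatch(
    nnet::multinom(.slide ~ ., data = df, trace = FALSE, maxit = 100L,
                   decay = decay,
                   MaxNWts = (ncol(reps) + 2L) * length(slide_levels) + 10L),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)                       # (N-1) x (1 + R)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1L)
  W <- matrix(0, ncol(reps), length(slide_levels))
  b <- numeric(length(slide_levels))
  W[, -1L] <- t(co[, -1L, drop = FALSE])
  b[-1L] <- co[, 1L]
  list(W = W, b = b)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      lr_mult = NULL, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && startsWith(nm, "W"))  # decoupled, weights only
      upd <- upd + weight_decay * params[[nm]]
    mult <- if (!is.null(lr_mult) && nm %in% names(lr_mult)) lr_mult[[nm]] else 1
    params[[nm]] <- params[[nm]] - lr * mult * upd
  }
  list(params = params, state = state)
}

#' Train a classifier with adversarial confounder suppression
#'
#' Builds the model (task classes from the bag labels; confounder classes
#' = training slide IDs when `alpha > 0`) and runs the Adam/cosine recipe.
#' One epoch visits every training slide, with `ceil(n_patches / batch)`
#' batches per slide, patches sampled with replacement. After each epoch
#' the patient-level validation AUC (median-aggregated patch
#' probabilities) is computed and the best-AUC parameters are retained.
#'
#' @param train_bags,val_bags patient bags ([cohort_bags()]); `val_bags`
#'   may be `NULL` (final parameters are then kept).
#' @param config a [training_config()].
#' @param spec a [backbone_spec()].
#' @param model optional pre-built `advcs_model` to continue training.
#' @return a trained `advcs_model`; `$history` holds per-step learning
#'   rate and losses plus per-epoch validation AUC.
#' @export
advcs_train <- function(train_bags, val_bags = NULL,
                        config = training_config(),
                        spec = backbone_spec(), model = NULL) {
  stopifnot(inherits(config, "training_config"))
  slides <- slide_table(train_bags)
  slides <- slides[vapply(slides, function(s) s$n > 0L, logical(1))]
  if (length(slides) == 0L) stop("no training patches", call. = FALSE)
  task_levels <- sort(unique(vapply(slides, `[[`, "", "class")))
  if (length(task_levels) < 2L)
    stop("need at least 2 task classes in the training labels", call. = FALSE)
  streams <- make_rng_streams(config$seed, c("init", "sample", "aug"))
  n_conf <- if (config$alpha > 0) length(slides) else 0L
  if (is.null(model)) {
    model <- with_stream(streams, "init",
      build_model(spec, length(task_levels), n_conf, lambda = config$lambda,
                  task_levels = task_levels,
                  confounder_levels = names(slides)))
  }
  model$config <- config

  if (config$epochs == 0L) {
    model$history <- data.frame(epoch = integer(0), step = integer(0),
                                lr = numeric(0), task_loss = numeric(0),
                                conf_loss = numeric(0), total_loss = numeric(0),
                                val_auc = numeric(0))
    return(model)
  }

  per_slide_batches <- vapply(slides, function(s)
    as.integer(ceiling(s$n / config$batch_size)), integer(1))
  batches_per_epoch <- if (is.null(config$batches_per_epoch))
    sum(per_slide_batches) else config$batches_per_epoch
  total_steps <- config$epochs * batches_per_epoch
  astate <- adam_init(model$params)
  pool_patches <- unlist(lapply(slides, `[[`, "patches"), recursive = FALSE,
                         use.names = FALSE)
  pool_index <- data.frame(
    slide = rep(names(slides), vapply(slides, `[[`, 0L, "n")),
    class = rep(vapply(slides, `[[`, "", "class"),
                vapply(slides, `[[`, 0L, "n")),
    stringsAsFactors = FALSE)
  hist <- vector("list", total_steps)
  val_auc_by_epoch <- rep(NA_real_, config$epochs)
  best_auc <- -Inf; best_params <- model$params
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    if (n_conf > 0L && config$conf_head_reset_every > 0L && epoch > 1L &&
        (epoch - 1L) %% config$conf_head_reset_every == 0L) {
      model$params$Wc[] <- 0; model$params$bc[] <- 0
      astate$m$Wc[] <- 0; astate$v$Wc[] <- 0
      astate$m$bc[] <- 0; astate$v$bc[] <- 0
    }
    if (n_conf > 0L && is.null(config$conf_head_refit_batches) &&
        config$conf_head_refit_every > 0L &&
        (epoch - 1L) %% config$conf_head_refit_every == 0L) {
      head <- fit_confounder_head(model, pool_patches, pool_index$slide,
                                  names(slides),
                                  decay = config$conf_head_decay,
                                  task_labels = if (config$conf_head_conditional)
                                    pool_index$class else NULL)
      if (!is.null(head)) {
        model$params$Wc <- head$W; model$params$bc <- head$b
        astate$m$Wc[] <- 0; astate$v$Wc[] <- 0
        astate$m$bc[] <- 0; astate$v$bc[] <- 0
      }
    }
    visit <- if (is.null(config$batches_per_epoch)) {
      with_stream(streams, "sample",
                  sample(rep(seq_along(slides), times = per_slide_batches)))
    } else {
      with_stream(streams, "sample",
                  sample.int(length(slides), batches_per_epoch, replace = TRUE))
    }
    for (si in visit) {
      step <- step + 1L
      if (n_conf > 0L && !is.null(config$conf_head_refit_batches) &&
          (step - 1L) %% config$conf_head_refit_batches == 0L) {
        head <- fit_confounder_head(model, pool_patches, pool_index$slide,
                                    names(slides),
                                    decay = config$conf_head_decay,
                                    task_labels = if (config$conf_head_conditional)
                                      pool_index$class else NULL)
        if (!is.null(head)) {
          model$params$Wc <- head$W; model$params$bc <- head$b
          astate$m$Wc[] <- 0; astate$v$Wc[] <- 0
          astate$m$bc[] <- 0; astate$v$bc[] <- 0
        }
      }
      t_frac <- if (total_steps > 1L) (step - 1) / (total_steps - 1) else 0
      lr <- cosine_lr(t_frac, config$lr_max, config$lr_min)
      lam <- if (config$lambda_warmup > 0)
        config$lambda * min(1, t_frac / config$lambda_warmup) else config$lambda
      if (config$mixed_slide_batches) {
        pick <- with_stream(streams, "sample",
                            sample.int(nrow(pool_index), config$batch_size,
                                       replace = TRUE))
        batch <- pool_patches[pick]
        batch_class <- pool_index$class[pick]
        batch_slide <- pool_index$slide[pick]
      } else {
        sl <- slides[[si]]
        idx <- with_stream(streams, "sample",
                           sample.int(sl$n, config$batch_size, replace = TRUE))
        batch <- sl$patches[idx]
        batch_class <- rep(sl$class, config$batch_size)
        batch_slide <- rep(sl$slide_id, config$batch_size)
      }
      if (config$aug_rot90 || config$aug_flip_p > 0) {
        batch <- with_stream(streams, "aug", lapply(batch, function(p)
          augment_patch(p, flip_p = config$aug_flip_p,
                        rot_k = if (config$aug_rot90) NULL else 0L)))
      }
      X <- stack_patches(model, batch)
      y <- match(batch_class, task_levels)
      s <- if (n_conf > 0L) match(batch_slide, names(slides)) else NULL
      gr <- advcs_gradients(model, X, y, s, alpha = config$alpha, lambda = lam,
                            project_conflict = config$grad_projection)
      if (!is.finite(gr$losses$total))
        stop(sprintf("non-finite loss at epoch %d step %d (task %.4g, conf %.4g)",
                     epoch, step, gr$losses$task, gr$losses$conf), call. = FALSE)
      upd <- adam_step(model$params, gr$grads, astate, lr, config$weight_decay,
                       lr_mult = if (n_conf > 0L)
                         list(Wc = config$conf_head_lr_mult,
                              bc = config$conf_head_lr_mult) else NULL)
      model$params <- upd$params; astate <- upd$state
      hist[[step]] <- data.frame(epoch = epoch, step = step, lr = lr,
                                 task_loss = gr$losses$task,
                                 conf_loss = gr$losses$conf,
                                 total_loss = gr$losses$total)
    }
    if (!is.null(val_bags)) {
      sc <- score_bags(model, val_bags)
      val_auc_by_epoch[epoch] <- roc_auc(sc$score, sc$class == "high")$auc
      if (val_auc_by_epoch[epoch] >= best_auc) {
        best_auc <- val_auc_by_epoch[epoch]
        best_params <- model$params
      }
    }
  }
  if (!is.null(val_bags)) model$params <- best_params
  history <- do.call(rbind, hist)
  history$val_auc <- val_auc_by_epoch[history$epoch]
  is_last <- c(history$epoch[-1] != history$epoch[-nrow(history)], TRUE)
  history$val_auc[!is_last] <- NA_real_
  model$history <- history
  model$trained <- TRUE
  model
}
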