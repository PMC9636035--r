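#' @export
print.advcs_model <- function(x, ...) {
  cat(sprintf("Adversarial confounder-suppression classifier (%s)\n",
              x$spec$architecture))
  cat(sprintf("  input %dpx, %d filters, representation dim %d\n",
              x$spec$input_px, x$spec$n_filters, x$spec$representation_dim))
  cat(sprintf("  task classes: %s\n",
              paste(if (is.null(x$task_levels))
                      seq_len(x$n_task_classes) else x$task_levels,
                    collapse = ", ")))
  if (x$n_confounder_classes > 0L)
    cat(sprintf("  confounder head over %d slide IDs (lambda = %g)\n",
                x$n_confounder_classes, x$lambda))
  else cat("  no confounder head\n")
  cat(if (isTRUE(x$trained)) "  trained" else "  untrained", "\n")
  invisible(x)
}

#' @export
summary.advcs_model <- function(object, ...) {
  print(object)
  h <- object$history
  if (!is.null(h) && nrow(h) > 0L) {
    cat(sprintf("  %d steps over %d epochs; task loss %.4f -> %.4f\n",
                nrow(h), max(h$epoch), h$task_loss[1], h$task_loss[nrow(h)]))
    va <- h$val_auc[!is.na(h$val_auc)]
    if (length(va) > 0L)
      cat(sprintf("  validation AUC: last %.3f, best %.3f\n",
                  va[length(va)], max(va)))
  }
  n_par <- sum(vapply(object$params, length, numeric(1)))
  cat(sprintf("  %d parameters\n", n_par))
  invisible(object)
}

#' Predict from a fitted model
#'
#' @param object an `advcs_model`.
#' @param newdata a list of patches (RGB arrays or `piter_patch`), or a
#'   list of patient bags (each with a `slides` element), in which case
#'   patient-level median scores are returned.
#' @param type `"task"`, `"representation"`, or `"confounder"` for patch
#'   input; ignored for bags.
#' @param ... unused.
#' @return probability matrix (patches) or score data.frame (bags).
#' @export
predict.advcs_model <- function(object, newdata,
                                type = c("task", "representation",
                                         "confounder"), ...) {
  type <- match.arg(type)
  is_bags <- length(newdata) > 0L && is.list(newdata[[1]]) &&
    !is.null(newdata[[1]]$slides)
  if (is_bags) return(score_bags(object, newdata))
  predict_patches(object, newdata, type = type)
}

#' Plot training history
#'
#' Task (and confounder) loss per step plus per-epoch validation AUC.
#'
#' @param x a trained `advcs_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.advcs_model <- function(x, ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0L) stop("model has no training history",
                                        call. = FALSE)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$step, h$task_loss, type = "l", xlab = "step",
                 ylab = "loss", main = "training loss", ...)
  if (any(h$conf_loss > 0))
    graphics::lines(h$step, h$conf_loss, lty = 2L)
  va <- h[!is.na(h$val_auc), ]
  if (nrow(va) > 0L)
    graphics::plot(va$epoch, va$val_auc, type = "b", xlab = "epoch",
                   ylab = "validation AUC", ylim = c(0, 1),
                   main = "validation")
  invisible(x)
}

#' @export
print.piter_report <- function(x, ...) {
  cat("Biomarker evaluation report\n")
  cat(sprintf("  patients: %d\n", x$n_patients))
  cat(sprintf("  AUC: %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci_low,
              x$auc_ci_high))
  cat(sprintf("  Spearman rho vs continuous TMB: %.3f\n", x$rho))
  cat(sprintf("  cutoff: %.4g  sensitivity: %.3f  specificity: %.3f\n",
              x$cutoff, x$sensitivity, x$specificity))
  if (!is.null(x$logrank_p))
    cat(sprintf("  log-rank: chi2 = %.3f, p = %.4g\n", x$logrank_chi2,
                x$logrank_p))
  invisible(x)
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d slides, %d patches (%s)\n",
              length(unique(x$manifest$patient_id)), nrow(x$manifest),
              length(x$patches), paste(unique(x$manifest$split),
                                       collapse = "/")))
  invisible(x)
}
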