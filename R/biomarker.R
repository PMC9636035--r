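#' Label a TMB measurement as high or low
#'
#' Exome count mode uses the 206-mutation cutoff (approximately 10 mut/Mb
#' on a targeted panel); panel mode uses 10 mut/Mb. A value equal to the
#' cutoff is labeled high in both modes.
#'
#' @param raw_value nonnegative mutation count (`count` mode) or mut/Mb
#'   (`per_mb` mode); vectorized.
#' @param mode `"count"` or `"per_mb"`.
#' @param cutoff override the mode's default cutoff (206 or 10).
#' @return data.frame with raw_value, mode, cutoff, tmb_class.
#' @export
label_tmb <- function(raw_value, mode = c("count", "per_mb"), cutoff = NULL) {
  mode <- match.arg(mode)
  if (any(raw_value < 0)) stop("TMB values must be nonnegative", call. = FALSE)
  if (is.null(cutoff)) cutoff <- if (mode == "count") 206 else 10
  data.frame(raw_value = raw_value, mode = mode, cutoff = cutoff,
             tmb_class = ifelse(raw_value >= cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Keep only confident tumor patches of the expected histology
#'
#' A patch is retained iff its total tumor probability `1 - p_normal` is
#' at least `tau` and its argmax class equals the patient's histology.
#'
#' @param probs matrix of 3-class probabilities with columns
#'   `normal`, `luad`, `lusc` (one row per patch).
#' @param histology `"LUAD"` or `"LUSC"`.
#' @param tau tumor-probability threshold (default 0.5).
#' @param patient_id used in the error message when nothing survives.
#' @return logical keep vector, with attribute `retention` (fraction kept).
#' @export
filter_tumor_patches <- function(probs, histology = c("LUAD", "LUSC"),
                                 tau = 0.5, patient_id = NULL) {
  histology <- match.arg(histology)
  probs <- as.matrix(probs)
  if (ncol(probs) != 3L) stop("need 3-class (normal/LUAD/LUSC) probabilities",
                              call. = FALSE)
  colnames(probs) <- c("normal", "luad", "lusc")
  target_col <- if (histology == "LUAD") 2L else 3L
  keep <- (1 - probs[, 1L]) >= tau &
    max.col(probs, ties.method = "first") == target_col
  if (!any(keep))
    stop(sprintf("all patches filtered out%s",
                 if (is.null(patient_id)) "" else paste0(" for patient ", patient_id)),
         call. = FALSE)
  attr(keep, "retention") <- mean(keep)
  keep
}

#' Aggregate patch scores into one bag score (median)
#'
#' Patch-level probabilities are pooled -- all patches across a patient's
#' slides form one bag -- and summarized by the median; for an even count
#' the mean of the two central order statistics is taken.
#'
#' @param patch_scores numeric vector of probabilities.
#' @return the median score.
#' @export
aggregate_bag <- function(patch_scores) {
  if (length(patch_scores) == 0L) stop("empty bag", call. = FALSE)
  stats::median(patch_scores)
}

#' Choose a score cutoff by the Youden index
#'
#' Candidate cutoffs are the midpoints between adjacent distinct sorted
#' scores plus -Inf/+Inf sentinels; patients with `score >= cutoff` are
#' called high. The cutoff maximizing J = sensitivity + specificity - 1 is
#' returned, ties broken toward the larger cutoff (higher specificity).
#'
#' @param scores per-patient scores.
#' @param labels logical (TRUE = high) or `"high"`/`"low"`.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "high"
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present to choose a cutoff", call. = FALSE)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (cut in cand) {
    pred <- scores >= cut
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    j <- sens + spec - 1
    if (is.null(best) || j >= best$youden_j - 1e-12) {
      if (is.null(best) || j > best$youden_j + 1e-12 || cut > best$cutoff)
        best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                     youden_j = j)
    }
  }
  best
}

# Patient-level scores from a TMBNet model over bags (no tumor filtering;
# used for validation during training and by score_patients).
score_bags <- function(model, bags) {
  rows <- lapply(bags, function(bag) {
    patches <- unlist(bag$slides, recursive = FALSE, use.names = FALSE)
    pr <- predict_patches(model, patches)
    p_high <- pr[, match("high", model$task_levels)]
    data.frame(patient_id = bag$patient_id, class = bag$class,
               score = aggregate_bag(p_high), n_patches_used = length(p_high),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Score patients with the full biomarker pipeline
#'
#' Per patient: (optionally) filter tumor patches with a 3-class tumor
#' model, run the TMB model on the survivors, take the median of the
#' high-TMB probabilities across all the patient's slides, and call the
#' class at `cutoff`. Deterministic for fixed model weights.
#'
#' @param tmbnet trained binary `advcs_model` (task levels high/low).
#' @param bags patient bags ([cohort_bags()]).
#' @param tumornet optional 3-class `advcs_model`
#'   (normal/LUAD/LUSC); `NULL` skips the tumor filter.
#' @param histology patient histology used by the filter.
#' @param tau tumor-probability threshold (default 0.5).
#' @param cutoff score cutoff for the binary call; `NA` leaves the call
#'   unset.
#' @return data.frame of PITER scores: patient_id, piter_score,
#'   n_patches_used, predicted_class, cutoff_used.
#' @export
score_patients <- function(tmbnet, bags, tumornet = NULL,
                           histology = "LUAD", tau = 0.5, cutoff = NA_real_) {
  stopifnot(inherits(tmbnet, "advcs_model"))
  rows <- lapply(bags, function(bag) {
    patches <- unlist(bag$slides, recursive = FALSE, use.names = FALSE)
    if (length(patches) == 0L)
      stop("no patches found for patient ", bag$patient_id, call. = FALSE)
    if (!is.null(tumornet)) {
      tp <- predict_patches(tumornet, patches)
      keep <- filter_tumor_patches(tp, histology = histology, tau = tau,
                                   patient_id = bag$patient_id)
      patches <- patches[keep]
    }
    pr <- predict_patches(tmbnet, patches)
    p_high <- pr[, match("high", tmbnet$task_levels)]
    sc <- aggregate_bag(p_high)
    data.frame(patient_id = bag$patient_id, piter_score = sc,
               n_patches_used = length(p_high),
               predicted_class = if (is.na(cutoff)) NA_character_
                                 else ifelse(sc >= cutoff, "high", "low"),
               cutoff_used = cutoff, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
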