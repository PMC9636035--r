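#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) score pairs correctly ordered, ties counted 1/2
#' (equivalently, Pearson's rank formulation). The returned curve steps
#' through every distinct score threshold; its trapezoidal area equals the
#' pair statistic.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (TRUE = positive) or `"high"`/`"low"`.
#' @return a `roc_curve`: list with `thresholds`, `sensitivity`, `fpr`
#'   (1 - specificity) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "high"
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute an ROC curve", call. = FALSE)
  r <- rank(scores)                       # mid-ranks handle ties at 1/2
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(labels & scores >= t) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / nneg, numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows of `data` (patients, not patches) with replacement and
#' takes nearest-rank percentiles of the replicate distribution:
#' with B sorted replicates and level 1 - a, the interval endpoints are
#' order statistics at ranks `max(1, ceiling(a/2 * B))` and
#' `ceiling((1 - a/2) * B)`. Resamples on which the statistic fails (e.g.
#' a one-class AUC resample) are redrawn and counted.
#'
#' @param data vector or data.frame; rows are the resampling unit.
#' @param statistic function mapping `data` to one number.
#' @param n_replicates number of bootstrap replicates (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed optional seed for reproducibility.
#' @return list with `point_estimate`, `lower`, `upper`, `level`,
#'   `n_replicates`, `n_redrawn`, `replicates`.
#' @export
bootstrap_ci <- function(data, statistic, n_replicates = 10000L,
                         level = 0.95, seed = NULL) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  take <- function(d, idx) if (is.data.frame(d)) d[idx, , drop = FALSE] else d[idx]
  point <- statistic(data)
  reps <- numeric(n_replicates)
  n_redrawn <- 0L
  for (b in seq_len(n_replicates)) {
    repeat {
      val <- tryCatch(statistic(take(data, sample.int(n, n, replace = TRUE))),
                      error = function(e) NA_real_)
      if (is.finite(val)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_replicates)
        stop("statistic failed on too many bootstrap resamples", call. = FALSE)
    }
    reps[b] <- val
  }
  a <- (1 - level) / 2
  sorted <- sort(reps)
  lo <- sorted[max(1L, ceiling(a * n_replicates))]
  hi <- sorted[ceiling((1 - a) * n_replicates)]
  list(point_estimate = point, lower = lo, upper = hi, level = level,
       n_replicates = n_replicates, n_redrawn = n_redrawn, replicates = reps)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance: correlation undefined", call. = FALSE)
  stats::cor(rx, ry)
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i); censored
#' subjects leave the risk set after their time; the curve is
#' right-continuous.
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return a `km_fit` data.frame: time, n_risk, n_event, n_censor, surv
#'   (one row per distinct observed time).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (length(time) == 0L) stop("empty group", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_fit", "data.frame"))
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic summed over distinct event times,
#' with the hypergeometric variance, referred to chi-square on 1 df.
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group two-level factor/character.
#' @return list with `chi2`, `p_value`, `observed`, `expected` (group 1).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required", call. = FALSE)
  if (sum(event) == 0L) stop("no events observed", call. = FALSE)
  g1 <- group == levels(group)[1L]
  ts <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       observed = O1, expected = E1)
}

#' Render a per-slide TMB probability heatmap
#'
#' Patch predictions are binned into a `ceil(H/patch_px) x ceil(W/patch_px)`
#' grid; a cell holds the mean probability of the patches whose top-left
#' corner falls in it (overlaps are averaged with a warning) and `NA`
#' where no patch landed. The PNG uses the viridis map, so warm yellow
#' marks regions predicted TMB-high; missing cells are grey.
#'
#' @param predictions data.frame with columns `x`, `y`, `p_tmb_high`.
#' @param slide_dims `c(width, height)` in pixels.
#' @param patch_px patch edge length.
#' @param out_png,out_csv optional output paths; the CSV holds
#'   (row, col, value) with 0-based indices.
#' @param cell_px PNG pixels per grid cell (default 16).
#' @return the grid matrix, invisibly when files are written.
#' @export
render_heatmap <- function(predictions, slide_dims, patch_px,
                           out_png = NULL, out_csv = NULL, cell_px = 16L) {
  stopifnot(all(c("x", "y", "p_tmb_high") %in% names(predictions)))
  W <- slide_dims[1]; H <- slide_dims[2]
  if (any(predictions$x < 0 | predictions$y < 0 |
          predictions$x >= W | predictions$y >= H))
    stop("patch coordinates outside slide bounds", call. = FALSE)
  nr <- ceiling(H / patch_px); nc <- ceiling(W / patch_px)
  grid <- matrix(NA_real_, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(predictions))) {
    r <- predictions$y[i] %/% patch_px + 1L
    c <- predictions$x[i] %/% patch_px + 1L
    if (cnt[r, c] == 0L) grid[r, c] <- 0
    grid[r, c] <- grid[r, c] + predictions$p_tmb_high[i]
    cnt[r, c] <- cnt[r, c] + 1L
  }
  if (any(cnt > 1L)) warning("overlapping patches in a grid cell; mean taken")
  grid[cnt > 0L] <- grid[cnt > 0L] / cnt[cnt > 0L]
  if (!is.null(out_csv)) {
    filled <- which(cnt > 0L, arr.ind = TRUE)
    df <- data.frame(row = filled[, 1L] - 1L, col = filled[, 2L] - 1L,
                     value = grid[filled])
    df <- df[order(df$row, df$col), , drop = FALSE]
    utils::write.csv(df, out_csv, row.names = FALSE)
  }
  if (!is.null(out_png)) {
    pal <- grDevices::hcl.colors(256L, "viridis")
    rgbfun <- grDevices::col2rgb
    img <- array(0.5, dim = c(nr * cell_px, nc * cell_px, 3L))  # grey = missing
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (cnt[r, c] > 0L) {
        col <- rgbfun(pal[1L + round(255 * clip01(grid[r, c]))]) / 255
        rows <- ((r - 1L) * cell_px + 1L):(r * cell_px)
        cols <- ((c - 1L) * cell_px + 1L):(c * cell_px)
        for (ch in 1:3) img[rows, cols, ch] <- col[ch]
      }
    }
    png::writePNG(img, target = out_png)
  }
  if (is.null(out_png) && is.null(out_csv)) grid else invisible(grid)
}

#' Evaluate the biomarker on a scored cohort
#'
#' Bundles the discrimination and association statistics for patient-level
#' scores against manifest labels: AUC with a percentile-bootstrap CI
#' (patients resampled jointly with their labels), Spearman rho against
#' the continuous TMB value, the confusion behavior at the cutoff
#' (Youden-derived from these scores when not supplied), and -- when
#' survival columns are present -- Kaplan-Meier curves by biomarker group
#' with a log-rank test.
#'
#' @param scores data.frame with `patient_id` and `piter_score` (or
#'   `score`).
#' @param manifest manifest data.frame (slide-level rows are collapsed to
#'   patients) with `tmb_class`, `tmb_value`, optional
#'   `surv_time_days`/`surv_event`.
#' @param cutoff score cutoff; `NULL` selects it by Youden index on these
#'   scores.
#' @param n_boot bootstrap replicates for the AUC CI (default 10000).
#' @param seed seed for the bootstrap.
#' @return a `piter_report` list.
#' @export
evaluate_cohort <- function(scores, manifest, cutoff = NULL,
                            n_boot = 10000L, seed = 1L) {
  score_col <- if ("piter_score" %in% names(scores)) "piter_score" else "score"
  need <- c("patient_id", "tmb_class", "tmb_value")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0L)
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pat <- manifest[!duplicated(manifest$patient_id), , drop = FALSE]
  df <- merge(scores, pat, by = "patient_id")
  y <- df$tmb_class == "high"
  roc <- roc_auc(df[[score_col]], y)
  ci <- bootstrap_ci(data.frame(s = df[[score_col]], y = y),
                     function(d) roc_auc(d$s, d$y)$auc,
                     n_replicates = n_boot, seed = seed)
  rho <- spearman_rho(df[[score_col]], df$tmb_value)
  if (is.null(cutoff)) {
    yc <- youden_cutoff(df[[score_col]], y)
    cutoff <- yc$cutoff
  }
  pred_high <- df[[score_col]] >= cutoff
  sens <- if (any(y)) sum(pred_high & y) / sum(y) else NA_real_
  spec <- if (any(!y)) sum(!pred_high & !y) / sum(!y) else NA_real_
  report <- list(n_patients = nrow(df), auc = roc$auc,
                 auc_ci_low = ci$lower, auc_ci_high = ci$upper,
                 rho = rho, cutoff = cutoff, sensitivity = sens,
                 specificity = spec, roc = roc,
                 confusion = table(predicted = ifelse(pred_high, "high", "low"),
                                   truth = ifelse(y, "high", "low")))
  if (all(c("surv_time_days", "surv_event") %in% names(df)) &&
      any(is.finite(df$surv_time_days))) {
    grp <- ifelse(pred_high, "PITER-high", "PITER-low")
    ok <- is.finite(df$surv_time_days) & is.finite(df$surv_event)
    if (length(unique(grp[ok])) == 2L && sum(df$surv_event[ok]) > 0) {
      report$km <- lapply(split(df[ok, ], grp[ok]), function(d)
        km_estimate(d$surv_time_days, d$surv_event))
      lr <- logrank_test(df$surv_time_days[ok], df$surv_event[ok], grp[ok])
      report$logrank_chi2 <- lr$chi2
      report$logrank_p <- lr$p_value
    }
  }
  class(report) <- "piter_report"
  report
}

#' Write a report as JSON plus readable text
#'
#' @param report a `piter_report`.
#' @param out_dir directory for `report.json` and `report.txt`.
#' @return path to the JSON file.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  keys <- c("n_patients", "auc", "auc_ci_low", "auc_ci_high", "rho",
            "cutoff", "sensitivity", "specificity", "logrank_chi2",
            "logrank_p")
  x <- report[intersect(keys, names(report))]
  json <- file.path(out_dir, "report.json")
  jsonlite::write_json(x, json, auto_unbox = TRUE, digits = NA)
  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  writeLines(utils::capture.output(print(report)), con)
  close(con)
  json
}
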