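#' Configuration for the synthetic H&E cohort generator
#'
#' The generator emulates the two data features the biomarker pipeline must
#' cope with: (i) a TMB-linked texture signal -- high-TMB patches carry more
#' and larger hematoxylin-like nucleus blobs on an eosin-like pink background
#' -- and (ii) a slide-level additive RGB color shift acting as a confounder,
#' whose sign can be correlated with the TMB label to a chosen degree, so
#' that train and validation splits can differ in how informative the color
#' shortcut is.
#'
#' @param n_patients number of patients (>= 2).
#' @param slides_per_patient slides per patient (>= 1).
#' @param patches_per_slide patches per slide (>= 1).
#' @param patch_px patch edge length in pixels (>= 16; 64 is the desk-scale
#'   default, 512 is supported).
#' @param signal_strength in `[0, 1]`; effect of the high-TMB label on nucleus
#'   density and radius. 0 means the two classes are indistinguishable.
#' @param confound_strength in `[0, 1]`; magnitude of the per-slide RGB shift.
#' @param confound_label_corr in `[-1, 1]`; expected correlation between the
#'   sign of a slide's color shift and the patient's TMB label. Set per split.
#' @param tmb_prevalence fraction of TMB-high patients, in (0, 1).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_patients = 40L, slides_per_patient = 1L,
                         patches_per_slide = 25L, patch_px = 64L,
                         signal_strength = 1, confound_strength = 0.5,
                         confound_label_corr = 0, tmb_prevalence = 0.5,
                         seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              slides_per_patient = as.integer(slides_per_patient),
              patches_per_slide = as.integer(patches_per_slide),
              patch_px = as.integer(patch_px),
              signal_strength = signal_strength,
              confound_strength = confound_strength,
              confound_label_corr = confound_label_corr,
              tmb_prevalence = tmb_prevalence,
              seed = as.integer(seed))
  if (cfg$n_patients < 1L || cfg$slides_per_patient < 1L ||
      cfg$patches_per_slide < 1L)
    stop("all counts must be >= 1", call. = FALSE)
  if (cfg$signal_strength < 0 || cfg$signal_strength > 1)
    stop("signal_strength must lie in [0, 1]", call. = FALSE)
  if (cfg$confound_strength < 0 || cfg$confound_strength > 1)
    stop("confound_strength must lie in [0, 1]", call. = FALSE)
  if (abs(cfg$confound_label_corr) > 1)
    stop("confound_label_corr must lie in [-1, 1]", call. = FALSE)
  if (cfg$tmb_prevalence <= 0 || cfg$tmb_prevalence >= 1)
    stop("tmb_prevalence must lie in (0, 1)", call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

# Fixed appearance constants of the texture model (at the 64 px reference
# scale): pink eosin background, blue-purple nuclei, Gaussian-profile
# ellipses. Blob counts are Poisson so that an independent connected-
# component count gives an oracle for "signal present". The high-TMB
# signal is ink-neutral: nucleus count and radius increase while the
# per-nucleus stain contrast decreases by the same total-ink factor, so
# the expected mean color of a patch is class-independent and the signal
# lives in the granularity of the texture, not in any channel mean. This
# keeps the morphological signal orthogonal to the additive slide-level
# color confound.
.synth_pars <- list(
  bg = c(233, 208, 223), bg_sd = 5,
  nucleus = c(95, 72, 150), nucleus_sd = 10,
  base_rate = 9, rate_gain = 0.35,     # high-label rate = base*(1 + gain*signal)
  base_radius = 2.6, radius_gain = 0.15,
  shift_dir = c(35, -14, -35), shift_jitter = 8
)

#' Generate one synthetic H&E-like patch
#'
#' Renders eosin-pink background noise plus hematoxylin-like nucleus blobs
#' (Gaussian-profile ellipses), then applies an additive per-slide RGB
#' confound shift and clips to 0..255. Nucleus count and radius increase
#' with `signal_strength` for high-TMB labels only. Draws come from the
#' current R RNG state, so a fixed state reproduces the patch exactly.
#'
#' @param label `"high"` or `"low"` TMB class (or 1/0).
#' @param confound_shift numeric length-3 additive RGB offset.
#' @param config a [synth_config()].
#' @return 8-bit RGB array (`patch_px` x `patch_px` x 3), values 0..255.
#' @export
generate_patch_image <- function(label, confound_shift = c(0, 0, 0),
                                 config = synth_config()) {
  px <- config$patch_px
  if (px < 16L) stop("patch_px < 16: nucleus blobs are unrenderable", call. = FALSE)
  hi <- label %in% c("high", 1, TRUE)
  p <- .synth_pars
  scale2 <- (px / 64)^2
  img <- array(0, dim = c(px, px, 3L))
  for (ch in 1:3)
    img[, , ch] <- p$bg[ch] + matrix(stats::rnorm(px * px, 0, p$bg_sd), px, px)

  s_hi <- config$signal_strength * as.numeric(hi)
  rate_f <- 1 + p$rate_gain * s_hi
  radius_f <- 1 + p$radius_gain * s_hi
  rate <- p$base_rate * scale2 * rate_f
  n_nuc <- stats::rpois(1L, rate)
  radius_mu <- p$base_radius * (px / 64) * radius_f
  # ink compensation: fainter nuclei when there are more / larger ones
  contrast <- 1 / (rate_f * radius_f^2)
  if (n_nuc > 0L) {
    for (i in seq_len(n_nuc)) {
      cx <- stats::runif(1L, 1, px)
      cy <- stats::runif(1L, 1, px)
      r <- pmax(1, stats::rnorm(1L, radius_mu, 0.35 * radius_mu))
      ecc <- stats::runif(1L, 0.75, 1.3)
      th <- stats::runif(1L, 0, pi)
      col <- p$bg - contrast * (p$bg - p$nucleus) +
        stats::rnorm(3L, 0, p$nucleus_sd)
      ext <- ceiling(3 * r * max(ecc, 1 / ecc))
      xs <- max(1L, floor(cx - ext)):min(px, ceiling(cx + ext))
      ys <- max(1L, floor(cy - ext)):min(px, ceiling(cy + ext))
      dx <- outer(rep(1, length(ys)), xs - cx)
      dy <- outer(ys - cy, rep(1, length(xs)))
      u <- (cos(th) * dx + sin(th) * dy) / (r * ecc)
      v <- (-sin(th) * dx + cos(th) * dy) / (r / ecc)
      w <- exp(-0.5 * (u^2 + v^2))
      w[w < 0.02] <- 0
      for (ch in 1:3)
        img[ys, xs, ch] <- (1 - w) * img[ys, xs, ch] + w * col[ch]
    }
  }
  for (ch in 1:3) img[, , ch] <- img[, , ch] + confound_shift[ch]
  round(clip255(img))
}

#' Generate a synthetic cohort
#'
#' Assigns each patient a latent TMB class with probability
#' `tmb_prevalence`, a TMB value consistent with the class (exome mutation
#' counts around the 206 cutoff), exponential survival tied to the class,
#' and each slide an additive RGB shift whose sign correlates with the
#' class at `confound_label_corr` in expectation. All of the patient's
#' patches inherit the patient-level label.
#'
#' @param config a [synth_config()].
#' @param split split tag written to the manifest (`"train"`, `"val"`,
#'   `"test"`).
#' @param cohort_name cohort tag written to the manifest.
#' @param survival if `TRUE` (default) simulate survival columns.
#' @return a `synth_cohort`: list with `manifest` (one row per slide),
#'   `patch_index` (one row per patch), `patches` (named list of 8-bit RGB
#'   arrays), `truth` (latent labels and slide shifts) and `config`.
#' @export
generate_cohort <- function(config = synth_config(), split = "train",
                            cohort_name = "synthetic", survival = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_patients < 2L) stop("n_patients must be >= 2", call. = FALSE)
  split <- match.arg(split, c("train", "val", "test"))
  set.seed(config$seed)
  p <- .synth_pars

  pid <- sprintf("%s_P%03d", split, seq_len(config$n_patients))
  # stratified label assignment: exact class proportions (fractional
  # remainder randomized), positions shuffled
  n_high <- floor(config$n_patients * config$tmb_prevalence)
  if (stats::runif(1L) < config$n_patients * config$tmb_prevalence - n_high)
    n_high <- n_high + 1L
  lab <- sample(rep(c(1L, 0L), c(n_high, config$n_patients - n_high)))
  tmb_value <- ifelse(lab == 1L,
                      round(stats::runif(config$n_patients, 206, 1000)),
                      round(stats::runif(config$n_patients, 20, 205)))
  if (survival) {
    # high TMB -> better outcome under checkpoint inhibition
    t_raw <- stats::rexp(config$n_patients, rate = ifelse(lab == 1L, 1 / 600, 1 / 250))
    surv_event <- as.integer(t_raw <= 1095)
    surv_time <- pmin(ceiling(t_raw), 1095)
  } else {
    surv_time <- rep(NA_real_, config$n_patients)
    surv_event <- rep(NA_integer_, config$n_patients)
  }

  r <- config$confound_label_corr
  # stratified confound signs: within each label group the fraction of
  # +1 slides is (1 +/- r)/2 exactly (fractional remainder randomized),
  # so the realized sign-label correlation matches the nominal value
  slide_lab <- rep(lab, each = config$slides_per_patient)
  sgn_all <- integer(length(slide_lab))
  for (lv in c(1L, 0L)) {
    idx <- which(slide_lab == lv)
    p_plus <- if (lv == 1L) (1 + r) / 2 else (1 - r) / 2
    n_plus <- floor(length(idx) * p_plus)
    if (stats::runif(1L) < length(idx) * p_plus - n_plus) n_plus <- n_plus + 1L
    sgn_all[sample(idx)] <- rep(c(1L, -1L),
                                c(n_plus, length(idx) - n_plus))
  }
  manifest <- NULL; patch_rows <- NULL
  patches <- list()
  slide_truth <- NULL
  ncol_grid <- ceiling(sqrt(config$patches_per_slide))
  slide_counter <- 0L
  for (i in seq_len(config$n_patients)) {
    for (j in seq_len(config$slides_per_patient)) {
      sid <- sprintf("%s_S%d", pid[i], j)
      slide_counter <- slide_counter + 1L
      sgn <- sgn_all[slide_counter]
      shift <- config$confound_strength *
        (sgn * p$shift_dir + stats::runif(3L, -p$shift_jitter, p$shift_jitter))
      slide_truth <- rbind(slide_truth, data.frame(
        slide_id = sid, shift_sign = sgn,
        shift_r = shift[1], shift_g = shift[2], shift_b = shift[3],
        stringsAsFactors = FALSE))
      manifest <- rbind(manifest, data.frame(
        patient_id = pid[i], slide_id = sid, cohort = cohort_name,
        split = split, tmb_value = tmb_value[i],
        tmb_class = ifelse(lab[i] == 1L, "high", "low"),
        surv_time_days = surv_time[i], surv_event = surv_event[i],
        stringsAsFactors = FALSE))
      for (k in seq_len(config$patches_per_slide)) {
        x <- ((k - 1L) %% ncol_grid) * config$patch_px
        y <- ((k - 1L) %/% ncol_grid) * config$patch_px
        key <- sprintf("%s_%d_%d", sid, x, y)
        patches[[key]] <- generate_patch_image(
          if (lab[i] == 1L) "high" else "low", shift, config)
        patch_rows <- rbind(patch_rows, data.frame(
          slide_id = sid, patient_id = pid[i], x = x, y = y,
          file = paste0(key, ".png"), stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(manifest = manifest, patch_index = patch_rows,
                 patches = patches,
                 truth = list(patients = data.frame(patient_id = pid,
                                                    label = lab,
                                                    stringsAsFactors = FALSE),
                              slides = slide_truth),
                 config = config, split = split),
            class = "synth_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Lays out `manifest.csv`, `patches.csv` and `patches/<slide_id>_<x>_<y>.png`
#' (8-bit RGB). Latent truth tables are written as
#' `truth_patients.csv` / `truth_slides.csv` (synthetic ground truth, not
#' part of the standard manifest contract).
#'
#' @param cohort a `synth_cohort`.
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return path of the written manifest CSV, invisibly usable.
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (length(cohort$patches) == 0L) stop("cohort has no patches", call. = FALSE)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite)
    stop("out_dir exists and is non-empty; use overwrite = TRUE", call. = FALSE)
  dir.create(file.path(out_dir, "patches"), recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(cohort$manifest, manifest_path, row.names = FALSE)
  utils::write.csv(cohort$patch_index, file.path(out_dir, "patches.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$patients, file.path(out_dir, "truth_patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$slides, file.path(out_dir, "truth_slides.csv"),
                   row.names = FALSE)
  for (key in names(cohort$patches))
    write_png255(cohort$patches[[key]],
                 file.path(out_dir, "patches", paste0(key, ".png")))
  manifest_path
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `manifest.csv` and `patches/`.
#' @return a `synth_cohort` (truth tables included when present).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  patch_index <- utils::read.csv(file.path(dir, "patches.csv"),
                                 stringsAsFactors = FALSE)
  patches <- list()
  for (i in seq_len(nrow(patch_index))) {
    key <- sub("\\.png$", "", patch_index$file[i])
    patches[[key]] <- read_png255(file.path(dir, "patches", patch_index$file[i]))
  }
  truth <- NULL
  tp <- file.path(dir, "truth_patients.csv")
  if (file.exists(tp))
    truth <- list(patients = utils::read.csv(tp, stringsAsFactors = FALSE),
                  slides = utils::read.csv(file.path(dir, "truth_slides.csv"),
                                           stringsAsFactors = FALSE))
  structure(list(manifest = manifest, patch_index = patch_index,
                 patches = patches, truth = truth, config = NULL,
                 split = unique(manifest$split)),
            class = "synth_cohort")
}

#' Group a cohort's patches into patient-level bags
#'
#' A bag holds all of one patient's patches, keyed by slide, with the
#' patient-level TMB class attached -- the multiple-instance unit the
#' classifier trains on and the aggregator scores.
#'
#' @param cohort a `synth_cohort`.
#' @return named list of bags: `list(patient_id, class, slides = list(...))`.
#' @export
cohort_bags <- function(cohort) {
  stopifnot(inherits(cohort, "synth_cohort"))
  bags <- list()
  for (pidv in unique(cohort$manifest$patient_id)) {
    rows <- cohort$manifest[cohort$manifest$patient_id == pidv, , drop = FALSE]
    slides <- list()
    for (sid in rows$slide_id) {
      idx <- cohort$patch_index[cohort$patch_index$slide_id == sid, , drop = FALSE]
      keys <- sub("\\.png$", "", idx$file)
      slides[[sid]] <- cohort$patches[keys]
    }
    bags[[pidv]] <- list(patient_id = pidv, class = rows$tmb_class[1],
                         slides = slides)
  }
  bags
}
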