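# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Count nucleus blobs by connected components on the green channel (the
# channel with the strongest hematoxylin contrast). EBImage::bwlabel is
# the independent labeling engine.
count_blobs <- function(img, threshold = 175) {
  bw <- img[, , 2] < threshold
  max(EBImage::bwlabel(EBImage::Image(bw)))
}

# AUC by explicit enumeration of (positive, negative) pairs, ties at 1/2.
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden search over midpoint candidates plus sentinels.
youden_oracle <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best_j <- -Inf
  for (cut in cand) {
    pred <- scores >= cut
    j <- sum(pred & labels) / sum(labels) +
      sum(!pred & !labels) / sum(!labels) - 1
    if (j > best_j) best_j <- j
  }
  best_j
}

# Spearman by explicit mid-rank computation and moment formula.
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# A flat-color RGB array.
flat_rgb <- function(h, w, col) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- col[ch]
  img
}

# Beer-Lambert synthesis of an H&E-like image from a known stain matrix.
beer_lambert_image <- function(M, n_side = 60, seed = 1) {
  set.seed(seed)
  n <- n_side^2
  conc <- cbind(rexp(n, 2), rexp(n, 2))
  od <- conc %*% t(M)
  img <- array(round(pmin(pmax(255 * exp(-od), 0), 255)),
               dim = c(n_side, n_side, 3))
  img
}

random_stain_matrix <- function() {
  repeat {
    M <- matrix(abs(rnorm(6)), 3, 2)
    M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    ang <- acos(min(1, sum(M[, 1] * M[, 2])))
    if (ang > 25 * pi / 180) return(M)
  }
}

angle_deg <- function(u, v) {
  acos(pmin(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

# Tiny cohorts / bags for training tests.
tiny_bags <- function(n_patients = 6, patches = 8, signal = 1, conf = 0,
                      corr = 0, seed = 1, px = 64) {
  co <- generate_cohort(synth_config(n_patients, 1, patches, patch_px = px,
                                     signal_strength = signal,
                                     confound_strength = conf,
                                     confound_label_corr = corr, seed = seed))
  cohort_bags(co)
}
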