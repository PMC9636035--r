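# Macenko optical-density stain estimation and normalization.
#
# Under Beer-Lambert, a pixel's optical density OD = -log(I / 255) is (to a
# good approximation) a nonnegative combination of two stain OD vectors
# (hematoxylin, eosin). The stain basis of an image is estimated from the
# extreme directions of the OD point cloud in its principal plane; patches
# are then normalized by deconvolving against their source basis, rescaling
# concentrations, and recomposing with a target basis.

rgb_to_od <- function(img) {
  -log(pmax(img, 1) / 255)
}

od_to_rgb <- function(od) {
  round(clip255(255 * exp(-od)))
}

#' Construct a stain reference
#'
#' @param stain_matrix 3x2 matrix of OD stain vectors, columns
#'   (hematoxylin, eosin); columns are normalized to unit length and must
#'   be nonnegative.
#' @param max_concentrations length-2 positive reference concentrations
#'   (robust maxima).
#' @return a `stain_reference`.
#' @export
stain_reference <- function(stain_matrix, max_concentrations = c(1, 1)) {
  stain_matrix <- as.matrix(stain_matrix)
  stopifnot(all(dim(stain_matrix) == c(3L, 2L)))
  if (any(stain_matrix < -1e-8))
    stop("stain matrix entries must be nonnegative", call. = FALSE)
  stain_matrix[stain_matrix < 0] <- 0
  stain_matrix <- sweep(stain_matrix, 2L, sqrt(colSums(stain_matrix^2)), "/")
  if (any(max_concentrations <= 0))
    stop("max_concentrations must be positive", call. = FALSE)
  structure(list(stain_matrix = stain_matrix,
                 max_concentrations = as.numeric(max_concentrations)),
            class = "stain_reference")
}

#' Estimate an image's stain basis (Macenko construction)
#'
#' Pixels whose OD vector norm exceeds `od_threshold` are projected onto
#' the top-2 principal plane of the OD cloud; the stain vectors are the
#' directions at the `percentile` and `1 - percentile` quantiles of the
#' projection angle. The hematoxylin column is, by convention, the one
#' with the larger blue OD component.
#'
#' @param image RGB array (0..255) or `piter_patch`.
#' @param od_threshold minimum OD norm for a pixel to count as stained
#'   (default 0.15).
#' @param percentile angular quantile for the extreme directions
#'   (default 0.01).
#' @return a [stain_reference()].
#' @export
fit_stain_reference <- function(image, od_threshold = 0.15,
                                percentile = 0.01) {
  if (inherits(image, "piter_patch")) image <- image$pixels
  stopifnot_rgb(image, "image")
  od <- cbind(as.vector(rgb_to_od(image[, , 1])),
              as.vector(rgb_to_od(image[, , 2])),
              as.vector(rgb_to_od(image[, , 3])))
  keep <- sqrt(rowSums(od^2)) > od_threshold
  if (sum(keep) < 100L)
    stop("insufficient stained tissue (fewer than 100 pixels above od_threshold)",
         call. = FALSE)
  od <- od[keep, , drop = FALSE]
  ev <- eigen(stats::cov(od), symmetric = TRUE)
  basis <- ev$vectors[, 1:2, drop = FALSE]
  # orient the plane basis so projections are mostly positive
  for (j in 1:2) if (mean(od %*% basis[, j]) < 0) basis[, j] <- -basis[, j]
  proj <- od %*% basis
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(percentile, 1 - percentile), names = FALSE)
  vecs <- sapply(qs, function(a) basis %*% c(cos(a), sin(a)))
  vecs[vecs < 0] <- 0
  vecs <- sweep(vecs, 2L, sqrt(colSums(vecs^2)), "/")
  # hematoxylin = more blue-heavy OD vector
  if (vecs[3, 1] < vecs[3, 2]) vecs <- vecs[, 2:1, drop = FALSE]
  conc <- t(solve(crossprod(vecs), crossprod(vecs, t(od))))
  maxc <- pmax(apply(conc, 2L, stats::quantile, probs = 0.99), 1e-6)
  stain_reference(vecs, maxc)
}

#' Normalize a patch's stain appearance to a target basis
#'
#' The patch is deconvolved against `source_ref` (least-squares
#' concentrations), concentrations are rescaled by the ratio of the
#' references' robust maxima, and the patch is recomposed with
#' `target_ref`'s stain matrix. Near-white background maps to near-white
#' because its concentrations are close to zero.
#'
#' @param patch `piter_patch` or RGB array (0..255).
#' @param source_ref stain basis of the patch's own slide.
#' @param target_ref stain basis to map to.
#' @return same type as `patch`, 8-bit RGB.
#' @export
stain_normalize <- function(patch, source_ref, target_ref) {
  stopifnot(inherits(source_ref, "stain_reference"),
            inherits(target_ref, "stain_reference"))
  img <- if (inherits(patch, "piter_patch")) patch$pixels else patch
  stopifnot_rgb(img, "patch")
  M <- source_ref$stain_matrix
  G <- crossprod(M)
  if (abs(det(G)) < 1e-8)
    stop("singular stain deconvolution: source stain vectors are collinear",
         call. = FALSE)
  d <- dim(img)
  od <- cbind(as.vector(rgb_to_od(img[, , 1])),
              as.vector(rgb_to_od(img[, , 2])),
              as.vector(rgb_to_od(img[, , 3])))
  conc <- od %*% M %*% solve(G)                       # n x 2 least squares
  conc <- sweep(conc, 2L,
                target_ref$max_concentrations / source_ref$max_concentrations,
                "*")
  od2 <- conc %*% t(target_ref$stain_matrix)
  out <- array(od_to_rgb(od2), dim = d)
  if (inherits(patch, "piter_patch")) {
    patch$pixels <- out
    patch
  } else out
}
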