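#' @keywords internal
"_PACKAGE"

# Internal numeric / image helpers shared across modules.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-wise softmax computed stably from logits
#' @noRd
softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Log-softmax rows (stable)
#' @noRd
log_softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  z <- logits - m
  z - log(rowSums(exp(z)))
}

stopifnot_rgb <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop(sprintf("%s must be an RGB array (height x width x 3)", what),
         call. = FALSE)
  }
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Integral-image box sum with edge clamping
#'
#' Mean filter over a (2r+1)^2 window, window truncated at the borders.
#' @noRd
box_blur <- function(mat, radius = 1L) {
  if (radius <= 0L) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  cs <- apply(mat, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  cs <- rbind(0, cbind(0, cs))          # (h+1) x (w+1), cs[i+1,j+1] = sum mat[1:i,1:j]
  r1 <- pmax(seq_len(h) - radius, 1L); r2 <- pmin(seq_len(h) + radius, h)
  c1 <- pmax(seq_len(w) - radius, 1L); c2 <- pmin(seq_len(w) + radius, w)
  # window sums via four corners of the integral image
  S <- cs[r2 + 1L, c2 + 1L, drop = FALSE] - cs[r1, c2 + 1L, drop = FALSE] -
       cs[r2 + 1L, c1, drop = FALSE] + cs[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  S / cnt
}

#' Downsample a 2-D matrix by an integer factor using block (area) averaging
#' @noRd
block_mean <- function(mat, f) {
  h <- nrow(mat); w <- ncol(mat)
  stopifnot(h %% f == 0L, w %% f == 0L)
  hh <- h %/% f; ww <- w %/% f
  a <- array(mat, dim = c(f, hh, f, ww))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2L)
}

#' Bilinear resample of a 2-D matrix to target dims
#' @noRd
bilinear_resize <- function(mat, hh, ww) {
  h <- nrow(mat); w <- ncol(mat)
  # sample at pixel centers
  ys <- (seq_len(hh) - 0.5) * h / hh + 0.5
  xs <- (seq_len(ww) - 0.5) * w / ww + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xs), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(ys - y0, 0), 1);  fx <- pmin(pmax(xs - x0, 0), 1)
  top <- mat[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
         mat[y0, x1, drop = FALSE] * outer(1 - fy, fx)
  bot <- mat[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
         mat[y1, x1, drop = FALSE] * outer(fy, fx)
  top + bot
}

#' Resize an 8-bit RGB array; integer shrink factors use area averaging
#' @noRd
resize_rgb <- function(img, hh, ww) {
  d <- dim(img)
  if (d[1] == hh && d[2] == ww) return(img)
  out <- array(0, dim = c(hh, ww, 3L))
  f <- d[1] / hh
  if (d[1] %% hh == 0L && d[2] %% ww == 0L && d[2] / ww == f) {
    for (ch in 1:3) out[, , ch] <- block_mean(img[, , ch], as.integer(f))
  } else {
    for (ch in 1:3) out[, , ch] <- bilinear_resize(img[, , ch], hh, ww)
  }
  out
}

#' Read / write 8-bit RGB PNG as 0..255 arrays
#' @noRd
read_png255 <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

write_png255 <- function(img, path) {
  png::writePNG(clip01(img / 255), target = path)
  invisible(path)
}

# Named RNG streams (stored in an environment) so that sampling, augmentation
# and initialization draws do not perturb one another; all streams are derived
# from one seed.
make_rng_streams <- function(seed, names) {
  streams <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  for (i in seq_along(names)) {
    set.seed(seed + i - 1L)
    assign(names[i], get(".Random.seed", globalenv()), envir = streams)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  streams
}

with_stream <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
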