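#' Render a trajectory set into a synthetic grayscale image stack
#'
#' Each frame is a constant background plus one isotropic Gaussian blob per
#' marker centered at its continuous (subpixel) position, optionally with
#' Poisson shot noise or additive Gaussian read noise. Pixel centers sit at
#' integer coordinates; `x` runs along columns (rightward), `y` along rows
#' (downward), origin at the top-left pixel `(1, 1)`.
#'
#' @param ts Trajectory tibble (`marker_id`, `frame`, `x_px`, `y_px`).
#' @param shape Frame shape `c(height, width)` in px.
#' @param spot_sigma Gaussian blob sigma, px.
#' @param spot_amplitude Peak blob intensity above background.
#' @param background Constant background level.
#' @param noise `"none"`, `"poisson"` (intensities used as photon counts) or
#'   `"gaussian"`.
#' @param noise_sd Read-noise standard deviation for `noise = "gaussian"`.
#' @param seed Optional integer seed for the noise draw.
#'
#' @return A `height x width x n_frames` numeric array, intensities clipped
#'   to `[0, 65535]`; sampling rate is carried over in `attr(, "fs")`.
#' @export
render_frames <- function(ts, shape = c(280, 320), spot_sigma = 3,
                          spot_amplitude = 2000, background = 200,
                          noise = c("none", "poisson", "gaussian"),
                          noise_sd = 10, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  h <- shape[1]; w <- shape[2]
  margin <- 3 * spot_sigma
  bad <- ts$x_px < 1 + margin | ts$x_px > w - margin |
    ts$y_px < 1 + margin | ts$y_px > h - margin
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "trajectory leaves the renderable area (marker %d, frame %d): keep markers >= 3*spot_sigma from the borders",
      ts$marker_id[i], ts$frame[i]))
  }
  n <- max(ts$frame)
  stack <- array(0, dim = c(h, w, n))
  half <- ceiling(4 * spot_sigma)
  xs <- split(ts$x_px, ts$frame)
  ys <- split(ts$y_px, ts$frame)
  for (f in seq_len(n)) {
    fr <- matrix(background, h, w)
    xf <- xs[[f]]; yf <- ys[[f]]
    for (m in seq_along(xf)) {
      cx <- xf[m]; cy <- yf[m]
      ix <- max(1, floor(cx) - half):min(w, floor(cx) + half + 1)
      iy <- max(1, floor(cy) - half):min(h, floor(cy) + half + 1)
      gx <- exp(-(ix - cx)^2 / (2 * spot_sigma^2))
      gy <- exp(-(iy - cy)^2 / (2 * spot_sigma^2))
      fr[iy, ix] <- fr[iy, ix] + spot_amplitude * outer(gy, gx)
    }
    if (noise == "poisson") {
      fr <- matrix(rpois(h * w, pmax(fr, 0)), h, w)
    } else if (noise == "gaussian") {
      fr <- fr + matrix(rnorm(h * w, 0, noise_sd), h, w)
    }
    fr[fr < 0] <- 0
    fr[fr > 65535] <- 65535
    stack[, , f] <- fr
  }
  attr(stack, "fs") <- attr(ts, "fs") %||% NULL
  stack
}

#' Write / read an image stack as multi-page 16-bit grayscale TIFF
#'
#' @param stack `height x width x n_frames` array with intensities in
#'   `[0, 65535]`.
#' @param path Output file path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   the array on the original `[0, 65535]` scale.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * 65535
  arr
}
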