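#' Synthetic fluorescent-cell image with ground truth
#'
#' Renders non-overlapping elliptical "cells" with a smooth interior
#' intensity profile on a noisy background, on the 0-256 arbitrary-unit
#' scale used for the quantification. The ground truth records each cell's
#' rendered mean intensity — the quantity the measurement pipeline should
#' recover.
#'
#' @param n_cells Number of cells (20 per condition in the modelled design).
#' @param intensity_mean,intensity_sd Mean and SD of the per-cell base
#'   intensity (arbitrary units).
#' @param radius_range Semi-axis range, px.
#' @param shape Image shape `c(height, width)`.
#' @param background_mean,background_sd Background level and Gaussian noise.
#' @param min_sep Minimum boundary separation between cells, px.
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts per cell before giving up.
#' @return List: `image` (matrix), `labels` (integer matrix, 0 background),
#'   `cells` (tibble `cell_id`, `true_mean`, `area_px`).
#' @export
synth_fluor_image <- function(n_cells = 20, intensity_mean = 120,
                              intensity_sd = 18, radius_range = c(8, 14),
                              shape = c(320, 320), background_mean = 15,
                              background_sd = 3, min_sep = 4, seed = NULL,
                              max_tries = 2000) {
  if (!is.null(seed)) set.seed(seed)
  h <- shape[1]; w <- shape[2]
  img <- matrix(rnorm(h * w, background_mean, background_sd), h, w)
  labels <- matrix(0L, h, w)
  placed <- matrix(numeric(0), ncol = 3) # cx, cy, rmax
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells %||% 0)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      a <- runif(1, radius_range[1], radius_range[2])
      b <- runif(1, radius_range[1], radius_range[2])
      rmax <- max(a, b)
      cx <- runif(1, rmax + 2, w - rmax - 2)
      cy <- runif(1, rmax + 2, h - rmax - 2)
      if (nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
        if (any(dd < placed[, 3] + rmax + min_sep)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) abort(sprintf("could not place cell %d without overlap after %d tries",
                           i, max_tries))
    placed <- rbind(placed, c(cx, cy, rmax))
    theta <- runif(1, 0, pi)
    base <- max(rnorm(1, intensity_mean, intensity_sd), background_mean + 20)
    ix <- max(1, floor(cx - rmax)):min(w, ceiling(cx + rmax))
    iy <- max(1, floor(cy - rmax)):min(h, ceiling(cy + rmax))
    XX <- outer(rep(1, length(iy)), ix - cx)
    YY <- outer(iy - cy, rep(1, length(ix)))
    xr <- XX * cos(theta) + YY * sin(theta)
    yr <- -XX * sin(theta) + YY * cos(theta)
    rr2 <- (xr / a)^2 + (yr / b)^2
    inside <- rr2 <= 1
    # smooth dome profile, brightest at the center
    val <- base * (1 - 0.3 * rr2)
    sub_img <- img[iy, ix]
    sub_lab <- labels[iy, ix]
    sub_img[inside] <- val[inside]
    sub_lab[inside] <- i
    img[iy, ix] <- sub_img
    labels[iy, ix] <- sub_lab
    cells[[i]] <- tibble(cell_id = i, true_mean = mean(val[inside]),
                         area_px = sum(inside))
  }
  img <- pmin(pmax(img, 0), 256)
  list(image = img, labels = labels,
       cells = if (n_cells > 0) dplyr::bind_rows(cells) else
         tibble(cell_id = integer(0), true_mean = numeric(0), area_px = integer(0)))
}

#' Segment fluorescent cells by global thresholding
#'
#' Otsu global threshold (default) or a percentile threshold, followed by
#' connected-component labelling and an area filter. Deterministic.
#'
#' @param image Intensity matrix on the 0-256 scale.
#' @param method `"otsu"` or `"percentile"`.
#' @param min_area Minimum component area, px.
#' @param percentile Threshold percentile for `method = "percentile"`.
#' @return Integer label matrix (0 = background), relabelled consecutively.
#' @export
segment_cells <- function(image, method = c("otsu", "percentile"),
                          min_area = 30, percentile = 0.95) {
  method <- match.arg(method)
  if (diff(range(image)) == 0) return(matrix(0L, nrow(image), ncol(image)))
  norm <- image / 256
  thr <- if (method == "otsu") EBImage::otsu(norm, range = c(0, 1))
  else quantile(norm, percentile, names = FALSE)
  mask <- norm > thr
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= min_area)
    if (length(keep) == 0)
      warn(sprintf("no component reaches min_area = %d", min_area))
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

#' Per-cell fluorescence measurements
#'
#' Mean intensity over each labelled region, the ImageJ-style per-cell
#' readout.
#'
#' @param image Intensity matrix.
#' @param labels Label matrix from [segment_cells()] (or a ground-truth
#'   mask).
#' @return Tibble with `cell_id`, `mean_intensity`, `area_px`.
#' @export
quantify_cells <- function(image, labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(tibble(cell_id = integer(0), mean_intensity = numeric(0),
                  area_px = integer(0)))
  means <- tapply(image[labels > 0], labels[labels > 0], mean)
  areas <- tapply(labels[labels > 0], labels[labels > 0], length)
  tibble(cell_id = as.integer(names(means)),
         mean_intensity = as.numeric(means),
         area_px = as.integer(areas))
}

#' Fold change of per-cell fluorescence against control
#'
#' Each condition measurement is divided by the control mean; the summary is
#' the mean fold with a t-based 95% confidence interval. The per-cell folds
#' feed the four-arm ANOVA/LSD comparison.
#'
#' @param values Numeric vector of per-cell intensities for one condition.
#' @param control Numeric vector of control per-cell intensities.
#' @param condition Condition label carried into the output.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `condition`, `n`, `mean_fold`, `ci_half`; the
#'   per-cell folds are in `attr(, "folds")`.
#' @export
fold_change <- function(values, control, condition = NA_character_,
                        conf_level = 0.95) {
  if (length(values) < 2 || length(control) < 2)
    abort("need at least 2 cells per group")
  m0 <- mean(control)
  if (!is.finite(m0) || m0 == 0) abort("degenerate normalization: control mean is zero")
  folds <- values / m0
  n <- length(folds)
  half <- qt(1 - (1 - conf_level) / 2, n - 1) * sd(folds) / sqrt(n)
  out <- tibble(condition = condition, n = n, mean_fold = mean(folds),
                ci_half = half)
  attr(out, "folds") <- folds
  out
}
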