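#' Read an RGB image
#'
#' Reads a PNG (or TIFF, when the tiff package is installed) into an
#' H x W x 3 array with values in \[0, 1\]. Grayscale images are replicated
#' across channels; an alpha channel is dropped.
#'
#' @param path image path.
#' @return H x W x 3 numeric array.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read TIFF images")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

# grayscale as the channel mean
.gray <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

# separable Gaussian blur with replicate-edge padding, FFT convolution per
# dimension; sigma in pixels
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- min(ceiling(3 * sigma), max(dim(m)) - 1L)
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  blur1d <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    out <- stats::filter(vp, g, sides = 2)
    as.numeric(out[(r + 1):(r + n)])
  }
  m2 <- apply(m, 2, blur1d)
  t(apply(m2, 1, blur1d))
}

#' Inpaint electrode pixels in a phase-contrast image
#'
#' Electrode disks appear as (near-)black regions. Pixels with grayscale
#' value 0 or below mean - 1 SD form a mask, dilated by 2 px; masked pixels
#' are then replaced per channel by iterative neighborhood averaging with
#' the unmasked boundary held fixed, until convergence (a harmonic fill, so
#' filled values stay within the range of the boundary values).
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param tol convergence tolerance (max per-iteration change; 1/512
#'   corresponds to under one 8-bit grayscale unit).
#' @param max_iter iteration cap.
#' @return List with `image` (inpainted array) and `mask` (logical matrix of
#'   replaced pixels).
#' @export
inpaint_electrodes <- function(img, tol = 1 / 512, max_iter = 2000) {
  g <- .gray(img)
  mask <- g == 0 | g < mean(g) - stats::sd(g)
  if (any(mask)) {
    mask <- EBImage::dilate(mask * 1, EBImage::makeBrush(5, "box")) > 0
  }
  if (all(mask)) stop("all pixels masked: nothing to inpaint from")
  if (!any(mask)) return(list(image = img, mask = mask))
  out <- img
  H <- nrow(g); W <- ncol(g)
  shift <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(H) + dr, 1L), H)
    c <- pmin(pmax(seq_len(W) + dc, 1L), W)
    m[r, c, drop = FALSE]
  }
  for (ch in 1:3) {
    x <- img[, , ch]
    x[mask] <- mean(x[!mask])
    for (it in seq_len(max_iter)) {
      avg <- (shift(x, 1, 0) + shift(x, -1, 0) +
              shift(x, 0, 1) + shift(x, 0, -1)) / 4
      delta <- max(abs(avg[mask] - x[mask]))
      x[mask] <- avg[mask]
      if (delta < tol) break
    }
    out[, , ch] <- x
  }
  list(image = out, mask = mask)
}

#' Hue map: band-passed red/blue ratio
#'
#' Cell clusters absorb light with a red (brownish) shift, so the per-pixel
#' red/blue ratio marks aggregated cells. The ratio image is band-pass
#' filtered with a difference of Gaussians — the small scale rejects
#' single-cell speckle, the large scale rejects illumination gradients — so
#' clusters stand out as positive blobs on a near-zero background.
#'
#' @param img inpainted H x W x 3 array in \[0, 1\].
#' @param scale_um_per_px pixel scale (um/px); required, never guessed.
#' @param sigma_low,sigma_high band-pass scales (um).
#' @param invert if `TRUE` compute blue/red instead of red/blue.
#' @return Object of class `hue_map`: list with `values` (matrix),
#'   `scale_um_per_px`, `sigma_low`, `sigma_high`.
#' @export
hue_map <- function(img, scale_um_per_px, sigma_low = 15, sigma_high = 300,
                    invert = FALSE) {
  if (missing(scale_um_per_px) || !is.numeric(scale_um_per_px) ||
      scale_um_per_px <= 0)
    stop("scale_um_per_px is required (um per pixel)")
  floor_v <- 1 / 255          # one 8-bit grayscale unit
  num <- img[, , if (invert) 3 else 1]
  den <- pmax(img[, , if (invert) 1 else 3], floor_v)
  ratio <- num / den
  lo_px <- sigma_low / scale_um_per_px
  hi_px <- sigma_high / scale_um_per_px
  bp <- .gauss_blur(ratio, lo_px) - .gauss_blur(ratio, hi_px)
  structure(list(values = bp, scale_um_per_px = scale_um_per_px,
                 sigma_low = sigma_low, sigma_high = sigma_high),
            class = "hue_map")
}

#' Segment clusters from a hue map
#'
#' Pixels more than `k` SDs above the mean of the hue map are classified as
#' cluster pixels; one binary erosion with a 3 x 3 square then removes
#' isolated noise pixels. A zero-variance map yields an empty mask.
#'
#' @param hue a [hue_map()].
#' @param k threshold in SD units above the mean.
#' @return Object of class `cluster_map`: list with `mask` (logical matrix,
#'   after erosion), `pre_erosion_mask`, `cluster_ratio`.
#' @export
segment_clusters <- function(hue, k = 1.4) {
  stopifnot(inherits(hue, "hue_map"))
  v <- hue$values
  s <- stats::sd(v)
  pre <- if (s == 0) matrix(FALSE, nrow(v), ncol(v)) else v > mean(v) + k * s
  mask <- if (any(pre))
    EBImage::erode(pre * 1, EBImage::makeBrush(3, "box")) > 0
  else pre
  structure(list(mask = mask, pre_erosion_mask = pre,
                 cluster_ratio = mean(mask)),
            class = "cluster_map")
}

#' Cluster ratio of a segmentation mask
#'
#' Fraction of pixels classified as belonging to large clusters.
#'
#' @param mask logical matrix or a `cluster_map`.
#' @return Scalar in \[0, 1\].
#' @export
cluster_ratio <- function(mask) {
  if (inherits(mask, "cluster_map")) mask <- mask$mask
  mean(mask)
}

#' Normalize a cluster-ratio series to its first day
#'
#' @param x numeric series ordered by day.
#' @return `x / x[1]`; errors when the first value is 0.
#' @export
normalize_cluster_ratio <- function(x) {
  if (!length(x)) return(x)
  if (x[1] <= 0) stop("first-day cluster ratio is zero: normalization undefined")
  x / x[1]
}

#' Per-electrode clusterness score
#'
#' Weighted mean of the hue map in a square window (default 31 x 31 um)
#' centred on each electrode, with isotropic Gaussian weights whose 1-SD
#' contour touches the window edge (sigma = half-window). Image content
#' outside the window never affects the score. Electrodes whose window
#' leaves the image get `NA`.
#'
#' @param hue a [hue_map()].
#' @param layout an [mea_layout()] with positions in um.
#' @param window_um window side length (um).
#' @param origin_um image position (um) of pixel (1, 1) as `c(x, y)`;
#'   x maps to columns, y to rows.
#' @return Named numeric vector of scores (electrode id -> clusterness).
#' @export
electrode_clusterness <- function(hue, layout, window_um = 31,
                                  origin_um = c(0, 0)) {
  stopifnot(inherits(hue, "hue_map"), inherits(layout, "mea_layout"))
  v <- hue$values
  sc <- hue$scale_um_per_px
  half_px <- (window_um / 2) / sc
  sigma_px <- half_px                       # window edge at 1 SD
  r <- floor(half_px)
  scores <- vapply(seq_len(nrow(layout)), function(i) {
    cc <- round((layout$x[i] - origin_um[1]) / sc) + 1L
    rr <- round((layout$y[i] - origin_um[2]) / sc) + 1L
    if (rr - r < 1 || rr + r > nrow(v) || cc - r < 1 || cc + r > ncol(v))
      return(NA_real_)
    rows <- (rr - r):(rr + r)
    cols <- (cc - r):(cc + r)
    d2 <- outer((rows - rr)^2, (cols - cc)^2, "+")
    w <- exp(-d2 / (2 * sigma_px^2))
    sum(w * v[rows, cols]) / sum(w)
  }, numeric(1))
  names(scores) <- layout$electrode_id
  scores
}

#' Full image quantification for one MEA image
#'
#' Inpaints electrodes, computes the hue map, segments clusters and scores
#' every electrode.
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param layout an [mea_layout()].
#' @param scale_um_per_px pixel scale (um/px).
#' @param k segmentation threshold (SDs above the mean).
#' @param sigma_low,sigma_high band-pass scales (um).
#' @param origin_um image position of pixel (1, 1), um.
#' @param invert hue orientation flag (see [hue_map()]).
#' @return List with `cluster_map`, `hue`, `clusterness`, `cluster_ratio`.
#' @export
quantify_image <- function(img, layout, scale_um_per_px, k = 1.4,
                           sigma_low = 15, sigma_high = 300,
                           origin_um = c(0, 0), invert = FALSE) {
  inp <- inpaint_electrodes(img)
  hue <- hue_map(inp$image, scale_um_per_px, sigma_low, sigma_high, invert)
  cm <- segment_clusters(hue, k)
  scores <- electrode_clusterness(hue, layout, origin_um = origin_um)
  list(cluster_map = cm, hue = hue, clusterness = scores,
       cluster_ratio = cm$cluster_ratio)
}
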