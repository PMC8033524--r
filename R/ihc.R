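#' Standard H-DAB stain vectors
#'
#' Row-normalized optical-density vectors for haematoxylin and DAB, plus an
#' orthogonal residual channel, as used by conventional brightfield colour
#' deconvolution.
#'
#' @return 3x3 matrix; rows are stains (H, DAB, residual), columns RGB.
#' @export
hdab_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  dab <- c(0.269, 0.568, 0.776)
  h <- h / sqrt(sum(h^2))
  dab <- dab / sqrt(sum(dab^2))
  # complementary third channel, componentwise non-negative by construction
  res <- sqrt(pmax(0, 1 - h^2 - dab^2))
  m <- rbind(H = h, DAB = dab, residual = res / sqrt(sum(res^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

# transmitted 8-bit intensity <-> optical density
rgb_to_od <- function(rgb) -log10(pmax(rgb, 1) / 255)
od_to_rgb <- function(od) pmin(pmax(255 * 10^-od, 0), 255)

#' Colour deconvolution of a brightfield RGB image
#'
#' Converts the image to optical densities and unmixes them into per-stain
#' densities with the (row-normalized) stain matrix.
#'
#' @param rgb Numeric `H x W x 3` array, 8-bit scale (0-255).
#' @param stains 3x3 stain matrix (rows = stains), e.g. [hdab_vectors()].
#' @return `H x W x 3` array of stain densities, third dimension named
#'   after the stain rows.
#' @export
deconvolve_stains <- function(rgb, stains = hdab_vectors()) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stopf("rgb must be an H x W x 3 array")
  od <- matrix(rgb_to_od(rgb), ncol = 3L)
  conc <- od %*% solve(stains)
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(stains))
  out
}

#' Render an RGB brightfield image from per-stain densities
#'
#' Forward model of [deconvolve_stains()]: useful for constructing images
#' with known ground-truth staining.
#'
#' @param conc `H x W x 3` array of stain densities.
#' @param stains 3x3 stain matrix (rows = stains).
#' @return Numeric `H x W x 3` array on the 0-255 scale.
#' @export
render_stains <- function(conc, stains = hdab_vectors()) {
  d <- dim(conc)
  od <- matrix(conc, ncol = 3L) %*% stains
  array(od_to_rgb(od), dim = d)
}

#' Rolling-ball background subtraction (light background)
#'
#' Implemented as grey-scale morphological opening with a disc structuring
#' element on the inverted image: the opened image estimates the smooth
#' background, which is subtracted so the field flattens to white.
#'
#' @param channel Numeric matrix (0-255) or `H x W x 3` array (each channel
#'   processed independently).
#' @param radius Ball radius in pixels; clipped with a warning when the
#'   image is smaller than the structuring element.
#' @return Same shape as the input, 0-255.
#' @export
subtract_background <- function(channel, radius = 50L) {
  one <- function(m) {
    r <- radius
    max_r <- floor((min(dim(m)) - 1) / 2)
    if (r > max_r) {
      warnf("rolling-ball radius %d clipped to %d for a %dx%d image",
            r, max_r, nrow(m), ncol(m))
      r <- max_r
    }
    inv <- (255 - m) / 255
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    bg <- EBImage::opening(EBImage::Image(inv), brush)
    out <- pmin(pmax(inv - as.matrix(bg), 0), 1)
    255 - out * 255
  }
  if (length(dim(channel)) == 3L) {
    out <- channel
    for (k in seq_len(dim(channel)[3])) out[, , k] <- one(channel[, , k])
    out
  } else {
    one(channel)
  }
}

#' DAB channel extraction for immunohistochemistry quantification
#'
#' The semi-automatic recipe applied to each region of interest: rolling-
#' ball background subtraction (50-px radius), H-DAB colour deconvolution,
#' extraction of the DAB channel as an 8-bit image where darker = more
#' stain, and Gaussian blur (sigma 5).
#'
#' @param rgb Numeric `H x W x 3` array, 0-255.
#' @param roi_mask Optional logical matrix; must select at least one pixel.
#' @param rolling_radius Rolling-ball radius (px); 0 skips subtraction.
#' @param blur_sigma Gaussian blur sigma (px); 0 skips the blur.
#' @param stains Stain matrix, rows = stains; channel 2 is extracted.
#' @return Numeric matrix (0-255), the processed DAB channel.
#' @export
preprocess_dab <- function(rgb, roi_mask = NULL, rolling_radius = 50L,
                           blur_sigma = 5, stains = hdab_vectors()) {
  if (!is.null(roi_mask) && sum(roi_mask) == 0L) {
    stopf("ROI is empty")
  }
  if (rolling_radius > 0) {
    rgb <- subtract_background(rgb, radius = rolling_radius)
  }
  conc <- deconvolve_stains(rgb, stains)
  dab <- od_to_rgb(pmax(conc[, , 2L], 0))
  if (blur_sigma > 0) {
    dab <- as.matrix(EBImage::gblur(EBImage::Image(dab / 255),
                                    sigma = blur_sigma)) * 255
    dab <- pmin(pmax(dab, 0), 255)
  }
  dab
}

#' DAB-positive area within a region of interest
#'
#' Positive pixels are ROI pixels whose DAB value is at or below the
#' threshold (stain is dark on the deconvolved channel). Panel thresholds
#' used by the screen's staining recipe: 222 for CD31 vessel areas, 170 for
#' NFIB/ERO1A/VEGFA.
#'
#' @param dab_channel Matrix from [preprocess_dab()].
#' @param roi_mask Logical matrix, same shape; must be non-empty.
#' @param threshold Positivity threshold in 0-255.
#' @param positive_below If `FALSE`, inverts the polarity (pixels >=
#'   threshold count as positive).
#' @return Object of class `stain_quant`: list with `positive_area_px`,
#'   `roi_area_px`, `positive_fraction`, `threshold_used`.
#' @export
positive_area <- function(dab_channel, roi_mask, threshold,
                          positive_below = TRUE) {
  if (threshold < 0 || threshold > 255) stopf("threshold must be in [0, 255]")
  if (!identical(dim(dab_channel), dim(roi_mask))) {
    stopf("dab_channel and roi_mask dimensions differ")
  }
  roi_n <- sum(roi_mask)
  if (roi_n == 0L) stopf("ROI is empty")
  vals <- dab_channel[roi_mask]
  pos <- if (positive_below) sum(vals <= threshold) else sum(vals >= threshold)
  structure(list(positive_area_px = pos, roi_area_px = roi_n,
                 positive_fraction = pos / roi_n, threshold_used = threshold),
            class = "stain_quant")
}

#' @export
print.stain_quant <- function(x, ...) {
  cat(sprintf("DAB-positive area: %d / %d px (%.1f%%) at threshold %g\n",
              x$positive_area_px, x$roi_area_px, 100 * x$positive_fraction,
              x$threshold_used))
  invisible(x)
}

#' Metastatic burden as percentage of lung area
#'
#' `100 x area(union of metastasis ROIs) / area(lung mask)`. Overlapping
#' ROIs are not double-counted; ROI pixels outside the lung are clipped
#' with a warning.
#'
#' @param lung_mask Logical matrix of the lung section area.
#' @param met_roi_masks List of logical matrices (one per metastasis ROI).
#' @return Percentage in `[0, 100]`.
#' @export
metastatic_burden <- function(lung_mask, met_roi_masks) {
  if (sum(lung_mask) == 0L) stopf("lung mask is empty")
  if (!is.list(met_roi_masks)) met_roi_masks <- list(met_roi_masks)
  union <- Reduce(`|`, met_roi_masks,
                  init = matrix(FALSE, nrow(lung_mask), ncol(lung_mask)))
  outside <- sum(union & !lung_mask)
  if (outside > 0L) {
    warnf("%d ROI pixel(s) outside the lung mask clipped", outside)
    union <- union & lung_mask
  }
  100 * sum(union) / sum(lung_mask)
}

#' Construct a synthetic stained brightfield image
#'
#' Renders a white-background RGB image in which `stain_mask` pixels carry
#' the given DAB (and optionally haematoxylin) optical density -- a
#' ground-truth fixture for the quantification pipeline.
#'
#' @param nrow,ncol Image size.
#' @param stain_mask Logical matrix of stained pixels.
#' @param dab_od,hema_od Optical densities applied within the mask.
#' @return Numeric `nrow x ncol x 3` array on the 0-255 scale.
#' @export
make_stain_image <- function(nrow, ncol, stain_mask, dab_od = 1, hema_od = 0) {
  conc <- array(0, dim = c(nrow, ncol, 3))
  conc[, , 1][stain_mask] <- hema_od
  conc[, , 2][stain_mask] <- dab_od
  render_stains(conc)
}
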