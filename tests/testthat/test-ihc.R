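# H-DAB deconvolution, background subtraction and positive-area measurement.

test_that("a pure-white ROI deconvolves to the no-stain level", {
  img <- array(255, dim = c(60, 60, 3))
  dab <- preprocess_dab(img, rolling_radius = 20, blur_sigma = 2)
  expect_true(all(abs(dab - 255) < 1))
})

test_that("a pure-DAB patch is dark in DAB and clean in haematoxylin", {
  mask <- matrix(FALSE, 80, 80)
  mask[30:50, 30:50] <- TRUE
  img <- make_stain_image(80, 80, mask, dab_od = 0.8)
  conc <- deconvolve_stains(img)
  expect_equal(mean(conc[, , "DAB"][mask]), 0.8, tolerance = 1e-6)
  expect_lt(max(abs(conc[, , "H"])), 1e-6)
  dab8 <- 255 * 10^-conc[, , "DAB"]
  expect_lt(mean(dab8[mask]), 50)
})

test_that("deconvolution inverts the forward render", {
  set.seed(371)
  conc <- array(runif(3 * 100, 0.05, 0.6), dim = c(10, 10, 3))
  rt <- deconvolve_stains(render_stains(conc))
  expect_equal(rt, conc, tolerance = 1e-10, ignore_attr = TRUE)
  # 8-bit quantized images recover light-to-moderate densities to ~0.02 OD;
  # darker mixtures approach transmittance saturation where quantization bites
  conc2 <- array(runif(3 * 100, 0.1, 0.4), dim = c(10, 10, 3))
  rt2 <- deconvolve_stains(round(render_stains(conc2)))
  expect_lt(max(abs(rt2 - conc2)), 0.02)
})

test_that("Gaussian blur preserves mean intensity in the ROI interior", {
  set.seed(372)
  img <- matrix(runif(150 * 150, 80, 200), 150, 150)
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(img / 255), sigma = 5)) * 255
  interior <- matrix(FALSE, 150, 150)
  interior[30:120, 30:120] <- TRUE
  expect_lt(abs(mean(img[interior]) - mean(blurred[interior])), 0.5)
})

test_that("background subtraction flattens gradients but keeps small features", {
  grad <- matrix(rep(seq(150, 230, length.out = 100), each = 100), 100, 100)
  spot <- matrix(FALSE, 100, 100)
  spot[45:55, 45:55] <- TRUE
  img <- grad
  img[spot] <- 40
  flat <- subtract_background(img, radius = 20)
  # background pixels end up near white, the dark spot stays dark
  expect_gt(mean(flat[!spot]), 250)
  expect_lt(mean(flat[spot]), 150)
  expect_warning(subtract_background(matrix(200, 20, 20), radius = 50),
                 "clipped")
})

test_that("positive fraction hits its limits and increases with threshold", {
  mask <- matrix(FALSE, 120, 120)
  mask[20:40, seq(10, 110, by = 25)] <- TRUE
  img <- make_stain_image(120, 120, mask, dab_od = 0.9)
  dab <- preprocess_dab(img, rolling_radius = 30, blur_sigma = 2)
  roi <- matrix(TRUE, 120, 120)
  expect_equal(positive_area(dab, roi, 255)$positive_fraction, 1)
  white <- preprocess_dab(array(255, dim = c(120, 120, 3)),
                          rolling_radius = 30, blur_sigma = 2)
  expect_equal(positive_area(white, roi, 0)$positive_fraction, 0)
  fr <- vapply(seq(0, 255, by = 5),
               function(th) positive_area(dab, roi, th)$positive_fraction, 0)
  expect_true(all(diff(fr) >= 0))
  expect_error(positive_area(dab, roi & FALSE, 100), "empty")
})

test_that("measured area is invariant to translating the ROI and pattern", {
  base_mask <- matrix(FALSE, 140, 140)
  base_mask[20:40, 20:50] <- TRUE
  measure <- function(offset) {
    mask <- matrix(FALSE, 140, 140)
    mask[(20:40) + offset, (20:50) + offset] <- TRUE
    img <- make_stain_image(140, 140, mask, dab_od = 0.7)
    roi <- matrix(FALSE, 140, 140)
    roi[(10:60) + offset, (10:60) + offset] <- TRUE
    positive_area(preprocess_dab(img, rolling_radius = 15, blur_sigma = 2),
                  roi, 170)$positive_fraction
  }
  expect_equal(measure(0), measure(40), tolerance = 1e-12)
})

test_that("metastatic burden is the union area over the lung area", {
  lung <- matrix(FALSE, 100, 100)
  lung[11:90, 11:90] <- TRUE  # 6400 px
  half <- matrix(FALSE, 100, 100)
  half[11:50, 11:90] <- TRUE  # 3200 px
  expect_equal(metastatic_burden(lung, list(half)), 50)
  a <- matrix(FALSE, 100, 100); a[11:30, 11:30] <- TRUE
  b <- matrix(FALSE, 100, 100); b[21:40, 21:40] <- TRUE
  got <- metastatic_burden(lung, list(a, b))
  expect_equal(got, 100 * sum(a | b) / sum(lung))  # no double counting
  outside <- matrix(FALSE, 100, 100); outside[1:20, 1:20] <- TRUE
  expect_warning(clipped <- metastatic_burden(lung, list(outside)), "clipped")
  expect_equal(clipped, 100 * sum(outside & lung) / sum(lung))
  expect_error(metastatic_burden(lung & FALSE, list(a)), "empty")
})
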