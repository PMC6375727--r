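#' Mean pixel intensity inside an ROI
#'
#' Arithmetic mean of the pixel values whose centers lie inside the
#' polygon (mean pixel intensity per unit area).
#'
#' @param img an [image_field].
#' @param roi an [roi_polygon].
#' @return mean intensity (AU).
#' @export
roi_mean_intensity <- function(img, roi) {
  mask <- roi_pixel_mask(img, roi)
  if (!any(mask)) stop("ROI contains no pixels")
  mean(img$pixels[mask])
}

#' Background subtraction
#'
#' Subtracts the background ROI mean from the signal ROI mean. Negative
#' results are returned as-is with a warning (clipping at zero would bias
#' downstream ratio distributions).
#'
#' @param signal_mean,bg_mean finite mean intensities (AU).
#' @return background-subtracted mean (AU).
#' @export
background_subtract <- function(signal_mean, bg_mean) {
  if (!is.finite(signal_mean) || !is.finite(bg_mean)) {
    stop("signal_mean and bg_mean must be finite")
  }
  out <- signal_mean - bg_mean
  if (out < 0) {
    warning("background-subtracted mean is negative (retained, not clipped)")
  }
  out
}

# Split the in-ROI pixel index set into near/far halves. Pixels whose
# centers fall exactly on the line go to the near side (fixed tie-break).
split_near_far <- function(img, roi, line) {
  stopifnot(inherits(line, "bisection_line"))
  mask <- roi_pixel_mask(img, roi)
  if (!any(mask)) stop("ROI contains no pixels")
  pts <- pixel_centers(img)
  idx <- which(as.vector(mask))
  cr <- line$direction[1] * (pts[idx, 2] - line$anchor[2]) -
    line$direction[2] * (pts[idx, 1] - line$anchor[1])
  side <- sign(cr)
  near <- side == line$near_side_sign | side == 0
  list(idx = idx, near = near, pts = pts)
}

#' Near:far fluorescence ratio of a bisected growth cone
#'
#' The growth cone is bisected by a line through the axon shaft; the
#' background-subtracted mean intensity is computed separately over the
#' pixels on the near (cue-facing) and far sides, and their ratio is
#' returned.
#'
#' @param img fluorescence [image_field].
#' @param roi growth-cone [roi_polygon].
#' @param line a [bisection_line].
#' @param bg_mean background level to subtract (AU).
#' @return list with `near_mean`, `far_mean` (background-subtracted, AU),
#'   `near_far_ratio`, `n_near`, `n_far`, and `flag` (`NA` or a text flag
#'   when the ratio is undefined).
#' @export
near_far_ratio <- function(img, roi, line, bg_mean = 0) {
  sp <- split_near_far(img, roi, line)
  if (!any(sp$near) || !any(!sp$near)) {
    stop("bisection line leaves one half of the ROI empty")
  }
  vals <- img$pixels[sp$idx]
  near_mean <- mean(vals[sp$near]) - bg_mean
  far_mean <- mean(vals[!sp$near]) - bg_mean
  flag <- NA_character_
  ratio <- if (far_mean > 0) {
    near_mean / far_mean
  } else {
    flag <- "far_mean <= 0 after background subtraction; ratio undefined"
    NA_real_
  }
  list(
    near_mean = near_mean, far_mean = far_mean, near_far_ratio = ratio,
    n_near = sum(sp$near), n_far = sum(!sp$near), flag = flag
  )
}

#' Center-of-mass shift of a fluorescence signal
#'
#' The fluorescence center of mass is the intensity-weighted mean pixel
#' location over the in-ROI pixels; the morphological reference point is
#' the unweighted centroid of the same pixel set (traced from the
#' brightfield image). Their difference measures signal polarization; its
#' projection onto the gradient axis is the headline statistic.
#'
#' @param fluor fluorescence [image_field].
#' @param brightfield brightfield [image_field] (same shape; used only to
#'   define the morphology mask via `roi`).
#' @param roi growth-cone [roi_polygon] traced on the brightfield image.
#' @param gradient_axis cue-gradient direction, degrees.
#' @return list with `com_fluor`, `com_brightfield`, `com_shift` (all
#'   (x, y) px) and `com_shift_along_gradient` (px).
#' @export
center_of_mass_shift <- function(fluor, brightfield, roi, gradient_axis) {
  if (!identical(dim(fluor$pixels), dim(brightfield$pixels))) {
    stop("fluorescence and brightfield images must have identical shape")
  }
  mask <- roi_pixel_mask(fluor, roi)
  if (!any(mask)) stop("ROI contains no pixels")
  pts <- pixel_centers(fluor)
  idx <- which(as.vector(mask))
  wgt <- fluor$pixels[idx]
  tot <- sum(wgt)
  if (tot <= 0) stop("zero total fluorescence intensity inside the ROI")
  com_fluor <- c(sum(wgt * pts[idx, 1]), sum(wgt * pts[idx, 2])) / tot
  com_bf <- c(mean(pts[idx, 1]), mean(pts[idx, 2]))
  shift <- com_fluor - com_bf
  u <- unit_vector(gradient_axis)
  list(
    com_fluor = com_fluor,
    com_brightfield = com_bf,
    com_shift = shift,
    com_shift_along_gradient = sum(shift * u)
  )
}

#' Full growth-cone asymmetry quantification
#'
#' Convenience wrapper running background measurement, the near:far ratio
#' and the center-of-mass shift on one growth cone.
#'
#' @param fluor,brightfield [image_field]s.
#' @param gc_roi,bg_roi growth-cone and background [roi_polygon]s.
#' @param line a [bisection_line].
#' @param gradient_axis cue-gradient direction, degrees.
#' @return one-row `data.frame` with means, ratio and COM fields.
#' @export
quantify_growth_cone <- function(fluor, brightfield, gc_roi, bg_roi, line,
                                 gradient_axis) {
  bg <- roi_mean_intensity(fluor, bg_roi)
  nf <- near_far_ratio(fluor, gc_roi, line, bg_mean = bg)
  cm <- center_of_mass_shift(fluor, brightfield, gc_roi, gradient_axis)
  data.frame(
    bg_mean = bg,
    near_mean = nf$near_mean,
    far_mean = nf$far_mean,
    near_far_ratio = nf$near_far_ratio,
    com_fluor_x = cm$com_fluor[1], com_fluor_y = cm$com_fluor[2],
    com_bf_x = cm$com_brightfield[1], com_bf_y = cm$com_brightfield[2],
    com_shift_x = cm$com_shift[1], com_shift_y = cm$com_shift[2],
    com_shift_along_gradient = cm$com_shift_along_gradient
  )
}
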