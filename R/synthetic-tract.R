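# Exact circle-overlay widths of a thickened-polyline tract, computed on
# the continuous geometry (no rasterization): each circle Ck (radius
# k/10 * D around the OC) is sampled at a very fine angular step, a sample
# is tract-positive when its exact Euclidean distance to any segment is
# within that segment's half-width, and the width is the arc length of
# the largest contiguous run. Serves as generator ground truth for the
# pixel-based measurement.
analytic_circle_widths <- function(oc, segments, D, step_deg = 0.02) {
  ang <- seq(0, 360 - step_deg, by = step_deg)
  ca <- cos(deg2rad(ang)); sa <- sin(deg2rad(ang))
  n <- length(ang)
  widths <- numeric(10)
  for (k in 1:10) {
    r <- k / 10 * D
    pts <- cbind(oc[1] + r * ca, oc[2] + r * sa)
    hit <- rep(FALSE, n)
    for (sg in segments) {
      hit <- hit | dist_to_segment(pts, sg$a, sg$b) <= sg$halfw
    }
    if (!any(hit)) next
    rl <- rle(hit)
    if (length(rl$lengths) > 1 && hit[1] && hit[n]) {
      first <- rl$lengths[1]
      last <- rl$lengths[length(rl$lengths)]
      rl$lengths <- c(rl$lengths[-c(1, length(rl$lengths))], first + last)
      rl$values <- c(rl$values[-c(1, length(rl$values))], TRUE)
    }
    widths[k] <- r * max(rl$lengths[rl$values]) * deg2rad(step_deg)
  }
  stats::setNames(widths, paste0("C", 1:10))
}

# Distance from each point in pts (n x 2) to the segment [a, b].
dist_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

#' Simulate a DiI-labeled optic-tract image
#'
#' Draws a two-segment thickened polyline emulating a DiI-filled optic
#' tract: a pre-turn bundle of constant width leaving the optic chiasm
#' (OC), a caudal turn deviating by `mdt_angle_deg` at the mid-diencephalic
#' turn (MDT) vertex placed at 0.45 of the OC-TPB distance, and a post-turn
#' bundle that continues until it leaves circle C10. A thin
#' anteriorly-projecting axon sprouts from the tract end at `tpa_deg`
#' (positive toward the tectal posterior boundary). The geometry crosses
#' concentric circles C1-C10 centered on the OC with C10 at the TPB.
#'
#' @param oc,tpb optic chiasm and tectal posterior boundary, (x, y) px.
#' @param mdt_angle_deg deviation-from-straight turn angle, `[0, 180)`.
#' @param pre_width_px,post_width_px tract widths (px), > 0.
#' @param tpa_deg signed tectal projection angle of the anterior axon.
#' @param noise_sd additive Gaussian noise on the intensity image (AU).
#' @param seed integer RNG seed.
#' @param shape_px optional image (height, width); default fits the scene.
#' @return list with `image` ([image_field]), `tract_mask` (logical
#'   matrix), `landmarks` (data.frame name/x/y), and `ground_truth`.
#' @export
make_tract_image <- function(oc, tpb, mdt_angle_deg = 45,
                             pre_width_px = 10, post_width_px = 10,
                             tpa_deg = -9, noise_sd = 0, seed = 1L,
                             shape_px = NULL) {
  oc <- as.numeric(oc); tpb <- as.numeric(tpb)
  if (all(oc == tpb)) stop("oc and tpb coincide: zero brain size")
  if (pre_width_px <= 0 || post_width_px <= 0) stop("widths must be > 0")
  if (mdt_angle_deg < 0 || mdt_angle_deg >= 180) {
    stop("mdt_angle_deg must lie in [0, 180)")
  }
  D <- vnorm(tpb - oc)
  d0 <- normalize(tpb - oc)
  vertex <- oc + 0.45 * D * d0
  d1 <- rotate2(d0, mdt_angle_deg)

  # Extend the post-turn segment until it leaves circle C10 (radius D).
  # |vertex + t*d1 - oc| = 1.02 D, take the positive root.
  w0 <- vertex - oc
  bq <- sum(w0 * d1)
  cq <- sum(w0^2) - (1.02 * D)^2
  t_end <- -bq + sqrt(bq^2 - cq)
  tip_base <- vertex + t_end * d1

  # Anterior axon: deviates from the post-turn direction by tpa_deg,
  # positive toward the TPB side of the post-turn axis.
  s_tpb <- sign(cross2(d1, tpb - vertex))
  if (s_tpb == 0) s_tpb <- 1
  axon_dir <- rotate2(d1, tpa_deg * s_tpb)
  axon_tip <- tip_base + 0.15 * D * axon_dir

  # TAB landmark: the TPB mirrored across the post-turn axis (used only
  # to orient the TPA sign).
  tt <- sum((tpb - vertex) * d1)
  foot <- vertex + tt * d1
  tab <- 2 * foot - tpb

  geom <- rbind(oc, tpb, vertex, tip_base, axon_tip, tab)
  if (is.null(shape_px)) {
    margin <- max(pre_width_px, post_width_px) + 10
    shape_px <- c(
      ceiling(max(geom[, 2]) + margin),
      ceiling(max(geom[, 1]) + margin)
    )
  }
  if (any(geom < 1)) stop("scene geometry extends outside the image")
  h <- as.integer(shape_px[1]); w <- as.integer(shape_px[2])

  blank <- image_field(matrix(0, h, w), "fluorescence")
  pts <- pixel_centers(blank)
  mask <- dist_to_segment(pts, oc, vertex) <= pre_width_px / 2 |
    dist_to_segment(pts, vertex, tip_base) <= post_width_px / 2 |
    dist_to_segment(pts, tip_base, axon_tip) <= 1
  mask <- matrix(mask, h, w)

  img <- with_seed(seed, {
    px <- matrix(20, h, w)
    px[mask] <- 200
    if (noise_sd > 0) {
      px <- px + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
      px[px < 0] <- 0
    }
    px
  })

  landmarks <- data.frame(
    name = c("oc", "tpb", "mdt_ventral", "pioneer_tip",
             "anterior_axon_tip", "tab"),
    x = c(oc[1], tpb[1], vertex[1], tip_base[1], axon_tip[1], tab[1]),
    y = c(oc[2], tpb[2], vertex[2], tip_base[2], axon_tip[2], tab[2])
  )

  widths_exact <- analytic_circle_widths(
    oc,
    list(
      list(a = oc, b = vertex, halfw = pre_width_px / 2),
      list(a = vertex, b = tip_base, halfw = post_width_px / 2),
      list(a = tip_base, b = axon_tip, halfw = 1)
    ),
    D
  )

  gt <- ground_truth("tract", list(
    oc = oc, tpb = tpb, brain_size = D,
    mdt_angle_deg = mdt_angle_deg,
    pre_width_px = pre_width_px, post_width_px = post_width_px,
    circle_widths = widths_exact,
    pre_width_arc = mean(widths_exact[2:4]),
    post_width_arc = mean(widths_exact[5:8]),
    tpa_deg = tpa_deg,
    mdt_vertex = vertex, pioneer_tip = tip_base,
    anterior_axon_tip = axon_tip, tab = tab,
    noise_sd = noise_sd
  ), seed)

  list(
    image = image_field(img, "fluorescence"),
    tract_mask = mask,
    landmarks = landmarks,
    ground_truth = gt
  )
}

#' Assemble a tract scene from a mask and landmarks
#'
#' @param tract_mask logical matrix of DiI-positive pixels (or a numeric
#'   matrix / [image_field] with `threshold`).
#' @param landmarks data.frame with columns `name, x, y` containing at
#'   least `oc`, `tpb`, `mdt_ventral`, `pioneer_tip`, `anterior_axon_tip`,
#'   `tab`.
#' @param threshold intensity threshold applied when `tract_mask` is not
#'   already logical.
#' @return object of class `tract_scene`.
#' @export
tract_scene <- function(tract_mask, landmarks, threshold = NULL) {
  if (inherits(tract_mask, "image_field")) tract_mask <- tract_mask$pixels
  if (!is.logical(tract_mask)) {
    if (is.null(threshold)) {
      stop("a numeric mask requires a threshold")
    }
    tract_mask <- tract_mask >= threshold
  }
  need <- c("oc", "tpb", "mdt_ventral", "pioneer_tip",
            "anterior_axon_tip", "tab")
  miss <- setdiff(need, landmarks$name)
  if (length(miss)) {
    stop("landmarks missing: ", paste(miss, collapse = ", "))
  }
  lm <- function(nm) {
    r <- landmarks[landmarks$name == nm, , drop = FALSE][1, ]
    c(r$x, r$y)
  }
  sc <- list(
    tract_mask = tract_mask,
    oc = lm("oc"), tpb = lm("tpb"), mdt_ventral = lm("mdt_ventral"),
    pioneer_tip = lm("pioneer_tip"),
    anterior_axon_tip = lm("anterior_axon_tip"), tab = lm("tab")
  )
  if (all(sc$oc == sc$tpb)) stop("oc and tpb coincide")
  structure(sc, class = "tract_scene")
}
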