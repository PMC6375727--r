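#' Ground-truth record for a synthetic instance
#'
#' Every generator returns a `ground_truth` object recording the seed and
#' every quantity a downstream analysis stage is expected to recover.
#'
#' @param kind one of `"growth_cone"`, `"tract"`, `"arbor"`, `"psilac"`.
#' @param parameters named list of generated quantities.
#' @param seed the integer seed used.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(kind, parameters, seed) {
  kind <- match.arg(kind, c("growth_cone", "tract", "arbor", "psilac"))
  structure(
    list(kind = kind, parameters = parameters, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> kind = %s, seed = %d, %d parameters\n",
    x$kind, x$seed, length(x$parameters)
  ))
  invisible(x)
}

#' Simulate a growth-cone gradient-assay image pair
#'
#' Draws a fan-shaped growth-cone palm (an annular sector opening along
#' the axon-shaft axis) with filopodial spikes, and paints a fluorescence
#' signal carrying a linear ramp along a cue gradient axis, emulating the
#' 90-degree polarized-gradient stimulation geometry. The ramp intercept
#' and slope are solved on the in-mask pixel set so that (i) the noiseless
#' near:far mean ratio equals exactly `1 + gradient_strength`, where the
#' near/far halves are delimited by the bisection line through the mask
#' centroid along the shaft axis (perpendicular to the gradient), (ii) the
#' mean noiseless signal over the mask equals `base_signal`, and (iii) the
#' signal stays strictly positive everywhere in the mask (gradients too
#' steep for the mask geometry are rejected).
#'
#' @param shape_px integer pair, image height and width in pixels.
#' @param gradient_strength (near mean - far mean) / far mean of the
#'   noiseless background-free signal; >= 0.
#' @param gradient_axis direction of increasing cue concentration, degrees
#'   in `[0, 360)` (x right, y down).
#' @param base_signal mean noiseless signal over the mask (AU), > 0.
#' @param background additive uniform background level (AU).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   fluorescence channel (AU); values are clipped at 0.
#' @param seed integer RNG seed.
#' @return list with elements `fluorescence` and `brightfield`
#'   ([image_field]s), `gc_roi` and `bg_roi` ([roi_polygon]s), `line`
#'   (the [bisection_line] used for normalization), and `ground_truth`.
#' @export
make_growth_cone_image <- function(shape_px = c(128L, 128L),
                                   gradient_strength = 0,
                                   gradient_axis = 0,
                                   base_signal = 100,
                                   background = 10,
                                   noise_sd = 0,
                                   seed = 1L) {
  if (length(shape_px) != 2 || any(shape_px <= 0)) {
    stop("shape_px must be two positive integers")
  }
  if (gradient_axis < 0 || gradient_axis >= 360) {
    stop("gradient_axis must lie in [0, 360)")
  }
  if (gradient_strength < 0) stop("gradient_strength must be >= 0")
  if (base_signal <= 0) stop("base_signal must be > 0")
  if (background < 0 || noise_sd < 0) {
    stop("background and noise_sd must be >= 0")
  }
  shape_px <- as.integer(shape_px)

  with_seed(seed, {
    h <- shape_px[1]
    w <- shape_px[2]
    ctr <- c(w, h) / 2 + 0.5
    rmax <- 0.32 * min(h, w)
    u <- unit_vector(gradient_axis)            # gradient direction
    shaft_deg <- (gradient_axis + 90) %% 360   # shaft axis, perpendicular
    s <- unit_vector(shaft_deg)

    # Palm outline: annular sector opening along the shaft axis with
    # half-angle 50 degrees, lobed rim plus 3-8 short filopodial spikes.
    # The inner rim (neck) keeps the across-axis pixel distribution close
    # to uniform so that steep ramps remain positive over the whole mask.
    n_arc <- 121L
    phi <- seq(shaft_deg - 50, shaft_deg + 50, length.out = n_arc)
    r <- rmax * (0.92 + 0.08 * cos(3 * deg2rad(phi - shaft_deg)))
    n_spikes <- sample(3:8, 1L)
    spike_at <- sort(sample(seq(5L, n_arc - 4L), n_spikes))
    for (k in spike_at) {
      idx <- (k - 2L):(k + 2L)
      prof <- c(0.05, 0.12, 0.2, 0.12, 0.05)
      r[idx] <- r[idx] * (1 + prof)
    }
    r_in <- 0.45 * rmax
    vx <- c(ctr[1] + r * cos(deg2rad(phi)),
            ctr[1] + r_in * cos(deg2rad(rev(phi))))
    vy <- c(ctr[2] + r * sin(deg2rad(phi)),
            ctr[2] + r_in * sin(deg2rad(rev(phi))))
    gc_roi <- roi_polygon(vx, vy, label = "growth_cone")

    blank <- image_field(matrix(0, h, w), "fluorescence")
    mask <- roi_pixel_mask(blank, gc_roi)
    pts <- pixel_centers(blank)
    in_idx <- which(as.vector(mask))
    if (length(in_idx) < 10) stop("growth-cone mask degenerate (too small)")

    anchor <- c(mean(pts[in_idx, 1]), mean(pts[in_idx, 2]))
    up <- (pts[in_idx, 1] - anchor[1]) * u[1] +
      (pts[in_idx, 2] - anchor[2]) * u[2]

    # Sign convention of the bisection line for the +gradient side.
    near_side_sign <- sign(cross2(s, u))
    line <- bisection_line(anchor, s, near_side_sign)

    near <- up >= 0
    if (!any(near) || !any(!near)) stop("bisection produced an empty half")
    m_n <- mean(up[near])
    m_f <- mean(up[!near])
    g <- gradient_strength
    # signal(u) = s0 + beta * (u - umin); solve the intercept and slope
    # from (near mean)/(far mean) = 1 + g and mean(signal) = base_signal.
    umin <- min(up)
    if (g == 0) {
      s0 <- base_signal
      beta <- 0
    } else {
      A <- m_n - umin
      B <- m_f - umin
      M <- mean(up) - umin
      K <- (A - (1 + g) * B) / g
      if (K <= 0) {
        stop("gradient_strength too steep for this mask geometry")
      }
      beta <- base_signal / (K + M)
      s0 <- beta * K
    }
    signal <- s0 + beta * (up - umin)
    fl <- matrix(background, h, w)
    fl[in_idx] <- fl[in_idx] + signal
    if (noise_sd > 0) {
      fl <- fl + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
      fl[fl < 0] <- 0
    }
    bf <- matrix(100, h, w)
    bf[in_idx] <- 50

    # Exact noiseless bookkeeping for parameter-recovery tests.
    wgt <- signal + background
    com_fluor <- c(
      sum(wgt * pts[in_idx, 1]) / sum(wgt),
      sum(wgt * pts[in_idx, 2]) / sum(wgt)
    )
    com_shift <- com_fluor - anchor
    com_proj <- sum(com_shift * u)

    # Background ROI: a square patch behind the apex, clear of the fan.
    bq <- ctr - 0.42 * min(h, w) * s
    hw <- max(3, 0.06 * min(h, w))
    bq[1] <- min(max(bq[1], hw + 1.5), w - hw - 0.5)
    bq[2] <- min(max(bq[2], hw + 1.5), h - hw - 0.5)
    bg_roi <- roi_polygon(
      bq[1] + c(-hw, hw, hw, -hw), bq[2] + c(-hw, -hw, hw, hw),
      label = "background"
    )

    gt <- ground_truth("growth_cone", list(
      gradient_strength = g,
      gradient_axis = gradient_axis,
      base_signal = base_signal,
      background = background,
      noise_sd = noise_sd,
      near_far_ratio = 1 + g,
      near_mean = s0 + beta * (m_n - umin),
      far_mean = s0 + beta * (m_f - umin),
      ramp_intercept = s0,
      ramp_slope = beta,
      ramp_umin = umin,
      com_shift = com_shift,
      com_shift_along_gradient = com_proj,
      line_anchor = anchor,
      line_direction = s,
      near_side_sign = near_side_sign,
      n_mask_pixels = length(in_idx)
    ), seed)

    list(
      fluorescence = image_field(fl, "fluorescence"),
      brightfield = image_field(bf, "brightfield"),
      gc_roi = gc_roi,
      bg_roi = bg_roi,
      line = line,
      ground_truth = gt
    )
  })
}
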