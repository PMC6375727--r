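# Independent oracles used by the tests; deliberately naive
# implementations, kept separate from the package code paths.

# Even-odd ray-casting point-in-polygon test (one point).
pip_ray_cast <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force ROI mean: loop over every pixel center.
roi_mean_brute <- function(img, roi) {
  vals <- c()
  for (yy in seq_len(nrow(img$pixels))) {
    for (xx in seq_len(ncol(img$pixels))) {
      if (pip_ray_cast(xx, yy, roi$x, roi$y)) {
        vals <- c(vals, img$pixels[yy, xx])
      }
    }
  }
  mean(vals)
}

# Brute-force BH step-up: q_(i) = min over j >= i of p_(j) * m / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive two-sided Fisher p for a 2x2 table: enumerate every table
# with the observed margins and sum the hypergeometric probabilities not
# exceeding the observed one (standard relative tolerance on ties).
fisher_brute <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Analytic first-moment oracle for the generated growth-cone ramp:
# projection of the intensity-weighted centroid shift onto the gradient
# axis, computed directly from the mask geometry and the recorded ramp
# coefficients, independent of the image-analysis code path.
com_projection_oracle <- function(gen) {
  p <- gen$ground_truth$parameters
  mask <- roi_pixel_mask(gen$fluorescence, gen$gc_roi)
  d <- dim(gen$fluorescence$pixels)
  xs <- rep(seq_len(d[2]), each = d[1])
  ys <- rep(seq_len(d[1]), times = d[2])
  idx <- which(as.vector(mask))
  u_axis <- c(cos(p$gradient_axis * pi / 180), sin(p$gradient_axis * pi / 180))
  up <- (xs[idx] - p$line_anchor[1]) * u_axis[1] +
    (ys[idx] - p$line_anchor[2]) * u_axis[2]
  w <- p$ramp_intercept + p$ramp_slope * (up - p$ramp_umin) + p$background
  sum(w * up) / sum(w) - mean(up)
}
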