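straight_scene <- function(width = 10, D = 150, seed = 1) {
  gen <- make_tract_image(
    oc = c(40, 200), tpb = c(40 + D, 200), mdt_angle_deg = 0,
    pre_width_px = width, post_width_px = width, tpa_deg = 0, seed = seed
  )
  list(scene = tract_scene(gen$tract_mask, gen$landmarks), gen = gen)
}

test_that("circle widths recover a constant-width straight tract", {
  st <- straight_scene(width = 10)
  w <- suppressWarnings(circle_widths(st$scene))
  # analytic chord-of-band arc length on a radial band of width 10
  for (k in 2:8) {
    r <- k / 10 * 150
    expect_equal(unname(w[k]), 2 * r * asin(10 / (2 * r)), tolerance = 2 / 10)
  }
})

test_that("circle widths handle empty masks and disjoint limbs", {
  st <- straight_scene()
  empty <- st$scene
  empty$tract_mask[] <- FALSE
  expect_equal(unname(circle_widths(empty)), rep(0, 10))

  # add a second, narrower limb: the larger run wins, with a warning
  two <- st$scene
  two$tract_mask[150:170, 38:42] <- TRUE   # thin vertical limb above the OC
  warns <- testthat::capture_warnings(w2 <- circle_widths(two))
  expect_true(any(grepl("disjoint", warns)))
  w1 <- suppressWarnings(circle_widths(st$scene))
  expect_equal(unname(w2[3]), unname(w1[3]), tolerance = 1e-9)
})

test_that("normalized widths follow the C2-C4 / C5-C8 averaging rule", {
  nw <- normalized_widths(rep(10, 10), c(0, 0), c(100, 0))
  expect_equal(nw$pre_width_norm, 0.1)
  expect_equal(nw$post_width_norm, 0.1)

  w <- c(0, 10, 12, 14, 20, 20, 20, 20, 0, 0)
  nw2 <- normalized_widths(w, c(0, 0), c(200, 0))
  expect_equal(nw2$pre_width_norm, 0.06)
  expect_equal(nw2$post_width_norm, 0.1)

  nw3 <- normalized_widths(w * 3, c(0, 0), c(600, 0))
  expect_equal(nw3$pre_width_norm, nw2$pre_width_norm, tolerance = 1e-6)
  expect_equal(nw3$post_width_norm, nw2$post_width_norm, tolerance = 1e-6)
})

test_that("MDT angle is the deviation from a straight continuation", {
  expect_equal(mdt_angle(c(0, 0), c(10, 0), c(20, 0)), 0)
  expect_equal(mdt_angle(c(0, 0), c(10, 0), c(10, 10)), 90)
  expect_equal(mdt_angle(c(0, 0), c(10, 0), c(20, 10)), 45)
  expect_error(mdt_angle(c(0, 0), c(0, 0), c(1, 1)), "coincident")
})

test_that("TPA is signed toward the posterior tectum and antisymmetric", {
  a <- c(0, 0); b <- c(10, 0)
  tpb <- c(15, 10); tab <- c(15, -10)
  # tip parallel to the tract
  expect_equal(tectal_projection_angle(a, b, c(20, 0), tpb, tab), 0)
  # 20 degrees toward the TPB side (y-down: TPB side is +y here)
  tip <- b + 5 * c(cos(20 * pi / 180), sin(20 * pi / 180))
  expect_equal(tectal_projection_angle(a, b, tip, tpb, tab), 20,
               tolerance = 1e-9)
  # mirroring the axon tip across the tract axis (anatomy fixed) flips
  # the sign exactly
  expect_equal(
    tectal_projection_angle(a, b, c(tip[1], -tip[2]), tpb, tab),
    -20, tolerance = 1e-9
  )
})

test_that("tract parameter recovery on noiseless synthetic scenes", {
  set.seed(13)
  for (i in 1:6) {
    mdt <- runif(1, 5, 60)
    pw <- runif(1, 8, 14)
    qw <- runif(1, 8, 16)
    tpa <- runif(1, -25, 25)
    gen <- make_tract_image(c(60, 240), c(270, 90), mdt_angle_deg = mdt,
                            pre_width_px = pw, post_width_px = qw,
                            tpa_deg = tpa, seed = i)
    sc <- tract_scene(gen$tract_mask, gen$landmarks)
    m <- suppressWarnings(tract_metrics(sc))
    gt <- gen$ground_truth$parameters
    D <- gt$brain_size
    expect_equal(m$pre_width_norm * D, gt$pre_width_arc, tolerance = 2 / 10)
    expect_equal(m$post_width_norm * D, gt$post_width_arc, tolerance = 2 / 10)
    expect_equal(m$mdt_angle_deg, mdt, tolerance = 2 / mdt)
    expect_equal(m$tpa_deg, tpa, tolerance = 2 / abs(tpa))
  }
})

test_that("tract metrics are invariant under a rigid 90-degree rotation", {
  gen <- make_tract_image(c(60, 240), c(270, 90), mdt_angle_deg = 48,
                          pre_width_px = 10, post_width_px = 12,
                          tpa_deg = -12, seed = 21)
  sc <- tract_scene(gen$tract_mask, gen$landmarks)
  m <- suppressWarnings(tract_metrics(sc))

  # rotate the mask and all landmarks by 90 degrees: (x, y) -> (H+1-y, x)
  H <- nrow(gen$tract_mask)
  lms <- gen$landmarks
  rot_lms <- data.frame(name = lms$name, x = H + 1 - lms$y, y = lms$x)
  mr <- matrix(FALSE, ncol(gen$tract_mask), H)
  idx <- which(gen$tract_mask, arr.ind = TRUE)
  mr[cbind(idx[, 2], H + 1 - idx[, 1])] <- TRUE
  sc_rot <- tract_scene(mr, rot_lms)
  m_rot <- suppressWarnings(tract_metrics(sc_rot))
  expect_equal(m_rot$pre_width_norm, m$pre_width_norm, tolerance = 1e-3)
  expect_equal(m_rot$post_width_norm, m$post_width_norm, tolerance = 1e-3)
  expect_equal(m_rot$mdt_angle_deg, m$mdt_angle_deg, tolerance = 1e-3)
  expect_equal(m_rot$tpa_deg, m$tpa_deg, tolerance = 1e-3)
})

test_that("penetrance counts threshold crossings and compares groups", {
  g1 <- data.frame(mdt_angle_deg = c(44, 46), tpa_deg = c(-10, 0))
  out <- penetrance(list(control = g1), control_mean_tpa = -8.6)
  expect_equal(out$frac_mdt_lt, 0.5)
  expect_equal(out$frac_tpa_lt, 0.5)

  out2 <- penetrance(list(control = g1, treated = g1),
                     control_mean_tpa = -8.6)
  expect_equal(out2$fisher_p_mdt[2], 1)
  expect_equal(out2$fisher_p_tpa[2], 1)
})

test_that("Fisher's exact p matches exhaustive hypergeometric enumeration", {
  # the 2x2 table [[8,2],[2,8]]
  expect_equal(
    fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value,
    fisher_brute(8, 2, 2, 8),
    tolerance = 1e-12
  )
})
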