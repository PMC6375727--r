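#' Tract widths on ten concentric circles
#'
#' Ten equally spaced concentric circles C1-C10 are centered on the optic
#' chiasm with C10 at the tectal posterior boundary (radius of Ck is
#' `k/10 * |OC-TPB|`). Each circle is sampled at a fixed angular step and
#' the tract width at Ck is the arc length (radius times angular extent)
#' of the maximal contiguous run of tract-positive samples; a Euclidean
#' chord measure is available by option. Circles with no intersection
#' report width 0; when a circle crosses several disjoint tract limbs only
#' the largest run is reported, with a multiplicity warning.
#'
#' @param scene a [tract_scene].
#' @param step_deg angular sampling step in degrees (default 0.2).
#' @param measure `"arc"` (default) or `"chord"`.
#' @return numeric vector of 10 widths (px), named C1..C10.
#' @export
circle_widths <- function(scene, step_deg = 0.2, measure = c("arc", "chord")) {
  stopifnot(inherits(scene, "tract_scene"))
  measure <- match.arg(measure)
  D <- vnorm(scene$tpb - scene$oc)
  if (D == 0) stop("|OC-TPB| is zero")
  h <- nrow(scene$tract_mask); w <- ncol(scene$tract_mask)
  ang <- seq(0, 360 - step_deg, by = step_deg)
  ca <- cos(deg2rad(ang)); sa <- sin(deg2rad(ang))
  n <- length(ang)
  widths <- numeric(10)
  for (k in 1:10) {
    r <- k / 10 * D
    xi <- as.integer(round(scene$oc[1] + r * ca))
    yi <- as.integer(round(scene$oc[2] + r * sa))
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    hit <- logical(n)
    hit[ok] <- scene$tract_mask[cbind(yi[ok], xi[ok])]
    if (!any(hit)) {
      widths[k] <- 0
      next
    }
    # contiguous runs on the circle, with wraparound
    rl <- rle(hit)
    if (length(rl$lengths) > 1 && hit[1] && hit[n]) {
      # merge the wrapped run
      first <- rl$lengths[1]
      last <- rl$lengths[length(rl$lengths)]
      rl$lengths <- rl$lengths[-c(1, length(rl$lengths))]
      rl$values <- rl$values[-c(1, length(rl$values))]
      rl$lengths <- c(rl$lengths, first + last)
      rl$values <- c(rl$values, TRUE)
    }
    runs <- rl$lengths[rl$values]
    if (length(runs) > 1) {
      warning(sprintf(
        "circle C%d crosses %d disjoint tract runs; using the largest",
        k, length(runs)
      ))
    }
    extent_rad <- max(runs) * deg2rad(step_deg)
    widths[k] <- if (measure == "arc") {
      r * extent_rad
    } else {
      2 * r * sin(extent_rad / 2)
    }
  }
  stats::setNames(widths, paste0("C", 1:10))
}

#' Brain-size-normalized pre/post-turn tract widths
#'
#' Pre-turn width is the mean of C2-C4 and post-turn the mean of C5-C8,
#' each normalized to the brain size defined as the OC-TPB distance.
#'
#' @param widths numeric vector C1..C10 from [circle_widths].
#' @param oc,tpb landmark points (x, y) px.
#' @return list with `pre_width_norm` and `post_width_norm`
#'   (dimensionless).
#' @export
normalized_widths <- function(widths, oc, tpb) {
  if (length(widths) != 10) stop("widths must have 10 entries (C1..C10)")
  D <- vnorm(as.numeric(tpb) - as.numeric(oc))
  if (D == 0) stop("|OC-TPB| is zero")
  list(
    pre_width_norm = mean(widths[2:4]) / D,
    post_width_norm = mean(widths[5:8]) / D
  )
}

#' Mid-diencephalic turn (MDT) angle
#'
#' Deviation-from-straight angle in `[0, 180]` between the pre-turn bundle
#' (OC to the ventral side of the MDT) and the post-turn bundle (MDT to
#' the tip of the most pioneer axon). A collinear continuation gives 0, so
#' larger values mean a sharper caudal turn and `MDT < 45` flags
#' under-turning.
#'
#' @param oc,mdt_ventral,pioneer_tip landmark points (x, y) px.
#' @return angle in degrees, `[0, 180]`.
#' @export
mdt_angle <- function(oc, mdt_ventral, pioneer_tip) {
  v1 <- as.numeric(mdt_ventral) - as.numeric(oc)
  v2 <- as.numeric(pioneer_tip) - as.numeric(mdt_ventral)
  if (vnorm(v1) == 0 || vnorm(v2) == 0) stop("coincident landmark points")
  rad2deg(atan2(abs(cross2(v1, v2)), sum(v1 * v2)))
}

#' Tectal projection angle (TPA)
#'
#' Signed angle between the post-turn tract direction and the most
#' anteriorly projecting axon: positive when the axon deviates toward the
#' posterior tectum (TPB side of the tract axis), negative toward the
#' anterior side (TAB side). The TAB landmark is used only to orient the
#' sign when the TPB lies on the tract axis.
#'
#' @param post_turn_a,post_turn_b two points defining the post-turn tract
#'   direction (b - a must be nonzero).
#' @param anterior_axon_tip tip of the most anteriorly projecting axon.
#' @param tpb,tab tectal posterior / anterior boundary landmarks.
#' @return signed angle in degrees.
#' @export
tectal_projection_angle <- function(post_turn_a, post_turn_b,
                                    anterior_axon_tip, tpb, tab) {
  a <- as.numeric(post_turn_a); b <- as.numeric(post_turn_b)
  d <- b - a
  if (vnorm(d) == 0) stop("post-turn direction is zero-length")
  v <- as.numeric(anterior_axon_tip) - b
  if (vnorm(v) == 0) stop("anterior axon tip coincides with the tract end")
  unsigned <- rad2deg(atan2(abs(cross2(d, v)), sum(d * v)))
  s_tip <- sign(cross2(d, v))
  if (s_tip == 0) return(0)
  s_post <- sign(cross2(d, as.numeric(tpb) - a))
  if (s_post == 0) s_post <- -sign(cross2(d, as.numeric(tab) - a))
  if (s_post == 0) stop("TPB and TAB both lie on the tract axis")
  if (s_tip == s_post) unsigned else -unsigned
}

#' All tract metrics for one scene
#'
#' @param scene a [tract_scene].
#' @param ... passed to [circle_widths].
#' @return one-row `data.frame` with C1-C10 widths, normalized pre/post
#'   widths, MDT angle, TPA, and the `mdt_lt_45` flag.
#' @export
tract_metrics <- function(scene, ...) {
  widths <- circle_widths(scene, ...)
  nw <- normalized_widths(widths, scene$oc, scene$tpb)
  mdt <- mdt_angle(scene$oc, scene$mdt_ventral, scene$pioneer_tip)
  tpa <- tectal_projection_angle(
    scene$mdt_ventral, scene$pioneer_tip, scene$anterior_axon_tip,
    scene$tpb, scene$tab
  )
  out <- as.data.frame(as.list(widths))
  out$pre_width_norm <- nw$pre_width_norm
  out$post_width_norm <- nw$post_width_norm
  out$mdt_angle_deg <- mdt
  out$tpa_deg <- tpa
  out$mdt_lt_45 <- mdt < 45
  out
}

#' Penetrance of tract phenotypes, with Fisher's exact test
#'
#' For each group, the fraction of brains with an under-turned MDT
#' (`mdt_angle_deg < mdt_threshold`) and with posterior-tectum avoidance
#' (`tpa_deg < control_mean_tpa`). Each non-reference group is compared
#' with the first (reference) group by a two-sided Fisher's exact test on
#' the 2x2 count table.
#'
#' @param groups named list of data.frames with columns `mdt_angle_deg`
#'   and `tpa_deg` (e.g. rows of [tract_metrics]); the first entry is the
#'   control group.
#' @param control_mean_tpa TPA threshold in degrees (mean control TPA;
#'   -8.6 in the reference dataset).
#' @param mdt_threshold MDT threshold in degrees (default 45).
#' @return data.frame with one row per group: n, counts and fractions
#'   below each threshold, and Fisher p-values vs the reference group.
#' @export
penetrance <- function(groups, control_mean_tpa, mdt_threshold = 45) {
  if (length(groups) < 1) stop("need at least one group")
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  tab <- do.call(rbind, lapply(names(groups), function(g) {
    m <- groups[[g]]
    n <- nrow(m)
    data.frame(
      group = g, n = n,
      n_mdt_lt = sum(m$mdt_angle_deg < mdt_threshold),
      frac_mdt_lt = mean(m$mdt_angle_deg < mdt_threshold),
      n_tpa_lt = sum(m$tpa_deg < control_mean_tpa),
      frac_tpa_lt = mean(m$tpa_deg < control_mean_tpa)
    )
  }))
  ref <- tab[1, ]
  fisher_p <- function(k1, n1, k2, n2) {
    stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2))$p.value
  }
  tab$fisher_p_mdt <- c(NA_real_, vapply(seq_len(nrow(tab))[-1], function(i) {
    fisher_p(ref$n_mdt_lt, ref$n, tab$n_mdt_lt[i], tab$n[i])
  }, numeric(1)))
  tab$fisher_p_tpa <- c(NA_real_, vapply(seq_len(nrow(tab))[-1], function(i) {
    fisher_p(ref$n_tpa_lt, ref$n, tab$n_tpa_lt[i], tab$n[i])
  }, numeric(1)))
  tab
}
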