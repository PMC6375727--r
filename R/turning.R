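#' Turning angle of a growth cone between 0 and 60 min
#'
#' Angle between the initial axon-shaft direction and the growth-cone
#' displacement vector over the assay, signed by the pipette side:
#' positive when the growth cone moves into the half-plane (relative to
#' the shaft axis through the starting position) that contains the
#' pipette (attraction), negative when it moves away (repulsion).
#' Displacement parallel to the shaft gives 0; anti-parallel gives 180
#' (side undefined, reported unsigned).
#'
#' @param shaft_dir_t0 length-2 initial shaft direction (normalized
#'   internally).
#' @param gc_pos_t0,gc_pos_t60 growth-cone positions at 0 and 60 min,
#'   (x, y) px.
#' @param pipette_pos pipette position, (x, y) px.
#' @return signed turning angle in degrees, |angle| <= 180.
#' @export
turning_angle <- function(shaft_dir_t0, gc_pos_t0, gc_pos_t60, pipette_pos) {
  s <- normalize(as.numeric(shaft_dir_t0))
  d <- as.numeric(gc_pos_t60) - as.numeric(gc_pos_t0)
  if (vnorm(d) == 0) stop("no net growth: displacement is zero")
  unsigned <- rad2deg(atan2(abs(cross2(s, d)), sum(s * d)))
  cr_d <- cross2(s, d)
  cr_p <- cross2(s, as.numeric(pipette_pos) - as.numeric(gc_pos_t0))
  if (cr_d == 0) return(unsigned)      # 0 or 180, no defined side
  sgn <- if (sign(cr_d) == sign(cr_p)) 1 else -1
  sgn * unsigned
}

#' Summary statistics for a set of turning angles
#'
#' Returns mean, SEM, n and the empirical cumulative distribution (sorted
#' angles with plotting positions i/n). When a second group is supplied,
#' the groups are compared by an unpaired two-sample t-test (pooled by
#' default, Welch by option).
#'
#' @param angles numeric vector of turning angles (degrees).
#' @param angles2 optional second group for comparison.
#' @param welch use the Welch (unequal-variance) t-test.
#' @return list with `mean`, `sem`, `n`, `ecdf` (data.frame `angle`,
#'   `cum_fraction`), and, with two groups, `t_statistic` and `p_value`.
#' @export
turning_summary <- function(angles, angles2 = NULL, welch = FALSE) {
  if (length(angles) < 1) stop("need at least one angle")
  n <- length(angles)
  srt <- sort(angles)
  out <- list(
    mean = mean(angles),
    sem = if (n > 1) stats::sd(angles) / sqrt(n) else NA_real_,
    n = n,
    ecdf = data.frame(angle = srt, cum_fraction = seq_len(n) / n)
  )
  if (!is.null(angles2)) {
    tt <- stats::t.test(angles, angles2, var.equal = !welch)
    out$t_statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
    out$mean2 <- mean(angles2)
    out$n2 <- length(angles2)
  }
  out
}

#' Turning angles for a table of assays
#'
#' @param tab data.frame with columns `x0, y0, x60, y60, shaft_dx,
#'   shaft_dy, pip_x, pip_y` (one row per axon).
#' @return the table with a `turning_angle_deg` column appended.
#' @export
turning_angles_table <- function(tab) {
  need <- c("x0", "y0", "x60", "y60", "shaft_dx", "shaft_dy", "pip_x", "pip_y")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("turning table is missing columns: ", paste(miss, collapse = ", "))
  }
  tab$turning_angle_deg <- vapply(seq_len(nrow(tab)), function(i) {
    turning_angle(
      c(tab$shaft_dx[i], tab$shaft_dy[i]),
      c(tab$x0[i], tab$y0[i]),
      c(tab$x60[i], tab$y60[i]),
      c(tab$pip_x[i], tab$pip_y[i])
    )
  }, numeric(1))
  tab
}
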