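# Shared geometry and RNG helpers.

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Unit vector at an angle in image coordinates
#'
#' Angles are measured in degrees from the +x axis, with y increasing
#' downward (row-major image convention shared by all generators and
#' analyses).
#'
#' @param angle_deg angle in degrees.
#' @return numeric length-2 unit vector (x, y).
#' @keywords internal
unit_vector <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  c(cos(a), sin(a))
}

# 2-D cross product z-component: d x v.
cross2 <- function(d, v) d[1] * v[2] - d[2] * v[1]

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Rotate a 2-D vector by an angle in degrees (y-down convention: positive
# angles rotate from +x toward +y, i.e. clockwise on screen).
rotate2 <- function(v, angle_deg) {
  a <- deg2rad(angle_deg)
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a base seed, kept below 2^31
# (double arithmetic: exact well beyond the 32-bit integer range).
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %%
               2147483647)
}
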