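# Inverse of the trigamma function by Newton iteration on 1/psi'(x)
# (globally convergent because 1/trigamma is nearly linear; same scheme
# as the classic empirical-Bayes variance-moderation literature).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

# Replicate columns of a pSILAC table.
rep_cols <- function(table) grep("^rep[0-9]+$", names(table), value = TRUE)

# Per-protein mean, sample variance and non-missing count.
row_moments <- function(table) {
  reps <- as.matrix(table[, rep_cols(table), drop = FALSE])
  n_g <- rowSums(!is.na(reps))
  mean_g <- rowMeans(reps, na.rm = TRUE)
  mean_g[n_g == 0] <- NA_real_
  s2_g <- apply(reps, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2) stats::var(r) else NA_real_
  })
  list(n = n_g, mean = mean_g, s2 = s2_g)
}

#' Fit the empirical-Bayes moderated one-sample t-test
#'
#' Tests, for every protein, whether its mean replicate log2 H/M ratio
#' differs from zero, with variance moderation: the variance prior
#' hyperparameters (`d0`, `s0_sq`) are estimated from the ensemble of
#' per-protein sample variances by moment matching on the log variances
#' (digamma/trigamma relations; the Smyth-2004 scheme), each variance is
#' shrunk to its posterior
#' `s2_tilde = (d0*s0_sq + (n_g-1)*s2_g) / (d0 + n_g - 1)`, and the
#' moderated statistic `t = mean / (s_tilde/sqrt(n_g))` is referred to a t
#' distribution with `d0 + n_g - 1` degrees of freedom (two-sided).
#' Proteins with fewer than 2 non-missing replicates are reported
#' untested (`NA`).
#'
#' The limits are exposed for validation: forcing `d0 = 0` reproduces the
#' ordinary one-sample t-test; `d0 = Inf` gives the common-variance
#' statistic `mean*sqrt(n)/s0` with a normal tail.
#'
#' @param table pSILAC data.frame with `protein_id` and `rep*` columns.
#' @param d0_override optional fixed prior df (0, positive, or `Inf`)
#'   bypassing estimation.
#' @param s0_sq_override optional fixed prior variance; with
#'   `d0_override = Inf` and no value supplied, the df-weighted pooled
#'   sample variance is used.
#' @return object of class `ebayes_fit`: list with `d0`, `s0_sq`,
#'   `results` (data.frame `protein_id, log2fc, n, s2, s2_tilde, t_mod,
#'   df, p`).
#' @export
fit_ebayes <- function(table, d0_override = NULL, s0_sq_override = NULL) {
  mo <- row_moments(table)
  tested <- which(mo$n >= 2)
  if (is.null(d0_override) && length(tested) < 10) {
    stop("hyperparameter fitting needs >= 10 proteins with >= 2 replicates")
  }

  if (is.null(d0_override)) {
    hp <- fit_variance_prior(mo$s2[tested], mo$n[tested] - 1)
    d0 <- hp$d0
    s0_sq <- hp$s0_sq
  } else {
    d0 <- d0_override
    if (d0 < 0) stop("d0_override must be >= 0")
    s0_sq <- if (!is.null(s0_sq_override)) {
      s0_sq_override
    } else if (is.infinite(d0)) {
      df <- mo$n[tested] - 1
      sum(df * mo$s2[tested]) / sum(df)
    } else {
      NA_real_  # unused when d0 = 0
    }
    if (is.finite(d0) && d0 > 0 && is.null(s0_sq_override)) {
      stop("a finite positive d0_override requires s0_sq_override")
    }
  }

  n <- length(mo$n)
  s2_tilde <- t_mod <- df_mod <- p <- rep(NA_real_, n)
  for (i in tested) {
    ng <- mo$n[i]
    if (is.infinite(d0)) {
      s2_tilde[i] <- s0_sq
      df_mod[i] <- Inf
      t_mod[i] <- mo$mean[i] * sqrt(ng) / sqrt(s0_sq)
      p[i] <- 2 * stats::pnorm(-abs(t_mod[i]))
    } else {
      s2_tilde[i] <- (d0 * ifelse(d0 > 0, s0_sq, 0) + (ng - 1) * mo$s2[i]) /
        (d0 + ng - 1)
      df_mod[i] <- d0 + ng - 1
      t_mod[i] <- mo$mean[i] / (sqrt(s2_tilde[i]) / sqrt(ng))
      p[i] <- 2 * stats::pt(-abs(t_mod[i]), df = df_mod[i])
    }
  }

  structure(list(
    d0 = d0, s0_sq = s0_sq,
    method = "moderated one-sample t (log-variance moment matching)",
    results = data.frame(
      protein_id = table$protein_id,
      log2fc = mo$mean, n = mo$n, s2 = mo$s2,
      s2_tilde = s2_tilde, t_mod = t_mod, df = df_mod, p = p
    )
  ), class = "ebayes_fit")
}

#' Estimate the scaled-inverse-chi-square variance prior
#'
#' Moment matching on `log(s2_g)`: with `z_g = log(s2_g)` and residual
#' degrees of freedom `d_g`, `e_g = z_g - digamma(d_g/2) + log(d_g/2)` has
#' mean `log(s0_sq) - digamma(d0/2) + log(d0/2)` and excess variance
#' `trigamma(d0/2)` beyond `trigamma(d_g/2)`; `d0` is recovered through
#' the trigamma inverse. Non-positive excess variance yields the
#' common-variance limit `d0 = Inf`.
#'
#' @param s2 per-protein sample variances (> 0 where defined).
#' @param df per-protein residual degrees of freedom (n_g - 1).
#' @return list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  keep <- is.finite(s2) & df > 0 & s2 > 0
  s2 <- s2[keep]; df <- df[keep]
  if (length(s2) < 2) stop("need >= 2 positive sample variances")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2) * n / (n - 1) - mean(trigamma(df / 2))
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(ebar)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' @export
print.ebayes_fit <- function(x, ...) {
  cat(sprintf(
    "<ebayes_fit> d0 = %.3g, s0_sq = %.4g, %d proteins (%d tested)\n",
    x$d0, x$s0_sq, nrow(x$results), sum(!is.na(x$results$p))
  ))
  invisible(x)
}
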