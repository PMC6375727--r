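#' Simulate a pulsed-SILAC protein ratio table
#'
#' Generates per-protein replicate log2 H/M ratios from the hierarchical
#' model the moderated one-sample test assumes: per-protein variances
#' follow a scaled-inverse-chi-square prior with `d0` degrees of freedom
#' and scale `s0_sq`; true means are 0 with probability
#' `1 - frac_regulated` and otherwise +/-`effect_log2` with equiprobable
#' sign; replicate values are Normal(mu_g + global_offset, sigma_g^2),
#' where `global_offset` is the systematic shift the median-centering
#' stage must remove. Ratio counts are >= 1 with a configurable fraction
#' below 2 to exercise the minimum-ratio-count filter; light-channel
#' intensities are log-normal. Optionally attaches random amino-acid
#' sequences for iBAQ.
#'
#' @param n_proteins number of proteins.
#' @param n_replicates biological replicates (>= 2; the reference design
#'   used 3).
#' @param frac_regulated fraction of proteins with a true effect, `[0,1]`.
#' @param effect_log2 absolute true log2 fold change of regulated
#'   proteins.
#' @param d0 prior degrees of freedom of the variance distribution.
#' @param s0_sq prior variance scale (log2 units squared).
#' @param global_offset systematic log2 shift added to every value.
#' @param frac_low_count fraction of proteins with ratio_count = 1.
#' @param with_sequences attach random tryptic-digestible sequences.
#' @param seed integer RNG seed.
#' @return list with `table` (data.frame: `protein_id`, `rep1..repK`,
#'   `ratio_count`, `light_intensity`, optional `sequence`) and
#'   `ground_truth` (true means, variances and hyperparameters).
#' @export
make_psilac_table <- function(n_proteins = 1000, n_replicates = 3,
                              frac_regulated = 0.1, effect_log2 = 1,
                              d0 = 4, s0_sq = 0.04, global_offset = 0,
                              frac_low_count = 0.1,
                              with_sequences = FALSE, seed = 1L) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (frac_regulated < 0 || frac_regulated > 1) {
    stop("frac_regulated must lie in [0, 1]")
  }
  if (d0 <= 0 || s0_sq <= 0) stop("d0 and s0_sq must be > 0")

  with_seed(seed, {
    sigma_sq <- d0 * s0_sq / stats::rchisq(n_proteins, df = d0)
    regulated <- stats::runif(n_proteins) < frac_regulated
    mu <- ifelse(
      regulated,
      effect_log2 * sample(c(-1, 1), n_proteins, replace = TRUE),
      0
    )
    reps <- matrix(
      stats::rnorm(n_proteins * n_replicates,
                   mean = rep(mu + global_offset, n_replicates),
                   sd = rep(sqrt(sigma_sq), n_replicates)),
      nrow = n_proteins
    )
    colnames(reps) <- paste0("rep", seq_len(n_replicates))
    ratio_count <- ifelse(
      stats::runif(n_proteins) < frac_low_count,
      1L,
      2L + stats::rpois(n_proteins, 3)
    )
    light <- stats::rlnorm(n_proteins, meanlog = log(1e6), sdlog = 1)

    tab <- data.frame(
      protein_id = sprintf("P%05d", seq_len(n_proteins)),
      reps,
      ratio_count = ratio_count,
      light_intensity = light
    )
    if (with_sequences) {
      aa <- c("A", "G", "L", "S", "V", "E", "D", "T", "I", "P", "K", "R")
      tab$sequence <- vapply(seq_len(n_proteins), function(i) {
        paste(sample(aa, 240, replace = TRUE, prob = c(rep(1, 10), 0.6, 0.6)),
              collapse = "")
      }, character(1))
    }

    gt <- ground_truth("psilac", list(
      n_proteins = n_proteins, n_replicates = n_replicates,
      frac_regulated = frac_regulated, effect_log2 = effect_log2,
      d0 = d0, s0_sq = s0_sq, global_offset = global_offset,
      frac_low_count = frac_low_count,
      true_mu = mu, true_sigma_sq = sigma_sq, regulated = regulated
    ), seed)
    list(table = tab, ground_truth = gt)
  })
}
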