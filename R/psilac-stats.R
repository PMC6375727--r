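#' Filter proteins by minimum ratio count
#'
#' Retains proteins quantified from at least `min_count` peptide ratios
#' (the reference processing used a minimum ratio count of 2).
#'
#' @param table pSILAC data.frame with a `ratio_count` column.
#' @param min_count minimum ratio count (default 2).
#' @return the filtered table; the number of removed proteins is reported
#'   via `message()`.
#' @export
filter_min_ratio_count <- function(table, min_count = 2) {
  if (!"ratio_count" %in% names(table)) {
    stop("table has no ratio_count column")
  }
  keep <- table$ratio_count >= min_count
  message(sprintf(
    "filter_min_ratio_count: removed %d of %d proteins (ratio_count < %d)",
    sum(!keep), length(keep), min_count
  ))
  table[keep, , drop = FALSE]
}

#' Median-center a table of log2 ratios
#'
#' Subtracts the global median of the per-protein mean log2 ratios from
#' every replicate value, centering the ratio distribution at 0 on the
#' log2 scale so that comparable numbers of proteins appear up- and
#' downregulated. Idempotent: centering a centered table is a no-op.
#'
#' @param table pSILAC data.frame with `rep*` columns.
#' @return the centered table, with the fitted offset in
#'   `attr(, "offset")`.
#' @export
median_center <- function(table) {
  cols <- rep_cols(table)
  if (!length(cols)) stop("table has no replicate (rep*) columns")
  means <- rowMeans(as.matrix(table[, cols, drop = FALSE]), na.rm = TRUE)
  means <- means[is.finite(means)]
  if (!length(means)) stop("no protein has any ratio value")
  offset <- stats::median(means)
  table[, cols] <- table[, cols, drop = FALSE] - offset
  attr(table, "offset") <- offset
  table
}

#' Simplified iBAQ abundance
#'
#' Intensity-based absolute quantification: the summed (light-channel)
#' intensity divided by the number of theoretically observable tryptic
#' peptides. The in-silico digest cleaves C-terminal to K or R except
#' before P, with zero missed cleavages; observable peptides have length
#' within `[min_len, max_len]` residues.
#'
#' @param light_intensity summed protein intensity (AU).
#' @param sequence amino-acid sequence (standard one-letter codes).
#' @param min_len,max_len observable peptide length bounds (defaults 7
#'   and 30).
#' @return the iBAQ value, or `NA` (with a warning) when no peptide is
#'   observable.
#' @export
ibaq <- function(light_intensity, sequence, min_len = 7, max_len = 30) {
  if (!nzchar(sequence)) stop("sequence is empty")
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence)) {
    stop("sequence contains invalid residue characters")
  }
  peps <- tryptic_peptides(sequence)
  lens <- nchar(peps)
  n_obs <- sum(lens >= min_len & lens <= max_len)
  if (n_obs == 0) {
    warning("iBAQ undefined: no observable tryptic peptide")
    return(NA_real_)
  }
  light_intensity / n_obs
}

#' In-silico tryptic digest
#'
#' @param sequence amino-acid string.
#' @return character vector of peptides (cleaved after K/R, not before P,
#'   zero missed cleavages).
#' @export
tryptic_peptides <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1] != "P"]
  starts <- c(1, cut_after + 1)
  ends <- c(cut_after, n)
  substring(sequence, starts, ends)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts the m p-values ascending, forms `p_(i) * m / i`, takes the
#' running minimum from the largest rank down (step-up), caps at 1 and
#' returns the adjusted values in input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Call significantly regulated proteins
#'
#' Flags proteins with the chosen p-value column strictly below `alpha`
#' and annotates the direction of regulation from the sign of the log2
#' fold change. Both raw-p and BH-adjusted modes are first-class: the
#' reference analysis reports "p < 0.10" while its methods describe BH
#' correction, so the mode is an explicit argument.
#'
#' @param results data.frame with columns `log2fc`, `p` and (for the
#'   adjusted mode) `p_adj`.
#' @param alpha significance threshold (default 0.10, strict `<`).
#' @param use_adjusted use `p_adj` instead of raw `p`.
#' @return `results` with `significant` (logical) and `direction`
#'   (`"up"`, `"down"`, or `NA` for non-significant/untested) appended.
#' @export
call_significant <- function(results, alpha = 0.10, use_adjusted = TRUE) {
  col <- if (use_adjusted) "p_adj" else "p"
  if (!col %in% names(results)) {
    stop("results table has no '", col, "' column")
  }
  pv <- results[[col]]
  results$significant <- !is.na(pv) & pv < alpha
  results$direction <- ifelse(
    results$significant,
    ifelse(results$log2fc > 0, "up", "down"),
    NA_character_
  )
  results
}

#' One-call pSILAC analysis pipeline
#'
#' Enforces the stage order: minimum-ratio-count filter, median centering,
#' moderated one-sample t-test, BH adjustment, significance calling.
#'
#' @param table pSILAC data.frame (`protein_id`, `rep*`, `ratio_count`,
#'   optional `light_intensity`, `sequence`).
#' @param min_count minimum ratio count (default 2).
#' @param alpha significance threshold (default 0.10).
#' @param use_adjusted call significance on BH-adjusted p-values (TRUE)
#'   or raw p-values (FALSE).
#' @param d0_override,s0_sq_override optional prior overrides, see
#'   [fit_ebayes].
#' @return list with `results` (per-protein data.frame incl. `p_adj`,
#'   `significant`, `direction`), `model` (`d0`, `s0_sq`, method label),
#'   and `offset` (the removed median shift).
#' @export
psilac_pipeline <- function(table, min_count = 2, alpha = 0.10,
                            use_adjusted = TRUE,
                            d0_override = NULL, s0_sq_override = NULL) {
  tab <- filter_min_ratio_count(table, min_count)
  tab <- median_center(tab)
  fit <- fit_ebayes(tab, d0_override, s0_sq_override)
  res <- fit$results
  tested <- !is.na(res$p)
  res$p_adj <- NA_real_
  res$p_adj[tested] <- bh_adjust(res$p[tested])
  res <- call_significant(res, alpha = alpha, use_adjusted = use_adjusted)
  list(
    results = res,
    model = list(d0 = fit$d0, s0_sq = fit$s0_sq, method = fit$method),
    offset = attr(tab, "offset")
  )
}

#' Correlation between pSILAC and qIF fold changes
#'
#' Pearson correlation between mass-spectrometry log2 fold changes and
#' quantitative-immunofluorescence log2 ratios for the same proteins.
#'
#' @param psilac_log2fc,qif_log2 paired numeric vectors (n >= 3).
#' @return list with `r`, `p_value`, `n`.
#' @export
psilac_qif_correlation <- function(psilac_log2fc, qif_log2) {
  if (length(psilac_log2fc) != length(qif_log2)) {
    stop("paired vectors must have equal length")
  }
  if (length(psilac_log2fc) < 3) stop("need at least 3 pairs")
  if (stats::sd(psilac_log2fc) == 0 || stats::sd(qif_log2) == 0) {
    stop("zero variance in one coordinate")
  }
  ct <- stats::cor.test(psilac_log2fc, qif_log2, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = length(psilac_log2fc))
}

#' Overlap of NSPs with upstream-regulator target sets
#'
#' For each translational regulator, the number and fraction of newly
#' synthesized proteins (NSPs) shared with its target set, plus the
#' fraction of NSPs appearing in no regulator set (pathway-specific).
#' Optionally computes hypergeometric enrichment given a background size.
#'
#' @param nsp_set character vector of NSP identifiers.
#' @param regulator_targets named list of identifier vectors.
#' @param background_size optional total identifier universe size for
#'   enrichment (`phyper` upper tail).
#' @return list with `per_regulator` (data.frame `regulator, n_targets,
#'   n_shared, frac_of_nsps`, optional `enrichment_p`) and
#'   `specific_fraction`.
#' @export
regulator_overlap <- function(nsp_set, regulator_targets,
                              background_size = NULL) {
  nsp_set <- unique(nsp_set)
  if (!length(nsp_set)) stop("NSP set is empty")
  per <- do.call(rbind, lapply(names(regulator_targets), function(rg) {
    tg <- unique(regulator_targets[[rg]])
    shared <- length(intersect(nsp_set, tg))
    row <- data.frame(
      regulator = rg, n_targets = length(tg), n_shared = shared,
      frac_of_nsps = shared / length(nsp_set)
    )
    if (!is.null(background_size)) {
      if (background_size < length(union(nsp_set, tg))) {
        stop("background_size smaller than the observed union")
      }
      row$enrichment_p <- stats::phyper(
        shared - 1, length(tg), background_size - length(tg),
        length(nsp_set), lower.tail = FALSE
      )
    }
    row
  }))
  all_targets <- unique(unlist(regulator_targets))
  list(
    per_regulator = per,
    specific_fraction = mean(!nsp_set %in% all_targets)
  )
}
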