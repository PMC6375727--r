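test_that("minimum ratio count filter keeps counts >= threshold", {
  tab <- data.frame(protein_id = c("a", "b", "c"),
                    rep1 = 0, rep2 = 0, ratio_count = c(1, 2, 3))
  expect_message(out <- filter_min_ratio_count(tab, 2), "removed 1 of 3")
  expect_equal(out$protein_id, c("b", "c"))
  expect_equal(nrow(suppressMessages(filter_min_ratio_count(tab, 0))), 3)

  gen <- make_psilac_table(n_proteins = 1000, frac_low_count = 0.1,
                          seed = 61)
  kept <- nrow(suppressMessages(filter_min_ratio_count(gen$table, 2)))
  # binomial 99% CI around 0.9 at n = 1000
  ci <- 0.9 + c(-1, 1) * qnorm(0.995) * sqrt(0.9 * 0.1 / 1000)
  expect_gte(kept / 1000, ci[1])
  expect_lte(kept / 1000, ci[2])
})

test_that("median centering zeroes the median of per-protein means", {
  tab <- data.frame(protein_id = c("a", "b", "c"),
                    rep1 = c(0.5, 1.0, 1.5), rep2 = c(0.5, 1.0, 1.5),
                    ratio_count = 2)
  out <- median_center(tab)
  expect_equal(out$rep1, c(-0.5, 0, 0.5))
  expect_equal(attr(out, "offset"), 1.0)
  # idempotent on its own output
  out2 <- median_center(out)
  expect_equal(attr(out2, "offset"), 0)
  expect_equal(out2$rep1, out$rep1)

  gen <- make_psilac_table(n_proteins = 10000, global_offset = 0.7,
                          frac_regulated = 0, seed = 62)
  centered <- median_center(gen$table)
  expect_equal(attr(centered, "offset"), 0.7, tolerance = 0.02 / 0.7)
  means <- rowMeans(as.matrix(centered[, c("rep1", "rep2", "rep3")]))
  expect_equal(median(means), 0, tolerance = 1e-12)
})

test_that("iBAQ divides intensity by the observable tryptic peptide count", {
  expect_equal(tryptic_peptides("AAAAAAAKAAAAAAAA"),
               c("AAAAAAAK", "AAAAAAAA"))
  expect_equal(ibaq(10, "AAAAAAAKAAAAAAAA"), 5)
  # no cleavage site: the whole chain is the single peptide
  expect_equal(ibaq(42, "AAAAAAAAAA"), 42)
  # K before P blocks cleavage
  expect_equal(tryptic_peptides("AAAKPAAAK"), c("AAAKPAAAK"))
  # all peptides below the length bound: undefined
  expect_warning(out <- ibaq(10, "KRK"), "undefined")
  expect_true(is.na(out))
  expect_error(ibaq(10, "AXZ!"), "invalid residue")
  expect_error(ibaq(10, ""), "empty")
})

test_that("BH adjustment reproduces the step-up construction", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(91)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-15)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    # invariance to input order
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
    # adjusted never below raw
    expect_true(all(bh_adjust(p) >= p - 1e-15))
  }
})

test_that("significance calling uses a strict threshold and sign direction", {
  res <- data.frame(log2fc = c(1, -1, 0.5), p = c(0.09, 0.10, 0.5),
                    p_adj = c(0.10, 0.12, 0.6))
  raw <- call_significant(res, alpha = 0.10, use_adjusted = FALSE)
  expect_equal(raw$significant, c(TRUE, FALSE, FALSE))
  expect_equal(raw$direction, c("up", NA, NA))
  adj <- call_significant(res, alpha = 0.10, use_adjusted = TRUE)
  expect_equal(adj$significant, c(FALSE, FALSE, FALSE))
  all_in <- call_significant(res, alpha = 1, use_adjusted = FALSE)
  expect_true(all(all_in$significant))
})

test_that("pSILAC/qIF correlation is Pearson's r with its test", {
  x <- c(-1, 0, 1, 2)
  out <- psilac_qif_correlation(x, 2 * x + 3)
  expect_equal(out$r, 1)
  expect_error(psilac_qif_correlation(x, rep(1, 4)), "zero variance")
  expect_error(psilac_qif_correlation(x[1:2], x[1:2]), "at least 3")

  # Monte-Carlo mean of r at rho = 0.9, n = 12 vs the Fisher-z oracle
  set.seed(93)
  rho <- 0.9; n <- 12
  rs <- vapply(1:1000, function(i) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    psilac_qif_correlation(x, y)$r
  }, numeric(1))
  oracle <- integrate(function(z) {
    tanh(z) * dnorm(z, atanh(rho), 1 / sqrt(n - 3))
  }, -Inf, Inf)$value
  expect_equal(mean(rs), oracle, tolerance = 0.02 / abs(oracle))
})

test_that("regulator overlap reports shared and pathway-specific fractions", {
  nsp <- paste0("p", 1:10)
  disj <- regulator_overlap(nsp, list(reg1 = paste0("q", 1:5)))
  expect_equal(disj$specific_fraction, 1.0)
  expect_equal(disj$per_regulator$n_shared, 0)

  sub <- regulator_overlap(nsp, list(reg1 = paste0("p", 1:20)))
  expect_equal(sub$per_regulator$frac_of_nsps, 1.0)
  expect_equal(sub$specific_fraction, 0)

  # mean random overlap matches the hypergeometric expectation 75*200/5000
  set.seed(94)
  ov <- vapply(1:1000, function(i) {
    a <- sample(5000, 75)
    b <- sample(5000, 200)
    regulator_overlap(a, list(r = b))$per_regulator$n_shared
  }, numeric(1))
  expect_equal(mean(ov), 3, tolerance = 0.5 / 3)

  expect_error(regulator_overlap(character(0), list()), "empty")
})

test_that("the full pSILAC pipeline enforces order and is reproducible", {
  gen <- make_psilac_table(n_proteins = 800, frac_regulated = 0.1,
                          effect_log2 = 1, global_offset = 0.4, seed = 95)
  out <- suppressMessages(psilac_pipeline(gen$table, alpha = 0.10,
                                          use_adjusted = TRUE))
  expect_equal(out$offset, 0.4, tolerance = 0.1)
  res <- out$results
  tested <- !is.na(res$p)
  expect_true(all(res$p_adj[tested] >= res$p[tested] - 1e-15))
  expect_true(all(res$direction[res$significant] %in% c("up", "down")))
  # called proteins are enriched in truly regulated ones
  gt <- gen$ground_truth$parameters
  kept_ids <- res$protein_id
  truth <- gt$regulated[match(kept_ids, gen$table$protein_id)]
  expect_gt(mean(truth[res$significant]), mean(truth))
})
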