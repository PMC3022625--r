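# Relative quantification and comparative-CT.

make_counts <- function(treated, untreated) {
  genes <- names(treated)
  m <- cbind(treated = unname(treated), untreated = unname(untreated))
  rownames(m) <- genes
  structure(list(counts = m,
                 unassigned = c(treated = 0L, untreated = 0L),
                 ambiguous = c(treated = 0L, untreated = 0L),
                 total = colSums(m)), class = "tag_count_table")
}

test_that("relative expression ratio is the control-normalised count ratio", {
  ct <- make_counts(c(A = 20L, ctrl = 40L), c(A = 10L, ctrl = 40L))
  est <- relative_expression(ct, "treated", "untreated", "ctrl")
  expect_equal(est$ratio, 2.0)
  expect_equal(est$log2_ratio, 1.0)
  expect_true(est$ci_low <= est$ratio && est$ratio <= est$ci_high)
  # Katz interval, computed directly
  se <- sqrt(1 / 20 + 1 / 40 + 1 / 10 + 1 / 40)
  expect_equal(est$ci_low, 2 * exp(-qnorm(0.975) * se))
  expect_equal(est$ci_high, 2 * exp(qnorm(0.975) * se))
})

test_that("identical samples give ratio 1 and unchanged calls", {
  cts <- c(A = 30L, B = 7L, ctrl = 50L)
  est <- relative_expression(make_counts(cts, cts), "treated", "untreated",
                             "ctrl")
  expect_true(all(est$ratio == 1))
  expect_true(all(est$call == "unchanged"))
})

test_that("zero counts are continuity-corrected and flagged; zero control errors", {
  ct <- make_counts(c(A = 0L, ctrl = 40L), c(A = 10L, ctrl = 40L))
  est <- relative_expression(ct, "treated", "untreated", "ctrl")
  expect_true(est$continuity_corrected)
  expect_equal(est$ratio, (0.5 / 40) / (10.5 / 40))
  bad <- make_counts(c(A = 5L, ctrl = 0L), c(A = 5L, ctrl = 10L))
  expect_error(relative_expression(bad, "treated", "untreated", "ctrl"),
               "zero in sample 'treated'")
})

test_that("relative expression is scale-invariant in sequencing depth", {
  set.seed(51)
  tr <- setNames(rpois(10, 50) + 1L, paste0("g", 1:10))
  un <- setNames(rpois(10, 50) + 1L, paste0("g", 1:10))
  names(tr)[1] <- names(un)[1] <- "ctrl"
  est1 <- relative_expression(make_counts(tr, un), "treated", "untreated",
                              "ctrl")
  est2 <- relative_expression(make_counts(tr * 7L, un), "treated",
                              "untreated", "ctrl")
  expect_equal(est1$ratio, est2$ratio)
})

test_that("delta-CT follows the control-minus-target convention, replicates averaged", {
  rec <- data.frame(sample_id = "s1", gene_id = c("g", "ctrl"),
                    replicate = 1L, ct = c(18, 20))
  d <- delta_ct(rec, "ctrl")
  expect_equal(d$dct_control_minus_target, 2)
  rec2 <- data.frame(sample_id = "s1", gene_id = c("g", "g", "g", "ctrl"),
                     replicate = c(1:3, 1L), ct = c(19.9, 20.0, 20.1, 22.0))
  expect_equal(delta_ct(rec2, "ctrl")$dct_control_minus_target, 2)
  rec3 <- data.frame(sample_id = "s1", gene_id = c("g", "ctrl"),
                     replicate = 1L, ct = c(20, 20))
  expect_equal(delta_ct(rec3, "ctrl")$dct_control_minus_target, 0)
  expect_error(delta_ct(data.frame(sample_id = "s1", gene_id = "g",
                                   replicate = 1L, ct = 20), "ctrl"),
               "missing control")
  expect_error(delta_ct(transform(rec, ct = c(18, 50)), "ctrl"), "45")
})

test_that("comparative-CT fold changes follow 2^ddCT exactly", {
  expect_identical(ddct_fold(1, 0), 2)
  expect_identical(ddct_fold(0, 0), 1)
  expect_identical(ddct_fold(-2, 0), 0.25)
  expect_identical(ddct_fold(3, 1), 4)
})

test_that("noise-free CT values generated from a known fold return it exactly", {
  # fold F = 8 for gene g: treated weight 8x untreated, control equal
  w <- c(g = 0.2, ctrl = 0.1)
  rec <- rbind(
    data.frame(sample_id = "untreated", gene_id = names(w), replicate = 1L,
               ct = 30 - log2(w)),
    data.frame(sample_id = "treated", gene_id = names(w), replicate = 1L,
               ct = 30 - log2(w * c(8, 1))))
  qf <- qpcr_fold_changes(rec, "ctrl", "treated", "untreated")
  expect_equal(qf$fold, 8)
})

test_that("amplification efficiency has the stated closed forms", {
  dil <- c(0, -1, -2, -3)
  slope <- -1 / log10(2)
  # perfect doubling: CT = a + slope * log10(dilution)
  fit <- amplification_efficiency(dil, 20 + slope * dil)
  expect_equal(fit$efficiency, 1.0)
  expect_equal(fit$slope, slope)
  expect_equal(fit$r_squared, 1.0)
  fit2 <- amplification_efficiency(dil, 20 + -3.6 * dil)
  expect_equal(fit2$efficiency, 10^(1 / 3.6) - 1)
  expect_error(amplification_efficiency(c(0, -1), c(20, 23)), "3 dilution")
  bad <- amplification_efficiency(dil, 20 + 3.3 * dil)
  expect_false(bad$valid)
})

test_that("concordance counts agreements and rejects disjoint gene sets", {
  est <- data.frame(gene_id = c("a", "b", "c"),
                    call = c("up", "down", "unchanged"),
                    ratio = c(3, 0.3, 1))
  qp <- data.frame(gene_id = c("a", "b", "c"), fold = c(2.5, 0.4, 1.1))
  cc <- concordance(est, qp)
  expect_identical(cc$n_agree, 3L)
  qp2 <- transform(qp, fold = c(2.5, 0.4, 2.0))  # c: unchanged vs up
  expect_identical(concordance(est, qp2)$n_agree, 2L)
  expect_error(concordance(est, data.frame(gene_id = "z", fold = 1)),
               "disjoint")
})

test_that("a known 4-fold up-regulation is covered by the 95% CI in >=17/20 seeded runs", {
  g <- fixture_genes()
  panel <- fixture_panel()
  ids <- g$gene_id
  base <- setNames(rep(1, length(ids)), ids)
  base["ACT1"] <- 4
  treated_w <- base; treated_w[["YPL122C"]] <- 4  # 4-fold up
  prof <- expression_profile(
    rep(c("untreated", "treated"), each = length(ids)),
    c(ids, ids), c(base, treated_w))
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_experiment(panel, g, prof,
                               sim_config(rng_seed = 5200L + seed))
    counts <- lapply(sim$samples, function(s)
      table(factor(s$truth$gene_id, levels = ids)))
    ct <- make_counts(
      setNames(as.integer(counts$treated), ids),
      setNames(as.integer(counts$untreated), ids))
    est <- relative_expression(ct, "treated", "untreated", "ACT1")
    row <- est[est$gene_id == "YPL122C", ]
    if (row$ci_low <= 4 && 4 <= row$ci_high) hits <- hits + 1L
  }
  expect_gte(hits, 17L)
})

test_that("joint simulation: qPCR and tag-count direction calls agree on >=18/20 genes", {
  sim <- fixture_sim()
  ref <- fixture_reference()
  ids <- ref$gene_id
  counts <- lapply(sim$samples, function(s)
    table(factor(s$truth$gene_id, levels = ids)))
  ct <- make_counts(setNames(as.integer(counts$treated), ids),
                    setNames(as.integer(counts$untreated), ids))
  est <- relative_expression(ct, "treated", "untreated", "ACT1")
  set.seed(53)
  agree <- vapply(1:5, function(i) {
    rec <- simulate_qpcr(fixture_profile(), n_replicates = 3,
                         ct_noise_sd = 0.2)
    qf <- qpcr_fold_changes(rec, "ACT1", "treated", "untreated")
    cc <- concordance(est, qf)
    cc$n_agree
  }, numeric(1))
  expect_gte(mean(agree), 18)
})
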