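# Relative quantification. Tag counts are turned into internal-control
# normalised expression ratios with count-based confidence intervals; a
# comparative-CT (delta-delta-CT) path handles real-time RT-PCR input for
# cross-validation of the tag-counting results.

#' Control-normalised relative expression from tag counts
#'
#' For each gene, `ratio = (count_t/control_t) / (count_u/control_u)`:
#' the tag count in the treated sample, normalised by the internal-control
#' count, relative to the same quantity in the untreated sample. The 95%
#' interval uses the normal approximation on the log ratio with variance
#' `sum(1/count)` over the four counts (Katz log method); zero cells get a
#' +0.5 continuity correction and are flagged. A gene is called `up` or
#' `down` when the interval excludes 1, else `unchanged`.
#'
#' @param counts a [count_tags()] `tag_count_table`.
#' @param treated,untreated sample ids (columns of the count matrix).
#' @param control_gene internal-control gene id (e.g. ACT1).
#' @param conf_level confidence level of the interval.
#' @return data.frame of class `expression_estimates`: gene_id, count_t,
#'   control_t, count_u, control_u, ratio, log2_ratio, ci_low, ci_high,
#'   call, continuity_corrected.
#' @export
relative_expression <- function(counts, treated, untreated, control_gene,
                                conf_level = 0.95) {
  stopifnot(inherits(counts, "tag_count_table"))
  m <- counts$counts
  if (!all(c(treated, untreated) %in% colnames(m)))
    stop("treated/untreated sample not present in count table", call. = FALSE)
  if (!control_gene %in% rownames(m))
    stop("control gene '", control_gene, "' not in count table", call. = FALSE)
  ct_t <- m[control_gene, treated]
  ct_u <- m[control_gene, untreated]
  if (ct_t == 0) stop("control gene count is zero in sample '", treated, "'",
                      call. = FALSE)
  if (ct_u == 0) stop("control gene count is zero in sample '", untreated,
                      "'", call. = FALSE)
  genes <- setdiff(rownames(m), control_gene)
  z <- qnorm(1 - (1 - conf_level) / 2)
  res <- lapply(genes, function(g) {
    a <- m[g, treated]; b <- m[g, untreated]
    cc <- a == 0 || b == 0
    a2 <- a + 0.5 * cc; b2 <- b + 0.5 * cc
    ratio <- (a2 / ct_t) / (b2 / ct_u)
    se <- sqrt(1 / a2 + 1 / ct_t + 1 / b2 + 1 / ct_u)
    lo <- ratio * exp(-z * se); hi <- ratio * exp(z * se)
    call <- if (lo > 1) "up" else if (hi < 1) "down" else "unchanged"
    data.frame(gene_id = g, count_t = a, control_t = ct_t, count_u = b,
               control_u = ct_u, ratio = ratio, log2_ratio = log2(ratio),
               ci_low = lo, ci_high = hi, call = call,
               continuity_corrected = cc, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res),
            class = c("expression_estimates", "data.frame"))
}

#' Per-sample delta-CT against the internal control
#'
#' Replicates are averaged per (sample, gene) first, then
#' `dCT = CT(control) - CT(target)`. Note the sign convention: the
#' control's threshold cycle minus the target's, so a LARGER dCT means
#' MORE transcript (output headers carry the convention explicitly).
#'
#' @param records data.frame with columns sample_id, gene_id, replicate,
#'   ct (0 < ct < 45).
#' @param control_gene internal-control gene id.
#' @return data.frame: sample_id, gene_id, mean_ct, control_ct,
#'   dct_control_minus_target.
#' @export
delta_ct <- function(records, control_gene) {
  stopifnot(all(c("sample_id", "gene_id", "ct") %in% names(records)))
  if (any(records$ct <= 0 | records$ct >= 45))
    stop("CT values must lie in (0, 45)", call. = FALSE)
  agg <- stats::aggregate(ct ~ sample_id + gene_id, data = records, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$sample_id), function(d) {
    ctrl <- d$ct[d$gene_id == control_gene]
    if (length(ctrl) != 1L)
      stop("missing control-gene CT in sample ", d$sample_id[1], call. = FALSE)
    d2 <- d[d$gene_id != control_gene, , drop = FALSE]
    data.frame(sample_id = d2$sample_id, gene_id = d2$gene_id,
               mean_ct = d2$ct, control_ct = ctrl,
               dct_control_minus_target = ctrl - d2$ct,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Comparative-CT fold change
#'
#' `fold = 2^(dCT_treated - dCT_untreated)`. With dCT defined as control
#' minus target, a larger treated dCT means more transcript, so fold > 1
#' is up-regulation.
#'
#' @param dct_treated,dct_untreated delta-CT values (control minus target).
#' @return numeric fold change(s).
#' @export
ddct_fold <- function(dct_treated, dct_untreated) {
  stopifnot(is.finite(dct_treated), is.finite(dct_untreated))
  2^(dct_treated - dct_untreated)
}

#' Per-gene comparative-CT fold changes between two samples
#'
#' @param records qPCR records (see [delta_ct()]).
#' @param control_gene internal-control gene id.
#' @param treated,untreated sample ids.
#' @return data.frame: gene_id, dct_treated, dct_untreated, fold.
#' @export
qpcr_fold_changes <- function(records, control_gene, treated, untreated) {
  d <- delta_ct(records, control_gene)
  dt <- d[d$sample_id == treated, ]
  du <- d[d$sample_id == untreated, ]
  genes <- intersect(dt$gene_id, du$gene_id)
  if (!length(genes)) stop("no shared genes between samples", call. = FALSE)
  it <- match(genes, dt$gene_id); iu <- match(genes, du$gene_id)
  data.frame(gene_id = genes,
             dct_treated = dt$dct_control_minus_target[it],
             dct_untreated = du$dct_control_minus_target[iu],
             fold = ddct_fold(dt$dct_control_minus_target[it],
                              du$dct_control_minus_target[iu]),
             stringsAsFactors = FALSE)
}

#' Amplification efficiency from a dilution standard curve
#'
#' Least-squares fit of CT against log10(dilution); efficiency
#' `E = 10^(-1/slope) - 1` (E = 1 means perfect doubling per cycle,
#' slope -1/log10(2) ~ -3.32).
#'
#' @param log10_dilution,ct numeric vectors (>= 3 points).
#' @param gene_id optional label.
#' @return object of class `efficiency_fit`: list with gene_id, slope,
#'   intercept, efficiency, r_squared, valid (slope < 0 and
#'   0 < E <= 1.1).
#' @export
amplification_efficiency <- function(log10_dilution, ct, gene_id = NA) {
  if (length(log10_dilution) < 3L || length(ct) != length(log10_dilution))
    stop("a standard curve needs at least 3 dilution points", call. = FALSE)
  fit <- lm(ct ~ log10_dilution)
  slope <- unname(coef(fit)[2])
  eff <- if (slope < 0) 10^(-1 / slope) - 1 else NA_real_
  valid <- !is.na(eff) && eff > 0 && eff <= 1.1
  # r^2 by hand: summary.lm warns on numerically perfect standard curves
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else NA_real_
  structure(list(gene_id = gene_id, slope = slope,
                 intercept = unname(coef(fit)[1]), efficiency = eff,
                 r_squared = r2, valid = valid),
            class = "efficiency_fit")
}

#' Direction-call concordance between tag counting and qPCR
#'
#' Tag-count calls come from the [relative_expression()] confidence
#' interval; qPCR calls use a fold-change threshold (default 1.5x in
#' either direction). Reports per-gene calls from both methods and the
#' number of agreements.
#'
#' @param estimates an [relative_expression()] result.
#' @param qpcr a [qpcr_fold_changes()] result.
#' @param fold_threshold fold beyond which qPCR calls up/down.
#' @return object of class `concordance`: list with `table` (per-gene
#'   calls) and `n_agree`, `n_genes`.
#' @export
concordance <- function(estimates, qpcr, fold_threshold = 1.5) {
  genes <- intersect(estimates$gene_id, qpcr$gene_id)
  if (!length(genes))
    stop("estimate and qPCR gene sets are disjoint", call. = FALSE)
  ie <- match(genes, estimates$gene_id); iq <- match(genes, qpcr$gene_id)
  qcall <- ifelse(qpcr$fold[iq] >= fold_threshold, "up",
                  ifelse(qpcr$fold[iq] <= 1 / fold_threshold, "down",
                         "unchanged"))
  tab <- data.frame(gene_id = genes, mgc_call = estimates$call[ie],
                    mgc_ratio = estimates$ratio[ie],
                    qpcr_call = qcall, qpcr_fold = qpcr$fold[iq],
                    agree = estimates$call[ie] == qcall,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_agree = sum(tab$agree),
                 n_genes = length(genes)), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance: %d/%d genes agree\n", x$n_agree, x$n_genes))
  print(x$table, digits = 3)
  invisible(x)
}
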