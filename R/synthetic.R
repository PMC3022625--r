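# Synthetic fixtures: a 20-gene yeast-like target set and two-condition
# ground-truth profiles. These emulate the validation design of the
# original protocol -- 20 S. cerevisiae genes under weak-acid stress with
# ACT1 as internal control, 10 induced and 9 repressed genes -- without
# requiring the real ORF sequences.

# 19 target ORFs (systematic names) + the ACT1 internal control.
.MGC_UP_GENES <- c("YPL122C", "YNR030W", "YDR343C", "YGR088W", "YPR149W",
                   "YCL040W", "YBR054W", "YNR001C", "YDR533C", "YDL222C")
.MGC_DOWN_GENES <- c("YML123C", "YEL046C", "YLR180W", "YLR355C", "YLR419W",
                     "YLR300W", "YNL300W", "YLR372W", "YAL059W")
.MGC_CONTROL <- "ACT1"

rand_dna <- function(n, gc = 0.6) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Remove every GGATCC/AAGCTT by mutating one base inside the site.
scrub_sites <- function(seqc) {
  repeat {
    pos <- c(find_all(seqc, BAMHI), find_all(seqc, HINDIII))
    if (!length(pos)) return(seqc)
    p <- pos[1] + sample.int(6L, 1L)
    old <- substr_v(seqc, p, p)
    substr(seqc, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
}

#' Generate the packaged synthetic 20-gene target set
#'
#' Random gene sequences at ~60% GC (which puts 16-20-nt primers near the
#' design target of ~67 C melting temperature in the default buffer),
#' scrubbed of BamHI/HindIII sites so every window is digestion-safe.
#' Gene ids follow the validation study's layout: ACT1 internal control
#' plus 19 yeast ORF systematic names. Sequences are synthetic
#' stand-ins, not the real ORFs.
#'
#' @param n_genes number of genes (2..20; default all 20).
#' @param gene_length length of each synthetic gene, bp.
#' @param gc GC fraction of the generated sequence.
#' @param seed RNG seed (NULL = use current stream).
#' @return a [gene_targets()] data.frame.
#' @export
synthesize_gene_targets <- function(n_genes = 20L, gene_length = 160L,
                                    gc = 0.6, seed = NULL) {
  ids <- c(.MGC_CONTROL, .MGC_UP_GENES, .MGC_DOWN_GENES)
  stopifnot(n_genes >= 2L, n_genes <= length(ids), gene_length >= 60L)
  if (!is.null(seed)) set.seed(seed)
  ids <- ids[seq_len(n_genes)]
  seqs <- vapply(ids, function(id) scrub_sites(rand_dna(gene_length, gc)),
                 character(1))
  gene_targets(ids, unname(seqs), control = .MGC_CONTROL)
}

#' Default two-condition ground-truth profiles
#'
#' Untreated baseline abundances cycle over a 16-fold range (1, 2, 4, 8,
#' 16 arbitrary units; control fixed at 8). Treated abundances multiply
#' the baseline by `2^lfc` with true log2 fold changes of +1/+2
#' (alternating) for the induced genes, -1/-2 for the repressed genes,
#' and 0 for the control -- mirroring the two-condition weak-acid design.
#'
#' @param genes a [gene_targets()] data.frame.
#' @param treated,untreated sample ids used in the profile.
#' @return list: `profile` (an [expression_profile()]) and `truth`
#'   (data.frame gene_id, baseline, lfc with the true log2 fold changes).
#' @export
default_truth_profiles <- function(genes, treated = "treated",
                                   untreated = "untreated") {
  ids <- genes$gene_id
  base <- rep(c(1, 2, 4, 8, 16), length.out = length(ids))
  lfc <- numeric(length(ids))
  names(base) <- names(lfc) <- ids
  base[genes$is_control] <- 8
  up <- intersect(ids, .MGC_UP_GENES); down <- intersect(ids, .MGC_DOWN_GENES)
  lfc[up] <- rep(c(1, 2), length.out = length(up))
  lfc[down] <- rep(c(-1, -2), length.out = length(down))
  lfc[genes$is_control] <- 0
  prof <- expression_profile(
    sample_id = rep(c(untreated, treated), each = length(ids)),
    gene_id = c(ids, ids),
    weight = c(base, base * 2^lfc))
  list(profile = prof,
       truth = data.frame(gene_id = ids, baseline = unname(base),
                          lfc = unname(lfc), stringsAsFactors = FALSE))
}

#' Simulate real-time RT-PCR threshold cycles from a ground truth
#'
#' CT values are generated as `base_ct - log2(weight) + noise` per
#' replicate, so that the comparative-CT fold change recovers the true
#' control-normalised ratio in expectation.
#'
#' @param profile an [expression_profile()].
#' @param n_replicates technical replicates per (sample, gene).
#' @param ct_noise_sd CT measurement noise, cycles.
#' @param base_ct CT of a transcript at relative weight 1.
#' @return data.frame: sample_id, gene_id, replicate, ct.
#' @export
simulate_qpcr <- function(profile, n_replicates = 3L, ct_noise_sd = 0.2,
                          base_ct = 30) {
  stopifnot(inherits(profile, "expression_profile"), n_replicates >= 1L)
  rows <- profile[rep(seq_len(nrow(profile)), each = n_replicates), ]
  data.frame(sample_id = rows$sample_id, gene_id = rows$gene_id,
             replicate = rep(seq_len(n_replicates), nrow(profile)),
             ct = base_ct - log2(rows$weight) +
               rnorm(nrow(rows), 0, ct_noise_sd),
             stringsAsFactors = FALSE)
}
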