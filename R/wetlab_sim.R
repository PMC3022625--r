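# In-silico MgC-GEP protocol: amplification -> double digestion ->
# sticky-end concatemer ligation -> size selection -> clone sequencing.
#
# Every stochastic step draws from the single R RNG stream, so a fixed
# seed reproduces the whole experiment. Truth (which gene, which
# orientation, which clone) is tracked through every stage.

#' Ground-truth expression profiles
#'
#' @param sample_id,gene_id,weight vectors of equal length giving the
#'   non-negative relative abundance of each gene in each sample.
#'   Weights are normalised to sum to one within each sample.
#' @return data.frame of class `expression_profile`.
#' @export
expression_profile <- function(sample_id, gene_id, weight) {
  stopifnot(length(sample_id) == length(gene_id),
            length(gene_id) == length(weight))
  if (any(weight < 0) || anyNA(weight))
    stop("weights must be non-negative and non-missing", call. = FALSE)
  d <- data.frame(sample_id = as.character(sample_id),
                  gene_id = as.character(gene_id),
                  weight = as.numeric(weight), stringsAsFactors = FALSE)
  if (anyDuplicated(d[c("sample_id", "gene_id")]))
    stop("duplicate (sample, gene) weight entries", call. = FALSE)
  for (s in unique(d$sample_id)) {
    i <- d$sample_id == s
    tot <- sum(d$weight[i])
    if (tot <= 0) stop("all-zero weights in sample ", s, call. = FALSE)
    d$weight[i] <- d$weight[i] / tot
  }
  structure(d, class = c("expression_profile", "data.frame"))
}

#' Simulation configuration
#'
#' @param n_clones clones sequenced per sample (protocol default 300).
#' @param tag_pool_depth number of tag molecules sampled from the
#'   amplified pool before ligation.
#' @param seq_error_rate per-base substitution probability in reads.
#' @param size_window inclusive insert-size selection window, bp.
#' @param stop_prob per-extension termination probability of the ligation
#'   chain-growth model (chain length is 1 + geometric). The default 0.075
#'   (mean ~13 tags) populates the 500-1200 bp window well.
#' @param n_chain_candidates ligation products grown before size selection.
#' @param rng_seed integer seed, or NULL to use the current RNG state.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_clones = 300L, tag_pool_depth = 1e5L,
                       seq_error_rate = 0, size_window = c(500L, 1200L),
                       stop_prob = 0.075, n_chain_candidates = 5000L,
                       rng_seed = NULL) {
  if (n_clones < 1L) stop("n_clones must be >= 1", call. = FALSE)
  if (seq_error_rate < 0 || seq_error_rate >= 0.1)
    stop("seq_error_rate must lie in [0, 0.1)", call. = FALSE)
  stopifnot(tag_pool_depth >= 1, length(size_window) == 2,
            size_window[1] < size_window[2],
            stop_prob > 0, stop_prob < 1, n_chain_candidates >= 1)
  structure(list(n_clones = as.integer(n_clones),
                 tag_pool_depth = as.integer(tag_pool_depth),
                 seq_error_rate = seq_error_rate,
                 size_window = as.integer(size_window),
                 stop_prob = stop_prob,
                 n_chain_candidates = as.integer(n_chain_candidates),
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
            class = "sim_config")
}

#' Assemble the PCR products of a panel
#'
#' Each product is `fwd_full + internal genomic span + revcomp(rev_full)`,
#' i.e. the forward adaptor tag, the genomic window, and the reverse
#' adaptor tag on the bottom strand.
#'
#' @param panel a [design_panel()] result.
#' @param genes the matching [gene_targets()].
#' @return data.frame with gene_id, sequence, length.
#' @export
make_amplicons <- function(panel, genes) {
  stopifnot(inherits(panel, "primer_panel"))
  adaptors <- attr(panel, "adaptors")
  i <- match(panel$gene_id, genes$gene_id)
  if (anyNA(i))
    stop("panel and gene set are inconsistent: missing ",
         paste(panel$gene_id[is.na(i)], collapse = ", "), call. = FALSE)
  window <- substr_v(genes$sequence[i], panel$amplicon_start + 1L,
                     panel$amplicon_end)
  if (any(nchar(window) != panel$amplicon_end - panel$amplicon_start))
    stop("amplicon interval outside gene sequence", call. = FALSE)
  if (!all(substr_v(window, 1L, nchar(panel$fwd_specific)) == panel$fwd_specific))
    stop("panel and gene set are inconsistent: forward primer does not ",
         "match its gene window", call. = FALSE)
  seqs <- paste0(adaptors$forward_tag, window, revcomp(adaptors$reverse_tag))
  data.frame(gene_id = panel$gene_id, sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Double-digest PCR products into concatemer-ready tags
#'
#' Cuts at G^GATCC (BamHI) and A^AGCTT (HindIII) and returns each released
#' tag in canonical form: written 5'->3' with overhangs filled in, BamHI
#' end first, including the full reconstituted hexamer at both ends. The
#' 5' overhangs (GATC on the BamHI side, AGCT on the HindIII side) are the
#' sticky ends that drive ligation compatibility.
#'
#' @param amplicons a [make_amplicons()] data.frame (or any data.frame
#'   with gene_id and sequence).
#' @param adaptors the [universal_adaptors()] used in the panel.
#' @return data.frame of class `digested_tags`: gene_id, tag, length,
#'   left_end ("GATC"), right_end ("AGCT").
#' @export
digest_amplicons <- function(amplicons, adaptors = universal_adaptors()) {
  stopifnot(is.data.frame(amplicons),
            all(c("gene_id", "sequence") %in% names(amplicons)))
  tags <- vapply(seq_len(nrow(amplicons)), function(i) {
    s <- amplicons$sequence[i]
    b <- find_all(s, BAMHI); h <- find_all(s, HINDIII)
    if (length(b) != 1L || length(h) != 1L)
      stop("gene ", amplicons$gene_id[i], ": digestion needs exactly one ",
           "GGATCC and one AAGCTT, found ", length(b), " GGATCC and ",
           length(h), " AAGCTT", call. = FALSE)
    if (h <= b)
      stop("gene ", amplicons$gene_id[i],
           ": HindIII site precedes BamHI site", call. = FALSE)
    substr_v(s, b + 1L, h + 6L)
  }, character(1))
  structure(data.frame(gene_id = amplicons$gene_id, tag = tags,
                       length = nchar(tags), left_end = "GATC",
                       right_end = "AGCT", stringsAsFactors = FALSE),
            class = c("digested_tags", "data.frame"))
}

#' Sample the amplified tag pool
#'
#' Models reverse transcription plus 28 PCR cycles with universal primers
#' as bias-free multinomial sampling of tag molecules from the profile
#' weights (optionally skewed by per-gene efficiency multipliers).
#'
#' @param weights named non-negative numeric vector (gene -> abundance).
#' @param depth number of molecules drawn.
#' @param efficiency optional named multiplier per gene (default 1).
#' @return named integer vector of per-gene molecule counts.
#' @export
sample_tag_pool <- function(weights, depth, efficiency = NULL) {
  if (all(weights <= 0)) stop("all-zero profile weights", call. = FALSE)
  stopifnot(depth >= 1)
  w <- weights
  if (!is.null(efficiency)) w <- w * efficiency[names(w)]
  counts <- as.integer(rmultinom(1, size = depth, prob = w))
  names(counts) <- names(weights)
  counts
}

# Grow one ligation chain: alternating orientations forced by sticky-end
# compatibility (BamHI GATC overhangs only mate with BamHI overhangs,
# HindIII AGCT with HindIII). Returns gene index vector + orientations.
grow_chain <- function(gene_prob, stop_prob) {
  k <- 1L + rgeom(1L, stop_prob)
  genes <- sample.int(length(gene_prob), k, replace = TRUE, prob = gene_prob)
  first_orient <- if (runif(1) < 0.5) "F" else "RC"
  orient <- rep(c("F", "RC"), length.out = k)
  if (first_orient == "RC") orient <- rep(c("RC", "F"), length.out = k)
  list(genes = genes, orient = orient)
}

#' Ligate digested tags into concatemer candidates
#'
#' Sequential random chain growth: a seed tag in random orientation is
#' extended by uniformly random compatible tags; each step terminates with
#' probability `stop_prob`. Like-overhang joining forces strictly
#' alternating orientations and alternating GGATCC/AAGCTT junctions; a
#' product is cloneable into a BamHI+HindIII-cut vector iff its two
#' termini expose one BamHI- and one HindIII-compatible end, which under
#' strict alternation happens exactly for odd tag counts.
#'
#' Junction hexamers are shared by the flanking tags, so insert length is
#' `sum(tag lengths) - 6*(k-1)`. Cloneable inserts are canonicalised to
#' start at their BamHI end.
#'
#' @param tag_counts named integer vector from [sample_tag_pool()].
#' @param tags a [digest_amplicons()] data.frame for the same genes.
#' @param stop_prob per-step termination probability.
#' @param n_chains number of chains to grow.
#' @return data.frame of class `clone_inserts`: chain_id, n_tags, length,
#'   left_end/right_end ("B"/"H"), cloneable, insert_sequence, plus a
#'   list-column `tag_genes` / `tag_orients` with the ordered truth.
#' @export
ligate_concatemers <- function(tag_counts, tags, stop_prob = 0.075,
                               n_chains = 5000L) {
  stopifnot(all(names(tag_counts) %in% tags$gene_id))
  if (sum(tag_counts) == 0) stop("empty tag pool", call. = FALSE)
  tag_seq <- setNames(tags$tag, tags$gene_id)
  tag_rc <- setNames(revcomp(tags$tag), tags$gene_id)
  gene_prob <- tag_counts / sum(tag_counts)
  gene_ids <- names(tag_counts)

  chains <- replicate(n_chains, grow_chain(gene_prob, stop_prob),
                      simplify = FALSE)
  res <- lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    gid <- gene_ids[ch$genes]
    orient <- ch$orient
    pieces <- ifelse(orient == "F", tag_seq[gid], tag_rc[gid])
    k <- length(pieces)
    seqs <- if (k == 1L) pieces else
      paste0(pieces[1], paste(substring(pieces[-1], 7L), collapse = ""))
    # terminal end types: F exposes B on the left / H on the right
    left <- if (orient[1] == "F") "B" else "H"
    right <- if (orient[k] == "F") "H" else "B"
    cloneable <- left != right  # equivalent to odd k under alternation
    if (cloneable && left == "H") {  # canonical orientation: BamHI end first
      seqs <- revcomp(seqs)
      gid <- rev(gid)
      orient <- rev(ifelse(orient == "F", "RC", "F"))
      left <- "B"; right <- "H"
    }
    list(gid = gid, orient = orient, seq = unname(seqs), k = k,
         left = left, right = right, cloneable = cloneable)
  })
  structure(data.frame(
    chain_id = sprintf("chain_%05d", seq_along(res)),
    n_tags = vapply(res, `[[`, integer(1), "k"),
    length = nchar(vapply(res, `[[`, character(1), "seq")),
    left_end = vapply(res, `[[`, character(1), "left"),
    right_end = vapply(res, `[[`, character(1), "right"),
    cloneable = vapply(res, `[[`, logical(1), "cloneable"),
    insert_sequence = vapply(res, `[[`, character(1), "seq"),
    tag_genes = I(lapply(res, `[[`, "gid")),
    tag_orients = I(lapply(res, `[[`, "orient")),
    stringsAsFactors = FALSE),
    class = c("clone_inserts", "data.frame"))
}

#' Size-select cloneable inserts
#'
#' Retains cloneable ligation products whose length lies inside the
#' inclusive window (the gel-isolation step).
#'
#' @param candidates a [ligate_concatemers()] data.frame.
#' @param window inclusive `[min, max]` length window, bp.
#' @return the retained subset (same class); empty with a warning if no
#'   candidate survives.
#' @export
size_select <- function(candidates, window = c(500L, 1200L)) {
  stopifnot(window[1] < window[2])
  keep <- candidates$cloneable & candidates$length >= window[1] &
    candidates$length <= window[2]
  out <- candidates[keep, , drop = FALSE]
  if (!nrow(out))
    warning("no cloneable insert falls inside the size-selection window")
  rownames(out) <- NULL
  out
}

# i.i.d. substitution errors on one read.
add_seq_errors <- function(seqc, rate) {
  n <- nchar(seqc)
  nerr <- rbinom(1L, n, rate)
  if (nerr == 0L) return(seqc)
  pos <- sample.int(n, nerr)
  ch <- strsplit(seqc, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Sequence randomly picked clones
#'
#' Samples `n_clones` inserts uniformly with replacement from the
#' size-selected pool and emits one full-length, insert-only read per
#' clone, with i.i.d. substitution errors at `seq_error_rate`.
#'
#' @param inserts a size-selected [ligate_concatemers()] data.frame.
#' @param n_clones number of clones to sequence.
#' @param seq_error_rate per-base substitution probability.
#' @param sample_id label used in clone ids.
#' @return list with `reads` (named character vector, names = clone ids)
#'   and `truth` (data.frame clone_id, position, gene_id, orientation,
#'   insert_length).
#' @export
sequence_clones <- function(inserts, n_clones, seq_error_rate = 0,
                            sample_id = "s") {
  if (n_clones <= 0L) stop("n_clones must be positive", call. = FALSE)
  if (!nrow(inserts)) stop("no inserts available to clone", call. = FALSE)
  pick <- sample.int(nrow(inserts), n_clones, replace = TRUE)
  clone_id <- sprintf("%s_clone_%04d", sample_id, seq_len(n_clones))
  reads <- vapply(seq_len(n_clones), function(i) {
    add_seq_errors(inserts$insert_sequence[pick[i]], seq_error_rate)
  }, character(1))
  names(reads) <- clone_id
  truth <- do.call(rbind, lapply(seq_len(n_clones), function(i) {
    g <- inserts$tag_genes[[pick[i]]]
    data.frame(clone_id = clone_id[i], position = seq_along(g),
               gene_id = g, orientation = inserts$tag_orients[[pick[i]]],
               insert_length = inserts$length[pick[i]],
               stringsAsFactors = FALSE)
  }))
  list(reads = reads, truth = truth)
}

#' Simulate the full protocol for every sample of a profile
#'
#' Runs pool sampling, digestion, ligation, size selection and clone
#' sequencing per sample, from one seeded RNG stream.
#'
#' @param panel a [design_panel()] result.
#' @param genes matching [gene_targets()].
#' @param profile an [expression_profile()] (control weight must be > 0).
#' @param config a [sim_config()].
#' @param efficiency optional named per-gene amplification multipliers.
#' @return list of class `mgc_simulation`: per sample a list with
#'   `reads`, `truth`, `inserts` (the size-selected pool), plus `tags`
#'   (the digested tag reference truth) and the resolved `config`.
#' @export
simulate_experiment <- function(panel, genes, profile, config = sim_config(),
                                efficiency = NULL) {
  stopifnot(inherits(profile, "expression_profile"),
            inherits(config, "sim_config"))
  control <- genes$gene_id[genes$is_control]
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  amp <- make_amplicons(panel, genes)
  tags <- digest_amplicons(amp, attr(panel, "adaptors"))
  samples <- unique(profile$sample_id)
  out <- lapply(samples, function(s) {
    d <- profile[profile$sample_id == s, ]
    w <- setNames(d$weight, d$gene_id)
    if (length(control) && (!control %in% names(w) || w[[control]] <= 0))
      stop("control gene has zero weight in sample ", s, call. = FALSE)
    pool <- sample_tag_pool(w, config$tag_pool_depth, efficiency)
    cands <- ligate_concatemers(pool, tags, config$stop_prob,
                                config$n_chain_candidates)
    surv <- size_select(cands, config$size_window)
    sq <- sequence_clones(surv, config$n_clones, config$seq_error_rate, s)
    list(reads = sq$reads, truth = sq$truth, inserts = surv)
  })
  names(out) <- samples
  structure(list(samples = out, tags = tags, config = config),
            class = "mgc_simulation")
}
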