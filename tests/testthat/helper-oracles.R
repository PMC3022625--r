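# Independent brute-force oracles. These deliberately re-derive results by
# the most naive route available so that the production code is checked
# against a second, unrelated path.

# Naive candidate enumeration: loop over every (start, fwd_len, rev_len)
# triple, assemble the full product, and test every constraint directly on
# the assembled string.
naive_enumerate <- function(gene, adaptors, constraints) {
  seqc <- gene$sequence
  glen <- nchar(seqc)
  ov <- nchar(adaptors$forward_tag) + nchar(adaptors$reverse_tag)
  lw <- constraints$amplicon_center + c(-1, 1) * constraints$amplicon_tol
  rows <- list()
  for (start in 0:max(0, glen - 1)) {
    for (span in 1:(glen - start)) {
      len <- span + ov
      if (len < lw[1] || len > lw[2]) next
      for (fl in constraints$specific_len_range[1]:constraints$specific_len_range[2]) {
        for (rl in constraints$specific_len_range[1]:constraints$specific_len_range[2]) {
          if (fl + rl > span) next
          window <- substring(seqc, start + 1, start + span)
          product <- paste0(adaptors$forward_tag, window,
                            revcomp(adaptors$reverse_tag))
          nb <- length(gregexpr("GGATCC", product, fixed = TRUE)[[1]])
          if (regexpr("GGATCC", product, fixed = TRUE) == -1) nb <- 0
          nh <- length(gregexpr("AAGCTT", product, fixed = TRUE)[[1]])
          if (regexpr("AAGCTT", product, fixed = TRUE) == -1) nh <- 0
          if (nb != 1 || nh != 1) next
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = gene$gene_id, start = start, end = start + span,
            fwd_len = fl, rev_len = rl,
            fwd_specific = substring(seqc, start + 1, start + fl),
            rev_specific = revcomp(substring(seqc, start + span - rl + 1,
                                             start + span)),
            amplicon_len = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  d <- do.call(rbind, rows)
  d[order(d$start, d$amplicon_len, d$fwd_len, d$rev_len), ]
}

# Naive panel selection: same documented objective as design_panel
# (per-gene best-centred candidates, then minimum Tm spread over the full
# cross product), solved by exhaustive enumeration of all assignments.
naive_design <- function(genes, adaptors, constraints) {
  cands <- lapply(seq_len(nrow(genes)), function(i) {
    d <- enumerate_candidates(genes[i, ], adaptors, constraints)
    dev <- abs(d$amplicon_len - constraints$amplicon_center)
    d[dev == min(dev), , drop = FALSE]
  })
  idx <- expand.grid(lapply(cands, function(d) seq_len(nrow(d))))
  lo <- hi <- matrix(0, nrow(idx), ncol(idx))
  for (g in seq_along(cands)) {
    lo[, g] <- pmin(cands[[g]]$tm_fwd, cands[[g]]$tm_rev)[idx[[g]]]
    hi[, g] <- pmax(cands[[g]]$tm_fwd, cands[[g]]$tm_rev)[idx[[g]]]
  }
  spread <- do.call(pmax, as.data.frame(hi)) -
    do.call(pmin, as.data.frame(lo))
  best <- which(spread <= min(spread) + 1e-12)[1]
  list(spread = min(spread),
       rows = lapply(seq_along(cands), function(g)
         cands[[g]][idx[[g]][best], , drop = FALSE]))
}

# Sliding-window junction scan.
naive_scan_junctions <- function(read) {
  n <- nchar(read)
  out <- list()
  if (n >= 6) for (p in 0:(n - 6)) {
    hex <- substring(read, p + 1, p + 6)
    if (hex %in% c("GGATCC", "AAGCTT"))
      out[[length(out) + 1]] <- data.frame(position = p, site = hex,
                                           stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(position = integer(0),
                                      site = character(0)))
  do.call(rbind, out)
}

# Character-by-character ungapped distance mirroring the documented rule:
# Hamming at equal length, otherwise best offset of the shorter within the
# longer plus the length difference.
naive_distance <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  best <- Inf
  for (off in 0:(lb - la)) {
    mm <- 0
    for (i in 1:la)
      if (substring(a, i, i) != substring(b, off + i, off + i)) mm <- mm + 1
    best <- min(best, mm)
  }
  best + (lb - la)
}

naive_assign <- function(s, reference, max_mismatch) {
  d <- vapply(seq_len(nrow(reference)), function(i)
    min(naive_distance(s, reference$tag[i]),
        naive_distance(s, reference$tag_rc[i])), numeric(1))
  o <- order(d)
  best <- d[o[1]]
  second <- if (length(d) > 1) d[o[2]] else Inf
  if (best <= max_mismatch && second - best >= 2)
    list(gene = reference$gene_id[o[1]], status = "assigned")
  else if (best <= max_mismatch) list(gene = NA_character_, status = "ambiguous")
  else list(gene = NA_character_, status = "unassigned")
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

# Mutate k random positions of a sequence.
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
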