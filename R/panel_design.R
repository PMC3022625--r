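# Multiplex chimeric-primer panel design.
#
# Each primer is chimeric: a gene-specific 3' part (16-20 nt by default)
# fused to a universal 5' adaptor tag. The forward adaptor (18 nt) carries
# one BamHI site (GGATCC), the reverse adaptor (19 nt) one HindIII site
# (AAGCTT), so that every PCR product can be double-digested and the
# released tags ligated into concatemers via their sticky ends.

BAMHI <- "GGATCC"
HINDIII <- "AAGCTT"

#' Gene target set
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param sequence DNA sequences (strictly ACGT; ambiguity codes rejected).
#' @param control gene_id of the internal-control gene (e.g. ACT1).
#' @return data.frame of class `gene_targets` with columns
#'   `gene_id`, `sequence`, `is_control`.
#' @export
gene_targets <- function(gene_id, sequence, control) {
  stopifnot(length(gene_id) == length(sequence), length(gene_id) >= 1)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in target set", call. = FALSE)
  assert_dna(sequence, "gene sequence")
  if (!control %in% gene_id)
    stop("control gene '", control, "' not among targets", call. = FALSE)
  structure(
    data.frame(gene_id = as.character(gene_id),
               sequence = toupper(sequence),
               is_control = gene_id == control,
               stringsAsFactors = FALSE),
    class = c("gene_targets", "data.frame"))
}

#' Universal adaptor tags
#'
#' The forward tag is 18 nt with exactly one BamHI site (GGATCC), the
#' reverse tag 19 nt with exactly one HindIII site (AAGCTT); neither tag
#' may contain the other enzyme's site. The default pair places each
#' hexamer at offset 10 so that digestion of an 85-bp product releases a
#' 65-bp tag (amplicon length minus 20), putting the designed panel's tags
#' in the 60-70 bp window.
#'
#' @param forward_tag 18-nt DNA string containing one GGATCC.
#' @param reverse_tag 19-nt DNA string containing one AAGCTT.
#' @return object of class `universal_adaptors` with fields `forward_tag`,
#'   `reverse_tag`, `bamhi_offset`, `hindiii_offset` (0-based).
#' @export
universal_adaptors <- function(forward_tag = "ACGTCGTTCAGGATCCTC",
                               reverse_tag = "TGCACTGACTAAGCTTGCA") {
  assert_dna(c(forward_tag, reverse_tag), "adaptor tag")
  if (nchar(forward_tag) != 18L)
    stop("forward tag must be 18 nt", call. = FALSE)
  if (nchar(reverse_tag) != 19L)
    stop("reverse tag must be 19 nt", call. = FALSE)
  fb <- find_all(forward_tag, BAMHI)
  rh <- find_all(reverse_tag, HINDIII)
  if (length(fb) != 1L)
    stop("forward tag must contain exactly one ", BAMHI, call. = FALSE)
  if (length(rh) != 1L)
    stop("reverse tag must contain exactly one ", HINDIII, call. = FALSE)
  if (length(find_all(forward_tag, HINDIII)) > 0L ||
      length(find_all(reverse_tag, BAMHI)) > 0L)
    stop("adaptor tags may not carry the other enzyme's site", call. = FALSE)
  structure(list(forward_tag = forward_tag, reverse_tag = reverse_tag,
                 bamhi_offset = fb, hindiii_offset = rh),
            class = "universal_adaptors")
}

#' Panel design constraints
#'
#' @param specific_len_range allowed length range of the gene-specific
#'   primer part, nt.
#' @param amplicon_center,amplicon_tol target PCR-product length (bp,
#'   adaptors included) and its tolerance: products must lie in
#'   `amplicon_center +/- amplicon_tol`.
#' @param max_pairwise_dtm maximum allowed pairwise melting-temperature
#'   difference among all gene-specific primer parts of a panel, degrees C.
#' @param tm a [tm_params()] object.
#' @return object of class `design_constraints`.
#' @export
design_constraints <- function(specific_len_range = c(16L, 20L),
                               amplicon_center = 85L, amplicon_tol = 7L,
                               max_pairwise_dtm = 5, tm = tm_params()) {
  stopifnot(length(specific_len_range) == 2,
            specific_len_range[1] >= 8, diff(specific_len_range) >= 0,
            amplicon_center > 0, amplicon_tol >= 0, max_pairwise_dtm > 0,
            inherits(tm, "tm_params"))
  structure(list(specific_len_range = as.integer(specific_len_range),
                 amplicon_center = as.integer(amplicon_center),
                 amplicon_tol = as.integer(amplicon_tol),
                 max_pairwise_dtm = max_pairwise_dtm, tm = tm),
            class = "design_constraints")
}

# Adaptor overhead added to the genomic span by the two tags.
adaptor_overhead <- function(adaptors)
  nchar(adaptors$forward_tag) + nchar(adaptors$reverse_tag)

#' Enumerate all feasible chimeric primer pairs for one gene
#'
#' Exhaustive enumeration over (amplicon start, forward length, reverse
#' length). A candidate is feasible iff the full PCR product length
#' (genomic span plus both adaptor tags) lies in the amplicon window and
#' the assembled product contains exactly one GGATCC and one AAGCTT (both
#' inside the adaptors) -- internal sites would be cleaved during
#' digestion and destroy the tag.
#'
#' @param gene one row of a [gene_targets()] data.frame (or a list with
#'   `gene_id` and `sequence`).
#' @param adaptors a [universal_adaptors()] object.
#' @param constraints a [design_constraints()] object.
#' @return data.frame of candidates sorted by (start, amplicon_len), with
#'   columns gene_id, start, end (0-based half-open on the gene's forward
#'   strand), fwd_len, rev_len, fwd_specific, rev_specific, amplicon_len,
#'   tm_fwd, tm_rev.
#' @export
enumerate_candidates <- function(gene, adaptors = universal_adaptors(),
                                 constraints = design_constraints()) {
  seqc <- gene$sequence
  gid <- gene$gene_id
  assert_dna(seqc, "gene sequence")
  glen <- nchar(seqc)
  ov <- adaptor_overhead(adaptors)
  span_rng <- c(constraints$amplicon_center - constraints$amplicon_tol,
                constraints$amplicon_center + constraints$amplicon_tol) - ov
  lmin <- constraints$specific_len_range[1]
  lmax <- constraints$specific_len_range[2]
  span_rng[1] <- max(span_rng[1], 2L * lmin)
  if (span_rng[1] > span_rng[2])
    stop("gene '", gid, "': amplicon window infeasible for the adaptor ",
         "geometry and primer lengths", call. = FALSE)
  if (glen < span_rng[1])
    stop("gene '", gid, "' (", glen, " bp) is shorter than the minimum ",
         "amplicon span of ", span_rng[1], " bp: no candidate possible",
         call. = FALSE)

  grid <- expand.grid(
    start = 0:(glen - span_rng[1]),
    span = span_rng[1]:span_rng[2],
    fwd_len = lmin:lmax, rev_len = lmin:lmax,
    KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$start + grid$span <= glen &
               grid$fwd_len + grid$rev_len <= grid$span, , drop = FALSE]

  # Forbidden-site screens. Sites can occur (a) inside the genomic window,
  # (b) straddling a tag/gene junction; the tags themselves are pre-validated.
  site_pos <- sort(c(find_all(seqc, BAMHI), find_all(seqc, HINDIII)))
  if (length(site_pos)) {
    bad <- vapply(seq_len(nrow(grid)), function(i) {
      any(site_pos >= grid$start[i] & site_pos <= grid$start[i] + grid$span[i] - 6L)
    }, logical(1))
    grid <- grid[!bad, , drop = FALSE]
  }
  if (nrow(grid)) {
    fwd_flank <- substr_v(adaptors$forward_tag, 13L, 18L)
    rev_flank <- substr_v(revcomp(adaptors$reverse_tag), 1L, 6L)
    starts <- sort(unique(grid$start))
    left_ok <- vapply(starts, function(s) {
      j <- paste0(fwd_flank, substr_v(seqc, s + 1L, s + 5L))
      !length(find_all(j, BAMHI)) && !length(find_all(j, HINDIII))
    }, logical(1))
    # left junction has GGATCC already upstream in the tag; only NEW sites
    # straddling the boundary matter, so scan the 11-mer minus known tag site
    left_ok <- left_ok | vapply(starts, function(s) {
      j <- paste0(fwd_flank, substr_v(seqc, s + 1L, s + 5L))
      p <- c(find_all(j, BAMHI), find_all(j, HINDIII))
      all(p + 6L <= 6L)  # entirely within the tag part: pre-validated
    }, logical(1))
    ends <- sort(unique(grid$start + grid$span))
    right_ok <- vapply(ends, function(e) {
      j <- paste0(substr_v(seqc, e - 4L, e), rev_flank)
      p <- c(find_all(j, BAMHI), find_all(j, HINDIII))
      all(p >= 5L)  # entirely within the tag part: pre-validated
    }, logical(1))
    grid <- grid[left_ok[match(grid$start, starts)] &
                 right_ok[match(grid$start + grid$span, ends)], , drop = FALSE]
  }
  if (!nrow(grid))  # feasible geometry but every window carries a site
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), fwd_len = integer(0),
                      rev_len = integer(0), fwd_specific = character(0),
                      rev_specific = character(0), amplicon_len = integer(0),
                      tm_fwd = numeric(0), tm_rev = numeric(0),
                      stringsAsFactors = FALSE))

  # Tm is a function of (start, fwd_len) and (end, rev_len) only.
  fkey <- paste(grid$start, grid$fwd_len)
  funiq <- !duplicated(fkey)
  fseq <- substr_v(seqc, grid$start[funiq] + 1L,
                   grid$start[funiq] + grid$fwd_len[funiq])
  ftm <- melting_temperature(fseq, constraints$tm)
  names(ftm) <- fkey[funiq]; names(fseq) <- fkey[funiq]
  ends_all <- grid$start + grid$span
  rkey <- paste(ends_all, grid$rev_len)
  runiq <- !duplicated(rkey)
  rseq <- revcomp(substr_v(seqc, ends_all[runiq] - grid$rev_len[runiq] + 1L,
                           ends_all[runiq]))
  rtm <- melting_temperature(rseq, constraints$tm)
  names(rtm) <- rkey[runiq]; names(rseq) <- rkey[runiq]

  out <- data.frame(
    gene_id = gid,
    start = as.integer(grid$start),
    end = as.integer(ends_all),
    fwd_len = as.integer(grid$fwd_len),
    rev_len = as.integer(grid$rev_len),
    fwd_specific = unname(fseq[fkey]),
    rev_specific = unname(rseq[rkey]),
    amplicon_len = as.integer(grid$span + ov),
    tm_fwd = unname(ftm[fkey]),
    tm_rev = unname(rtm[rkey]),
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$amplicon_len, out$fwd_len, out$rev_len), ]
  rownames(out) <- NULL
  out
}

#' Design a multiplex chimeric-primer panel
#'
#' Selects one primer pair per gene so that the maximum pairwise
#' melting-temperature difference over all gene-specific primer parts is
#' minimised (and must not exceed `constraints$max_pairwise_dtm`).
#' Candidates are first restricted, per gene, to those with the smallest
#' achievable `|amplicon_len - center|`: pure spread minimisation would
#' otherwise chase thermodynamically meaningless fractions of a degree by
#' pushing products to the window edges, which drags the digested tags
#' out of their 60-70 bp band. Over these best-centred candidates the
#' spread objective is solved exactly by sweeping candidate lower Tm
#' bounds with the tightest achievable upper bound per gene. Ties are
#' broken deterministically: smallest feasible window lower bound, then
#' per gene leftmost amplicon start, then shortest primers.
#'
#' @param genes a [gene_targets()] data.frame with exactly one control.
#' @param adaptors a [universal_adaptors()] object.
#' @param constraints a [design_constraints()] object.
#' @return object of class `primer_panel`: a data.frame with one row per
#'   gene (gene_id, fwd_specific, rev_specific, fwd_full, rev_full, tm_fwd,
#'   tm_rev, amplicon_start, amplicon_end, amplicon_len) and attributes
#'   `adaptors`, `constraints`, `summary` (mean/sd Tm, max pairwise dTm).
#' @export
design_panel <- function(genes, adaptors = universal_adaptors(),
                         constraints = design_constraints()) {
  stopifnot(inherits(genes, "gene_targets"))
  if (nrow(genes) < 2L)
    stop("panel design needs at least two genes", call. = FALSE)
  if (sum(genes$is_control) != 1L)
    stop("exactly one internal-control gene is required", call. = FALSE)

  cands <- lapply(seq_len(nrow(genes)), function(i) {
    d <- enumerate_candidates(genes[i, ], adaptors, constraints)
    if (!nrow(d))
      stop("gene '", genes$gene_id[i], "': no primer-pair candidate ",
           "satisfies the amplicon-window and forbidden-site constraints",
           call. = FALSE)
    dev <- abs(d$amplicon_len - constraints$amplicon_center)
    d[dev == min(dev), , drop = FALSE]  # best-centred candidates only
  })
  names(cands) <- genes$gene_id

  lo <- lapply(cands, function(d) pmin(d$tm_fwd, d$tm_rev))
  hi <- lapply(cands, function(d) pmax(d$tm_fwd, d$tm_rev))

  # Per gene: step function L -> min{ hi : lo >= L } via sort + cummin.
  steps <- lapply(seq_along(cands), function(g) {
    o <- order(lo[[g]])
    list(lo = lo[[g]][o], minhi = rev(cummin(rev(hi[[g]][o]))))
  })
  Ls <- sort(unique(unlist(lapply(steps, `[[`, "lo"))))
  U <- rep(-Inf, length(Ls))
  feasible <- rep(TRUE, length(Ls))
  for (st in steps) {
    idx <- findInterval(Ls, st$lo + 1e-12) + 1L  # first lo >= L
    ok <- idx <= length(st$lo)
    feasible <- feasible & ok
    U[ok] <- pmax(U[ok], st$minhi[idx[ok]])
    U[!ok] <- Inf
  }
  if (!any(feasible))
    stop("no joint primer assignment exists", call. = FALSE)
  spread_ub <- U - Ls
  best <- which(feasible & spread_ub <= min(spread_ub[feasible]) + 1e-12)[1]
  Lb <- Ls[best]; Ub <- U[best]

  pick <- lapply(seq_along(cands), function(g) {
    d <- cands[[g]]
    inw <- lo[[g]] >= Lb - 1e-12 & hi[[g]] <= Ub + 1e-12
    d <- d[inw, , drop = FALSE]
    d[order(abs(d$amplicon_len - constraints$amplicon_center),
            d$start, d$fwd_len, d$rev_len), ][1, , drop = FALSE]
  })
  sel <- do.call(rbind, pick)

  tms <- c(sel$tm_fwd, sel$tm_rev)
  spread <- max(tms) - min(tms)
  if (spread > constraints$max_pairwise_dtm) {
    gmin <- sel$gene_id[which.min(pmin(sel$tm_fwd, sel$tm_rev))]
    gmax <- sel$gene_id[which.max(pmax(sel$tm_fwd, sel$tm_rev))]
    stop(sprintf(paste0("no panel satisfies the pairwise dTm constraint: ",
                        "best achievable spread %.2f C > %.2f C ",
                        "(widest-spread genes: %s, %s)"),
                 spread, constraints$max_pairwise_dtm, gmin, gmax),
         call. = FALSE)
  }

  panel <- data.frame(
    gene_id = sel$gene_id,
    fwd_specific = sel$fwd_specific,
    rev_specific = sel$rev_specific,
    fwd_full = paste0(adaptors$forward_tag, sel$fwd_specific),
    rev_full = paste0(adaptors$reverse_tag, sel$rev_specific),
    tm_fwd = sel$tm_fwd,
    tm_rev = sel$tm_rev,
    amplicon_start = sel$start,
    amplicon_end = sel$end,
    amplicon_len = sel$amplicon_len,
    stringsAsFactors = FALSE)
  structure(panel,
            adaptors = adaptors, constraints = constraints,
            summary = list(mean_tm = mean(tms), sd_tm = sd(tms),
                           max_pairwise_dtm = spread),
            class = c("primer_panel", "data.frame"))
}

#' @export
print.primer_panel <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("primer_panel: %d chimeric pairs | Tm %.1f +/- %.1f C | max pairwise dTm %.2f C\n",
              nrow(x), s$mean_tm, s$sd_tm, s$max_pairwise_dtm))
  print.data.frame(utils::head(as.data.frame(x), 20), digits = 4)
  invisible(x)
}

#' Validate a primer panel against its gene set
#'
#' Report-only check of all panel invariants: per-pair Tm and amplicon
#' length, panel-wide pairwise dTm, internal restriction-site violations
#' in the assembled products, and duplicate digested-tag sequences
#' (ambiguity between genes).
#'
#' @param panel a [design_panel()] result.
#' @param genes the [gene_targets()] the panel was designed from.
#' @return object of class `panel_validation`: list with `per_pair`
#'   data.frame, character vector `violations`, and logical `pass`.
#' @export
validate_panel <- function(panel, genes) {
  stopifnot(inherits(panel, "primer_panel"), inherits(genes, "gene_targets"))
  adaptors <- attr(panel, "adaptors")
  constraints <- attr(panel, "constraints")
  if (!all(panel$gene_id %in% genes$gene_id))
    stop("panel refers to genes absent from the target set", call. = FALSE)
  viol <- character(0)
  if (anyDuplicated(panel$gene_id))
    viol <- c(viol, "duplicate gene_id rows in panel")
  amp <- make_amplicons(panel, genes)
  lw <- constraints$amplicon_center + c(-1, 1) * constraints$amplicon_tol
  per <- data.frame(gene_id = panel$gene_id,
                    tm_fwd = panel$tm_fwd, tm_rev = panel$tm_rev,
                    amplicon_len = panel$amplicon_len,
                    len_ok = panel$amplicon_len >= lw[1] &
                             panel$amplicon_len <= lw[2],
                    n_bamhi = vapply(amp$sequence, function(s)
                      length(find_all(s, BAMHI)), integer(1), USE.NAMES = FALSE),
                    n_hindiii = vapply(amp$sequence, function(s)
                      length(find_all(s, HINDIII)), integer(1), USE.NAMES = FALSE),
                    stringsAsFactors = FALSE)
  for (i in which(!per$len_ok))
    viol <- c(viol, sprintf("gene %s: amplicon length %d bp outside [%d, %d]",
                            per$gene_id[i], per$amplicon_len[i], lw[1], lw[2]))
  for (i in which(per$n_bamhi != 1L | per$n_hindiii != 1L))
    viol <- c(viol, sprintf("gene %s: product carries %d GGATCC / %d AAGCTT (need 1/1)",
                            per$gene_id[i], per$n_bamhi[i], per$n_hindiii[i]))
  tms <- c(panel$tm_fwd, panel$tm_rev)
  if (max(tms) - min(tms) > constraints$max_pairwise_dtm + 1e-9)
    viol <- c(viol, sprintf("max pairwise dTm %.2f C exceeds %.2f C",
                            max(tms) - min(tms), constraints$max_pairwise_dtm))
  ok_digest <- per$n_bamhi == 1L & per$n_hindiii == 1L
  if (any(ok_digest)) {
    tags <- digest_amplicons(amp[ok_digest, , drop = FALSE], adaptors)
    dup <- duplicated(tags$tag) | duplicated(tags$tag, fromLast = TRUE)
    if (any(dup))
      viol <- c(viol, sprintf("ambiguity: genes %s share identical tag sequences",
                              paste(tags$gene_id[dup], collapse = ", ")))
  }
  structure(list(per_pair = per, violations = viol, pass = !length(viol)),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat("panel validation:", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$violations)) cat(paste0(" - ", x$violations, "\n"), sep = "")
  invisible(x)
}
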