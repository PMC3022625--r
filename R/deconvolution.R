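# Clone-read deconvolution: recover the ordered, oriented tags of each
# concatemer insert, assign each tag to a panel gene by mismatch-tolerant
# matching (replacing the original manual + BLAST step), and count tag
# occurrences per sample.

#' Locate restriction-site junction hexamers in a read
#'
#' Exact occurrences of GGATCC and AAGCTT, 0-based positions. The two
#' hexamers cannot overlap themselves, so positions are overlap-free.
#'
#' @param read a single read (ACGTN).
#' @return data.frame with `position` (0-based) and `site`, sorted by
#'   position; zero rows if no site occurs.
#' @export
find_junctions <- function(read) {
  stopifnot(length(read) == 1L, nchar(read) > 0L)
  assert_dna(read, "read", allow_n = TRUE)
  b <- find_all(read, BAMHI)
  h <- find_all(read, HINDIII)
  d <- data.frame(position = c(b, h),
                  site = c(rep(BAMHI, length(b)), rep(HINDIII, length(h))),
                  stringsAsFactors = FALSE)
  d[order(d$position), , drop = FALSE]
}

# Best degenerate junction (<=1 mismatch to either hexamer) strictly inside
# [from, to] (0-based start positions). Used to rescue two tags merged by a
# sequencing error inside their shared junction hexamer.
best_degenerate_junction <- function(read, from, to) {
  if (to < from) return(NULL)
  best <- NULL
  for (p in from:to) {
    hex <- substr_v(read, p + 1L, p + 6L)
    for (site in c(BAMHI, HINDIII)) {
      mm <- sum(charToRaw(hex) != charToRaw(site))
      if (mm <= 1L && (is.null(best) || mm < best$mm ||
                       (mm == best$mm && abs(p - (from + to) / 2) <
                          abs(best$position - (from + to) / 2)))) {
        best <- list(position = p, site = site, mm = mm)
      }
    }
  }
  best
}

#' Extract ordered, oriented tags from clone reads
#'
#' Splits each read at its junction hexamers using the shared-boundary
#' convention (each fragment keeps the full hexamer at both ends, mirroring
#' the simulator/digestion convention). Orientations are assigned by strict
#' alternation anchored at the BamHI-proximal end when the junction pattern
#' is consistent, otherwise `unknown`. Fragments whose length falls outside
#' `tag_len_range` are flagged, not dropped; over-long fragments are first
#' offered a single rescue split at the best degenerate hexamer (<=1
#' mismatch to GGATCC or AAGCTT), recovering tags merged by a sequencing
#' error inside a junction.
#'
#' @param reads named character vector of reads (names = clone ids).
#' @param tag_len_range plausible tag length range including slack, bp.
#' @return data.frame of class `oriented_tags`: clone_id, index, sequence,
#'   orientation ("F"/"RC"/"unknown"), left_site, right_site, flagged,
#'   reason.
#' @export
extract_tags <- function(reads, tag_len_range = c(55L, 75L)) {
  stopifnot(is.character(reads), !is.null(names(reads)))
  per_read <- lapply(seq_along(reads), function(ri) {
    read <- reads[[ri]]
    cid <- names(reads)[ri]
    jn <- find_junctions(read)
    n <- nchar(read)

    # fragment boundaries: consecutive junction starts; terminal partials
    # (corrupted end hexamer) become flagged fragments.
    if (nrow(jn) == 0L) {
      inrange <- n >= tag_len_range[1] && n <= tag_len_range[2]
      return(data.frame(clone_id = cid, index = 1L, sequence = read,
                        orientation = "unknown", left_site = NA_character_,
                        right_site = NA_character_, flagged = TRUE,
                        reason = if (inrange) "no junction hexamer"
                                 else "malformed clone: no junctions, length out of range",
                        stringsAsFactors = FALSE))
    }
    starts <- jn$position
    sites <- jn$site
    frags <- list()
    if (starts[1] > 0L)  # leading partial before the first intact site
      frags[[length(frags) + 1L]] <- list(
        seq = substr_v(read, 1L, starts[1] + 6L),
        left = NA_character_, right = sites[1], partial = TRUE)
    if (nrow(jn) >= 2L) {
      for (i in seq_len(nrow(jn) - 1L)) {
        frags[[length(frags) + 1L]] <- list(
          seq = substr_v(read, starts[i] + 1L, starts[i + 1L] + 6L),
          left = sites[i], right = sites[i + 1L], partial = FALSE)
      }
    }
    last <- nrow(jn)
    if (starts[last] + 6L < n)  # trailing partial after the last intact site
      frags[[length(frags) + 1L]] <- list(
        seq = substr_v(read, starts[last] + 1L, n),
        left = sites[last], right = NA_character_, partial = TRUE)

    # rescue merged fragments (length >~ two tags) with one internal split
    rescued <- list()
    for (f in frags) {
      flen <- nchar(f$seq)
      if (flen > tag_len_range[2] && flen >= 2L * tag_len_range[1] - 6L) {
        dj <- best_degenerate_junction(f$seq, tag_len_range[1] - 6L,
                                       flen - tag_len_range[1])
        if (!is.null(dj)) {
          p <- dj$position
          left_seq <- paste0(substr_v(f$seq, 1L, p), dj$site)
          right_seq <- paste0(dj$site, substr_v(f$seq, p + 7L, flen))
          rescued[[length(rescued) + 1L]] <- list(
            seq = left_seq, left = f$left, right = dj$site,
            partial = f$partial)
          rescued[[length(rescued) + 1L]] <- list(
            seq = right_seq, left = dj$site, right = f$right,
            partial = f$partial)
          next
        }
      }
      rescued[[length(rescued) + 1L]] <- f
    }
    frags <- rescued

    lefts <- vapply(frags, function(f) f$left %||% NA_character_, character(1))
    rights <- vapply(frags, function(f) f$right %||% NA_character_, character(1))
    k <- length(frags)
    # alternation check over the full junction chain
    chain <- c(lefts[1], rights)
    chain_ok <- all(chain[-1] != chain[-length(chain)], na.rm = TRUE)
    orient <- rep("unknown", k)
    if (chain_ok) {
      # a canonical tag starts with GGATCC and ends with AAGCTT, so a
      # fragment's flanking junctions determine its orientation directly
      for (i in seq_len(k)) {
        if (!is.na(lefts[i]))
          orient[i] <- if (lefts[i] == BAMHI) "F" else "RC"
        else if (!is.na(rights[i]))
          orient[i] <- if (rights[i] == HINDIII) "F" else "RC"
      }
    }
    lens <- vapply(frags, function(f) nchar(f$seq), integer(1))
    partial <- vapply(frags, function(f) f$partial, logical(1))
    len_ok <- lens >= tag_len_range[1] & lens <= tag_len_range[2]
    flagged <- partial | !len_ok | !chain_ok
    reason <- rep(NA_character_, k)
    reason[partial] <- "terminal fragment missing a junction hexamer"
    reason[!len_ok] <- "fragment length outside expected tag range"
    if (!chain_ok) reason[is.na(reason)] <- "non-alternating junction pattern"
    if (!chain_ok) orient <- rep("unknown", k)
    data.frame(clone_id = cid, index = seq_len(k),
               sequence = vapply(frags, function(f) f$seq, character(1)),
               orientation = orient, left_site = lefts, right_site = rights,
               flagged = flagged, reason = reason, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, per_read),
            class = c("oriented_tags", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the expected-tag reference for a panel
#'
#' Digests each gene's assembled product in silico and stores the
#' canonical tag and its reverse complement. Warns if two reference tags
#' come closer than `2*max_mismatch + 1` Hamming distance in either
#' orientation (assignment ambiguity guard).
#'
#' @param panel a [design_panel()] result.
#' @param genes matching [gene_targets()].
#' @param max_mismatch mismatch tolerance the reference will be used with.
#' @return data.frame of class `tag_reference`: gene_id, tag, tag_rc, length.
#' @export
tag_reference <- function(panel, genes, max_mismatch = 2L) {
  tags <- digest_amplicons(make_amplicons(panel, genes),
                           attr(panel, "adaptors"))
  ref <- data.frame(gene_id = tags$gene_id, tag = tags$tag,
                    tag_rc = revcomp(tags$tag), length = tags$length,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(c(ref$tag, ref$tag_rc)))
    stop("reference tags are not unique across orientations", call. = FALSE)
  guard <- 2L * max_mismatch + 1L
  n <- nrow(ref)
  for (i in seq_len(max(0L, n - 1L))) for (j in (i + 1L):n) {
    d <- min(tag_distance(ref$tag[i], ref$tag[j]),
             tag_distance(ref$tag[i], ref$tag_rc[j]))
    if (d < guard)
      warning(sprintf("reference tags for %s and %s are only %d mismatches apart (< %d): assignments may be ambiguous",
                      ref$gene_id[i], ref$gene_id[j], d, guard))
  }
  structure(ref, class = c("tag_reference", "data.frame"))
}

# Ungapped distance between two sequences: Hamming when equal length,
# otherwise best sliding offset of the shorter within the longer, with the
# length difference itself counted as mismatches.
tag_distance <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  la <- length(ra); lb <- length(rb)
  if (la == lb) return(sum(ra != rb))
  if (la > lb) { tmp <- ra; ra <- rb; rb <- tmp; tmp <- la; la <- lb; lb <- tmp }
  d <- lb - la
  best <- la  # upper bound
  for (off in 0:d) {
    mm <- sum(ra != rb[(off + 1L):(off + la)])
    if (mm < best) best <- mm
  }
  best + d
}

#' Assign extracted tags to panel genes
#'
#' Best ungapped-distance match over both orientations of every reference
#' tag. A tag is assigned iff its best distance is at most `max_mismatch`
#' AND the margin to the best other gene is at least 2; it is `ambiguous`
#' if the margin rule fails and `unassigned` if no gene comes close
#' enough.
#'
#' @param tags an [extract_tags()] data.frame, or a character vector of
#'   tag sequences.
#' @param reference a [tag_reference()] data.frame.
#' @param max_mismatch maximum tolerated distance (default 2).
#' @return the input data.frame with columns `gene_id` (NA when not
#'   assigned), `status` ("assigned"/"unassigned"/"ambiguous"), `distance`.
#' @export
assign_tags <- function(tags, reference, max_mismatch = 2L) {
  if (!nrow(reference)) stop("empty tag reference", call. = FALSE)
  if (is.character(tags))
    tags <- data.frame(clone_id = NA_character_, index = seq_along(tags),
                       sequence = tags, orientation = "unknown",
                       stringsAsFactors = FALSE)
  res <- lapply(tags$sequence, function(s) {
    dists <- pmin(
      vapply(reference$tag, tag_distance, numeric(1), a = s, USE.NAMES = FALSE),
      vapply(reference$tag_rc, tag_distance, numeric(1), a = s, USE.NAMES = FALSE))
    o <- order(dists)
    best <- dists[o[1]]
    second <- if (length(dists) > 1L) dists[o[2]] else Inf
    if (best <= max_mismatch && second - best >= 2)
      list(gene = reference$gene_id[o[1]], status = "assigned", d = best)
    else if (best <= max_mismatch)
      list(gene = NA_character_, status = "ambiguous", d = best)
    else list(gene = NA_character_, status = "unassigned", d = best)
  })
  tags$gene_id <- vapply(res, `[[`, character(1), "gene")
  tags$status <- vapply(res, `[[`, character(1), "status")
  tags$distance <- vapply(res, function(r) as.numeric(r$d), numeric(1))
  tags
}

#' Count assigned tags per sample and gene
#'
#' @param assignments an [assign_tags()] result with a `sample_id` column
#'   (or a list of such data.frames named by sample).
#' @param gene_ids full panel gene set (zero counts are kept).
#' @return object of class `tag_count_table`: list with `counts` (gene x
#'   sample integer matrix), `unassigned`, `ambiguous` (per-sample
#'   vectors) and `total` (total extracted tags per sample).
#' @export
count_tags <- function(assignments, gene_ids) {
  if (is.data.frame(assignments)) {
    if (!"sample_id" %in% names(assignments))
      stop("assignments need a sample_id column", call. = FALSE)
    assignments <- split(assignments, assignments$sample_id)
  }
  samples <- names(assignments)
  counts <- matrix(0L, nrow = length(gene_ids), ncol = length(samples),
                   dimnames = list(gene_ids, samples))
  unass <- ambig <- total <- setNames(integer(length(samples)), samples)
  for (s in samples) {
    a <- assignments[[s]]
    bad <- setdiff(unique(a$gene_id[a$status == "assigned"]), gene_ids)
    if (length(bad))
      stop("assignment to unknown gene(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    tab <- table(factor(a$gene_id[a$status == "assigned"], levels = gene_ids))
    counts[, s] <- as.integer(tab)
    unass[s] <- sum(a$status == "unassigned")
    ambig[s] <- sum(a$status == "ambiguous")
    total[s] <- nrow(a)
  }
  stopifnot(all(colSums(counts) + unass + ambig == total))
  structure(list(counts = counts, unassigned = unass, ambiguous = ambig,
                 total = total), class = "tag_count_table")
}

#' @export
print.tag_count_table <- function(x, ...) {
  cat("tag_count_table:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  print(x$counts)
  cat("unassigned:", paste(names(x$unassigned), x$unassigned, sep = "=",
                           collapse = " "), "\n")
  cat("ambiguous: ", paste(names(x$ambiguous), x$ambiguous, sep = "=",
                           collapse = " "), "\n")
  invisible(x)
}

#' Deconvolve clone reads into a tag count table
#'
#' End-to-end wrapper: extract tags from each sample's reads, assign them
#' against the panel reference, and tabulate.
#'
#' @param reads_by_sample named list of named read vectors (sample ->
#'   reads).
#' @param reference a [tag_reference()].
#' @param max_mismatch mismatch tolerance.
#' @param tag_len_range plausible tag length window, bp.
#' @return list of class `deconvolution`: `counts` (a
#'   [count_tags()] table), `audit` (tag-level assignments), `malformed`
#'   (flagged fragments).
#' @export
deconvolve_reads <- function(reads_by_sample, reference, max_mismatch = 2L,
                             tag_len_range = c(55L, 75L)) {
  stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
  audits <- lapply(names(reads_by_sample), function(s) {
    tg <- extract_tags(reads_by_sample[[s]], tag_len_range)
    tg <- assign_tags(tg, reference, max_mismatch)
    tg$sample_id <- s
    tg
  })
  audit <- do.call(rbind, audits)
  counts <- count_tags(split(audit, audit$sample_id), reference$gene_id)
  structure(list(counts = counts, audit = audit,
                 malformed = audit[audit$flagged, , drop = FALSE]),
            class = "deconvolution")
}
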