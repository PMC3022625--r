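# File formats: FASTA via Biostrings, TSV (tab, UTF-8, header row),
# YAML run configuration.

#' Read a FASTA file into a named character vector
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Lowercase bases are uppercased with a warning; duplicate ids are an
#' error; an empty file yields an empty vector with a warning.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- as.character(ss)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase bases in ", path, " were uppercased")
    seqs <- toupper(seqs)
  }
  setNames(unname(seqs), ids)
}

#' Write a named character vector as FASTA
#'
#' @param x named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(is.character(x), !is.null(names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    n <- nchar(s)
    if (n == 0L) next
    writeLines(substring(s, seq(1L, n, width),
                         pmin(seq(1L, n, width) + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read gene targets from FASTA
#'
#' @param path multi-FASTA of target genes.
#' @param control gene id of the internal control.
#' @return a [gene_targets()] data.frame.
#' @export
read_gene_targets <- function(path, control) {
  x <- read_fasta(path)
  gene_targets(names(x), unname(x), control = control)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, comment.char = "#",
             ...)
}

#' Write a designed panel as TSV (+ optional primer FASTA)
#'
#' @param panel a [design_panel()] result.
#' @param path output TSV.
#' @param fasta_path optional FASTA of the full chimeric primer sequences
#'   (ids `<gene>_F` / `<gene>_R`).
#' @export
write_panel <- function(panel, path, fasta_path = NULL) {
  stopifnot(inherits(panel, "primer_panel"))
  write_tsv(as.data.frame(panel), path)
  if (!is.null(fasta_path)) {
    pr <- c(setNames(panel$fwd_full, paste0(panel$gene_id, "_F")),
            setNames(panel$rev_full, paste0(panel$gene_id, "_R")))
    write_fasta(pr[order(names(pr))], fasta_path)
  }
  invisible(path)
}

#' Read a panel TSV back into a `primer_panel`
#'
#' The TSV stores only the per-pair table; adaptors and constraints are
#' re-attached from the arguments and checked against the stored full
#' primer sequences.
#'
#' @param path panel TSV written by [write_panel()].
#' @param adaptors,constraints the adaptors/constraints the panel was
#'   designed with.
#' @return a `primer_panel`.
#' @export
read_panel <- function(path, adaptors = universal_adaptors(),
                       constraints = design_constraints()) {
  d <- read_tsv(path)
  need <- c("gene_id", "fwd_specific", "rev_specific", "fwd_full",
            "rev_full", "tm_fwd", "tm_rev", "amplicon_start",
            "amplicon_end", "amplicon_len")
  if (!all(need %in% names(d)))
    stop("panel TSV is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  if (!all(startsWith(d$fwd_full, adaptors$forward_tag)) ||
      !all(startsWith(d$rev_full, adaptors$reverse_tag)))
    stop("panel TSV does not match the supplied universal adaptors",
         call. = FALSE)
  tms <- c(d$tm_fwd, d$tm_rev)
  structure(d[need], adaptors = adaptors, constraints = constraints,
            summary = list(mean_tm = mean(tms), sd_tm = sd(tms),
                           max_pairwise_dtm = max(tms) - min(tms)),
            class = c("primer_panel", "data.frame"))
}

#' Read an expression-profile TSV (sample_id, gene_id, weight)
#' @param path TSV file.
#' @return an [expression_profile()].
#' @export
read_profiles <- function(path) {
  d <- read_tsv(path)
  expression_profile(d$sample_id, d$gene_id, d$weight)
}

#' Write a tag-count table as long TSV (sample, gene, count)
#'
#' Bookkeeping rows `__unassigned__` and `__ambiguous__` keep the
#' conservation invariant visible in the file.
#'
#' @param counts a `tag_count_table`.
#' @param path output TSV.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "tag_count_table"))
  m <- counts$counts
  long <- data.frame(
    sample_id = rep(colnames(m), each = nrow(m)),
    gene_id = rep(rownames(m), ncol(m)),
    count = as.integer(m), stringsAsFactors = FALSE)
  extra <- data.frame(
    sample_id = rep(colnames(m), 2),
    gene_id = rep(c("__unassigned__", "__ambiguous__"), each = ncol(m)),
    count = c(as.integer(counts$unassigned), as.integer(counts$ambiguous)),
    stringsAsFactors = FALSE)
  write_tsv(rbind(long, extra), path)
}

#' Read a long count TSV back into a `tag_count_table`
#' @param path TSV written by [write_counts()].
#' @return a `tag_count_table`.
#' @export
read_counts <- function(path) {
  d <- read_tsv(path)
  special <- d$gene_id %in% c("__unassigned__", "__ambiguous__")
  body <- d[!special, ]
  genes <- unique(body$gene_id)
  samples <- unique(d$sample_id)
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(body$gene_id, genes), match(body$sample_id, samples))] <-
    as.integer(body$count)
  pick <- function(tag) {
    x <- d[d$gene_id == tag, ]
    setNames(as.integer(x$count[match(samples, x$sample_id)]), samples)
  }
  un <- pick("__unassigned__"); am <- pick("__ambiguous__")
  un[is.na(un)] <- 0L; am[is.na(am)] <- 0L
  structure(list(counts = m, unassigned = un, ambiguous = am,
                 total = colSums(m) + un + am), class = "tag_count_table")
}

#' Path to a packaged fixture file
#' @param file file name under the package's `extdata/`.
#' @return absolute path.
#' @export
mgc_fixture <- function(file) {
  p <- system.file("extdata", file, package = "mgcgep", mustWork = FALSE)
  if (!nzchar(p)) stop("no packaged fixture '", file, "'", call. = FALSE)
  p
}
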