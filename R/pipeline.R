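# End-to-end pipeline and command-line surface.

#' Default run configuration
#'
#' A nested list of every tunable the pipeline exposes; it round-trips
#' losslessly through YAML. `genes_fasta`/`profiles_tsv` default to the
#' packaged synthetic fixtures.
#'
#' @param seed integer RNG seed for the whole run.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    genes_fasta = mgc_fixture("genes_synthetic.fa"),
    profiles_tsv = mgc_fixture("profiles_synthetic.tsv"),
    control_gene = "ACT1",
    treated = "treated", untreated = "untreated",
    adaptors = list(forward_tag = "ACGTCGTTCAGGATCCTC",
                    reverse_tag = "TGCACTGACTAAGCTTGCA"),
    constraints = list(specific_len_range = c(16L, 20L),
                       amplicon_center = 85L, amplicon_tol = 7L,
                       max_pairwise_dtm = 5),
    tm = list(primer_conc_M = 2.5e-7, monovalent_mM = 50, mg_mM = 5),
    sim = list(n_clones = 300L, tag_pool_depth = 100000L,
               seq_error_rate = 0, size_window = c(500L, 1200L),
               stop_prob = 0.075, n_chain_candidates = 5000L),
    deconv = list(max_mismatch = 2L, tag_len_range = c(55L, 75L)),
    quant = list(conf_level = 0.95, fold_threshold = 1.5),
    qpcr = list(simulate = TRUE, n_replicates = 3L, ct_noise_sd = 0.2,
                records_tsv = NULL)),
    class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return a `run_config` (for the reader).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (k in names(raw)) {
    if (is.list(cfg[[k]]) && is.list(raw[[k]])) {
      for (k2 in names(raw[[k]])) cfg[[k]][[k2]] <- raw[[k]][[k2]]
    } else cfg[[k]] <- raw[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config` list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

cfg_objects <- function(cfg) {
  list(adaptors = universal_adaptors(cfg$adaptors$forward_tag,
                                     cfg$adaptors$reverse_tag),
       constraints = design_constraints(
         specific_len_range = cfg$constraints$specific_len_range,
         amplicon_center = cfg$constraints$amplicon_center,
         amplicon_tol = cfg$constraints$amplicon_tol,
         max_pairwise_dtm = cfg$constraints$max_pairwise_dtm,
         tm = tm_params(primer_conc_M = cfg$tm$primer_conc_M,
                        monovalent_mM = cfg$tm$monovalent_mM,
                        mg_mM = cfg$tm$mg_mM)),
       sim = sim_config(n_clones = cfg$sim$n_clones,
                        tag_pool_depth = cfg$sim$tag_pool_depth,
                        seq_error_rate = cfg$sim$seq_error_rate,
                        size_window = cfg$sim$size_window,
                        stop_prob = cfg$sim$stop_prob,
                        n_chain_candidates = cfg$sim$n_chain_candidates,
                        rng_seed = cfg$seed))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline: design, simulate, deconvolve, quantify, compare
#'
#' Executes every stage in order, writes all artifacts into `out_dir`,
#' and finishes with `manifest.json` listing each output with its MD5
#' checksum. Identical configuration and seed give identical checksums.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the in-memory results and the manifest.
#' @export
run_end_to_end <- function(config = default_run_config(), out_dir) {
  stopifnot(!missing(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- run_stage("config", cfg_objects(config))

  genes <- run_stage("design",
    read_gene_targets(config$genes_fasta, config$control_gene))
  panel <- run_stage("design",
    design_panel(genes, obj$adaptors, obj$constraints))
  write_panel(panel, file.path(out_dir, "panel.tsv"),
              file.path(out_dir, "primers.fasta"))

  profile <- run_stage("simulate", read_profiles(config$profiles_tsv))
  sim <- run_stage("simulate",
    simulate_experiment(panel, genes, profile, obj$sim))
  for (s in names(sim$samples)) {
    write_fasta(sim$samples[[s]]$reads,
                file.path(out_dir, paste0("reads_", s, ".fasta")))
    write_tsv(sim$samples[[s]]$truth,
              file.path(out_dir, paste0("truth_", s, ".tsv")))
  }

  ref <- run_stage("deconvolve", tag_reference(panel, genes,
                                               config$deconv$max_mismatch))
  dec <- run_stage("deconvolve", deconvolve_reads(
    lapply(sim$samples, `[[`, "reads"), ref,
    config$deconv$max_mismatch, config$deconv$tag_len_range))
  write_counts(dec$counts, file.path(out_dir, "counts.tsv"))
  write_tsv(dec$audit, file.path(out_dir, "tag_audit.tsv"))
  write_tsv(dec$malformed, file.path(out_dir, "malformed.tsv"))

  est <- run_stage("quantify", relative_expression(
    dec$counts, config$treated, config$untreated, config$control_gene,
    config$quant$conf_level))
  write_tsv(as.data.frame(est), file.path(out_dir, "estimates.tsv"))

  qrec <- run_stage("compare", {
    if (!is.null(config$qpcr$records_tsv)) read_tsv(config$qpcr$records_tsv)
    else simulate_qpcr(profile, config$qpcr$n_replicates,
                       config$qpcr$ct_noise_sd)
  })
  qf <- run_stage("compare", qpcr_fold_changes(
    qrec, config$control_gene, config$treated, config$untreated))
  conc <- run_stage("compare",
    concordance(est, qf, config$quant$fold_threshold))
  write_tsv(qf, file.path(out_dir, "qpcr_folds.tsv"))
  write_tsv(conc$table, file.path(out_dir, "concordance.tsv"))

  write_run_config(config, file.path(out_dir, "config_resolved.yaml"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(list(panel = panel, simulation = sim, deconvolution = dec,
                 estimates = est, qpcr_folds = qf, concordance = conc,
                 manifest = manifest))
}

# ---- command-line surface ------------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]; i <- i + 2L
    }
  }
  out
}

need_opt <- function(opts, key) {
  if (is.null(opts[[key]]))
    stop("missing required option --", key, call. = FALSE)
  opts[[key]]
}

load_cli_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
         else default_run_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  cfg
}

#' Command-line entry point
#'
#' Subcommands: `design`, `simulate`, `deconvolve`, `quantify`,
#' `compare`, `run-all`. Options are `--key value` pairs; global options
#' `--config YAML` and `--seed INT`. Returns the process exit code
#' (0 ok, 2 usage error, 3 data error); the installed `exec/mgcgep`
#' script forwards it to `quit()`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
mgc_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mgcgep <design|simulate|deconvolve|quantify|compare|run-all>",
    "[--config YAML] [--seed INT] [options]")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[[1]]
  code <- tryCatch({
    opts <- parse_cli_args(args[-1])
    cfg <- load_cli_config(opts)
    obj <- cfg_objects(cfg)
    switch(cmd,
      design = {
        genes <- read_gene_targets(need_opt(opts, "genes"),
                                   need_opt(opts, "control"))
        panel <- design_panel(genes, obj$adaptors, obj$constraints)
        prefix <- need_opt(opts, "out")
        write_panel(panel, paste0(prefix, ".panel.tsv"),
                    paste0(prefix, ".primers.fasta"))
        message("wrote ", prefix, ".panel.tsv")
      },
      simulate = {
        genes <- read_gene_targets(need_opt(opts, "genes"),
                                   opts$control %||% cfg$control_gene)
        panel <- read_panel(need_opt(opts, "panel"), obj$adaptors,
                            obj$constraints)
        profile <- read_profiles(need_opt(opts, "profiles"))
        out <- need_opt(opts, "out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        sim <- simulate_experiment(panel, genes, profile, obj$sim)
        for (s in names(sim$samples)) {
          write_fasta(sim$samples[[s]]$reads,
                      file.path(out, paste0("reads_", s, ".fasta")))
          write_tsv(sim$samples[[s]]$truth,
                    file.path(out, paste0("truth_", s, ".tsv")))
        }
        writeLines(paste("seed:", cfg$seed), file.path(out, "run_log.txt"))
      },
      deconvolve = {
        genes <- read_gene_targets(need_opt(opts, "genes"),
                                   opts$control %||% cfg$control_gene)
        panel <- read_panel(need_opt(opts, "panel"), obj$adaptors,
                            obj$constraints)
        mm <- as.integer(opts[["max-mismatch"]] %||% cfg$deconv$max_mismatch)
        ref <- tag_reference(panel, genes, mm)
        paths <- strsplit(need_opt(opts, "reads"), ",", fixed = TRUE)[[1]]
        reads <- lapply(paths, read_fasta)
        names(reads) <- sub("^reads_", "",
                            tools::file_path_sans_ext(basename(paths)))
        out <- need_opt(opts, "out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        dec <- deconvolve_reads(reads, ref, mm, cfg$deconv$tag_len_range)
        write_counts(dec$counts, file.path(out, "counts.tsv"))
        write_tsv(dec$audit, file.path(out, "tag_audit.tsv"))
        write_tsv(dec$malformed, file.path(out, "malformed.tsv"))
      },
      quantify = {
        counts <- read_counts(need_opt(opts, "counts"))
        est <- relative_expression(counts,
                                   opts$treated %||% cfg$treated,
                                   opts$untreated %||% cfg$untreated,
                                   opts$control %||% cfg$control_gene,
                                   cfg$quant$conf_level)
        write_tsv(as.data.frame(est), need_opt(opts, "out"))
      },
      compare = {
        est <- read_tsv(need_opt(opts, "estimates"))
        qrec <- read_tsv(need_opt(opts, "qpcr"))
        qf <- qpcr_fold_changes(qrec, opts$control %||% cfg$control_gene,
                                opts$treated %||% cfg$treated,
                                opts$untreated %||% cfg$untreated)
        conc <- concordance(est, qf, cfg$quant$fold_threshold)
        write_tsv(conc$table, need_opt(opts, "out"))
        message(sprintf("concordance: %d/%d", conc$n_agree, conc$n_genes))
      },
      `run-all` = {
        run_end_to_end(cfg, need_opt(opts, "out"))
      },
      stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("usage|unknown subcommand|missing required", conditionMessage(e)))
      2L else 3L
  })
  invisible(code)
}
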