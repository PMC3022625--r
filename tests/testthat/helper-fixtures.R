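# Shared fixtures, built once per test run. The packaged 20-gene panel
# takes a couple of seconds to design, so it is memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture_genes <- function() {
  if (is.null(.fixture_cache$genes))
    .fixture_cache$genes <- read_gene_targets(
      mgc_fixture("genes_synthetic.fa"), "ACT1")
  .fixture_cache$genes
}

fixture_panel <- function() {
  if (is.null(.fixture_cache$panel))
    .fixture_cache$panel <- design_panel(fixture_genes())
  .fixture_cache$panel
}

fixture_profile <- function() {
  read_profiles(mgc_fixture("profiles_synthetic.tsv"))
}

fixture_truth_lfc <- function() {
  read.delim(mgc_fixture("truth_lfc_synthetic.tsv"))
}

# One default error-free simulation of the packaged design, memoised.
fixture_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_experiment(
      fixture_panel(), fixture_genes(), fixture_profile(),
      sim_config(rng_seed = 20110118))
  .fixture_cache$sim
}

fixture_reference <- function() {
  if (is.null(.fixture_cache$ref))
    .fixture_cache$ref <- tag_reference(fixture_panel(), fixture_genes())
  .fixture_cache$ref
}

# Tiny toy gene sets with deliberately small candidate spaces, for
# brute-force cross-product comparisons.
toy_constraints <- function() {
  # tiny candidate spaces for cross-product oracles; the dTm cap is opened
  # up so random toy genes stay feasible and the objective is exercised
  design_constraints(specific_len_range = c(17L, 19L),
                     max_pairwise_dtm = 30)
}

toy_genes <- function(n, len = 52L, gc = 0.5, seed = 101L, control = NULL) {
  set.seed(seed)
  ids <- paste0("T", seq_len(n))
  seqs <- vapply(ids, function(i) {
    repeat {
      s <- random_dna(len, gc)
      if (regexpr("GGATCC", s, fixed = TRUE) == -1 &&
          regexpr("AAGCTT", s, fixed = TRUE) == -1) return(s)
    }
  }, character(1))
  gene_targets(ids, unname(seqs), control = control %||% ids[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
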