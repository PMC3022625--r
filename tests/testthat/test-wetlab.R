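# Protocol simulation: amplification, digestion, ligation, size
# selection, clone sequencing.

test_that("make_amplicons assembles products exactly as tag + window + rc(tag)", {
  g <- fixture_genes()
  panel <- fixture_panel()
  a <- attr(panel, "adaptors")
  amp <- make_amplicons(panel, g)
  expect_identical(nrow(amp), nrow(panel))
  i <- 3L
  win <- substring(g$sequence[match(panel$gene_id[i], g$gene_id)],
                   panel$amplicon_start[i] + 1, panel$amplicon_end[i])
  expect_identical(amp$sequence[i],
                   paste0(a$forward_tag, win, revcomp(a$reverse_tag)))
  expect_true(all(amp$length >= 78 & amp$length <= 92))
  expect_error(make_amplicons(panel, g[-1, ]), "inconsistent")
})

test_that("digestion releases canonical tags of hand-computable length", {
  g <- fixture_genes()
  panel <- fixture_panel()
  a <- attr(panel, "adaptors")
  amp <- make_amplicons(panel, g)
  tags <- digest_amplicons(amp, a)
  # hand count from the configured offsets: everything before the BamHI
  # hexamer and after the HindIII hexamer is discarded
  # the reconstituted amplicon ends with revcomp(reverse_tag), so the
  # bases 5' of AAGCTT in the reverse tag reappear 3' of it here
  discard_left <- a$bamhi_offset
  discard_right <- a$hindiii_offset
  expect_identical(tags$length, amp$length - discard_left - discard_right)
  expect_true(all(tags$length >= 60 & tags$length <= 70))
  expect_true(all(startsWith(tags$tag, "GGATCC")))
  expect_true(all(endsWith(tags$tag, "AAGCTT")))
  expect_identical(unique(tags$left_end), "GATC")
  expect_identical(unique(tags$right_end), "AGCT")
  # injective on the packaged panel: no two genes share a tag
  expect_identical(anyDuplicated(tags$tag), 0L)
})

test_that("digestion rejects products with missing or extra sites", {
  a <- universal_adaptors()
  good <- paste0(a$forward_tag, random_dna(48, 0.5), revcomp(a$reverse_tag))
  bad_extra <- paste0(a$forward_tag, "GGATCC", random_dna(42, 0.5),
                      revcomp(a$reverse_tag))
  expect_error(
    digest_amplicons(data.frame(gene_id = "x", sequence = bad_extra),
                     a), "2 GGATCC")
  bad_missing <- gsub("AAGCTT", "AAGATT", good, fixed = TRUE)
  expect_error(
    digest_amplicons(data.frame(gene_id = "x", sequence = bad_missing),
                     a), "0 AAGCTT")
})

test_that("tag-pool sampling is multinomial with the profile weights", {
  set.seed(31)
  w <- c(a = 0.5, b = 0.5)
  n <- sample_tag_pool(w, 1e5)
  expect_identical(sum(n), 100000L)
  sd_bin <- sqrt(1e5 * 0.25)
  expect_lt(abs(n[["a"]] - 5e4), 4 * sd_bin)
  expect_identical(unname(sample_tag_pool(c(x = 1, y = 0), 50)[["x"]]), 50L)
  expect_error(sample_tag_pool(c(x = 0, y = 0), 10), "all-zero")
  set.seed(99); first <- sample_tag_pool(w, 1000)
  set.seed(99); again <- sample_tag_pool(w, 1000)
  expect_identical(first, again)
})

test_that("ligation enforces sticky-end rules: alternation, junctions, odd-count cloneability", {
  set.seed(32)
  tags <- digest_amplicons(make_amplicons(fixture_panel(), fixture_genes()),
                           universal_adaptors())
  pool <- setNames(rep(10L, nrow(tags)), tags$gene_id)
  cand <- ligate_concatemers(pool, tags, stop_prob = 0.3, n_chains = 400)
  expect_identical(xor(cand$n_tags %% 2 == 1, !cand$cloneable),
                   rep(TRUE, nrow(cand)))
  expect_true(all(cand$left_end[cand$cloneable] == "B" &
                  cand$right_end[cand$cloneable] == "H"))
  expect_true(all(cand$left_end[!cand$cloneable] ==
                  cand$right_end[!cand$cloneable]))
  for (i in seq_len(nrow(cand))) {
    jn <- find_junctions(cand$insert_sequence[i])
    expect_identical(nrow(jn), cand$n_tags[i] + 1L)   # shared junctions
    expect_true(all(jn$site[-1] != jn$site[-nrow(jn)]))  # strict alternation
    ori <- cand$tag_orients[[i]]
    expect_true(all(ori[-1] != ori[-length(ori)]))
  }
  # insert length accounting: sum of tag lengths minus shared hexamers
  len_by_gene <- setNames(tags$length, tags$gene_id)
  expected_len <- vapply(cand$tag_genes, function(gs)
    sum(len_by_gene[gs]) - 6L * (length(gs) - 1L), numeric(1))
  expect_identical(cand$length, as.integer(expected_len))
})

test_that("single-tag chains are cloneable concatemers of themselves", {
  set.seed(33)
  tags <- digest_amplicons(make_amplicons(fixture_panel(), fixture_genes()),
                           universal_adaptors())
  pool <- setNames(rep(1L, nrow(tags)), tags$gene_id)
  cand <- ligate_concatemers(pool, tags, stop_prob = 0.999, n_chains = 50)
  ones <- cand[cand$n_tags == 1L, ]
  expect_gt(nrow(ones), 0)
  expect_true(all(ones$cloneable))
  expect_true(all(ones$insert_sequence %in% tags$tag))
})

test_that("size selection keeps exactly the in-window cloneable inserts, boundaries inclusive", {
  set.seed(34)
  tags <- digest_amplicons(make_amplicons(fixture_panel(), fixture_genes()),
                           universal_adaptors())
  pool <- setNames(rep(5L, nrow(tags)), tags$gene_id)
  cand <- ligate_concatemers(pool, tags, stop_prob = 0.08, n_chains = 600)
  sel <- size_select(cand, c(500L, 1200L))
  oracle_keep <- cand$cloneable & cand$length >= 500 & cand$length <= 1200
  expect_identical(nrow(sel), sum(oracle_keep))
  expect_setequal(sel$chain_id, cand$chain_id[oracle_keep])
  # inclusive boundary behaviour on synthetic entries
  fake <- cand[rep(1L, 3L), ]
  fake$cloneable <- TRUE
  fake$length <- c(499L, 500L, 1200L)
  expect_identical(size_select(fake, c(500L, 1200L))$length, c(500L, 1200L))
  fake$length <- rep(10L, 3L)
  expect_warning(size_select(fake, c(500L, 1200L)), "no cloneable insert")
})

test_that("clone sequencing: exact reads at error 0, binomial errors otherwise, truth rows complete", {
  sim <- fixture_sim()
  s <- sim$samples[["untreated"]]
  expect_length(s$reads, 300L)
  expect_identical(sort(unique(s$truth$clone_id)), sort(names(s$reads)))
  # error rate 0: every read is literally one of the surviving inserts
  expect_true(all(s$reads %in% s$inserts$insert_sequence))
  # per-clone truth matches the read content
  one <- names(s$reads)[5]
  tr <- s$truth[s$truth$clone_id == one, ]
  expect_identical(tr$position, seq_len(nrow(tr)))
  expect_identical(nchar(s$reads[[one]]), tr$insert_length[1])

  set.seed(35)
  ins <- s$inserts[rep(1L, 1L), ]
  reads <- replicate(300, {
    sequence_clones(ins, 1L, seq_error_rate = 0.01, "e")$reads[[1]]
  })
  n_sub <- vapply(reads, function(r)
    sum(charToRaw(r) != charToRaw(ins$insert_sequence[1])), numeric(1))
  expected <- 0.01 * nchar(ins$insert_sequence[1])
  expect_lt(abs(mean(n_sub) - expected), 3 * sqrt(expected) / sqrt(300))
  expect_error(sequence_clones(ins, 0L), "positive")
})

test_that("simulation configuration validates its bounds", {
  expect_error(sim_config(n_clones = 0), ">= 1")
  expect_error(sim_config(seq_error_rate = 0.2), "0.1")
  expect_error(sim_config(size_window = c(1200, 500)))
})

test_that("a fixed seed reproduces the whole simulated experiment", {
  cfgA <- sim_config(n_clones = 30L, tag_pool_depth = 1e4L,
                     n_chain_candidates = 800L, rng_seed = 77L)
  simA <- simulate_experiment(fixture_panel(), fixture_genes(),
                              fixture_profile(), cfgA)
  simB <- simulate_experiment(fixture_panel(), fixture_genes(),
                              fixture_profile(), cfgA)
  expect_identical(lapply(simA$samples, `[[`, "reads"),
                   lapply(simB$samples, `[[`, "reads"))
  expect_identical(lapply(simA$samples, `[[`, "truth"),
                   lapply(simB$samples, `[[`, "truth"))
})
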