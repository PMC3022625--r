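# Read deconvolution: junction finding, tag extraction, assignment,
# counting.

test_that("find_junctions reports exact hand-checked positions", {
  expect_identical(nrow(find_junctions("ACGTACGTACGT")), 0L)
  jn <- find_junctions("AAGGATCCTTAAGCTTGG")
  expect_identical(jn$position, c(2L, 10L))
  expect_identical(jn$site, c("GGATCC", "AAGCTT"))
})

test_that("find_junctions equals the sliding-window oracle scan", {
  set.seed(41)
  for (i in 1:20) {
    r <- paste(sample(c("A", "C", "G", "T", "GGATCC", "AAGCTT"),
                      sample(10:60, 1), TRUE, prob = c(rep(0.23, 4), .04, .04)),
               collapse = "")
    mine <- find_junctions(r)
    oracle <- naive_scan_junctions(r)
    expect_identical(`rownames<-`(mine, NULL), `rownames<-`(oracle, NULL))
  }
})

test_that("extract_tags recovers a hand-built three-tag concatemer (F, RC, F)", {
  ref <- fixture_reference()
  t1 <- ref$tag[1]; t2 <- ref$tag[2]; t3 <- ref$tag[3]
  # F-RC-F chain with shared junction hexamers
  read <- paste0(t1, substring(revcomp(t2), 7), substring(t3, 7))
  out <- extract_tags(setNames(read, "c1"))
  expect_identical(nrow(out), 3L)
  expect_identical(out$orientation, c("F", "RC", "F"))
  expect_identical(out$sequence, c(t1, revcomp(t2), t3))
  expect_false(any(out$flagged))
})

test_that("a single-tag read resolves via its terminal sites", {
  ref <- fixture_reference()
  out <- extract_tags(setNames(ref$tag[5], "c1"))
  expect_identical(nrow(out), 1L)
  expect_identical(out$orientation, "F")
  out_rc <- extract_tags(setNames(ref$tag_rc[5], "c2"))
  expect_identical(out_rc$orientation, "RC")
  expect_false(out$flagged || out_rc$flagged)
})

test_that("round trip: error-free deconvolution reproduces the simulator truth exactly", {
  sim <- fixture_sim()
  ref <- fixture_reference()
  for (s in names(sim$samples)) {
    tg <- extract_tags(sim$samples[[s]]$reads)
    tg <- assign_tags(tg, ref)
    truth <- sim$samples[[s]]$truth
    expect_false(any(tg$flagged))
    expect_identical(nrow(tg), nrow(truth))
    o1 <- order(tg$clone_id, tg$index)
    o2 <- order(truth$clone_id, truth$position)
    expect_identical(tg$clone_id[o1], truth$clone_id[o2])
    expect_identical(tg$index[o1], truth$position[o2])
    expect_identical(tg$gene_id[o1], truth$gene_id[o2])     # assignment
    expect_identical(tg$orientation[o1], truth$orientation[o2])
    expect_true(all(tg$status == "assigned"))
    expect_true(all(tg$distance == 0))
  }
})

test_that("tag assignment matches the all-pairs brute-force oracle on 500 random tags", {
  set.seed(42)
  ref <- fixture_reference()
  tags <- character(500)
  for (i in 1:500) {
    r <- runif(1)
    base <- ref$tag[sample.int(nrow(ref), 1)]
    if (r < 0.35) tags[i] <- mutate_seq(base, sample(0:3, 1))
    else if (r < 0.6) tags[i] <- mutate_seq(revcomp(base), sample(0:3, 1))
    else if (r < 0.75) {        # length-perturbed: trimmed or padded
      s <- mutate_seq(base, sample(0:2, 1))
      tags[i] <- if (runif(1) < 0.5) substring(s, 2)
                 else paste0(s, sample(c("A", "C", "G", "T"), 1))
    } else tags[i] <- random_dna(sample(55:75, 1))
  }
  mine <- assign_tags(tags, ref, max_mismatch = 2)
  for (i in seq_along(tags)) {
    o <- naive_assign(tags[i], ref, max_mismatch = 2)
    expect_identical(mine$status[i], o$status)
    expect_identical(mine$gene_id[i], o$gene)
  }
})

test_that("exact and 1-mismatch reference tags assign to their gene", {
  ref <- fixture_reference()
  set.seed(43)
  a <- assign_tags(ref$tag, ref)
  expect_identical(a$gene_id, ref$gene_id)
  expect_true(all(a$distance == 0))
  mut <- vapply(ref$tag, mutate_seq, character(1), k = 1)
  a1 <- assign_tags(unname(mut), ref, max_mismatch = 2)
  expect_identical(a1$gene_id, ref$gene_id)
  expect_error(assign_tags("ACGT", ref[0, ]), "empty")
})

test_that("merged-junction rescue recovers tags hit by an error inside the hexamer", {
  set.seed(44)
  ref <- fixture_reference()
  t1 <- ref$tag[7]; t2 <- ref$tag[8]; t3 <- ref$tag[9]
  read <- paste0(t1, substring(revcomp(t2), 7), substring(t3, 7))
  # corrupt one base of the middle junction hexamer (an AAGCTT at the
  # t1|rc(t2) boundary)
  pos <- nchar(t1) - 3L
  substr(read, pos, pos) <- "C"
  out <- assign_tags(extract_tags(setNames(read, "c1")), ref)
  expect_identical(nrow(out), 3L)
  expect_identical(out$gene_id, ref$gene_id[7:9])
  expect_true(all(out$status == "assigned"))
})

test_that("counting conserves totals and is permutation-invariant over clones", {
  sim <- fixture_sim()
  ref <- fixture_reference()
  reads <- sim$samples[["treated"]]$reads
  tg <- assign_tags(extract_tags(reads), ref)
  tg$sample_id <- "treated"
  ct <- count_tags(tg, ref$gene_id)
  expect_equal(unname(colSums(ct$counts) + ct$unassigned + ct$ambiguous),
               unname(as.numeric(ct$total)))
  # permute clone order: identical table
  perm <- tg[sample.int(nrow(tg)), ]
  expect_identical(count_tags(perm, ref$gene_id)$counts, ct$counts)
  # counts equal the truth tally at error rate 0
  truth_tab <- table(factor(sim$samples[["treated"]]$truth$gene_id,
                            levels = ref$gene_id))
  expect_identical(as.integer(ct$counts[, "treated"]),
                   as.integer(truth_tab))
  expect_error(count_tags(transform(tg, gene_id = "nope",
                                    status = "assigned"), ref$gene_id),
               "unknown gene")
  expect_identical(unname(count_tags(
    data.frame(sample_id = "s", gene_id = ref$gene_id[1], status = "assigned",
               flagged = FALSE)[rep(1, 10), ], ref$gene_id)$counts[1, 1]), 10L)
})

test_that("noisy reads still assign >=99% of tags correctly at max_mismatch 2", {
  g <- fixture_genes()
  panel <- fixture_panel()
  prof <- fixture_profile()
  sim <- simulate_experiment(panel, g, prof,
                             sim_config(n_clones = 100L,
                                        seq_error_rate = 0.005,
                                        n_chain_candidates = 2000L,
                                        rng_seed = 4242L))
  ref <- tag_reference(panel, g)
  s <- sim$samples[["treated"]]
  tg <- assign_tags(extract_tags(s$reads), ref)
  truth <- s$truth
  o1 <- order(tg$clone_id, tg$index); o2 <- order(truth$clone_id, truth$position)
  # compare only clones where extraction found the true number of tags
  n1 <- table(tg$clone_id); n2 <- table(truth$clone_id)
  okc <- names(n1)[n1[names(n2)] == n2]
  m1 <- tg[o1, ][tg$clone_id[o1] %in% okc, ]
  m2 <- truth[o2, ][truth$clone_id[o2] %in% okc, ]
  acc <- mean(m1$gene_id == m2$gene_id, na.rm = FALSE)
  expect_gte(sum(n1), 0.98 * sum(n2))  # few clones lose tags to errors
  expect_gte(mean(m1$status == "assigned" & m1$gene_id == m2$gene_id), 0.99)
})
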