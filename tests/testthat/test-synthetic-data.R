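test_that("canonical and pseudo genes round-trip through the detector", {
  for (seed in c(1, 2, 9)) {
    ala <- make_canonical_trna("Ala", seed)
    ile <- make_canonical_trna("Ile", seed)
    expect_equal(nchar(ala), 73)
    expect_equal(nchar(ile), 74)
    expect_identical(unclass(make_canonical_trna("Ala", seed))[1],
                     unclass(ala)[1])
    f <- fold_cloverleaf(unclass(ala)[1])
    expect_equal(f$anticodon, "TGC")
    f2 <- fold_cloverleaf(unclass(ile)[1])
    expect_equal(f2$anticodon, "GAT")
    ps <- make_pseudo_trna(ala)
    # one hard constraint disrupted: anticodon stem below 4/5 pairs, score
    # still above threshold, T-loop motif intact
    fp <- fold_cloverleaf(unclass(ps)[1])
    expect_lt(fp$ac_pairs, 4)
    expect_true(fp$motif)
    expect_gte(fp$score, cloverleaf_model()$min_score)
  }
})

test_that("evolution follows the JC expectation and respects protection", {
  # no divergence, no indels -> identical descendants
  anc <- paste(rep(c("A", "C", "G", "T"), 150), collapse = "")
  expect_equal(unique(evolve_clade(anc, 3, 0, 0, seed = 1)), anc)
  # observed mismatch fraction ~= JC-expected p for d = 0.1 (3 SD band)
  set.seed(40)
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  obs <- vapply(1:100, function(i) {
    d <- evolve_clade(anc, 1, 0.1, 0)
    mean(strsplit(d, "")[[1]] != strsplit(anc, "")[[1]])
  }, numeric(1))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - p_exp), 3 * se + 1e-9)
  # fixed seed -> identical output
  expect_identical(evolve_clade(anc, 2, 0.2, 1, seed = 7),
                   evolve_clade(anc, 2, 0.2, 1, seed = 7))
  # protected sites never substituted
  prot <- seq(10, 500, by = 7)
  for (i in 1:10) {
    d <- evolve_clade(anc, 1, 0.4, 0, seed = i, protected_sites = prot)
    expect_equal(strsplit(d, "")[[1]][prot], strsplit(anc, "")[[1]][prot])
  }
})

test_that("single operons honour the envelope and round-trip excision", {
  for (seed in 1:10) {
    op <- generate_operon(seed = seed)
    tr <- op$truth
    expect_gte(tr$its_len, 415); expect_lte(tr$its_len, 849)
    x <- excise(op$seq)
    expect_equal(nchar(x$seq), tr$its_len)
    expect_identical(x$seq, substr(op$seq$residues, tr$its_start, tr$its_end))
    if (tr$its_type == "ITS_none") expect_equal(tr$n_genes, 0)
  }
})

test_that("panels have the study geometry and are byte-deterministic", {
  cfg <- panel_config(seed = 42)
  p <- generate_panel(cfg)
  expect_equal(nrow(p$seqs), 37)
  expect_equal(sum(p$truth$role == "reference"), 14)
  expect_equal(sum(p$truth$role == "isolate"), 23)
  p2 <- generate_panel(cfg)
  expect_identical(p$seqs$residues, p2$seqs$residues)
  expect_identical(p$truth, p2$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(p$seqs, f1); write_fasta(p2$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
  # no isolates -> references only
  expect_equal(nrow(generate_panel(panel_config(n_isolates = 0, seed = 1))$seqs),
               14)
})

test_that("generated spacers respect the length and G+C envelopes", {
  lens <- numeric(0); gcs <- numeric(0)
  for (s in 1:6) {
    p <- generate_panel(panel_config(seed = s))
    lens <- c(lens, p$truth$its_len)
    gcs <- c(gcs, p$truth$gc_molpct)
  }
  expect_true(all(lens >= 415 & lens <= 849))
  expect_true(all(gcs >= 42.2 - 0.5 & gcs <= 57.9 + 0.5))
})

test_that("ground truth matches the emitted sequences by slicing", {
  p <- generate_panel(panel_config(seed = 3))
  for (i in seq_len(nrow(p$truth))) {
    tr <- p$truth[i, ]
    operon <- p$seqs$residues[p$seqs$id == tr$seq_id]
    its <- substr(operon, tr$its_start, tr$its_end)
    expect_equal(nchar(its), tr$its_len)
    expect_equal(round(100 * gc_content(its), 2), tr$gc_molpct)
    if (!is.na(tr$gene1_start)) {
      gene1 <- substr(its, tr$gene1_start, tr$gene1_end)
      f <- fold_cloverleaf(gene1)
      expect_false(is.null(f))
      want_ac <- if (tr$gene1_isotype == "Ala") "TGC" else "GAT"
      expect_equal(f$anticodon, want_ac)
    }
    if (!is.na(tr$its2_start)) {
      its2 <- substr(its, tr$its2_start, tr$its2_end)
      expect_match(its2, "^CCAACCAT")
      expect_match(its2, "TGGT$")
      expect_equal(tr$its2_group, assign_its2_group(nchar(its2)))
    }
  }
})

test_that("full-pipeline ground-truth recovery is exact on a default panel", {
  p <- generate_panel(panel_config(seed = 1))
  for (i in seq_len(nrow(p$seqs))) {
    x <- excise(p$seqs[i, ])
    a <- annotate_its(x$seq, seq_id = p$seqs$id[i])
    tr <- p$truth[i, ]
    expect_equal(a$its_type, tr$its_type, info = tr$seq_id)
    if (!is.na(tr$gene1_start)) {
      expect_equal(a$trnas$start[1], tr$gene1_start, info = tr$seq_id)
      expect_equal(a$trnas$end[1], tr$gene1_end, info = tr$seq_id)
    }
    if (!is.na(tr$gene2_start)) {
      expect_equal(a$trnas$start[2], tr$gene2_start, info = tr$seq_id)
      expect_equal(a$trnas$end[2], tr$gene2_end, info = tr$seq_id)
    }
    if (!is.na(tr$its2_group)) {
      expect_equal(a$its2_group, tr$its2_group, info = tr$seq_id)
    }
  }
})
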