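test_that("pairwise NW matches the exhaustive alignment oracle on small inputs", {
  set.seed(7)
  for (i in 1:20) {
    la <- sample(3:6, 1); lb <- sample(3:6, 1)
    a <- rand_seq(la); b <- rand_seq(lb)
    r <- needleman_wunsch(a, b)
    expect_equal(r$score, nw_oracle_score(a, b), info = paste(a, b))
    # gap-strip round trip
    expect_equal(gsub("-", "", r$aln$rows), c(a, b))
  }
  # identical sequences align gaplessly at score length * match
  r <- needleman_wunsch(strrep("ACGT", 5), strrep("ACGT", 5))
  expect_equal(r$score, 20)
  expect_false(any(grepl("-", r$aln$rows)))
  expect_error(needleman_wunsch("ACGT", ""), "non-empty")
})

test_that("progressive MSA preserves sequences and aligns planted motifs", {
  # three identical sequences -> gapless
  m <- progressive_msa(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_false(any(grepl("-", m$rows)))
  # two sequences reduce to pairwise NW
  m2 <- progressive_msa(c(x = "ACGTAAA", y = "ACGAAA"))
  nw <- needleman_wunsch("ACGTAAA", "ACGAAA")
  expect_equal(unname(m2$rows), nw$aln$rows)
  # planted common 8-mer ends up in one column block for all rows
  set.seed(8)
  motif <- "GGCCGGTT"
  seqs <- vapply(1:5, function(i) {
    paste0(rand_seq(sample(5:20, 1), c("A", "T")), motif,
           rand_seq(sample(5:20, 1), c("A", "T")))
  }, character(1))
  names(seqs) <- paste0("s", 1:5)
  m3 <- progressive_msa(seqs)
  mat <- ribospacer:::msa_matrix(m3)
  hit <- which(apply(mat, 2, function(col) all(col == col[1] & col[1] != "-")))
  runs <- rle(diff(hit))
  expect_true(any(with(runs, lengths[values == 1] >= 7)))
  # gap-strip round trip for every row
  expect_equal(gsub("-", "", m3$rows), unname(seqs))
})

test_that("percent identity and conservation summary follow their definitions", {
  expect_equal(percent_identity("AC-T", "AG-T"), 100 * 2 / 3)
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  expect_equal(percent_identity("ACGT", "TGCA"), 0)
  # indels: counted in the union denominator, ignored in the ungapped one
  expect_equal(percent_identity("ACGT--AA", "ACGTGGAA"), 75)
  expect_equal(percent_identity("ACGT--AA", "ACGTGGAA", "ungapped"), 100)
  # symmetric, invariant under column permutation
  set.seed(9)
  a <- paste(sample(c("A", "C", "-"), 30, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "-"), 30, TRUE), collapse = "")
  expect_equal(percent_identity(a, b), percent_identity(b, a))
  perm <- sample(30)
  pa <- paste(strsplit(a, "")[[1]][perm], collapse = "")
  pb <- paste(strsplit(b, "")[[1]][perm], collapse = "")
  expect_equal(percent_identity(a, b), percent_identity(pa, pb))

  cs <- conservation_summary(new_msa(c("a", "b"), c("ACGTA", "ACGAA")))
  expect_equal(cs$mean_pid, 80)
  expect_equal(cs$sd_pid, 0)
  k <- new_msa(letters[1:4], rep("ACGTACGT", 4))
  csk <- conservation_summary(k)
  expect_equal(csk$mean_pid, 100)
  expect_equal(csk$sd_pid, 0)
  # summary equals brute-force recomputation from the pid matrix
  set.seed(3)
  rows <- vapply(1:5, function(i) rand_seq(40), character(1))
  aln <- progressive_msa(setNames(rows, letters[1:5]))
  cs2 <- conservation_summary(aln)
  ut <- cs2$pid_matrix[upper.tri(cs2$pid_matrix)]
  expect_equal(cs2$mean_pid, mean(ut))
  expect_equal(cs2$sd_pid, sd(ut))
  expect_true(cs2$min_pid <= cs2$mean_pid && cs2$mean_pid <= cs2$max_pid)
  expect_true(isSymmetric(cs2$pid_matrix))
  expect_true(all(diag(cs2$pid_matrix) == 100))
})

test_that("conserved blocks find terminal consensus motifs and avoid random MSAs", {
  set.seed(21)
  rows <- vapply(1:6, function(i) {
    paste0("CCAACCAT", rand_seq(30), "TGGT")
  }, character(1))
  aln <- new_msa(paste0("s", 1:6), rows)
  b <- find_conserved_blocks(aln, min_len = 4, min_col_identity = 100)
  expect_equal(b$consensus[1], "CCAACCAT")
  expect_equal(b$start[1], 1)
  expect_equal(b$consensus[nrow(b)], "TGGT")
  expect_equal(b$end[nrow(b)], 42)
  # consensus ties become IUPAC unions
  tie <- new_msa(c("a", "b"), c("AAAAA", "AAGAA"))
  bt <- find_conserved_blocks(tie, min_len = 5, min_col_identity = 50)
  expect_equal(bt$consensus, "AARAA")
  # random gapless MSAs almost never contain long high-identity blocks
  set.seed(5)
  hits <- vapply(1:40, function(i) {
    aln <- new_msa(paste0("r", 1:6),
                   vapply(1:6, function(j) rand_seq(80), character(1)))
    b <- find_conserved_blocks(aln, min_len = 6, min_col_identity = 90)
    nrow(b) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("indel events are maximal runs with 1-based coordinates", {
  aln <- new_msa(c("a", "b"),
                 c("ACGTACGTAC", "ACG---GTAC"))
  ev <- count_indel_events(aln, "b")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$aln_start, 4)
  expect_equal(ev$aln_end, 6)
  expect_equal(ev$length, 3)
  # gapless alignment -> no events
  expect_equal(nrow(count_indel_events(new_msa(c("a", "b"),
                                               c("ACGT", "AGGT")), "a")), 0)
  # three separated gap runs -> exactly three events
  aln3 <- new_msa(c("a", "b"),
                  c("ACGTACGTACGTACGTACGT", "A--TAC--ACGTAC-TACGT"))
  expect_equal(nrow(count_indel_events(aln3, "b")), 3)
  # an insertion private to the focus row
  aln4 <- new_msa(c("a", "b", "c"),
                  c("ACGTTTACGT", "ACG----CGT", "ACG----CGT"))
  ev4 <- count_indel_events(aln4, "a")
  ins <- ev4[ev4$kind == "insertion", ]
  expect_equal(ins$aln_start, 4)
  expect_equal(ins$length, 4)
  expect_equal(ins$focus_start, 4)
  expect_equal(ins$focus_end, 7)
})

test_that("a 10-column deletion is reported at its alignment position", {
  # mirrors the deep-branching reference case: one 10 bp deletion at
  # alignment columns 672-681 of a long two-row alignment
  set.seed(22)
  a <- rand_seq(800)
  b <- paste0(substr(a, 1, 671), substr(a, 682, 800))
  ch <- strsplit(a, "")[[1]]
  rowb <- ch; rowb[672:681] <- "-"
  aln <- new_msa(c("ref", "focal"), c(a, paste(rowb, collapse = "")))
  ev <- count_indel_events(aln, "focal")
  expect_equal(ev$kind, "deletion")
  expect_equal(c(ev$aln_start, ev$aln_end, ev$length), c(672, 681, 10))
})

test_that("group-specific length stretches are located at planted columns", {
  set.seed(23)
  core1 <- rand_seq(22); core2 <- rand_seq(50); core3 <- rand_seq(42)
  mk_a <- function() paste0(rand_seq(0), "ACGTACGTAC", core1, "GGTTGGTTGG",
                            core2, "CCAACCAACC", core3, "TTGGTTGGTT")
  mk_b <- function() paste0("ACGTACGTAC", strrep("-", 22), "GGTTGGTTGG",
                            strrep("-", 50), "CCAACCAACC", strrep("-", 42),
                            "TTGGTTGGTT")
  rows <- c(a1 = mk_a(), a2 = mk_a(), b1 = mk_b(), b2 = mk_b())
  aln <- new_msa(names(rows), unname(rows))
  st <- locate_length_stretches(aln, c("a1", "a2"), c("b1", "b2"), min_len = 20)
  expect_equal(nrow(st), 3)
  expect_equal(st$length, c(22, 50, 42))
  expect_equal(st$start[1], 11)
  # identical groups -> none; stretches below min_len are excluded
  expect_equal(nrow(locate_length_stretches(aln, c("a1", "a2"), c("b1", "b2"),
                                            min_len = 60)), 0)
  same <- new_msa(c("x", "y"), c("ACGT", "ACGT"))
  expect_equal(nrow(locate_length_stretches(same, "x", "y", 2)), 0)
})
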