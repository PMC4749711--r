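test_that("canonical genes are detected at the planted offset with correct geometry", {
  set.seed(10)
  for (iso in c("Ala", "Ile")) {
    g <- make_canonical_trna(iso, seed = 3)
    want_len <- if (iso == "Ala") 73 else 74
    expect_equal(nchar(g), want_len)
    for (off in c(0, 120, 400)) {
      its <- paste0(rand_seq(off + 30), unclass(g)[1], rand_seq(60))
      hits <- scan_trnas(its)
      expect_equal(nrow(hits), 1)
      expect_equal(hits$start, off + 31)
      expect_equal(hits$length, want_len)
      expect_equal(hits$isotype, iso)
      expect_false(hits$pseudo)
    }
  }
})

test_that("anticodon isotype mapping follows the genetic code labels", {
  expect_equal(classify_isotype(c("TGC", "GAT", "CAT", "NGC", "RAT")),
               c("Ala", "Ile", "other", "other", "other"))
})

test_that("fold_cloverleaf recovers the construction blueprint", {
  g <- make_canonical_trna("Ala", seed = 1)
  f <- fold_cloverleaf(unclass(g)[1])
  expect_equal(f$score, 65)          # 21 fully paired GC stems + motif bonus
  expect_equal(f$acc_pairs, 7)
  expect_equal(f$ac_pairs, 5)
  expect_true(f$motif)
  expect_equal(f$anticodon, "TGC")
  # blueprint arm intervals: acceptor arms pair the gene termini
  acc <- f$arms[f$arms$arm == "acceptor", ]
  expect_equal(acc$start[1], 1)
  expect_equal(acc$end[2], 72)       # discriminator occupies position 73
  # no pairing possible / wrong size -> NULL
  expect_null(fold_cloverleaf(strrep("A", 73)))
  expect_null(fold_cloverleaf(strrep("ACG", 10)))
})

test_that("a disrupted anticodon stem yields a pseudo hit, not a miss", {
  set.seed(11)
  ala <- make_canonical_trna("Ala", seed = 2)
  ps <- make_pseudo_trna(ala)
  # exactly three substitutions, all inside the anticodon 3' strand
  d <- which(strsplit(unclass(ala)[1], "")[[1]] != strsplit(unclass(ps)[1], "")[[1]])
  expect_length(d, 3)
  expect_true(all(d >= 39 & d <= 43))
  its <- paste0(rand_seq(150), unclass(ps)[1], rand_seq(150))
  hits <- scan_trnas(its)
  expect_equal(nrow(hits), 1)
  expect_true(hits$pseudo)
  expect_equal(hits$start, 151)
  expect_equal(hits$length, 73)
})

test_that("composition-matched shuffled spacers are almost never called", {
  set.seed(1)
  clean <- vapply(1:10, function(i) {
    s <- rand_seq(600)
    nrow(scan_trnas(s)[!scan_trnas(s)$pseudo, ]) == 0
  }, logical(1))
  expect_gte(sum(clean), 9)
})

test_that("detection is translation invariant and score drops under stem damage", {
  g <- unclass(make_canonical_trna("Ile", seed = 5))[1]
  set.seed(12)
  base <- scan_trnas(paste0(rand_seq(40), g, rand_seq(40)))
  for (off in c(5, 77, 201)) {
    h <- scan_trnas(paste0(rand_seq(off), g, rand_seq(40)))
    expect_equal(h$length, base$length)
    expect_equal(h$score, base$score)
    expect_equal(h$isotype, base$isotype)
  }
  # random substitutions at stem positions never increase the fold score
  prot <- which(attr(make_canonical_trna("Ile", seed = 5), "protect"))
  set.seed(13)
  for (i in 1:10) {
    ch <- strsplit(g, "")[[1]]
    k <- sample(3:8, 1)
    sites <- sample(prot, k)
    ch[sites] <- vapply(ch[sites],
                        function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        character(1))
    f <- fold_cloverleaf(paste(ch, collapse = ""))
    expect_lte(f$score, 65)
  }
})
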