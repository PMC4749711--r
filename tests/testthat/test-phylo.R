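test_that("complete deletion keeps exactly the unambiguous gapless columns", {
  aln <- new_msa(c("a", "b", "c"),
                 c("ACGTNCGTAC", "ACGT-CGTAC", "ACGTACGTAC"))
  cd <- complete_deletion(aln)
  expect_equal(nchar(cd$rows[1]), 9)
  expect_equal(cd$rows[3], "ACGTCGTAC")
  # gapless unambiguous input is untouched
  g <- new_msa(c("a", "b"), c("ACGT", "AGGT"))
  expect_equal(complete_deletion(g)$rows, g$rows)
  allgap <- new_msa(c("a", "b"), c("A-", "-A"))
  expect_error(complete_deletion(allgap), "every column")
})

test_that("JC distance matches its closed form and saturates at p >= 3/4", {
  expect_equal(as.numeric(jc69_distance("AAAA", "AAAA")), 0)
  d <- jc69_distance(paste0(strrep("A", 9), "T"), strrep("A", 10))
  expect_equal(as.numeric(d), -0.75 * log(1 - 0.4 / 3))
  expect_equal(round(as.numeric(d), 5), 0.10733)
  s <- jc69_distance("ACGT", "CAGG")   # p = 0.75
  expect_equal(as.numeric(s), 5)
  expect_true(attr(s, "saturated"))
  # monotone increasing in p on [0, 3/4)
  ds <- vapply(0:13, function(k) {
    a <- strrep("A", 20)
    b <- paste0(strrep("C", k), strrep("A", 20 - k))
    as.numeric(jc69_distance(a, b))
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("NJ solves the three-point equations and recovers additive trees", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")

  # additive matrices from random trees up to 8 leaves: exact recovery
  set.seed(30)
  for (n in 4:8) {
    tr0 <- ape::rtree(n, br = function(k) stats::runif(k, 0.2, 1))
    D0 <- ape::cophenetic.phylo(tr0)
    rec <- neighbor_joining(D0)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), rec)), 0)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(D0), colnames(D0)], D0)
  }
  # degenerate equidistant matrix: all branch lengths non-negative
  De <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(De) <- 0
  expect_true(all(neighbor_joining(De)$edge.length >= 0))
})

test_that("the pruning likelihood matches closed forms and an independent engine", {
  # two identical single-column rows at total length 0 and 0.3
  aln <- new_msa(c("a", "b"), c("A", "A"))
  expect_equal(jc_log_likelihood(ape::read.tree(text = "(a:0,b:0);"), aln),
               log(0.25))
  expect_equal(jc_log_likelihood(ape::read.tree(text = "(a:0.1,b:0.2);"), aln),
               log(0.25 * (0.25 + 0.75 * exp(-0.4))))
  # the two-taxon closed form on all 16 ordered base pairs, random lengths
  set.seed(31)
  for (r in 1:10) {
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    tt <- t1 + t2
    for (x in c("A", "C", "G", "T")) for (y in c("A", "C", "G", "T")) {
      alnxy <- new_msa(c("a", "b"), c(x, y))
      tr <- ape::read.tree(text = sprintf("(a:%.12f,b:%.12f);", t1, t2))
      p_same <- 0.25 + 0.75 * exp(-4 * tt / 3)
      p_diff <- 0.25 - 0.25 * exp(-4 * tt / 3)
      want <- log(0.25 * if (x == y) p_same else p_diff)
      expect_equal(jc_log_likelihood(tr, alnxy), want, tolerance = 1e-10)
    }
  }
  # stationary limit: any base pair tends to log(1/16)
  far <- ape::read.tree(text = "(a:400,b:400);")
  expect_equal(jc_log_likelihood(far, new_msa(c("a", "b"), c("A", "G"))),
               log(1 / 16), tolerance = 1e-6)
  # agreement with phangorn on a larger random case
  skip_if_not_installed("phangorn")
  set.seed(32)
  anc6 <- rand_seq(60)
  rows <- vapply(1:6, function(i) {
    ch <- strsplit(anc6, "")[[1]]
    k <- sample(4:12, 1)
    ch[sample(60, k)] <- sample(c("A", "C", "G", "T"), k, TRUE)
    paste(ch, collapse = "")
  }, character(1))
  aln6 <- new_msa(letters[1:6], rows)
  tr6 <- neighbor_joining(jc_dist_matrix(aln6))
  dat <- phangorn::phyDat(setNames(strsplit(rows, ""), letters[1:6]))
  fit <- phangorn::pml(tr6, dat, model = "JC")
  expect_equal(jc_log_likelihood(tr6, aln6), fit$logLik, tolerance = 1e-6)
})

test_that("branch-length optimisation ascends and solves the two-taxon MLE", {
  aln <- new_msa(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAT"))
  opt <- optimize_branch_lengths(ape::read.tree(text = "(a:0.05,b:0.05);"), aln)
  expect_equal(sum(opt$edge.length),
               as.numeric(jc69_distance(aln$rows[1], aln$rows[2])),
               tolerance = 1e-5)
  # already-optimal input is a fixed point; logLik never decreases
  set.seed(33)
  anc <- rand_seq(80)
  rows <- vapply(1:5, function(i) {
    ch <- strsplit(anc, "")[[1]]
    k <- sample(5:15, 1)
    ch[sample(80, k)] <- sample(c("A", "C", "G", "T"), k, TRUE)
    paste(ch, collapse = "")
  }, character(1))
  aln5 <- new_msa(letters[1:5], rows)
  tr <- neighbor_joining(jc_dist_matrix(aln5))
  ll0 <- jc_log_likelihood(tr, aln5)
  o1 <- optimize_branch_lengths(tr, aln5)
  expect_gte(attr(o1, "logLik"), ll0)
  o2 <- optimize_branch_lengths(o1, aln5)
  expect_equal(o2$edge.length, o1$edge.length, tolerance = 1e-3)
})

test_that("bootstrap consensus is deterministic with supports in range", {
  set.seed(34)
  half1 <- paste(sample(c("A", "C"), 60, TRUE), collapse = "")
  half2 <- paste(sample(c("G", "T"), 60, TRUE), collapse = "")
  aln <- new_msa(c("a", "b", "c", "d"), c(half1, half1, half2, half2))
  bc <- bootstrap_consensus(aln, n_reps = 100, seed = 5)
  expect_equal(sort(bc$tip.label), c("a", "b", "c", "d"))
  # perfect clade signal -> the ab|cd bipartition in every replicate
  expect_true(any(bc$node.label == 100))
  expect_true(all(bc$node.label >= 0 & bc$node.label <= 100))
  # majority rule: no bipartition below 50 support
  internal <- bc$node.label[-1]
  expect_true(all(internal[!is.na(internal)] > 50))
  bc2 <- bootstrap_consensus(aln, n_reps = 100, seed = 5)
  expect_identical(ape::write.tree(bc), ape::write.tree(bc2))
  # a single replicate is its own consensus at support 100
  b1 <- bootstrap_consensus(aln, n_reps = 1, seed = 9, optimize_lengths = FALSE)
  expect_equal(b1$node.label, rep(100, b1$Nnode))
  # newick round trip preserves leaves and supports
  nw <- ape::write.tree(bc)
  rt <- ape::read.tree(text = nw)
  expect_setequal(rt$tip.label, bc$tip.label)
})
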