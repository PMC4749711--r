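test_that("primer sites are found with degeneracy and mismatch tolerance", {
  set.seed(4)
  fwd <- primer("f", "AAGTCGTAACAAGGTARCCG", "forward")
  site <- "AAGTCGTAACAAGGTAGCCG"   # R position carries G
  tpl <- paste0(rand_seq(60), site, rand_seq(40))
  hit <- find_primer_sites(tpl, fwd, max_mismatch = 0)
  expect_equal(hit$start, 61)
  expect_equal(hit$end, 80)

  # one substitution: rejected at 0 mismatches, found at 1
  mut <- sub("AACAAG", "AACTAG", site)
  tpl2 <- paste0(rand_seq(60), mut, rand_seq(40))
  expect_equal(nrow(find_primer_sites(tpl2, fwd, 0)), 0)
  expect_equal(nrow(find_primer_sites(tpl2, fwd, 1)), 1)

  # reverse primer matched as reverse complement
  rev <- primer("r", "YYGCCAAGGCATCCACC", "reverse")
  tpl3 <- paste0(rand_seq(30), revcomp("CCGCCAAGGCATCCACC"), rand_seq(20))
  hit3 <- find_primer_sites(tpl3, rev, 0)
  expect_equal(hit3$start, 31)
  expect_equal(hit3$strand, "-")

  # primer longer than template -> empty
  expect_equal(nrow(find_primer_sites("ACGTACGTAC", fwd, 0)), 0)
})

test_that("amplification enumerates site pairs under length limits", {
  set.seed(5)
  fwd <- primer("f", "GCGTAACGCGTGGGAATCTG", "forward")
  rev <- primer("r", "TTACAACCCTAAGGCCTTC", "reverse")
  fsite <- "GCGTAACGCGTGGGAATCTG"
  rsite <- revcomp("TTACAACCCTAAGGCCTTC")
  mid <- rand_seq(500 - nchar(fsite) - nchar(rsite))
  tpl <- paste0(rand_seq(80), fsite, mid, rsite, rand_seq(50))
  amp <- amplify(tpl, fwd, rev, min_len = 100, max_len = 2000)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 500)
  expect_equal(amp$start, 81)
  # products outside limits are dropped
  expect_equal(nrow(amplify(tpl, fwd, rev, min_len = 100, max_len = 300)), 0)
  # amplification is invariant under extra flanking sequence
  amp2 <- amplify(paste0(rand_seq(200), tpl, rand_seq(150)), fwd, rev)
  expect_equal(amp2$length, amp$length)
  expect_equal(amp2$residues, amp$residues)
  # two forward sites sharing one reverse site -> two products (oracle:
  # every upstream fwd/rev combination within limits)
  tpl3 <- paste0(rand_seq(30), fsite, rand_seq(100), fsite, rand_seq(150),
                 rsite, rand_seq(20))
  amp3 <- amplify(tpl3, fwd, rev, min_len = 50, max_len = 2000)
  expect_equal(nrow(amp3), 2)
  expect_true(all(diff(amp3$start) > 0))
})

test_that("spacer excision recovers the planted spacer exactly", {
  set.seed(6)
  for (len in c(415, 600, 849)) {
    its <- rand_seq(len)
    tpl <- wrap_spacer(its)
    amp <- amplify(tpl, "16S-1511f", "23S-23r")
    expect_equal(nrow(amp), 1)
    x <- extract_its(amp[1, ], "16S-1511f", "23S-23r")
    expect_equal(nchar(x$seq), len)
    expect_identical(x$seq, its)
    expect_equal(x$start, 201)
    expect_equal(x$end, 200 + len)
  }
  # abutting anchors -> degenerate spacer error
  tpl0 <- wrap_spacer("")
  amp0 <- amplify(tpl0, "16S-1511f", "23S-23r", min_len = 10)
  expect_error(extract_its(amp0[1, ], "16S-1511f", "23S-23r"), "degenerate")
})

test_that("the packaged primer table carries both assays", {
  p <- default_primers()
  expect_true(all(c("16S-1511f", "23S-23r", "1492f", "115r",
                    "Sphingo108f", "Sphingo420r") %in% p$name))
  expect_true(all(p$role %in% c("forward", "reverse")))
  expect_true(all(nchar(p$residues) >= 10))
})
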