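trna_row <- function(start, len, iso, pseudo = FALSE) {
  data.frame(start = start, end = start + len - 1, length = len,
             isotype = iso, anticodon = if (iso == "Ala") "TGC" else "GAT",
             score = 60, pseudo = pseudo, stringsAsFactors = FALSE)
}

test_that("the five arrangements and the catch-all are classified correctly", {
  expect_equal(classify_its_type(trna_row(1, 73, "Ala")[0, ]), "ITS_none")
  expect_equal(classify_its_type(trna_row(100, 73, "Ala")), "ITS_Ala")
  two <- rbind(trna_row(100, 73, "Ala"), trna_row(400, 74, "Ile"))
  expect_equal(classify_its_type(two), "ITS_AlaIle")
  expect_equal(classify_its_type(rbind(trna_row(100, 74, "Ile"),
                                       trna_row(400, 73, "Ala"))), "ITS_IleAla")
  expect_equal(classify_its_type(rbind(trna_row(100, 74, "Ile"),
                                       trna_row(400, 73, "Ala", TRUE))),
               "ITS_IlePseudo")
  # arrangements never seen in the study stay ITS_other
  expect_equal(classify_its_type(trna_row(100, 74, "Ile")), "ITS_other")
  expect_equal(classify_its_type(rbind(trna_row(100, 73, "Ala"),
                                       trna_row(400, 73, "Ala"))), "ITS_other")
  # overlap is an annotation conflict
  expect_error(classify_its_type(rbind(trna_row(100, 73, "Ala"),
                                       trna_row(150, 74, "Ile"))), "overlap")
})

test_that("partitioning tiles the spacer and flags degenerate ITS-2", {
  its <- strrep("A", 600)
  two <- rbind(trna_row(101, 73, "Ala"), trna_row(401, 74, "Ile"))
  p <- partition_its(its, two)
  expect_equal(p$length[p$region == "ITS-1"], 100)
  expect_equal(p$length[p$region == "ITS-2"], 227)
  expect_equal(p$length[p$region == "ITS-3"], 126)
  # tiling conservation: subregions + genes = spacer
  expect_equal(sum(p$length) + sum(two$length), 600)

  # abutting genes -> ITS-2 of length 0, flagged
  ab <- rbind(trna_row(101, 73, "Ala"), trna_row(174, 74, "Ile"))
  p0 <- partition_its(its, ab)
  expect_equal(p0$length[p0$region == "ITS-2"], 0)
  expect_true(isTRUE(attr(p0, "degenerate")))

  # single gene -> spacer-a / spacer-b, no ITS-2
  p1 <- partition_its(its, trna_row(101, 73, "Ala"))
  expect_setequal(p1$region, c("spacer-a", "spacer-b"))
  expect_equal(sum(p1$length), 600 - 73)
})

test_that("ITS-2 size groups are total and disjoint", {
  expect_equal(assign_its2_group(c(17, 61, 90, 130)),
               c("short(16-19)", "mid(60-61)", "other(90)", "long(122-138)"))
  # totality + disjointness over an exhaustive range
  labs <- assign_its2_group(0:200)
  expect_length(labs, 201)
  bins <- sub("\\(.*", "", labs)
  expect_equal(sum(bins == "short"), 4)
  expect_equal(sum(bins == "mid"), 2)
  expect_equal(sum(bins == "long"), 17)
})

test_that("the Ala-then-Ile convention check distinguishes the arrangements", {
  a <- list(its_type = "ITS_AlaIle")
  expect_true(check_arrangement_convention(a))
  expect_false(check_arrangement_convention(list(its_type = "ITS_IleAla")))
  expect_true(is.na(check_arrangement_convention(list(its_type = "ITS_none"))))
})

test_that("annotate_its composes detector, typing and partition", {
  set.seed(20)
  ala <- unclass(make_canonical_trna("Ala", 7))[1]
  ile <- unclass(make_canonical_trna("Ile", 7))[1]
  its <- paste0(rand_seq(120), ala, rand_seq(61), ile, rand_seq(150))
  a <- annotate_its(its, seq_id = "x")
  expect_equal(a$its_type, "ITS_AlaIle")
  expect_equal(a$its2_len, 61)
  expect_equal(a$its2_group, "mid(60-61)")
  expect_equal(a$its_len, nchar(its))
  tab <- annotation_table(list(a))
  expect_equal(tab$trna_isotypes, "Ala;Ile")
  expect_match(tab$trna_positions, "^121-193;")
})
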