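# Seeded generator of synthetic rRNA operon panels with known ground truth.
#
# An operon is kept internally as a list of segments (16S tail scaffold,
# spacer fillers, tRNA genes, ITS-2 motif blocks, 23S head scaffold), each
# with a per-position substitution-protection mask and an indel permission
# flag. All coordinates in the emitted ground truth are recomputed from the
# segment lengths after evolution, so truth and FASTA always agree.

# fixed 200-nt rRNA scaffolds carrying the spacer-assay primer sites:
# the forward site (16S end) occupies positions 181-200 of the 16S tail and
# the reverse site (23S start) positions 1-17 of the 23S head, so the spacer
# excised between the primer footprints is exactly the planted one.
SCAFFOLD_16S <- "GGTACACTTTTTCGCGATTTGTTCTCTCATAGTGTAGAACGTAGAGCGTATGTTCTAGGTACTACGCGTACCAGGTTAATCATCAATTGCCCTCCGCACGAGAGGATTCTCACTGAAAACGAGAGTCCGCTAAGGCCCAGGTCACACAATCTGCTTAATAAGGTTTTAAATCAATCGGGTAAGTCGTAACAAGGTAACCG"
SCAFFOLD_23S <- "GGTGGATGCCTTGGCGGGGATTTAATCGACGTCTTCGGATCGATATCCTAACCGGTCACCATCGCTTCTGGATAACCTGAGCCCTGAATAAATGAAACCTCTGAATGGGGGAACCCAGTGTCTGACTCCTGTGCGGCTTGGGGATTAGGACGAAGGGTGTAGCCAGTTCCGGTGTCATCTAGTTAGTGTGTGGCTCCCAT"

# within-panel ITS-2 divergence (Jukes-Cantor substitutions/site applied to
# each isolate relative to its clade template). Calibrated once, with
# scripts/calibrate_its2.R, so that the default panel's mean pairwise ITS-2
# identity lands on the 22.5% headline; see the methods vignette.
ITS2_DIVERGENCE_DEFAULT <- 0.50

ITS_TYPES <- c("ITS_none", "ITS_Ala", "ITS_AlaIle", "ITS_IleAla", "ITS_IlePseudo")

# evaluate code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Panel generator configuration
#'
#' Defaults emulate the study design this generator is modelled on: a panel
#' of 14 reference operons plus 23 isolate descendants, spacer lengths
#' inside 415-849 bp, spacer G+C inside 42.2-57.9 mol%, the five tRNA
#' arrangement types with the Ala+Ile arrangement dominant, ITS-2 size
#' groups at 16-19 / 60-61 / 122-138 nt plus an unbinned remainder, the
#' conserved CCAACCAT / TGGT blocks at the ITS-2 termini, and
#' Jukes-Cantor substitutions plus short indels within each clade.
#'
#' @param n_references number of reference (clade template) operons.
#' @param n_isolates number of isolate descendants distributed over clades.
#' @param its_len_bounds admissible spacer lengths (nt).
#' @param gc_bounds_molpct admissible spacer G+C (mol%).
#' @param type_mix draw frequencies over the five arrangement types.
#' @param its2_group_mix draw frequencies over ITS-2 size groups.
#' @param its2_divergence JC distance from clade template to each isolate.
#' @param between_clade_factor multiplier on `its2_divergence` giving the
#'   divergence between same-size-group templates (they share a group
#'   ancestor, mirroring the common origin of same-sized spacers).
#' @param indel_rate expected indel events per isolate.
#' @param indel_mean_len mean indel length (nt, geometric; capped at 12).
#' @param motif_head,motif_tail conserved blocks at the ITS-2 termini.
#' @param seed integer seed; one seed reproduces the panel byte-for-byte.
#' @return list of class `"panel_config"`.
#' @export
panel_config <- function(n_references = 14, n_isolates = 23,
                         its_len_bounds = c(415, 849),
                         gc_bounds_molpct = c(42.2, 57.9),
                         type_mix = c(ITS_none = 0.08, ITS_Ala = 0.08,
                                      ITS_AlaIle = 0.60, ITS_IleAla = 0.12,
                                      ITS_IlePseudo = 0.12),
                         its2_group_mix = c(short = 0.25, mid = 0.20,
                                            long = 0.25, other = 0.30),
                         its2_divergence = ITS2_DIVERGENCE_DEFAULT,
                         between_clade_factor = 3,
                         indel_rate = 1.0, indel_mean_len = 3,
                         motif_head = "CCAACCAT", motif_tail = "TGGT",
                         seed = 42) {
  stopifnot(its_len_bounds[1] < its_len_bounds[2],
            gc_bounds_molpct[1] < gc_bounds_molpct[2],
            abs(sum(type_mix) - 1) < 1e-6, abs(sum(its2_group_mix) - 1) < 1e-6,
            all(names(type_mix) %in% ITS_TYPES),
            its2_divergence >= 0, indel_rate >= 0)
  structure(list(
    n_references = n_references, n_isolates = n_isolates,
    its_len_bounds = its_len_bounds, gc_bounds_molpct = gc_bounds_molpct,
    type_mix = type_mix, its2_group_mix = its2_group_mix,
    its2_divergence = its2_divergence,
    between_clade_factor = between_clade_factor,
    indel_rate = indel_rate, indel_mean_len = indel_mean_len,
    motif_head = motif_head, motif_tail = motif_tail, seed = seed
  ), class = "panel_config")
}

rand_ac <- function(n) paste(sample(c("A", "C"), n, TRUE), collapse = "")

# sample one element of a vector (safe for length-1 vectors)
pick1 <- function(v) v[sample.int(length(v), 1)]

# random filler with an exact G+C count
make_filler <- function(len, gc_frac) {
  if (len <= 0) return("")
  n_gc <- max(0, min(len, round(len * gc_frac)))
  ch <- c(sample(c("G", "C"), n_gc, TRUE), sample(c("A", "T"), len - n_gc, TRUE))
  paste(sample(ch), collapse = "")
}

# canonical gene internals ---------------------------------------------------

trna_blueprint <- function(isotype) {
  stopifnot(isotype %in% c("Ala", "Ile"))
  anticodon <- if (isotype == "Ala") "TGC" else "GAT"
  v_len <- if (isotype == "Ala") 5L else 6L
  list(
    acc5 = "GGCGGCC", link1 = "TA", d5 = "GCGC", d_loop_len = 8L, d3 = "GCGC",
    link2 = "A", ac5 = "GGCGC", anticodon = anticodon, ac3 = "GCGCC",
    v_len = v_len, t5 = "GGGCC", t_loop_tail_len = 4L, t3 = "GGCCC",
    acc3 = "GGCCGCC", disc = "A"
  )
}

# assemble gene sequence + protection mask; assumes RNG already seeded
build_trna <- function(isotype) {
  bp <- trna_blueprint(isotype)
  parts <- c(
    acc5 = bp$acc5, link1 = bp$link1, d5 = bp$d5, d_loop = rand_ac(bp$d_loop_len),
    d3 = bp$d3, link2 = bp$link2, ac5 = bp$ac5,
    ac_loop = paste0("CC", bp$anticodon, "AA"), ac3 = bp$ac3,
    v_loop = rand_ac(bp$v_len), t5 = bp$t5,
    t_loop = paste0("TTC", rand_ac(bp$t_loop_tail_len)), t3 = bp$t3,
    acc3 = bp$acc3, disc = bp$disc
  )
  lens <- nchar(parts)
  protect <- rep(FALSE, sum(lens))
  off <- c(0, cumsum(lens))
  names(off) <- c(names(parts), "end")
  prot_part <- function(name, idx = NULL) {
    rng <- (off[[name]] + 1):(off[[name]] + lens[[name]])
    if (!is.null(idx)) rng <- rng[idx]
    protect[rng] <<- TRUE
  }
  for (nm in c("acc5", "d5", "d3", "ac5", "ac3", "t5", "t3", "acc3")) prot_part(nm)
  prot_part("ac_loop", 3:5)   # the anticodon itself
  prot_part("t_loop", 1:3)    # the TTC signature
  list(seq = paste(parts, collapse = ""), protect = protect, isotype = isotype,
       anticodon = bp$anticodon)
}

#' Construct a canonical tRNA gene
#'
#' Builds a gene of the canonical length for the isotype (Ala: 73 nt,
#' Ile: 74 nt) satisfying every hard constraint of the default
#' [cloverleaf_model]: fully paired GC-rich stems, the anticodon at
#' cloverleaf positions 34-36 and a TTC T-loop signature. Loop residues are
#' drawn (from A/C, which cannot pair) using `seed`, so the gene is
#' deterministic given the seed and is always recovered by [scan_trnas()].
#'
#' @param isotype `"Ala"` or `"Ile"`.
#' @param seed integer seed for the loop residues.
#' @return character string of class `"trna_gene"` with attributes
#'   `protect` (logical mask of structurally constrained positions),
#'   `isotype` and `anticodon`.
#' @export
make_canonical_trna <- function(isotype = c("Ala", "Ile"), seed = 1) {
  isotype <- match.arg(isotype)
  g <- with_seed(seed, build_trna(isotype))
  structure(g$seq, class = "trna_gene", protect = g$protect,
            isotype = g$isotype, anticodon = g$anticodon, pseudo = FALSE)
}

# break anticodon-stem pairs 1, 3 and 5 on the 3' side; the substituted
# bases (A against G/C partners) can form neither Watson-Crick nor GT pairs
disrupt_ac_stem <- function(gene_chars) {
  ac3_off <- 7 + 2 + 4 + 8 + 4 + 1 + 5 + 7   # = 38; ac3 occupies 39..43
  gene_chars[ac3_off + c(1, 3, 5)] <- "A"
  gene_chars
}

#' Derive a pseudo-tRNA gene from a canonical gene
#'
#' Disrupts exactly one hard constraint of the detector - the anticodon
#' stem, by three substitutions on its 3' strand - while the remaining
#' structure keeps the score above threshold, so [scan_trnas()] reports the
#' gene with `pseudo = TRUE`. The disruption is deterministic.
#'
#' @param base a gene from [make_canonical_trna()].
#' @param seed accepted for interface symmetry; the disruption itself is
#'   deterministic in the base gene.
#' @return a `"trna_gene"` string with `pseudo = TRUE`.
#' @export
make_pseudo_trna <- function(base, seed = 1) {
  stopifnot(inherits(base, "trna_gene"))
  ch <- strsplit(unclass(base)[1], "", fixed = TRUE)[[1]]
  ch <- disrupt_ac_stem(ch)
  protect <- attr(base, "protect")
  structure(paste(ch, collapse = ""), class = "trna_gene", protect = protect,
            isotype = attr(base, "isotype"), anticodon = attr(base, "anticodon"),
            pseudo = TRUE)
}

# segment constructors --------------------------------------------------------

seg <- function(name, seq, protect = NULL, indel_ok = FALSE, meta = NULL) {
  n <- nchar(seq)
  if (is.null(protect)) protect <- rep(FALSE, n)
  stopifnot(length(protect) == n)
  list(name = name, seq = seq, protect = protect, indel_ok = indel_ok,
       meta = meta)
}

gene_seg <- function(name, gene) {
  seg(name, unclass(gene)[1], attr(gene, "protect"), indel_ok = FALSE,
      meta = list(isotype = attr(gene, "isotype"),
                  anticodon = attr(gene, "anticodon"),
                  pseudo = isTRUE(attr(gene, "pseudo"))))
}

scaffold_seg <- function(name, s) {
  seg(name, s, protect = rep(TRUE, nchar(s)), indel_ok = FALSE)
}

motif_seg <- function(name, s) {
  seg(name, s, protect = rep(TRUE, nchar(s)), indel_ok = FALSE)
}

# group ancestor ITS-2 fillers (between the terminal motifs)
ITS2_GROUP_BOUNDS <- list(short = c(16, 19), mid = c(60, 61), long = c(122, 138))

draw_its2_len <- function(group) {
  if (group %in% names(ITS2_GROUP_BOUNDS)) {
    b <- ITS2_GROUP_BOUNDS[[group]]
    pick1(b[1]:b[2])
  } else {
    # anything outside the three printed bins
    pick1(c(20:59, 62:121))
  }
}

make_group_ancestors <- function(cfg) {
  motif_len <- nchar(cfg$motif_head) + nchar(cfg$motif_tail)
  lapply(ITS2_GROUP_BOUNDS, function(b) {
    make_filler(b[2] - motif_len, 0.5)
  })
}

# substitute a fraction p of the positions of a plain string (no protection)
jc_substitute <- function(s, jc_d) {
  n <- nchar(s)
  p <- 0.75 * (1 - exp(-4 * jc_d / 3))
  k <- min(n, stats::rpois(1, n * p))
  if (k == 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  sites <- sample.int(n, k)
  ch[sites] <- vapply(ch[sites], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(ch, collapse = "")
}

# build one reference (clade template) operon; RNG must already be seeded
make_template_operon <- function(cfg, ancestors, clade_id) {
  its_type <- sample(names(cfg$type_mix), 1, prob = cfg$type_mix)
  motif_len <- nchar(cfg$motif_head) + nchar(cfg$motif_tail)
  two_gene <- its_type %in% c("ITS_AlaIle", "ITS_IleAla", "ITS_IlePseudo")

  genes <- list()
  its2 <- NULL
  its2_group <- NA_character_
  if (two_gene) {
    ala <- make_canonical_trna("Ala", sample.int(1e8, 1))
    ile <- make_canonical_trna("Ile", sample.int(1e8, 1))
    genes <- switch(its_type,
      ITS_AlaIle = list(ala, ile),
      ITS_IleAla = list(ile, ala),
      ITS_IlePseudo = list(ile, make_pseudo_trna(ala)))
    its2_group <- sample(names(cfg$its2_group_mix), 1, prob = cfg$its2_group_mix)
    its2_len <- draw_its2_len(its2_group)
    fill_len <- its2_len - motif_len
    fill <- if (its2_group %in% names(ancestors)) {
      anc <- ancestors[[its2_group]]
      ev <- jc_substitute(anc, cfg$between_clade_factor * cfg$its2_divergence)
      if (nchar(ev) >= fill_len) substr(ev, 1, fill_len)
      else paste0(ev, make_filler(fill_len - nchar(ev), 0.5))
    } else {
      make_filler(fill_len, stats::runif(1, 0.4, 0.6))
    }
    its2 <- list(head = cfg$motif_head, fill = fill, tail = cfg$motif_tail)
  } else if (its_type == "ITS_Ala") {
    genes <- list(make_canonical_trna("Ala", sample.int(1e8, 1)))
  }

  gene_len <- sum(vapply(genes, nchar, numeric(1)))
  its2_total <- if (two_gene) nchar(its2$head) + nchar(its2$fill) + nchar(its2$tail) else 0
  min_len <- max(cfg$its_len_bounds[1], gene_len + its2_total + 80)
  its_len <- pick1(min_len:cfg$its_len_bounds[2])
  rem <- its_len - gene_len - its2_total
  left <- pick1(40:(rem - 40))
  right <- rem - left

  # tune the flanking fillers so the whole spacer lands on the target G+C
  target_gc <- stats::runif(1, cfg$gc_bounds_molpct[1], cfg$gc_bounds_molpct[2]) / 100
  fixed_seq <- paste0(paste(vapply(genes, function(g) unclass(g)[1], character(1)),
                            collapse = ""),
                      if (two_gene) paste0(its2$head, its2$fill, its2$tail) else "")
  fixed_gc <- if (nchar(fixed_seq) > 0) {
    sum(strsplit(fixed_seq, "")[[1]] %in% c("G", "C"))
  } else 0
  need <- round(target_gc * its_len) - fixed_gc
  fill_frac <- min(1, max(0, need / (left + right)))

  segs <- list(scaffold_seg("scaffold16", SCAFFOLD_16S))
  add <- function(x) segs[[length(segs) + 1]] <<- x
  if (its_type == "ITS_none") {
    add(seg("its_fill", make_filler(its_len, fill_frac), indel_ok = TRUE))
  } else if (its_type == "ITS_Ala") {
    add(seg("spacer_a", make_filler(left, fill_frac), indel_ok = TRUE))
    add(gene_seg("gene1", genes[[1]]))
    add(seg("spacer_b", make_filler(right, fill_frac), indel_ok = TRUE))
  } else {
    add(seg("its1", make_filler(left, fill_frac), indel_ok = TRUE))
    add(gene_seg("gene1", genes[[1]]))
    add(motif_seg("its2_head", its2$head))
    add(seg("its2_fill", its2$fill, indel_ok = TRUE))
    add(motif_seg("its2_tail", its2$tail))
    add(gene_seg("gene2", genes[[2]]))
    add(seg("its3", make_filler(right, fill_frac), indel_ok = TRUE))
  }
  add(scaffold_seg("scaffold23", SCAFFOLD_23S))

  structure(list(segments = segs, its_type = its_type, its2_group = its2_group,
                 clade = clade_id), class = "operon")
}

operon_sequence <- function(op) {
  paste(vapply(op$segments, `[[`, character(1), "seq"), collapse = "")
}

# ground-truth record for one operon (gene/ITS-2 coordinates relative to the
# spacer, 1-based inclusive; spacer coordinates relative to the operon)
operon_truth <- function(op, seq_id, role) {
  lens <- vapply(op$segments, function(s) nchar(s$seq), numeric(1))
  names(lens) <- vapply(op$segments, `[[`, character(1), "name")
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  its_idx <- which(!names(lens) %in% c("scaffold16", "scaffold23"))
  its_start <- starts[its_idx[1]]
  its_end <- ends[its_idx[length(its_idx)]]
  its_len <- its_end - its_start + 1
  rel <- function(i) c(starts[i] - its_start + 1, ends[i] - its_start + 1)

  gidx <- which(names(lens) %in% c("gene1", "gene2"))
  gene_info <- lapply(gidx, function(i) {
    m <- op$segments[[i]]$meta
    r <- rel(i)
    list(start = r[1], end = r[2], isotype = m$isotype, pseudo = m$pseudo)
  })
  g1 <- if (length(gene_info) >= 1) gene_info[[1]] else list(start = NA, end = NA, isotype = NA, pseudo = NA)
  g2 <- if (length(gene_info) >= 2) gene_info[[2]] else list(start = NA, end = NA, isotype = NA, pseudo = NA)

  two_gene <- "its2_head" %in% names(lens)
  if (two_gene) {
    i1 <- which(names(lens) == "its2_head")
    i2 <- which(names(lens) == "its2_tail")
    its2_start <- rel(i1)[1]; its2_end <- rel(i2)[2]
    its2_len <- its2_end - its2_start + 1
    its2_group <- assign_its2_group(its2_len)
  } else {
    its2_start <- NA; its2_end <- NA; its2_len <- NA; its2_group <- NA_character_
  }

  its_seq <- substr(operon_sequence(op), its_start, its_end)
  data.frame(
    seq_id = seq_id, role = role, clade = op$clade,
    its_start = unname(its_start), its_end = unname(its_end),
    its_len = unname(its_len),
    gc_molpct = round(100 * gc_content(its_seq), 2),
    its_type = op$its_type, n_genes = length(gene_info),
    gene1_start = g1$start, gene1_end = g1$end,
    gene1_isotype = g1$isotype, gene1_pseudo = g1$pseudo,
    gene2_start = g2$start, gene2_end = g2$end,
    gene2_isotype = g2$isotype, gene2_pseudo = g2$pseudo,
    its2_start = unname(its2_start), its2_end = unname(its2_end),
    its2_len = unname(its2_len), its2_group = its2_group,
    stringsAsFactors = FALSE
  )
}

# apply JC substitutions and indels to an operon; RNG must be seeded.
# Substitutions hit unprotected spacer positions; indels hit indel_ok
# segments only. Resamples (bounded) until the spacer length stays inside
# its_bounds and the spacer G+C inside gc_bounds (mol%, +/- a small
# feasibility margin), so descendants honour the panel envelope.
evolve_operon <- function(op, jc_d, indel_rate, indel_mean_len, its_bounds,
                          gc_bounds = NULL) {
  for (try in 1:20) {
    segs <- op$segments
    # substitutions
    p <- 0.75 * (1 - exp(-4 * jc_d / 3))
    mut <- lapply(segs, function(s) {
      if (s$name %in% c("scaffold16", "scaffold23")) return(integer(0))
      which(!s$protect)
    })
    n_mut <- sum(lengths(mut))
    k <- min(n_mut, stats::rpois(1, n_mut * p))
    if (k > 0 && n_mut > 0) {
      flat_seg <- rep(seq_along(mut), lengths(mut))
      flat_pos <- unlist(mut, use.names = FALSE)
      hit <- sample.int(length(flat_seg), k)
      for (si in unique(flat_seg[hit])) {
        pos <- flat_pos[hit[flat_seg[hit] == si]]
        ch <- strsplit(segs[[si]]$seq, "", fixed = TRUE)[[1]]
        ch[pos] <- vapply(ch[pos], function(b) {
          pick1(setdiff(c("A", "C", "G", "T"), b))
        }, character(1))
        segs[[si]]$seq <- paste(ch, collapse = "")
      }
    }
    # indels
    n_ind <- stats::rpois(1, indel_rate)
    for (e in seq_len(n_ind)) {
      ok <- which(vapply(segs, `[[`, logical(1), "indel_ok") &
                    vapply(segs, function(s) nchar(s$seq), numeric(1)) > 4)
      if (length(ok) == 0) break
      w <- vapply(segs[ok], function(s) nchar(s$seq), numeric(1))
      si <- ok[sample.int(length(ok), 1, prob = w)]
      len <- min(12, 1 + stats::rgeom(1, 1 / indel_mean_len))
      s <- segs[[si]]$seq
      n <- nchar(s)
      if (stats::runif(1) < 0.5) {           # deletion
        pos <- sample.int(max(1, n - len + 1), 1)
        segs[[si]]$seq <- paste0(substr(s, 1, pos - 1), substr(s, pos + len, n))
      } else {                                # insertion
        pos <- sample.int(n + 1, 1) - 1
        ins <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
        segs[[si]]$seq <- paste0(substr(s, 1, pos), ins, substr(s, pos + 1, n))
      }
      segs[[si]]$protect <- rep(FALSE, nchar(segs[[si]]$seq))
    }
    new_op <- op
    new_op$segments <- segs
    its_seg <- !vapply(segs, `[[`, character(1), "name") %in%
      c("scaffold16", "scaffold23")
    its_len <- sum(vapply(segs[its_seg], function(s) nchar(s$seq), numeric(1)))
    if (its_len < its_bounds[1] || its_len > its_bounds[2]) next
    if (!is.null(gc_bounds)) {
      its_seq <- paste(vapply(segs[its_seg], `[[`, character(1), "seq"),
                       collapse = "")
      gc <- 100 * gc_content(its_seq)
      if (gc < gc_bounds[1] - 0.4 || gc > gc_bounds[2] + 0.4) next
    }
    return(new_op)
  }
  stop("could not keep the spacer inside the length/G+C envelope after 20 attempts")
}

#' Evolve descendants of an ancestor sequence
#'
#' Each descendant receives `Poisson(L * p)` substitutions at uniformly drawn
#' unprotected positions (where `p` is the JC-expected mismatch fraction for
#' distance `jc_d`) and `Poisson(indel_rate)` indel events with geometric
#' lengths (mean `indel_mean_len`, cap 12 nt) away from protected positions.
#'
#' @param ancestor nucleotide string.
#' @param n_desc number of descendants.
#' @param jc_d Jukes-Cantor distance (substitutions/site) to each descendant.
#' @param indel_rate expected indels per descendant.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @param protected_sites 1-based positions shielded from substitutions
#'   (and, as contiguous runs, from indels).
#' @param indel_mean_len mean indel length.
#' @return character vector of `n_desc` descendant sequences.
#' @export
evolve_clade <- function(ancestor, n_desc, jc_d, indel_rate = 0, seed = NULL,
                         protected_sites = integer(0), indel_mean_len = 3) {
  stopifnot(jc_d >= 0)
  run <- function() {
    n <- nchar(ancestor)
    protect <- rep(FALSE, n)
    protect[protected_sites] <- TRUE
    # split into alternating mutable / protected runs so that indels cannot
    # touch protected positions
    runs <- rle(protect)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    segments <- lapply(seq_along(runs$values), function(i) {
      s <- substr(ancestor, starts[i], ends[i])
      if (runs$values[i]) {
        seg(paste0("prot", i), s, protect = rep(TRUE, nchar(s)), indel_ok = FALSE)
      } else {
        seg(paste0("fill", i), s, indel_ok = TRUE)
      }
    })
    op <- structure(list(segments = segments, its_type = "ITS_none",
                         its2_group = NA, clade = 1), class = "operon")
    vapply(seq_len(n_desc), function(i) {
      operon_sequence(evolve_operon(op, jc_d, indel_rate, indel_mean_len,
                                    c(0, .Machine$integer.max)))
    }, character(1))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate one synthetic operon
#'
#' Either builds a fresh clade-template operon under the configuration, or
#' evolves one descendant from the given template.
#'
#' @param cfg a [panel_config].
#' @param clade_template an `"operon"` object to descend from, or `NULL`.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return list with `seq` (a one-row [dna_set]), `truth` (one ground-truth
#'   row) and `operon` (the internal segment representation).
#' @export
generate_operon <- function(cfg = panel_config(), clade_template = NULL,
                            seed = NULL) {
  run <- function() {
    op <- if (is.null(clade_template)) {
      make_template_operon(cfg, make_group_ancestors(cfg), clade_id = 1L)
    } else {
      evolve_operon(clade_template, cfg$its2_divergence, cfg$indel_rate,
                    cfg$indel_mean_len, cfg$its_len_bounds,
                    cfg$gc_bounds_molpct)
    }
    truth <- operon_truth(op, "operon1",
                          if (is.null(clade_template)) "reference" else "isolate")
    list(seq = dna_set("operon1", operon_sequence(op),
                       paste0("synthetic rRNA operon fragment [", op$its_type, "]")),
         truth = truth, operon = op)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a full synthetic operon panel
#'
#' Draws `n_references` clade-template operons and distributes `n_isolates`
#' descendants over them (each clade keeps at least its template). With the
#' defaults this reproduces the 37-sequence, 14-reference study design. The
#' panel is byte-identical for a fixed `cfg$seed`.
#'
#' @param cfg a [panel_config].
#' @return list of class `"operon_panel"` with `seqs` (a [dna_set] of
#'   operons, references first) and `truth` (ground-truth data frame).
#' @export
generate_panel <- function(cfg = panel_config()) {
  with_seed(cfg$seed, {
    ancestors <- make_group_ancestors(cfg)
    templates <- lapply(seq_len(cfg$n_references), function(r) {
      make_template_operon(cfg, ancestors, clade_id = r)
    })
    assign_clade <- if (cfg$n_isolates > 0 && cfg$n_references > 0) {
      sort(sample.int(cfg$n_references, cfg$n_isolates, replace = TRUE))
    } else integer(0)

    ids <- character(0); seqs <- character(0); desc <- character(0)
    truth <- list()
    for (r in seq_len(cfg$n_references)) {
      id <- sprintf("REF%02d", r)
      op <- templates[[r]]
      ids <- c(ids, id)
      seqs <- c(seqs, operon_sequence(op))
      desc <- c(desc, paste0("reference clade ", r, " [", op$its_type, "]"))
      truth[[length(truth) + 1]] <- operon_truth(op, id, "reference")
    }
    for (i in seq_along(assign_clade)) {
      r <- assign_clade[i]
      id <- sprintf("ISO%02d", i)
      op <- evolve_operon(templates[[r]], cfg$its2_divergence, cfg$indel_rate,
                          cfg$indel_mean_len, cfg$its_len_bounds,
                          cfg$gc_bounds_molpct)
      ids <- c(ids, id)
      seqs <- c(seqs, operon_sequence(op))
      desc <- c(desc, paste0("isolate of clade ", r, " [", op$its_type, "]"))
      truth[[length(truth) + 1]] <- operon_truth(op, id, "isolate")
    }
    structure(list(seqs = dna_set(ids, seqs, desc),
                   truth = do.call(rbind, truth),
                   config = cfg),
              class = "operon_panel")
  })
}

#' @export
print.operon_panel <- function(x, ...) {
  cat("operon_panel:", nrow(x$seqs), "operons (",
      sum(x$truth$role == "reference"), "references,",
      sum(x$truth$role == "isolate"), "isolates )\n")
  print(table(x$truth$its_type))
  invisible(x)
}
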