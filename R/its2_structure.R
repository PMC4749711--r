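# ITS-2 hairpin folding by dynamic programming with a simple integer
# stability model. The stability score is unitless and only
# ordering-comparable (more negative = more stable): pair weights GC -3,
# AT -2, GT -1 and a -1 stacking bonus per adjacent pair. This fills the
# role of a thermodynamic folder for stem-versus-hairpin comparisons but
# does not predict free energies.

#' Folding parameters
#' @param wGC,wAT,wGT per-pair weights (positive magnitudes).
#' @param stack_bonus bonus per stacked adjacent pair.
#' @param min_loop minimum unpaired span enclosed by any pair (default 3).
#' @return named list.
#' @export
fold_params <- function(wGC = 3, wAT = 2, wGT = 1, stack_bonus = 1,
                        min_loop = 3) {
  list(wGC = wGC, wAT = wAT, wGT = wGT, stack_bonus = stack_bonus,
       min_loop = min_loop)
}

#' Fold an ITS-2 sequence into its optimal nested structure
#'
#' Nussinov-style dynamic programming maximising total (negated) stability,
#' with deterministic traceback (pairing preferred, then the leftmost
#' split). No pseudoknots; each base pairs at most once; at least
#' `min_loop` unpaired bases are enforced inside every pair.
#'
#' @param its2 nucleotide string or one-row [dna_set] (length >= 8 for a
#'   meaningful hairpin; shorter input folds trivially).
#' @param params folding parameters ([fold_params]).
#' @return list of class `"rna_structure"`: `pairs` (2-column matrix of
#'   1-based index pairs), `dot_bracket`, `stem_len` (longest helix),
#'   `loop_len` (unpaired span enclosed by that helix), `stability`
#'   (<= 0; 0 when nothing pairs) and `length`.
#' @export
fold_its2 <- function(its2, params = fold_params()) {
  seq <- one_sequence(its2)
  n <- nchar(seq)
  res <- cpp_nussinov(seq, params$wGC, params$wAT, params$wGT,
                      params$stack_bonus, params$min_loop)
  pairs <- res$pairs
  if (nrow(pairs) > 0) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  db <- rep(".", n)
  if (nrow(pairs) > 0) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  helix <- longest_helix(pairs)
  loop_len <- 0L
  if (!is.null(helix)) {
    inner <- helix[nrow(helix), ]
    inside <- setdiff(seq(inner[1] + 1, inner[2] - 1),
                      c(pairs[, 1], pairs[, 2]))
    loop_len <- length(inside)
  }
  structure(list(
    pairs = pairs, dot_bracket = paste(db, collapse = ""),
    stem_len = if (is.null(helix)) 0L else nrow(helix),
    loop_len = loop_len,
    stability = -res$score, length = n, sequence = seq
  ), class = "rna_structure")
}

# longest run of consecutive stacked pairs (i,j),(i+1,j-1),... ; returns the
# matrix of pairs of that helix (outermost first), or NULL
longest_helix <- function(pairs) {
  if (nrow(pairs) == 0) return(NULL)
  p <- pairs[order(pairs[, 1]), , drop = FALSE]
  key <- paste(p[, 1], p[, 2])
  best <- NULL
  seen <- character(0)
  for (r in seq_len(nrow(p))) {
    if (key[r] %in% seen) next
    run <- list(p[r, ])
    i <- p[r, 1]; j <- p[r, 2]
    repeat {
      nxt <- paste(i + 1, j - 1)
      if (nxt %in% key) {
        i <- i + 1; j <- j - 1
        run[[length(run) + 1]] <- c(i, j)
        seen <- c(seen, nxt)
      } else break
    }
    m <- do.call(rbind, run)
    if (is.null(best) || nrow(m) > nrow(best)) best <- m
  }
  best
}

#' Classify a folded structure as long-stem or short-hairpin
#'
#' Structures whose longest helix reaches `long_stem_bp` base pairs are the
#' stable long-stem form; helices of 3 to `long_stem_bp - 1` pairs are short
#' hairpins, additionally flagged as putative RNase III processing targets;
#' anything weaker is unstructured.
#'
#' @param s an `"rna_structure"` from [fold_its2()].
#' @param long_stem_bp threshold in base pairs (default 8).
#' @return character label with attribute `putative_rnase3_target`.
#' @export
classify_hairpin <- function(s, long_stem_bp = 8) {
  stopifnot(inherits(s, "rna_structure"))
  if (s$stem_len >= long_stem_bp) {
    structure("long_stem", putative_rnase3_target = FALSE)
  } else if (s$stem_len >= 3) {
    structure("short_hairpin", putative_rnase3_target = TRUE)
  } else {
    structure("unstructured", putative_rnase3_target = FALSE)
  }
}

#' Compare the stability of two structures
#'
#' @param a,b `"rna_structure"` objects.
#' @return `-1` if `a` is more stable (lower stability score), `1` if `b`
#'   is, `0` on a tie.
#' @export
stability_compare <- function(a, b) {
  stopifnot(inherits(a, "rna_structure"), inherits(b, "rna_structure"))
  sign(a$stability - b$stability)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  cat(sprintf("stem %d bp, loop %d nt, stability %d\n",
              x$stem_len, x$loop_len, x$stability))
  invisible(x)
}

#' Write structures in Vienna dot-bracket format
#' @param structures named list of `"rna_structure"` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dot_bracket <- function(structures, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(structures)) {
    s <- structures[[nm]]
    writeLines(c(paste0(">", nm), s$sequence,
                 paste0(s$dot_bracket, " (", s$stability, ")")), con)
  }
  invisible(path)
}
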