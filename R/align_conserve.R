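# Pairwise and progressive multiple alignment plus conservation statistics,
# conserved-block discovery, and indel-event counting. The aligner fills the
# role of an external MSA program but makes no attempt to reproduce its
# columns; scoring is standard nucleotide NW (match +1, mismatch -1,
# gap open -5, gap extend -1; a gap of length k costs open + (k-1)*extend).

#' Default alignment parameters
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return named list.
#' @export
aln_params <- function(match = 1, mismatch = -1, gap_open = -5,
                       gap_extend = -1) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Construct an alignment object
#'
#' @param ids sequence identifiers.
#' @param rows gapped strings, all the same length.
#' @param params the scoring parameters the alignment was built with.
#' @return list of class `"msa"` with `ids`, `rows`, `params`.
#' @export
new_msa <- function(ids, rows, params = aln_params()) {
  stopifnot(length(ids) == length(rows))
  if (length(rows) > 0 && length(unique(nchar(rows))) != 1) {
    stop("all alignment rows must have equal length")
  }
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 params = params), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$rows), "rows x", if (length(x$rows)) nchar(x$rows[1]) else 0,
      "columns\n")
  invisible(x)
}

msa_matrix <- function(aln) {
  if (length(aln$rows) == 0) return(matrix(character(0), 0, 0))
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

# one-hot / frequency profile (rows A, C, G, T, gap) of an msa
msa_profile <- function(aln) {
  m <- msa_matrix(aln)
  L <- ncol(m)
  prof <- matrix(0, 5, L)
  lets <- c("A", "C", "G", "T", "-")
  for (k in 1:5) prof[k, ] <- colMeans(m == lets[k])
  prof
}

apply_path <- function(rows, ops, gap_in) {
  # ops: 0 diag, 1 up (gap in second group), 2 left (gap in first group)
  vapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    out <- character(length(ops))
    i <- 0
    for (k in seq_along(ops)) {
      if (ops[k] == gap_in) {
        out[k] <- "-"
      } else {
        i <- i + 1
        out[k] <- ch[i]
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

merge_alignments <- function(a, b, params) {
  ops <- cpp_nw_profile(msa_profile(a), msa_profile(b),
                        params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
  new_msa(c(a$ids, b$ids),
          c(apply_path(a$rows, ops, gap_in = 2L),
            apply_path(b$rows, ops, gap_in = 1L)),
          params)
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment with deterministic tie-breaking (diagonal
#' preferred, then a gap in `b`, then a gap in `a`).
#'
#' @param a,b nucleotide strings or one-row [dna_set]s (non-empty).
#' @param params scoring parameters ([aln_params]).
#' @return list with `aln` (two-row `"msa"`) and `score`.
#' @export
needleman_wunsch <- function(a, b, params = aln_params()) {
  sa <- one_sequence(a); sb <- one_sequence(b)
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("sequences must be non-empty")
  a1 <- new_msa("a", sa, params)
  b1 <- new_msa("b", sb, params)
  ops <- cpp_nw_profile(msa_profile(a1), msa_profile(b1),
                        params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
  aln <- new_msa(c("a", "b"),
                 c(apply_path(sa, ops, gap_in = 2L),
                   apply_path(sb, ops, gap_in = 1L)),
                 params)
  list(aln = aln, score = attr(ops, "score"))
}

# k-mer (default 4) distance between plain sequences: 1 - fraction of
# shared k-mer occurrences (profile intersection over mean length)
kmer_distance_matrix <- function(seqs, k = 4) {
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      common <- intersect(names(kmers[[i]]), names(kmers[[j]]))
      shared <- sum(pmin(kmers[[i]][common], kmers[[j]][common]))
      denom <- max(1, min(sum(kmers[[i]]), sum(kmers[[j]])))
      D[i, j] <- D[j, i] <- 1 - shared / denom
    }
  }
  D
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by UPGMA on k-mer distances, then merges profiles
#' bottom-up with profile-profile NW under the same affine scoring as
#' [needleman_wunsch()]. Stripping gaps from any output row recovers the
#' input sequence exactly.
#'
#' @param seqs a [dna_set], or a named character vector of sequences
#'   (>= 2 sequences).
#' @param params scoring parameters.
#' @return an `"msa"` with rows in input order.
#' @export
progressive_msa <- function(seqs, params = aln_params()) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id; ss <- seqs$residues
  } else {
    ss <- as.character(seqs)
    ids <- if (!is.null(names(seqs))) names(seqs) else paste0("seq", seq_along(ss))
  }
  n <- length(ss)
  if (n < 2) stop("progressive_msa needs at least 2 sequences")
  if (n == 2) {
    r <- needleman_wunsch(ss[1], ss[2], params)
    return(new_msa(ids, r$aln$rows, params))
  }
  D <- kmer_distance_matrix(ss)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  nodes <- vector("list", n - 1)
  leaf <- function(i) new_msa(ids[i], ss[i], params)
  for (m in seq_len(n - 1)) {
    l <- hc$merge[m, 1]; r <- hc$merge[m, 2]
    a <- if (l < 0) leaf(-l) else nodes[[l]]
    b <- if (r < 0) leaf(-r) else nodes[[r]]
    nodes[[m]] <- merge_alignments(a, b, params)
  }
  res <- nodes[[n - 1]]
  ord <- match(ids, res$ids)
  new_msa(ids, res$rows[ord], params)
}

#' Percent identity between two gapped rows
#'
#' 100 x matches over columns where at least one of the two rows is non-gap,
#' so indels count as differences (columns gapped in both rows are ignored).
#' With `denominator = "ungapped"` only columns where both rows are non-gap
#' are counted, so indels are ignored instead.
#'
#' @param row_a,row_b gapped strings of equal length.
#' @param denominator `"union"` (default; indels count as differences) or
#'   `"ungapped"` (indels ignored).
#' @return percent in `[0, 100]`.
#' @export
percent_identity <- function(row_a, row_b,
                             denominator = c("union", "ungapped")) {
  denominator <- match.arg(denominator)
  stopifnot(nchar(row_a) == nchar(row_b))
  a <- strsplit(row_a, "", fixed = TRUE)[[1]]
  b <- strsplit(row_b, "", fixed = TRUE)[[1]]
  keep <- if (denominator == "union") a != "-" | b != "-" else a != "-" & b != "-"
  if (!any(keep)) return(NaN)
  100 * sum(a[keep] == b[keep] & a[keep] != "-") / sum(keep)
}

#' Pairwise conservation summary of an alignment
#'
#' Mean, standard deviation (n-1 denominator; 0 for a single pair), minimum
#' and maximum of the upper-triangle pairwise percent identities.
#'
#' @param aln an `"msa"` with >= 2 rows.
#' @return list of class `"conservation_summary"`: `pid_matrix`, `mean_pid`,
#'   `sd_pid`, `min_pid`, `max_pid`, `n_pairs`.
#' @export
conservation_summary <- function(aln) {
  n <- length(aln$rows)
  stopifnot(n >= 2)
  pid <- matrix(100, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid[i, j] <- pid[j, i] <- percent_identity(aln$rows[i], aln$rows[j])
    }
  }
  ut <- pid[upper.tri(pid)]
  structure(list(
    pid_matrix = pid, mean_pid = mean(ut),
    sd_pid = if (length(ut) > 1) stats::sd(ut) else 0,
    min_pid = min(ut), max_pid = max(ut), n_pairs = length(ut)
  ), class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("pairwise identity over %d pairs: mean %.1f%% +/- %.1f (range %.1f-%.1f)\n",
              x$n_pairs, x$mean_pid, x$sd_pid, x$min_pid, x$max_pid))
  invisible(x)
}

# per-column majority residue, fraction, and gap-freeness
column_stats <- function(m) {
  L <- ncol(m)
  maj <- character(L); frac <- numeric(L); gapfree <- logical(L)
  consensus <- character(L)
  iupac_union <- c(
    "A" = "A", "C" = "C", "G" = "G", "T" = "T",
    "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
    "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
  )
  for (j in seq_len(L)) {
    col <- m[, j]
    gapfree[j] <- all(col != "-")
    tab <- table(col[col != "-"])
    if (length(tab) == 0) {
      maj[j] <- "-"; frac[j] <- 0; consensus[j] <- "-"
      next
    }
    top <- names(tab)[tab == max(tab)]
    maj[j] <- top[1]
    frac[j] <- max(tab) / nrow(m)
    consensus[j] <- if (length(top) == 1) top else {
      iupac_union[[paste(sort(top), collapse = "")]]
    }
  }
  list(maj = maj, frac = frac, gapfree = gapfree, consensus = consensus)
}

#' Find conserved blocks in an alignment
#'
#' Maximal runs of at least `min_len` gap-free columns whose majority
#' residue reaches `min_col_identity` percent of the rows. The consensus is
#' the per-column majority residue; ties are encoded as the IUPAC union
#' symbol, never an arbitrary residue.
#'
#' @param aln an `"msa"`.
#' @param min_len minimum block length in columns (>= 2).
#' @param min_col_identity per-column majority threshold (percent).
#' @return data frame (`start`, `end`, `length`, `consensus`), columns
#'   1-based, sorted by start.
#' @export
find_conserved_blocks <- function(aln, min_len = 4, min_col_identity = 90) {
  stopifnot(min_len >= 2)
  m <- msa_matrix(aln)
  st <- column_stats(m)
  ok <- st$gapfree & (100 * st$frac >= min_col_identity)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep],
                    consensus = vapply(which(keep), function(i) {
                      paste(st$consensus[starts[i]:ends[i]], collapse = "")
                    }, character(1)),
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Count indel events for one row of an alignment
#'
#' A deletion event is a maximal run of columns where the focus row is
#' gapped while at least one other row is not; an insertion event is a
#' maximal run where the focus row is the only non-gapped row. Each run
#' counts as one event. Alignment-column positions are 1-based; for
#' insertions the event's own coordinates on the focus sequence are also
#' reported.
#'
#' @param aln an `"msa"`.
#' @param focus_row a sequence id present in the alignment.
#' @return data frame (`aln_start`, `aln_end`, `length`, `kind`,
#'   `focus_start`, `focus_end`).
#' @export
count_indel_events <- function(aln, focus_row) {
  i <- match(focus_row, aln$ids)
  if (is.na(i)) stop("focus row not found: ", focus_row)
  m <- msa_matrix(aln)
  focus <- m[i, ]
  others <- m[-i, , drop = FALSE]
  some_other <- apply(others != "-", 2, any)
  del <- focus == "-" & some_other
  ins <- focus != "-" & !some_other
  # focus-sequence coordinate of each column (position of last consumed base)
  fpos <- cumsum(focus != "-")
  events <- function(mask, kind) {
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep) == 0) {
      return(data.frame(aln_start = integer(0), aln_end = integer(0),
                        length = integer(0), kind = character(0),
                        focus_start = integer(0), focus_end = integer(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(
      aln_start = starts[keep], aln_end = ends[keep],
      length = r$lengths[keep], kind = kind,
      focus_start = if (kind == "insertion") fpos[starts[keep]] else fpos[starts[keep]],
      focus_end = fpos[ends[keep]],
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(events(del, "deletion"), events(ins, "insertion"))
  out[order(out$aln_start), , drop = FALSE]
}

#' Locate group-specific length stretches
#'
#' Maximal runs of at least `min_len` columns where every `group_a` row is
#' non-gap and every `group_b` row is gapped - the signature of a long
#' insertion carried by one group (or equivalently a deletion in the other).
#'
#' @param aln an `"msa"`.
#' @param group_a,group_b disjoint, non-empty sets of sequence ids.
#' @param min_len minimum stretch length in columns.
#' @return data frame (`start`, `end`, `length`), 1-based columns.
#' @export
locate_length_stretches <- function(aln, group_a, group_b, min_len = 20) {
  stopifnot(length(group_a) > 0, length(group_b) > 0,
            length(intersect(group_a, group_b)) == 0)
  ia <- match(group_a, aln$ids); ib <- match(group_b, aln$ids)
  if (anyNA(ia) || anyNA(ib)) stop("group ids not all present in alignment")
  m <- msa_matrix(aln)
  mask <- apply(m[ia, , drop = FALSE] != "-", 2, all) &
    apply(m[ib, , drop = FALSE] == "-", 2, all)
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Write an alignment as FASTA
#' @param aln an `"msa"`.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(aln, path, width = 70) {
  df <- data.frame(id = aln$ids, residues = aln$rows, description = "",
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(paste0(">", df$id[i]), con)
    s <- df$residues[i]; n <- nchar(s)
    starts <- seq(1, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, n)), con)
  }
  invisible(path)
}
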