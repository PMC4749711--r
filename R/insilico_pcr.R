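# In-silico PCR: degenerate primer site search, amplicon extraction, and
# excision of the spacer between the primer footprints.

#' Packaged primer set
#'
#' The two assays shipped with the package: a sphingomonad-specific 16S rDNA
#' assay (Sphingo 108f / Sphingo 420r, ~352 bp product) and the 16S-23S
#' spacer assay with two interchangeable pairs (16S-1511f / 23S-23r and
#' 1492f / 115r), the forward primers sitting at the end of the 16S rRNA
#' gene and the reverse primers at the start of the 23S rRNA gene.
#'
#' @return data frame with columns `name`, `residues`, `role`, `assay`,
#'   `annealing_c`.
#' @export
default_primers <- function() {
  path <- system.file("extdata", "primers.tsv", package = "ribospacer")
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Define a primer
#'
#' @param name primer name.
#' @param residues IUPAC string, 5'->3', length >= 10.
#' @param role `"forward"` or `"reverse"`; reverse primers are matched
#'   against the template as reverse complements.
#' @return one-row data frame.
#' @export
primer <- function(name, residues, role = c("forward", "reverse")) {
  role <- match.arg(role)
  residues <- normalize_residues(residues)
  if (nchar(residues) < 10) stop("primer must be at least 10 nt")
  data.frame(name = name, residues = residues, role = role,
             stringsAsFactors = FALSE)
}

get_primer <- function(x, name = NULL) {
  if (is.character(x) && length(x) == 1) {
    p <- default_primers()
    p <- p[p$name == x, , drop = FALSE]
    if (nrow(p) == 0) stop("unknown primer: ", x)
    return(p[1, ])
  }
  stopifnot(is.data.frame(x), nrow(x) == 1)
  x
}

#' Find degenerate primer binding sites
#'
#' Ungapped matching of the primer (or, for reverse primers, its reverse
#' complement) against the template under IUPAC-intersection semantics
#' ([iupac_matches]), allowing up to `max_mismatch` mismatching positions.
#' Delegates to `Biostrings::matchPattern(fixed = FALSE)`.
#'
#' @param template a nucleotide string or one-row [dna_set].
#' @param primer a primer (from [primer()] / [default_primers()]) or a
#'   packaged primer name.
#' @param max_mismatch maximum number of mismatches (default 2).
#' @return data frame of intervals (`start`, `end`, 1-based inclusive,
#'   `strand`), sorted by start; empty when the primer is longer than the
#'   template or there is no hit.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 2) {
  stopifnot(max_mismatch >= 0)
  tpl <- one_sequence(template)
  p <- get_primer(primer)
  pat <- if (p$role == "reverse") revcomp(p$residues) else p$residues
  if (nchar(pat) > nchar(tpl)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                Biostrings::DNAString(tpl),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE, fixed = FALSE)
  out <- data.frame(start = Biostrings::start(m), end = Biostrings::end(m),
                    strand = rep(if (p$role == "reverse") "-" else "+",
                                 length(m)),
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Extract PCR amplicons
#'
#' Every forward site upstream of a reverse site whose product length falls
#' inside `[min_len, max_len]` yields one amplicon, spanning both primer
#' footprints. Default limits bracket the expected spacer amplicons.
#'
#' @param template a nucleotide string or one-row [dna_set].
#' @param fwd,rev forward and reverse primers (or packaged names).
#' @param max_mismatch maximum mismatches per site (default 2).
#' @param min_len,max_len product length limits.
#' @param template_id identifier recorded in the output.
#' @return data frame of amplicons (`template_id`, `start`, `end`, `length`,
#'   `residues`), sorted by start then length; empty when no site pair
#'   qualifies.
#' @export
amplify <- function(template, fwd, rev, max_mismatch = 2,
                    min_len = 200, max_len = 2000,
                    template_id = NULL) {
  stopifnot(min_len <= max_len)
  tpl <- one_sequence(template)
  if (is.null(template_id)) {
    template_id <- if (is.data.frame(template)) template$id else "template"
  }
  fwd <- get_primer(fwd); rev <- get_primer(rev)
  if (fwd$role != "forward" || rev$role != "reverse") {
    stop("amplify() needs one forward and one reverse primer")
  }
  fs <- find_primer_sites(tpl, fwd, max_mismatch)
  rs <- find_primer_sites(tpl, rev, max_mismatch)
  out <- list()
  for (i in seq_len(nrow(fs))) {
    for (j in seq_len(nrow(rs))) {
      if (fs$start[i] >= rs$start[j]) next
      len <- rs$end[j] - fs$start[i] + 1
      if (len < min_len || len > max_len) next
      out[[length(out) + 1]] <- data.frame(
        template_id = template_id, start = fs$start[i], end = rs$end[j],
        length = len, residues = substr(tpl, fs$start[i], rs$end[j]),
        fwd_len = nchar(fwd$residues), rev_len = nchar(rev$residues),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      residues = character(0), fwd_len = integer(0),
                      rev_len = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out[order(out$start, out$length), , drop = FALSE]
}

#' Excise the intergenic spacer from an amplicon
#'
#' Returns the sub-sequence strictly between the primer footprints: the
#' forward primer sits at the annotated 3' end of the 16S gene and the
#' reverse primer at the annotated 5' start of the 23S gene, so what lies
#' between them is the spacer used by all downstream analysis.
#'
#' @param amplicon one row of [amplify()] output.
#' @param fwd_anchor,rev_anchor the primers the amplicon was produced with
#'   (used for footprint lengths when the amplicon row lacks them).
#' @return list with `seq` (spacer string), `start`, `end` (1-based interval
#'   on the original template).
#' @export
extract_its <- function(amplicon, fwd_anchor = NULL, rev_anchor = NULL) {
  stopifnot(nrow(amplicon) == 1)
  fl <- if (!is.null(fwd_anchor)) nchar(get_primer(fwd_anchor)$residues) else amplicon$fwd_len
  rl <- if (!is.null(rev_anchor)) nchar(get_primer(rev_anchor)$residues) else amplicon$rev_len
  n <- nchar(amplicon$residues)
  its_len <- n - fl - rl
  if (its_len <= 0) {
    stop("degenerate spacer: primer footprints abut or overlap")
  }
  list(seq = substr(amplicon$residues, fl + 1, n - rl),
       start = amplicon$start + fl, end = amplicon$end - rl)
}

#' Write intervals as a GFF-like TSV
#'
#' @param df data frame with at least `start` and `end` (1-based inclusive).
#' @param path output path.
#' @param seq_id sequence identifier column or constant.
#' @return `path`, invisibly.
#' @export
write_intervals_tsv <- function(df, path, seq_id = "seq") {
  out <- cbind(seq_id = if (length(seq_id) == 1) rep(seq_id, nrow(df)) else seq_id,
               df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
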