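#' @useDynLib ribospacer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC nucleotide expansion sets (DNA alphabet; U is normalised to T on input)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
IUPAC_CHARS <- names(IUPAC_SETS)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Build a sequence set
#'
#' The universal container of the package: a data frame with one row per
#' sequence and columns `id`, `residues` and `description`. Residues are
#' uppercase IUPAC DNA characters; `U` is mapped to `T`.
#'
#' @param id character vector of unique sequence identifiers.
#' @param residues character vector of nucleotide strings.
#' @param description optional free-text descriptions (default "").
#' @return A `data.frame` of class `c("dna_set", "data.frame")`.
#' @export
dna_set <- function(id, residues, description = "") {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("sequence ids must be unique")
  residues <- normalize_residues(residues)
  out <- data.frame(
    id = id, residues = residues,
    description = rep_len(as.character(description), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dna_set", "data.frame")
  out
}

# Uppercase, U -> T, and reject non-IUPAC characters.
normalize_residues <- function(residues, where = NULL) {
  residues <- chartr("u", "t", toupper(as.character(residues)))
  residues <- gsub("U", "T", residues, fixed = TRUE)
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), residues)
  if (any(bad)) {
    lab <- if (is.null(where)) which(bad)[1] else where[which(bad)[1]]
    stop("non-IUPAC character in sequence (record ", lab, ")")
  }
  residues
}

#' Read a FASTA file
#'
#' Accepts wrapped or unwrapped sequence lines. Residues are uppercased and
#' `U` is converted to `T`; any non-IUPAC character is a parse error naming
#' the offending line. An empty file yields an empty set.
#'
#' @param path path to a FASTA file.
#' @return A [dna_set] with one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) {
    return(dna_set(character(0), character(0), character(0)))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) stop("malformed FASTA: line 1 does not start with '>'")
  rec <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    stop("malformed FASTA header at line ", which(is_header & lines == ">")[1])
  }
  body <- lines[!is_header]
  body_lineno <- which(!is_header)
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")),
               chartr("uU", "tT", toupper(body)))
  if (any(bad)) {
    stop("non-IUPAC character at line ", body_lineno[which(bad)[1]], " of ", path)
  }
  res <- vapply(split(body, rec[!is_header][seq_along(body)]),
                paste, character(1), collapse = "")
  # records with a header but no sequence lines become empty strings
  full <- rep("", length(ids))
  full[as.integer(names(res))] <- res
  dna_set(ids, normalize_residues(full), desc)
}

#' Write a FASTA file
#'
#' @param seqs a [dna_set] (or data frame with `id` and `residues`).
#' @param path output path.
#' @param width line width for wrapping (default 70, must be >= 1).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(width >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    hdr <- if (!is.null(seqs$description) && nzchar(seqs$description[i])) {
      paste0(">", seqs$id[i], " ", seqs$description[i])
    } else paste0(">", seqs$id[i])
    writeLines(hdr, con)
    s <- seqs$residues[i]
    n <- nchar(s)
    if (n > 0) {
      starts <- seq(1, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, n)), con)
    }
  }
  invisible(path)
}

#' G+C content of a sequence
#'
#' Fraction of G+C among unambiguous positions. `S` (G or C) counts toward
#' both numerator and denominator, `W` (A or T) toward the denominator only;
#' all other ambiguity codes are excluded entirely, which keeps the estimate
#' unbiased for unknown bases. Multiply by 100 for mol%.
#'
#' @param seq a nucleotide string (or vector of strings).
#' @return numeric fraction(s) in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- normalize_residues(seq)
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    num <- sum(ch %in% c("G", "C", "S"))
    den <- sum(ch %in% c("A", "C", "G", "T", "S", "W"))
    if (den == 0) stop("G+C content undefined: sequence entirely ambiguous")
    num / den
  }, numeric(1), USE.NAMES = FALSE)
}

#' Do two IUPAC symbols match?
#'
#' TRUE iff the expansion sets of the two symbols intersect: `R` = \{A,G\}
#' matches `A`, `G`, `N` or `D`, but not `C` and not `Y` = \{C,T\}.
#'
#' @param symbol_a,symbol_b single IUPAC characters (vectorised).
#' @return logical vector.
#' @export
iupac_matches <- function(symbol_a, symbol_b) {
  a <- toupper(symbol_a); b <- toupper(symbol_b)
  if (!all(a %in% IUPAC_CHARS) || !all(b %in% IUPAC_CHARS)) {
    stop("non-IUPAC symbol")
  }
  mapply(function(x, y) length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0,
         a, b, USE.NAMES = FALSE)
}

#' Reverse complement
#'
#' @param seq nucleotide string(s), IUPAC ambiguity codes allowed.
#' @return reverse-complemented string(s).
#' @export
revcomp <- function(seq) {
  seq <- normalize_residues(seq)
  vapply(seq, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(IUPAC_COMPLEMENT[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.dna_set <- function(x, ...) {
  cat("dna_set with", nrow(x), "sequence(s)\n")
  if (nrow(x) > 0) {
    show <- utils::head(x, 10)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  %-20s %6d nt  %s\n", show$id[i], nchar(show$residues[i]),
                  substr(show$residues[i], 1, 40)))
    }
    if (nrow(x) > 10) cat("  ...\n")
  }
  invisible(x)
}
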