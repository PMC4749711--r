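# Spacer typing by tRNA gene content and order, ITS-1/2/3 partition, and
# ITS-2 size groups.

#' Classify a spacer by its tRNA arrangement
#'
#' The five arrangements observed in sphingomonad spacers, by gene content
#' and 5'->3' order: no gene, Ala alone, Ala+Ile, Ile+Ala, and Ile followed
#' by a pseudo gene. Any other content or order (e.g. Ile alone, or three
#' genes) is reported as `ITS_other`, never coerced.
#'
#' @param trnas data frame from [scan_trnas()], sorted by start.
#' @return one of `"ITS_none"`, `"ITS_Ala"`, `"ITS_AlaIle"`, `"ITS_IleAla"`,
#'   `"ITS_IlePseudo"`, `"ITS_other"`.
#' @export
classify_its_type <- function(trnas) {
  n <- nrow(trnas)
  if (n == 0) return("ITS_none")
  if (is.unsorted(trnas$start)) stop("tRNA genes must be sorted by start")
  if (n > 1 && any(trnas$start[-1] <= trnas$end[-n])) {
    stop("annotation conflict: overlapping tRNA genes")
  }
  iso <- trnas$isotype
  ps <- trnas$pseudo
  if (n == 1 && iso == "Ala" && !ps) return("ITS_Ala")
  if (n == 2) {
    if (!ps[1] && !ps[2] && iso[1] == "Ala" && iso[2] == "Ile") return("ITS_AlaIle")
    if (!ps[1] && !ps[2] && iso[1] == "Ile" && iso[2] == "Ala") return("ITS_IleAla")
    if (!ps[1] && ps[2] && iso[1] == "Ile") return("ITS_IlePseudo")
  }
  "ITS_other"
}

#' Partition a spacer around its tRNA genes
#'
#' With two gene-like features the spacer splits into ITS-1 (upstream of the
#' first gene), ITS-2 (between the genes) and ITS-3 (downstream of the
#' second); pseudo genes count as spacer-dividing features. With a single
#' gene the two flanks are labelled `spacer-a` / `spacer-b` (no ITS-2: the
#' three-part nomenclature is defined only for the two-gene case). With no
#' genes the whole spacer is one region.
#'
#' @param its spacer string or one-row [dna_set] (only its length is used).
#' @param trnas data frame from [scan_trnas()], sorted by start.
#' @return data frame of regions (`region`, `start`, `end`, `length`,
#'   1-based inclusive; empty regions have `length` 0 and `start` > `end`).
#'   An ITS-2 of length 0 (abutting genes) is flagged with the attribute
#'   `degenerate = TRUE`.
#' @export
partition_its <- function(its, trnas) {
  L <- nchar(one_sequence(its))
  n <- nrow(trnas)
  region <- function(name, s, e) {
    data.frame(region = name, start = s, end = e,
               length = max(0L, e - s + 1L), stringsAsFactors = FALSE)
  }
  if (n == 0) {
    return(region("spacer", 1L, L))
  }
  if (is.unsorted(trnas$start)) stop("tRNA genes must be sorted by start")
  if (n > 1 && any(trnas$start[-1] <= trnas$end[-n])) {
    stop("annotation conflict: overlapping tRNA genes")
  }
  if (n == 1) {
    return(rbind(region("spacer-a", 1L, trnas$start - 1L),
                 region("spacer-b", trnas$end + 1L, L)))
  }
  if (n > 2) stop("partition is defined for at most two tRNA genes")
  out <- rbind(region("ITS-1", 1L, trnas$start[1] - 1L),
               region("ITS-2", trnas$end[1] + 1L, trnas$start[2] - 1L),
               region("ITS-3", trnas$end[2] + 1L, L))
  if (out$length[out$region == "ITS-2"] == 0) {
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Bin an ITS-2 length into the observed size groups
#'
#' Groups observed among sphingomonad spacers: 16-19 nt (short), 60-61 nt
#' (mid) and 122-138 nt (long); anything else reports its own length.
#'
#' @param its2_len non-negative integer length (vectorised).
#' @return character labels.
#' @export
assign_its2_group <- function(its2_len) {
  stopifnot(all(its2_len >= 0))
  vapply(its2_len, function(n) {
    if (n >= 16 && n <= 19) "short(16-19)"
    else if (n >= 60 && n <= 61) "mid(60-61)"
    else if (n >= 122 && n <= 138) "long(122-138)"
    else sprintf("other(%d)", n)
  }, character(1))
}

#' Check the canonical Ala+Ile arrangement convention
#'
#' In the dominant arrangement the Ala gene lies just downstream of the 16S
#' gene and the Ile gene just upstream of the 23S gene. Returns `TRUE` when
#' an `ITS_AlaIle` annotation respects that order, `FALSE` when the order is
#' inverted (`ITS_IleAla`), and `NA` when the convention does not apply.
#'
#' @param annotation an annotation list from [annotate_its()], or a data
#'   frame of tRNA genes with an `its_type` attribute.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
check_arrangement_convention <- function(annotation) {
  type <- if (is.list(annotation) && !is.null(annotation$its_type)) {
    annotation$its_type
  } else {
    attr(annotation, "its_type")
  }
  if (is.null(type)) return(NA)
  switch(type, ITS_AlaIle = TRUE, ITS_IleAla = FALSE, NA)
}

#' Annotate one spacer
#'
#' Runs the detector, classifies the arrangement, partitions the spacer and
#' bins ITS-2.
#'
#' @param its spacer string or one-row [dna_set].
#' @param model a [cloverleaf_model].
#' @param seq_id identifier recorded in the annotation.
#' @return list of class `"its_annotation"`: `seq_id`, `its_len`,
#'   `gc_molpct`, `trnas`, `its_type`, `subregions`, `its2_len`,
#'   `its2_group`.
#' @export
annotate_its <- function(its, model = cloverleaf_model(), seq_id = "its") {
  seq <- one_sequence(its)
  trnas <- scan_trnas(seq, model)
  type <- classify_its_type(trnas)
  sub <- partition_its(seq, if (nrow(trnas) <= 2) trnas else trnas[0, ])
  its2_len <- if (type %in% c("ITS_AlaIle", "ITS_IleAla", "ITS_IlePseudo")) {
    sub$length[sub$region == "ITS-2"]
  } else NA_integer_
  structure(list(
    seq_id = seq_id, its_len = nchar(seq),
    gc_molpct = round(100 * gc_content(seq), 2),
    trnas = trnas, its_type = type, subregions = sub,
    its2_len = its2_len,
    its2_group = if (is.na(its2_len)) NA_character_ else assign_its2_group(its2_len)
  ), class = "its_annotation")
}

#' Collapse annotations into a per-sequence table
#'
#' One row per spacer with the columns of the study's summary table: length,
#' G+C, arrangement type, tRNA positions (1-based "start-end" strings),
#' ITS-2 length and size group.
#'
#' @param annotations list of `"its_annotation"` objects.
#' @return data frame.
#' @export
annotation_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    pos <- if (nrow(a$trnas) > 0) {
      paste(sprintf("%d-%d%s", a$trnas$start, a$trnas$end,
                    ifelse(a$trnas$pseudo, "(pseudo)", "")), collapse = ";")
    } else ""
    iso <- paste(a$trnas$isotype, collapse = ";")
    data.frame(seq_id = a$seq_id, its_len = a$its_len,
               gc_molpct = a$gc_molpct, its_type = a$its_type,
               trna_isotypes = iso, trna_positions = pos,
               its2_len = if (is.na(a$its2_len)) NA_integer_ else a$its2_len,
               its2_group = a$its2_group, stringsAsFactors = FALSE)
  }))
}

#' @export
print.its_annotation <- function(x, ...) {
  cat(sprintf("spacer %s: %d nt, G+C %.1f mol%%, type %s\n",
              x$seq_id, x$its_len, x$gc_molpct, x$its_type))
  if (nrow(x$trnas) > 0) {
    for (i in seq_len(nrow(x$trnas))) {
      cat(sprintf("  tRNA-%s(%s) %d-%d%s score %d\n", x$trnas$isotype[i],
                  x$trnas$anticodon[i], x$trnas$start[i], x$trnas$end[i],
                  if (x$trnas$pseudo[i]) " [pseudo]" else "", x$trnas$score[i]))
    }
  }
  if (!is.na(x$its2_len)) {
    cat(sprintf("  ITS-2: %d nt, group %s\n", x$its2_len, x$its2_group))
  }
  invisible(x)
}
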