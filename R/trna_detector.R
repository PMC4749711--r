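#' Cloverleaf model for rule-based tRNA gene detection
#'
#' Structural constraints and scoring weights used by [scan_trnas()]. The
#' model describes a canonical bacterial tRNA gene (no intron, no CCA tail):
#' an acceptor stem pairing the gene termini, D-arm, a 5-bp anticodon stem
#' with a 7-nt loop carrying the anticodon at its centre, and a 5-bp T-stem
#' whose loop contains the TTC signature. Stems are scored per base pair
#' (GC 3, AT 2, GT 1) plus a motif bonus; a candidate must reach `min_score`.
#'
#' `min_score` was calibrated once on the synthetic panel generator so that
#' canonical genes pass comfortably while composition-matched shuffled
#' spacers essentially never do (see the methods vignette).
#'
#' @param acceptor_bp range of acceptor stem lengths (bp).
#' @param d_stem_bp range of D-stem lengths (bp).
#' @param d_loop_nt range of D-loop lengths (nt).
#' @param t_loop_nt range of T-loop lengths (nt).
#' @param var_loop_nt range of variable-loop lengths (nt).
#' @param total_len_nt admissible total gene lengths (nt).
#' @param t_loop_motif T-loop signature (default "TTC").
#' @param min_score detection threshold on the structural score.
#' @param pair_scores per-pair stem scores.
#' @param motif_bonus score bonus when the T-loop motif is present.
#' @param min_stem_frac minimum fraction of paired positions per stem.
#' @return a list of class `"cloverleaf_model"`.
#' @export
cloverleaf_model <- function(acceptor_bp = c(6, 7), d_stem_bp = c(3, 4),
                             d_loop_nt = c(4, 12), t_loop_nt = c(6, 9),
                             var_loop_nt = c(2, 20), total_len_nt = c(70, 95),
                             t_loop_motif = "TTC", min_score = 52,
                             pair_scores = c(GC = 3, AT = 2, GT = 1),
                             motif_bonus = 2, min_stem_frac = 0.8) {
  stopifnot(min_score > 0, acceptor_bp[1] <= acceptor_bp[2],
            d_stem_bp[1] <= d_stem_bp[2], total_len_nt[1] <= total_len_nt[2])
  structure(list(
    acceptor_bp = acceptor_bp, d_stem_bp = d_stem_bp, d_loop_nt = d_loop_nt,
    anticodon_stem_bp = 5L, anticodon_loop_nt = 7L, t_stem_bp = 5L,
    t_loop_nt = t_loop_nt, var_loop_nt = var_loop_nt,
    total_len_nt = total_len_nt, t_loop_motif = t_loop_motif,
    min_score = min_score, pair_scores = pair_scores,
    motif_bonus = motif_bonus, min_stem_frac = min_stem_frac
  ), class = "cloverleaf_model")
}

#' Map an anticodon to a tRNA isotype label
#'
#' `TGC` is alanine, `GAT` is isoleucine (DNA alphabet); every other
#' anticodon, and any anticodon containing an ambiguity code, is labelled
#' `"other"`.
#'
#' @param anticodon 3-character string(s).
#' @return character vector over `{"Ala", "Ile", "other"}`.
#' @export
classify_isotype <- function(anticodon) {
  anticodon <- toupper(anticodon)
  out <- rep("other", length(anticodon))
  out[anticodon == "TGC"] <- "Ala"
  out[anticodon == "GAT"] <- "Ile"
  out[!grepl("^[ACGT]{3}$", anticodon)] <- "other"
  out
}

# decomposition matrix row -> arm intervals (1-based, relative to gene start)
decomp_arms <- function(row) {
  A <- row[["a_bp"]]; D <- row[["d_bp"]]; LD <- row[["d_loop"]]
  LT <- row[["t_loop"]]; V <- row[["v_loop"]]
  acc5 <- c(1, A)
  d5 <- c(A + 3, A + 2 + D)
  d3 <- c(d5[2] + LD + 1, d5[2] + LD + D)
  ac5 <- c(d3[2] + 2, d3[2] + 1 + 5)
  acl <- c(ac5[2] + 1, ac5[2] + 7)
  ac3 <- c(acl[2] + 1, acl[2] + 5)
  t5 <- c(ac3[2] + V + 1, ac3[2] + V + 5)
  tl <- c(t5[2] + 1, t5[2] + LT)
  t3 <- c(tl[2] + 1, tl[2] + 5)
  acc3 <- c(t3[2] + 1, t3[2] + A)
  list(
    acceptor = data.frame(arm = "acceptor", start = c(acc5[1], acc3[1]),
                          end = c(acc5[2], acc3[2])),
    D = data.frame(arm = "D", start = c(d5[1], d3[1]), end = c(d5[2], d3[2])),
    anticodon = data.frame(arm = "anticodon", start = c(ac5[1], ac3[1]),
                           end = c(ac5[2], ac3[2])),
    T = data.frame(arm = "T", start = c(t5[1], t3[1]), end = c(t5[2], t3[2])),
    anticodon_loop = acl,
    anticodon_pos = c(acl[1] + 2, acl[1] + 4)
  )
}

#' Scan a spacer for tRNA genes
#'
#' Slides a cloverleaf decomposition search along the sequence. At every
#' offset the best-scoring decomposition passing the structural gates
#' (acceptor, D and T stems each at least `min_stem_frac` paired) is kept;
#' candidates reaching `min_score` are then classified against two hard
#' constraints: an intact anticodon stem (>= 4 of 5 pairs) and the presence
#' of the T-loop motif. A candidate satisfying both is a tRNA gene; one
#' violating exactly one of them is reported with `pseudo = TRUE`; violating
#' both disqualifies it. Overlapping candidates are resolved by score
#' (ties to the leftmost).
#'
#' @param its a nucleotide string, or a single-row [dna_set].
#' @param model a [cloverleaf_model].
#' @return data frame with one row per detected gene, sorted by start:
#'   `start`, `end`, `length`, `isotype`, `anticodon`, `score`, `pseudo`,
#'   plus the decomposition geometry (`a_bp`, `d_bp`, `d_loop`, `t_loop`,
#'   `v_loop`) from which [trna_arms()] reconstructs arm coordinates.
#' @export
scan_trnas <- function(its, model = cloverleaf_model()) {
  seq <- one_sequence(its)
  cand <- cpp_scan_cloverleaf(
    seq,
    model$acceptor_bp[1], model$acceptor_bp[2],
    model$d_stem_bp[1], model$d_stem_bp[2],
    model$d_loop_nt[1], model$d_loop_nt[2],
    model$t_loop_nt[1], model$t_loop_nt[2],
    model$var_loop_nt[1], model$var_loop_nt[2],
    model$total_len_nt[1], model$total_len_nt[2],
    model$t_loop_motif, model$motif_bonus, model$min_stem_frac
  )
  empty <- data.frame(
    start = integer(0), end = integer(0), length = integer(0),
    isotype = character(0), anticodon = character(0), score = integer(0),
    pseudo = logical(0), a_bp = integer(0), d_bp = integer(0),
    d_loop = integer(0), t_loop = integer(0), v_loop = integer(0),
    stringsAsFactors = FALSE
  )
  if (nrow(cand) == 0) return(empty)
  cand <- as.data.frame(cand)
  cand <- cand[cand$score >= model$min_score, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  v_ac <- cand$ac_pairs < ceiling(model$min_stem_frac * 5 - 1e-9)
  v_motif <- cand$motif == 0
  nviol <- v_ac + v_motif
  cand$pseudo <- nviol == 1
  cand <- cand[nviol <= 1, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  # resolve overlaps by score, ties to the leftmost
  cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
  kept <- logical(nrow(cand))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$start[i] + cand$total[i] - 1
    if (!any(s <= occ_end & e >= occ_start)) {
      kept[i] <- TRUE
      occ_start <- c(occ_start, s); occ_end <- c(occ_end, e)
    }
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]

  anticodon <- vapply(seq_len(nrow(cand)), function(i) {
    arms <- decomp_arms(cand[i, ])
    substr(seq, cand$start[i] + arms$anticodon_pos[1] - 1,
           cand$start[i] + arms$anticodon_pos[2] - 1)
  }, character(1))

  data.frame(
    start = cand$start, end = cand$start + cand$total - 1,
    length = cand$total, isotype = classify_isotype(anticodon),
    anticodon = anticodon, score = cand$score, pseudo = cand$pseudo,
    a_bp = cand$a_bp, d_bp = cand$d_bp, d_loop = cand$d_loop,
    t_loop = cand$t_loop, v_loop = cand$v_loop,
    stringsAsFactors = FALSE
  )
}

#' Arm coordinates of a detected tRNA gene
#'
#' @param hit one row of the data frame returned by [scan_trnas()].
#' @return data frame of arm intervals (1-based, on the scanned sequence).
#' @export
trna_arms <- function(hit) {
  stopifnot(nrow(hit) == 1)
  arms <- decomp_arms(hit)
  out <- rbind(arms$acceptor, arms$D, arms$anticodon, arms$T)
  out$start <- out$start + hit$start - 1
  out$end <- out$end + hit$start - 1
  out
}

#' Best cloverleaf decomposition of a fixed window
#'
#' Exhaustively enumerates arm-boundary placements within the model ranges
#' for a window whose total length is taken as the gene length, and returns
#' the maximum-score decomposition (no structural gates applied), or `NULL`
#' when no decomposition fits the window.
#'
#' @param window nucleotide string with length inside `total_len_nt`.
#' @param model a [cloverleaf_model].
#' @return list with `score`, `arms`, `anticodon`, per-stem pair counts and
#'   `motif`, or `NULL`.
#' @export
fold_cloverleaf <- function(window, model = cloverleaf_model()) {
  seq <- one_sequence(window)
  if (nchar(seq) < model$total_len_nt[1] || nchar(seq) > model$total_len_nt[2]) {
    return(NULL)
  }
  m <- cpp_fold_window(
    seq,
    model$acceptor_bp[1], model$acceptor_bp[2],
    model$d_stem_bp[1], model$d_stem_bp[2],
    model$d_loop_nt[1], model$d_loop_nt[2],
    model$t_loop_nt[1], model$t_loop_nt[2],
    model$var_loop_nt[1], model$var_loop_nt[2],
    model$t_loop_motif, model$motif_bonus
  )
  if (nrow(m) == 0) return(NULL)
  row <- as.data.frame(m)
  if (row$score <= 0) return(NULL)   # nothing pairs at all
  arms <- decomp_arms(row)
  list(
    score = row$score,
    arms = rbind(arms$acceptor, arms$D, arms$anticodon, arms$T),
    anticodon = substr(seq, arms$anticodon_pos[1], arms$anticodon_pos[2]),
    acc_pairs = row$acc_pairs, d_pairs = row$d_pairs,
    ac_pairs = row$ac_pairs, t_pairs = row$t_pairs,
    motif = row$motif == 1,
    geometry = row[, c("a_bp", "d_bp", "d_loop", "t_loop", "v_loop")]
  )
}

# accept a bare string or a 1-row dna_set
one_sequence <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    return(x$residues)
  }
  normalize_residues(x)
}
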