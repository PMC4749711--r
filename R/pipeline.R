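# Orchestration: simulate (or read) operons, excise spacers, detect tRNA
# genes, type and partition, align, summarise conservation, build the
# bootstrap tree, fold ITS-2, and assemble a machine-readable report.
# Failures are isolated per sequence (skip-and-record); the run only errors
# when no sequence survives a stage.

#' Pipeline configuration
#'
#' Exactly one of `input_fasta` and `simulate` must be given.
#'
#' @param input_fasta path to a FASTA of operon fragments, or `NULL`.
#' @param simulate a [panel_config] (used when `input_fasta` is `NULL`).
#' @param primer_pair character vector of two packaged primer names
#'   (forward, reverse) used to excise the spacer.
#' @param max_mismatch mismatches tolerated per primer site.
#' @param model a [cloverleaf_model].
#' @param params alignment scoring parameters ([aln_params]).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed seed for bootstrap resampling.
#' @param long_stem_bp threshold for the long-stem structure class.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_fasta = NULL, simulate = panel_config(),
                            primer_pair = c("16S-1511f", "23S-23r"),
                            max_mismatch = 2,
                            model = cloverleaf_model(),
                            params = aln_params(),
                            n_boot = 1000, seed = 1, long_stem_bp = 8) {
  if (!is.null(input_fasta) && !is.null(simulate)) {
    simulate <- NULL
  }
  if (is.null(input_fasta) && is.null(simulate)) {
    stop("either input_fasta or a simulate block is required")
  }
  stopifnot(n_boot >= 1, length(primer_pair) == 2)
  structure(list(input_fasta = input_fasta, simulate = simulate,
                 primer_pair = primer_pair, max_mismatch = max_mismatch,
                 model = model, params = params, n_boot = n_boot,
                 seed = seed, long_stem_bp = long_stem_bp),
            class = "pipeline_config")
}

pipeline_log <- function(verbose, stage, msg) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full spacer analysis pipeline
#'
#' Stages: simulate/read -> excise spacer -> detect tRNA genes -> type and
#' partition -> align (whole spacer and per subregion) -> conservation,
#' conserved blocks, indel events -> JC/NJ bootstrap consensus tree with ML
#' branch lengths -> ITS-2 folding -> summary. Per-sequence failures (e.g.
#' no amplicon) are recorded and skipped; the run errors only when no
#' sequence is analysable. Deterministic given the seeds in the
#' configuration.
#'
#' @param cfg a [pipeline_config].
#' @param verbose log one line per stage (default FALSE).
#' @return list of class `"its_report"`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  # stage 1: inputs
  if (!is.null(cfg$input_fasta)) {
    seqs <- read_fasta(cfg$input_fasta)
    truth <- NULL
    pipeline_log(verbose, "input", paste(nrow(seqs), "sequences read"))
  } else {
    panel <- generate_panel(cfg$simulate)
    seqs <- panel$seqs
    truth <- panel$truth
    pipeline_log(verbose, "simulate", paste(nrow(seqs), "operons generated"))
  }
  if (nrow(seqs) == 0) stop("no input sequences")

  fwd <- get_primer(cfg$primer_pair[1])
  rev <- get_primer(cfg$primer_pair[2])

  failures <- data.frame(seq_id = character(0), stage = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  fail <- function(id, stage, reason) {
    failures[nrow(failures) + 1, ] <<- list(id, stage, reason)
    pipeline_log(verbose, stage, paste(id, "failed:", reason))
  }

  # stage 2: excision; stage 3-4: annotation
  annotations <- list()
  its_seqs <- character(0)
  for (i in seq_len(nrow(seqs))) {
    id <- seqs$id[i]
    amp <- amplify(seqs[i, ], fwd, rev, max_mismatch = cfg$max_mismatch)
    if (nrow(amp) == 0) {
      fail(id, "amplify", "no amplicon")
      next
    }
    its <- tryCatch(extract_its(amp[1, ], fwd, rev), error = function(e) NULL)
    if (is.null(its)) {
      fail(id, "extract", "degenerate spacer")
      next
    }
    ann <- annotate_its(its$seq, cfg$model, seq_id = id)
    annotations[[id]] <- ann
    its_seqs[id] <- its$seq
    pipeline_log(verbose, "annotate",
                 sprintf("%s: %d nt, %s", id, ann$its_len, ann$its_type))
  }
  if (length(annotations) == 0) stop("no analysable sequences")
  ann_tab <- annotation_table(annotations)

  # stage 5: alignments and conservation
  region_seqs <- function(region) {
    out <- character(0)
    for (id in names(annotations)) {
      a <- annotations[[id]]
      r <- a$subregions[a$subregions$region == region, ]
      if (nrow(r) == 1 && r$length > 0) {
        out[id] <- substr(its_seqs[id], r$start, r$end)
      }
    }
    out
  }
  conservation <- list()
  msa_whole <- NULL
  if (length(its_seqs) >= 2) {
    msa_whole <- progressive_msa(its_seqs, cfg$params)
    conservation$ITS <- conservation_summary(msa_whole)
    pipeline_log(verbose, "align",
                 sprintf("whole spacer: %d columns, mean identity %.1f%%",
                         nchar(msa_whole$rows[1]), conservation$ITS$mean_pid))
  }
  region_msas <- list()
  for (region in c("ITS-1", "ITS-2", "ITS-3")) {
    rs <- region_seqs(region)
    if (length(rs) >= 2) {
      region_msas[[region]] <- progressive_msa(rs, cfg$params)
      conservation[[region]] <- conservation_summary(region_msas[[region]])
    }
  }

  blocks <- if (!is.null(msa_whole)) {
    find_conserved_blocks(msa_whole, min_len = 4, min_col_identity = 90)
  } else NULL
  indels <- if (!is.null(msa_whole)) {
    do.call(rbind, lapply(msa_whole$ids, function(id) {
      ev <- count_indel_events(msa_whole, id)
      if (nrow(ev) == 0) return(NULL)
      cbind(seq_id = id, ev)
    }))
  } else NULL

  # stage 6: tree
  tree <- NULL
  tree_newick <- NULL
  deletion_mode <- "complete"
  if (!is.null(msa_whole) && length(msa_whole$ids) >= 3) {
    cd <- tryCatch(complete_deletion(msa_whole), error = function(e) NULL)
    if (is.null(cd) || nchar(cd$rows[1]) < 10) {
      deletion_mode <- "pairwise"
      tree <- bootstrap_consensus(msa_whole, n_reps = cfg$n_boot,
                                  seed = cfg$seed, deletion = "pairwise")
    } else {
      tree <- bootstrap_consensus(cd, n_reps = cfg$n_boot, seed = cfg$seed)
    }
    tree_newick <- ape::write.tree(tree)
    pipeline_log(verbose, "tree",
                 sprintf("%d-leaf bootstrap consensus (%d replicates, %s deletion)",
                         length(tree$tip.label), cfg$n_boot, deletion_mode))
  }

  # stage 7: ITS-2 structures
  structures <- list()
  struct_tab <- NULL
  its2s <- region_seqs("ITS-2")
  for (id in names(its2s)) {
    if (nchar(its2s[id]) >= 8) {
      s <- fold_its2(its2s[id])
      structures[[id]] <- s
      cls <- classify_hairpin(s, cfg$long_stem_bp)
      struct_tab <- rbind(struct_tab, data.frame(
        seq_id = id, its2_len = s$length, stem_len = s$stem_len,
        loop_len = s$loop_len, stability = s$stability,
        class = as.character(cls),
        putative_rnase3_target = attr(cls, "putative_rnase3_target"),
        stringsAsFactors = FALSE
      ))
    }
  }

  report <- structure(list(
    annotations = ann_tab,
    conservation = conservation,
    blocks = blocks,
    indel_events = indels,
    tree = tree,
    tree_newick = tree_newick,
    structures = struct_tab,
    type_summary = NULL,
    failures = failures,
    truth = truth,
    msa = msa_whole,
    region_msas = region_msas,
    meta = list(
      seed = cfg$seed, n_boot = cfg$n_boot,
      deletion_mode = deletion_mode,
      n_input = nrow(seqs), n_analysed = length(annotations),
      package_version = as.character(utils::packageVersion("ribospacer")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  ), class = "its_report")
  report$type_summary <- summarize_types(report)
  report
}

#' Frequency table of spacer types and ITS-2 size groups
#'
#' @param report an `"its_report"` (or its annotation table).
#' @return list with data frames `types` (count, percent per arrangement
#'   type, all five canonical types always present) and `its2_groups`, plus
#'   `mode_type`.
#' @export
summarize_types <- function(report) {
  tab <- if (inherits(report, "its_report")) report$annotations else report
  if (is.null(tab) || nrow(tab) == 0) stop("empty report")
  lv <- unique(c(ITS_TYPES, "ITS_other", tab$its_type))
  tt <- table(factor(tab$its_type, levels = lv))
  types <- data.frame(its_type = names(tt), count = as.integer(tt),
                      percent = round(100 * as.integer(tt) / nrow(tab), 1),
                      stringsAsFactors = FALSE)
  gg <- table(tab$its2_group[!is.na(tab$its2_group)])
  groups <- data.frame(its2_group = names(gg), count = as.integer(gg),
                       percent = if (sum(gg) > 0) round(100 * as.integer(gg) / sum(gg), 1) else numeric(0),
                       stringsAsFactors = FALSE)
  list(types = types, its2_groups = groups,
       mode_type = types$its_type[which.max(types$count)])
}

#' @export
print.its_report <- function(x, ...) {
  cat("ITS pipeline report:", x$meta$n_analysed, "of", x$meta$n_input,
      "sequences analysed\n")
  print(x$type_summary$types)
  if (!is.null(x$conservation$`ITS-2`)) {
    cat("ITS-2 ")
    print(x$conservation$`ITS-2`)
  }
  if (!is.null(x$tree)) {
    cat("tree:", length(x$tree$tip.label), "leaves,", x$meta$n_boot,
        "bootstrap replicates\n")
  }
  invisible(x)
}

#' Serialise a report to JSON
#'
#' Writes every table of the report plus run metadata; the tree goes in as
#' its newick string. The output validates against the schema shipped at
#' `inst/extdata/report-schema.json` (see [validate_report_json()]).
#'
#' @param report an `"its_report"`.
#' @param path output path.
#' @param include_timestamp keep the timestamp in the metadata (set FALSE
#'   for byte-reproducible output).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, include_timestamp = TRUE) {
  cons <- lapply(report$conservation, function(cs) {
    list(mean_pid = cs$mean_pid, sd_pid = cs$sd_pid, min_pid = cs$min_pid,
         max_pid = cs$max_pid, n_pairs = cs$n_pairs)
  })
  meta <- report$meta
  if (!include_timestamp) meta$timestamp <- NULL
  out <- list(
    annotations = report$annotations,
    conservation = cons,
    blocks = report$blocks,
    indel_events = report$indel_events,
    tree_newick = report$tree_newick,
    structures = report$structures,
    type_summary = report$type_summary,
    failures = report$failures,
    meta = meta
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a report JSON file against the shipped schema
#'
#' A lightweight structural check: every field required by the schema must
#' be present with the declared JSON type.
#'
#' @param path path to a JSON file written by [write_report_json()].
#' @return TRUE (invisibly) or an error describing the first violation.
#' @export
validate_report_json <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "ribospacer"))
  doc <- jsonlite::read_json(path)
  for (field in names(schema$required)) {
    if (!field %in% names(doc)) stop("report JSON missing field: ", field)
    want <- schema$required[[field]]
    val <- doc[[field]]
    ok <- switch(want,
      array = is.list(val) || is.null(val),
      object = is.list(val),
      string = is.character(val) || is.null(val),
      TRUE)
    if (!ok) stop("report JSON field ", field, " should be ", want)
  }
  invisible(TRUE)
}
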