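# Jukes-Cantor distances, neighbour joining, JC likelihood by pruning,
# branch-length optimisation, and bootstrap majority-rule consensus.
# Trees are ape "phylo" objects throughout; newick round-trips via ape.

#' Remove alignment columns with gaps or ambiguity (complete deletion)
#'
#' Retains exactly the columns where every row is an unambiguous A/C/G/T,
#' preserving column order.
#'
#' @param aln an `"msa"` with >= 2 rows.
#' @return an `"msa"` containing the surviving columns.
#' @export
complete_deletion <- function(aln) {
  stopifnot(length(aln$rows) >= 2)
  m <- msa_matrix(aln)
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep)) stop("complete deletion removed every column")
  new_msa(aln$ids, apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
          aln$params)
}

#' Jukes-Cantor distance between two aligned rows
#'
#' `d = -(3/4) ln(1 - 4p/3)` with `p` the mismatch fraction. When
#' `p >= 3/4` the distance is saturated: it is set to `cap` and flagged via
#' the `"saturated"` attribute.
#'
#' @param row_a,row_b equal-length strings (complete-deleted: A/C/G/T only).
#' @param cap distance assigned to saturated pairs (default 5.0).
#' @return numeric distance (substitutions/site) with attribute
#'   `saturated`.
#' @export
jc69_distance <- function(row_a, row_b, cap = 5.0) {
  L <- nchar(row_a)
  stopifnot(L >= 1, nchar(row_b) == L)
  a <- strsplit(row_a, "", fixed = TRUE)[[1]]
  b <- strsplit(row_b, "", fixed = TRUE)[[1]]
  p <- mean(a != b)
  if (p >= 0.75) {
    return(structure(cap, saturated = TRUE))
  }
  structure(-0.75 * log(1 - 4 * p / 3), saturated = FALSE)
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' @param aln an `"msa"` (complete-deleted for the strict JC interpretation;
#'   with `deletion = "pairwise"` each pair uses its own gap-free columns).
#' @param cap saturation cap.
#' @param deletion `"none"` (use columns as they are) or `"pairwise"`.
#' @return symmetric matrix with zero diagonal; attribute `saturated` is a
#'   logical matrix flagging capped entries. Errors if any full row is
#'   saturated against all others.
#' @export
jc_dist_matrix <- function(aln, cap = 5.0, deletion = c("none", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- msa_matrix(aln)
  n <- nrow(m)
  good <- matrix(m %in% c("A", "C", "G", "T"), n)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  sat <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- if (deletion == "pairwise") good[i, ] & good[j, ] else rep(TRUE, ncol(m))
      L <- sum(use)
      if (L == 0) stop("no usable columns for pair ", aln$ids[i], "/", aln$ids[j])
      p <- sum(m[i, use] != m[j, use]) / L
      if (p >= 0.75) {
        D[i, j] <- D[j, i] <- cap
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  if (n > 2 && any(apply(sat | diag(TRUE, n), 1, all))) {
    stop("a sequence is saturated against every other; cannot build a tree")
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbour joining
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`). Negative branch
#' lengths are clamped to zero, the deficit being moved to the sibling edge
#' (floored at zero) so total path lengths are approximately preserved.
#'
#' @param D symmetric distance matrix with >= 3 labelled rows.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (nrow(D) < 3) stop("neighbour joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent)
    sib <- setdiff(sib, e)
    if (length(sib) > 0) {
      s <- sib[1]
      tr$edge.length[s] <- max(0, tr$edge.length[s] + deficit)
    }
  }
  tr
}

# alignment rows -> integer matrix (1..4, NA for gap/ambiguity)
aln_int_matrix <- function(aln) {
  m <- msa_matrix(aln)
  im <- matrix(match(m, c("A", "C", "G", "T")), nrow(m),
               dimnames = list(aln$ids, NULL))
  im
}

#' Log-likelihood of a tree under the Jukes-Cantor model
#'
#' Felsenstein pruning with equal base frequencies (1/4):
#' `P(same) = 1/4 + 3/4 exp(-4t/3)`, `P(diff) = 1/4 - 1/4 exp(-4t/3)`,
#' summed over alignment columns. Gaps and ambiguity codes are treated as
#' missing data (all four bases equally compatible). Polytomies are allowed.
#'
#' @param tree an `ape::phylo` whose tip labels equal the alignment ids.
#' @param aln an `"msa"`.
#' @return total log-likelihood.
#' @export
jc_log_likelihood <- function(tree, aln) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  sum(jc_site_loglik(tree, aln))
}

jc_pmat <- function(t) {
  e <- exp(-4 * t / 3)
  m <- matrix(0.25 - 0.25 * e, 4, 4)
  diag(m) <- 0.25 + 0.75 * e
  m
}

# site-pattern-compressed pruning data: postorder tree, tip partials over
# unique column patterns, and pattern weights
jc_pruning_data <- function(tree, aln) {
  if (anyNA(match(tree$tip.label, aln$ids))) {
    stop("tree tips and alignment ids differ")
  }
  tree <- stats::reorder(tree, "postorder")
  im <- aln_int_matrix(aln)
  im <- im[match(tree$tip.label, rownames(im)), , drop = FALSE]
  pat <- apply(im, 2, paste, collapse = ",")
  w <- as.vector(table(pat)[unique(pat)])
  im <- im[, match(unique(pat), pat), drop = FALSE]
  S <- ncol(im)
  ntip <- length(tree$tip.label)
  tipD <- lapply(seq_len(ntip), function(i) {
    p <- matrix(0, 4, S)
    b <- im[i, ]
    known <- !is.na(b)
    p[, !known] <- 1
    p[cbind(b[known], which(known))] <- 1
    p
  })
  list(tree = tree, tipD = tipD, w = w, S = S, ntip = ntip,
       nnode = ntip + tree$Nnode, root = ntip + 1)
}

# down-pass: per-node partials and per-edge child messages M_e = P_e D[child]
jc_down_pass <- function(pd, elens) {
  D <- vector("list", pd$nnode)
  D[seq_len(pd$ntip)] <- pd$tipD
  M <- vector("list", nrow(pd$tree$edge))
  for (n in (pd$ntip + 1):pd$nnode) D[[n]] <- matrix(1, 4, pd$S)
  for (e in seq_len(nrow(pd$tree$edge))) {
    pa <- pd$tree$edge[e, 1]; ch <- pd$tree$edge[e, 2]
    M[[e]] <- jc_pmat(elens[e]) %*% D[[ch]]
    D[[pa]] <- D[[pa]] * M[[e]]
  }
  list(D = D, M = M)
}

# up-pass: U[v] = partial likelihood of everything outside the subtree of v,
# transported to v (U[root] = 1/4). Leave-one-out sibling products are built
# by prefix/suffix so that zero entries (t = 0 branches) stay exact.
jc_up_pass <- function(pd, elens, down) {
  U <- vector("list", pd$nnode)
  H <- vector("list", nrow(pd$tree$edge))  # parent-side message per edge
  U[[pd$root]] <- matrix(0.25, 4, pd$S)
  edges <- pd$tree$edge
  pre <- rev(seq_len(nrow(edges)))
  parents <- unique(edges[pre, 1])
  children_of <- split(seq_len(nrow(edges)), edges[, 1])
  for (pa in parents) {
    eidx <- children_of[[as.character(pa)]]
    k <- length(eidx)
    ones <- matrix(1, 4, pd$S)
    prefix <- vector("list", k); suffix <- vector("list", k)
    acc <- ones
    for (i in seq_len(k)) { prefix[[i]] <- acc; acc <- acc * down$M[[eidx[i]]] }
    acc <- ones
    for (i in rev(seq_len(k))) { suffix[[i]] <- acc; acc <- acc * down$M[[eidx[i]]] }
    for (i in seq_len(k)) {
      e <- eidx[i]; ch <- edges[e, 2]
      H[[e]] <- U[[pa]] * prefix[[i]] * suffix[[i]]
      U[[ch]] <- crossprod(jc_pmat(elens[e]), H[[e]])
    }
  }
  list(U = U, H = H)
}

jc_site_loglik_pd <- function(pd, elens) {
  down <- jc_down_pass(pd, elens)
  log(colSums(0.25 * down$D[[pd$root]]))
}

jc_site_loglik <- function(tree, aln) {
  pd <- jc_pruning_data(tree, aln)
  ll <- jc_site_loglik_pd(pd, pd$tree$edge.length)
  rep(ll, pd$w)  # expand back (order differs from input columns)
}

#' Maximum-likelihood branch lengths by coordinate ascent
#'
#' Optimises each branch in turn with bounded scalar optimisation under the
#' JC likelihood, sweeping until the log-likelihood improves by less than
#' `tol` (at most `max_sweeps` sweeps). The log-likelihood is
#' non-decreasing across sweeps.
#'
#' @param tree an `ape::phylo`.
#' @param aln an `"msa"` with rows matching the tip labels.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_sweeps maximum number of sweeps over all branches.
#' @param max_branch upper bound per branch (substitutions/site).
#' @return the tree with optimised `edge.length` and attribute `logLik`.
#' @export
optimize_branch_lengths <- function(tree, aln, tol = 1e-6, max_sweeps = 20,
                                    max_branch = 10) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  pd <- jc_pruning_data(tree, aln)
  elens <- pd$tree$edge.length
  ll <- sum(pd$w * jc_site_loglik_pd(pd, elens))
  for (sweep in seq_len(max_sweeps)) {
    # refresh the conditional messages once per sweep block: the likelihood
    # of one branch given the rest factorises as w' log(H^T P(t) D[child])
    for (e in seq_len(nrow(pd$tree$edge))) {
      down <- jc_down_pass(pd, elens)
      up <- jc_up_pass(pd, elens, down)
      Dch <- down$D[[pd$tree$edge[e, 2]]]
      H <- up$H[[e]]
      f <- function(t) {
        sum(pd$w * log(colSums((jc_pmat(t) %*% Dch) * H)))
      }
      cur <- f(elens[e])
      opt <- stats::optimize(f, c(0, max_branch), maximum = TRUE, tol = 1e-7)
      if (opt$objective > cur) elens[e] <- opt$maximum
    }
    new_ll <- sum(pd$w * jc_site_loglik_pd(pd, elens))
    if (new_ll - ll < tol) {
      ll <- new_ll
      break
    }
    ll <- new_ll
  }
  # map optimised lengths back onto the caller's edge ordering
  key <- function(m) paste(m[, 1], m[, 2])
  tree$edge.length <- elens[match(key(tree$edge), key(pd$tree$edge))]
  attr(tree, "logLik") <- ll
  tree
}

#' Bootstrap majority-rule consensus tree
#'
#' Resamples alignment columns with replacement (seeded), builds a JC
#' distance / neighbour-joining tree per replicate, and returns the
#' majority-rule (> 50%) consensus with bipartition supports (percent of
#' replicates) as internal node labels. Maximum-likelihood branch lengths
#' for the consensus are fitted once against the input alignment.
#'
#' @param aln an `"msa"`; for the strict JC interpretation apply
#'   [complete_deletion()] first, or set `deletion = "pairwise"`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed governing all resampling.
#' @param deletion passed to [jc_dist_matrix()].
#' @param optimize_lengths fit ML branch lengths on the consensus
#'   (default TRUE).
#' @param cap saturation cap for distances.
#' @return an `ape::phylo` consensus tree; `node.label` holds supports.
#' @export
bootstrap_consensus <- function(aln, n_reps = 1000, seed = 1,
                                deletion = c("none", "pairwise"),
                                optimize_lengths = TRUE, cap = 5.0) {
  stopifnot(n_reps >= 1)
  deletion <- match.arg(deletion)
  m <- msa_matrix(aln)
  L <- ncol(m)
  trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- new_msa(aln$ids,
                         apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                         aln$params)
      D <- jc_dist_matrix(rep_aln, cap = cap, deletion = deletion)
      neighbor_joining(D)
    })
  })
  class(trees) <- "multiPhylo"
  if (n_reps == 1) {
    cons <- trees[[1]]
    cons$node.label <- rep(100, cons$Nnode)
  } else {
    cons <- ape::consensus(trees, p = 0.5, check.labels = TRUE)
    counts <- ape::prop.clades(cons, trees, rooted = FALSE)
    counts[is.na(counts)] <- 0
    cons$node.label <- round(100 * counts / n_reps, 1)
  }
  if (optimize_lengths) {
    if (is.null(cons$edge.length)) cons$edge.length <- rep(0.05, nrow(cons$edge))
    cons <- optimize_branch_lengths(cons, aln)
  }
  cons
}

#' Write a distance matrix as a PHYLIP-style square TSV
#' @param D labelled matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(D, path) {
  utils::write.table(cbind(id = rownames(D), as.data.frame(D)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
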