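# Independent oracles used by the property suites. These deliberately share
# no code with the package implementations they check.

# exhaustive global-alignment score by naive prefix recursion over all edit
# paths (affine gaps: first gap char costs `open`, each further one `ext`)
nw_oracle_score <- function(a, b, match = 1, mismatch = -1, open = -5, ext = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  rec <- function(i, j, last) {
    if (i == la && j == lb) return(0)
    best <- -Inf
    if (i < la && j < lb) {
      s <- if (av[i + 1] == bv[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0L))
    }
    if (i < la) {
      g <- if (last == 1L) ext else open
      best <- max(best, g + rec(i + 1, j, 1L))
    }
    if (j < lb) {
      g <- if (last == 2L) ext else open
      best <- max(best, g + rec(i, j + 1, 2L))
    }
    best
  }
  rec(0L, 0L, 0L)
}

# enumerate every nested structure (set of pairs, min_loop enforced) of a
# sequence; returns the optimum of the stability score (negative)
nussinov_oracle <- function(seq, wGC = 3, wAT = 2, wGT = 1, stack = 1,
                            min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pairable <- function(x, y) {
    p <- paste0(ch[x], ch[y])
    p %in% c("GC", "CG", "AT", "TA", "GT", "TG")
  }
  weight <- function(x, y) {
    p <- paste0(ch[x], ch[y])
    if (p %in% c("GC", "CG")) wGC else if (p %in% c("AT", "TA")) wAT else wGT
  }
  # all structures of [i, j] as lists of 2-col matrices
  structs <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(list(NULL))
    out <- structs(i + 1, j)                 # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (!pairable(i, k)) next
      left <- structs(i + 1, k - 1)
      right <- if (k + 1 <= j) structs(k + 1, j) else list(NULL)
      for (s1 in left) for (s2 in right) {
        out[[length(out) + 1]] <- rbind(c(i, k), s1, s2)
      }
    }
    out
  }
  score <- function(m) {
    if (is.null(m)) return(0)
    sc <- sum(apply(m, 1, function(p) weight(p[1], p[2])))
    key <- paste(m[, 1], m[, 2])
    st <- sum(paste(m[, 1] + 1, m[, 2] - 1) %in% key)
    -(sc + st)
  }
  min(vapply(structs(1, n), score, numeric(1)))
}

# random nucleotide string
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

# build an operon-shaped template around a given spacer using the packaged
# primer pair sites (for PCR tests independent of the generator internals)
wrap_spacer <- function(its) {
  paste0(ribospacer:::SCAFFOLD_16S, its, ribospacer:::SCAFFOLD_23S)
}

# spacer excision shorthand used across tests
excise <- function(operon_row) {
  amp <- amplify(operon_row, "16S-1511f", "23S-23r")
  extract_its(amp[1, ], "16S-1511f", "23S-23r")
}
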