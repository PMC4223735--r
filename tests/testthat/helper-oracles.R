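# Independent oracles used to cross-check the implementation. These stay
# deliberately separate from the package code paths: plain dynamic
# programming for alignment scores, string-based deletion enumeration for
# TDRL products, and the two-cell goodness-of-fit formula written out.

# affine-gap global alignment score by three-state dynamic programming;
# a gap of length L costs gap_open + L * gap_ext, as in the package
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 4, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in a
  M[1, 1] <- 0
  for (i in 1:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (i > 1) {
        X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                       X[i - 1, j] - gap_ext,
                       Y[i - 1, j] - gap_open - gap_ext)
      }
      if (j > 1) {
        Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                       Y[i, j - 1] - gap_ext,
                       X[i, j - 1] - gap_open - gap_ext)
      }
      if (i > 1 && j > 1) {
        s <- if (av[i - 1] == bv[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                       Y[i - 1, j - 1]) + s
      }
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# smallest rotation of a comma-joined circular label sequence
oracle_circ_key <- function(x) {
  n <- length(x)
  min(vapply(seq_len(n), function(k) {
    paste(x[c(k:n, seq_len(k - 1))], collapse = ",")
  }, character(1)))
}

# every order reachable by one TDRL of block [start, start+len-1]:
# double the block, then delete disjoint subsets from the two copies
# (deleting a gene from copy 2 keeps its first copy, and vice versa)
oracle_tdrl_products <- function(x, start, len) {
  n <- length(x)
  idx <- ((start - 1 + 0:(len - 1)) %% n) + 1
  rest <- if (len == n) character(0) else
    x[((start - 1 + len:(n - 1)) %% n) + 1]
  block <- x[idx]
  keys <- character(0)
  subsets <- function(k) {
    if (k == 0) return(list(integer(0)))
    unlist(lapply(0:(2^k - 1), function(mask) {
      list(which(bitwAnd(mask, 2^(0:(k - 1))) > 0))
    }), recursive = FALSE)
  }
  for (d1 in subsets(len)) {
    for (d2 in subsets(len)) {
      if (length(intersect(d1, d2)) > 0) next
      c1 <- if (length(d1)) block[-d1] else block
      c2 <- if (length(d2)) block[-d2] else block
      keys <- c(keys, oracle_circ_key(c(c1, c2, rest)))
    }
  }
  unique(keys)
}

oracle_chi2 <- function(obs, panel) {
  p <- panel[1] / (panel[1] + panel[2])
  e <- c(p, 1 - p) * (obs[1] + obs[2])
  (obs[1] - e[1])^2 / e[1] + (obs[2] - e[2])^2 / e[2]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all distinct circular orders (rotations identified) over n labels
all_circular_orders <- function(labels) {
  n <- length(labels)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  ps <- lapply(perms(labels[-1]), function(p) c(labels[1], p))
  ps
}
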