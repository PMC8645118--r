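# Independent oracles used to validate the package's own implementations.
# Each is written directly from the textbook definition of the algorithm it
# checks and shares no code with the implementation under test.

# Smith-Waterman with affine gaps (gap of length L costs open + L * extend),
# plain O(n*m) dynamic programming over three state matrices.
oracle_sw_score <- function(a, b, mat, open = 11, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)     # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], X[i, j], Y[i, j]) +
                               mat[A[i], B[j]])
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Exhaustive best colinear chain: enumerate all subsets of hit rows, keep
# those forming a valid chain (same contig/strand, advancing in query and
# genome, genomic gaps within max_intron_bp), return the best total score.
oracle_best_chain <- function(hits, max_intron_bp = 20000L, overlap = 10L) {
  n <- nrow(hits)
  best <- 0
  best_set <- integer()
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- hits[idx, , drop = FALSE]
    sub <- sub[order(sub$qstart), , drop = FALSE]
    okc <- length(unique(sub$contig_id)) == 1 &&
      length(unique(sub$strand)) == 1
    if (okc && nrow(sub) > 1) {
      for (i in seq_len(nrow(sub) - 1)) {
        a <- sub[i, ]; b <- sub[i + 1, ]
        gap <- if (a$strand == "+") b$gstart - a$gend else a$gstart - b$gend
        if (b$qstart < a$qstart + 1 || a$qend - overlap > b$qstart ||
            b$qend <= a$qend || gap < -15 || gap > max_intron_bp) {
          okc <- FALSE
          break
        }
      }
    }
    if (okc && sum(sub$score) > best) {
      best <- sum(sub$score)
      best_set <- sort(idx)
    }
  }
  list(score = best, idx = best_set)
}

# Dense-matrix MCL reference following van Dongen's published iteration:
# add self loops, column-normalize, square, inflate, renormalize, repeat;
# read clusters off the converged matrix's support.
oracle_mcl <- function(A, inflation = 2, iters = 200) {
  diag(A) <- apply(A, 2, max)
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M[M < 1e-8] <- 0
    M <- sweep(M, 2, colSums(M), "/")
  }
  supp <- (M > 1e-4) | t(M > 1e-4)
  n <- nrow(A)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (supp[i, j] && lab[j] != lab[i]) {
          l <- min(lab[i], lab[j])
          lab[i] <- l; lab[j] <- l
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  split(rownames(A), lab)
}

# NG86 pair counts by direct pathway enumeration (all orderings of the
# differing positions; pathways through stops dropped, falling back to all).
oracle_ng86_pair <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(d)) return(c(sd = 0, nd = 0))
  perms <- if (length(d) == 1) matrix(d, 1) else
    do.call(rbind, combinat_perms(d))
  rows <- apply(perms, 1, function(ord) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[[nxt]] == "*") blocked <- TRUE
      if (code[[nxt]] == code[[cur]] && code[[cur]] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  })
  rows <- t(rows)
  ok <- rows[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(rows))
  c(sd = mean(rows[ok, 1]), nd = mean(rows[ok, 2]))
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# exhaustive transitive closure over a pairwise relation (event oracle)
oracle_transitive_partition <- function(ids, related) {
  lab <- setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (related[i, j] && lab[j] != lab[i]) {
          l <- min(lab[i], lab[j])
          lab[i] <- l; lab[j] <- l
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  unname(split(ids, lab))
}

blosum62_test <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}
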