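# Progressive multiple alignment, neighbor-joining trees with bootstrap
# support, and newick I/O. Trees use ape's `phylo` container throughout.
#
# Branch-length comparisons between parental and duplicate clades (parents
# short, duplicates long) are the downstream use; NJ on Poisson-corrected
# protein distances is the in-package tree method.

aln_to_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), ""))
}

#' Pairwise distances from a protein alignment
#'
#' p-distance or Poisson-corrected distance (`-log(1 - p)`), with pairwise
#' deletion of gap columns.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param method `"poisson"` (default) or `"p"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
msa_distances <- function(msa, method = c("poisson", "p")) {
  method <- match.arg(method)
  m <- aln_to_matrix(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
      if (method == "poisson") {
        if (p >= 1) {
          stopf("Poisson correction undefined for p = %.3f (%s vs %s); use the p-distance (method = \"p\")",
                p, names(msa)[i], names(msa)[j])
        }
        p <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  D
}

#' Neighbor joining on a distance matrix
#'
#' Standard NJ; negative branch lengths are clamped to zero with the deficit
#' moved to the sister edge. Returns an unrooted `phylo` tree (trifurcating
#' root).
#'
#' @param D symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An [ape::as.phylo] object.
#' @export
nj_from_dist <- function(D) {
  labels <- rownames(D)
  n <- length(labels)
  stopifnot(n >= 3, identical(rownames(D), colnames(D)))
  active <- seq_len(n)           # current node ids
  node_id <- seq_len(n)          # tips 1..n; internals get n+1, n+2, ...
  next_internal <- 0L            # temporary internal ids are negative
  Dcur <- D
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  ids <- active
  while (length(ids) > 3) {
    m <- length(ids)
    r <- rowSums(Dcur)
    Q <- (m - 2) * Dcur - outer(r, r, "+")
    diag(Q) <- Inf
    k <- arrayInd(which.min(Q), dim(Q))   # deterministic: first minimum
    i <- k[1]; j <- k[2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    bi <- Dcur[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- Dcur[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    next_internal <- next_internal - 1L
    edges <- rbind(edges, c(next_internal, ids[i]), c(next_internal, ids[j]))
    lens <- c(lens, bi, bj)
    dnew <- (Dcur[i, ] + Dcur[j, ] - Dcur[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dcur <- rbind(cbind(Dcur[keep, keep, drop = FALSE], dnew[keep]),
                  c(dnew[keep], 0))
    ids <- c(ids[keep], next_internal)
    rownames(Dcur) <- colnames(Dcur) <- as.character(ids)
  }
  # final trifurcation (three-point formula)
  next_internal <- next_internal - 1L
  d12 <- Dcur[1, 2]; d13 <- Dcur[1, 3]; d23 <- Dcur[2, 3]
  b <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  for (i in 1:3) {
    if (b[i] < 0) {
      others <- setdiff(1:3, i)
      b[others] <- b[others] + b[i] / 2
      b[i] <- 0
    }
  }
  edges <- rbind(edges, c(next_internal, ids[1]), c(next_internal, ids[2]),
                 c(next_internal, ids[3]))
  lens <- c(lens, b)
  # renumber: root -> n+1, other internals in creation order n+2 ...
  internals <- sort(unique(edges[edges < 0]))   # most recent first
  map <- integer(0)
  map[as.character(next_internal)] <- n + 1L
  rest <- setdiff(internals, next_internal)
  rest <- rest[order(-rest)]   # creation order: -1, -2, ...
  for (k in seq_along(rest)) map[as.character(rest[k])] <- n + 1L + k
  renum <- function(x) ifelse(x < 0, map[as.character(x)], x)
  edge <- cbind(renum(edges[, 1]), renum(edges[, 2]))
  storage.mode(edge) <- "integer"
  tree <- structure(list(edge = edge, edge.length = lens,
                         tip.label = labels,
                         Nnode = length(internals)),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Neighbor-joining tree from a protein alignment
#'
#' @inheritParams msa_distances
#' @param distance `"poisson"` (default) or `"p"`.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(msa, distance = c("poisson", "p")) {
  distance <- match.arg(distance)
  if (length(msa) < 3) stopf("nj_tree needs at least 3 sequences")
  nj_from_dist(msa_distances(msa, distance))
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates containing that bipartition. Supports are stored
#' in `node.label`.
#'
#' @inheritParams nj_tree
#' @param n_replicates bootstrap replicates (default 100).
#' @param seed RNG seed (reproducible; caller's RNG state is untouched).
#' @return The original tree with `node.label` percentages (root label empty)
#'   and an attribute `"replicates"`.
#' @export
nj_bootstrap <- function(msa, n_replicates = 100L, seed = 1L,
                         distance = c("poisson", "p")) {
  distance <- match.arg(distance)
  tree <- nj_tree(msa, distance)
  m <- aln_to_matrix(msa)
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_msa <- setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                          names(msa))
      tryCatch(nj_tree(rep_msa, distance), error = function(e) NULL)
    })
  })
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / length(reps))
  labs <- as.character(support)
  labs[1] <- ""   # root of the unrooted representation carries no support
  tree$node.label <- labs
  attr(tree, "replicates") <- length(reps)
  tree
}

#' Write / read a newick tree
#'
#' Bootstrap supports travel as internal-node labels. `read_newick` performs
#' a light syntax check (balanced parentheses, terminating semicolon) and
#' reports the offending character position before delegating to
#' [ape::read.tree].
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `write_newick` the path (invisibly); `read_newick` a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (k in seq_len(nchar(txt))) {
    ch <- substr(txt, k, k)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0) stopf("newick parse error: unmatched ')' at position %d", k)
    }
  }
  if (depth != 0) {
    stopf("newick parse error: %d unclosed '(' at end of input", depth)
  }
  if (!grepl(";\\s*$", txt)) stopf("newick parse error: missing terminal ';'")
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stopf("newick parse error in %s", path)
  tree
}

# ---- progressive multiple alignment -------------------------------------

kmer_distance_matrix <- function(seqs, k = 3L) {
  ids <- names(seqs)
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- min(length(sets[[i]]), length(sets[[j]]))
      d <- if (denom == 0) 1 else 1 - length(intersect(sets[[i]], sets[[j]])) / denom
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

profile_from_rows <- function(rows, alphabet) {
  L <- nchar(rows[[1]])
  m <- do.call(rbind, strsplit(unlist(rows), ""))
  P <- matrix(0, length(alphabet), L, dimnames = list(alphabet, NULL))
  for (a in alphabet) P[a, ] <- colMeans(m == a)
  P
}

merge_profiles <- function(p1, p2, S, gap_open, gap_extend) {
  C <- t(p1$P) %*% S %*% p2$P
  res <- cpp_affine_profile_align(C, gap_open, gap_extend)
  moves <- res$moves
  i <- 0L; j <- 0L
  idx1 <- integer(length(moves)); idx2 <- integer(length(moves))
  for (k in seq_along(moves)) {
    if (moves[k] != 2L) i <- i + 1L
    if (moves[k] != 1L) j <- j + 1L
    idx1[k] <- if (moves[k] != 2L) i else 0L
    idx2[k] <- if (moves[k] != 1L) j else 0L
  }
  expand <- function(rows, idx) {
    lapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      paste(ifelse(idx == 0L, "-", ch[pmax(idx, 1L)]), collapse = "")
    })
  }
  rows <- c(expand(p1$rows, idx1), expand(p2$rows, idx2))
  alphabet <- rownames(p1$P)
  list(rows = rows, P = profile_from_rows(rows, alphabet))
}

#' Progressive multiple alignment of proteins
#'
#' Guide tree from k-mer distances (NJ), then profile-profile alignment with
#' affine gaps under the chosen substitution matrix. Deterministic.
#'
#' @param seqs named character vector of amino-acid sequences (>= 2).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties.
#' @param k guide-tree k-mer size.
#' @return Named character vector of aligned rows (class `dup_msa`), input
#'   order preserved; ungapping any row returns its input sequence.
#' @export
progressive_align <- function(seqs, matrix = "BLOSUM62", gap_open = 10,
                              gap_extend = 0.1, k = 3L) {
  if (length(seqs) < 2) stopf("progressive_align needs at least 2 sequences")
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  S <- subst_matrix(matrix)
  alphabet <- rownames(S)
  mk_profile <- function(id) {
    list(rows = setNames(list(unname(seqs[[id]])), id),
         P = profile_from_rows(setNames(list(unname(seqs[[id]])), id), alphabet))
  }
  if (length(seqs) == 2) {
    p <- merge_profiles(mk_profile(names(seqs)[1]), mk_profile(names(seqs)[2]),
                        S, gap_open, gap_extend)
  } else {
    guide <- nj_from_dist(kmer_distance_matrix(seqs, k))
    # postorder merge over the guide tree
    align_node <- function(node) {
      kids <- guide$edge[guide$edge[, 1] == node, 2]
      if (!length(kids)) return(mk_profile(guide$tip.label[node]))
      profs <- lapply(kids, align_node)
      acc <- profs[[1]]
      for (q in profs[-1]) acc <- merge_profiles(acc, q, S, gap_open, gap_extend)
      acc
    }
    p <- align_node(length(guide$tip.label) + 1L)
  }
  out <- unlist(p$rows)
  out <- out[names(seqs)]
  class(out) <- "dup_msa"
  out
}
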