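# Protein similarity graph and Markov clustering (MCL) into gene families.
# Families with more than one member flag duplicated genes.

#' Build a protein similarity graph
#'
#' An undirected edge joins two proteins when their optimal local alignment
#' identity reaches `min_identity`; the edge weight is that identity.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param min_identity identity threshold (default 0.50, the conventional
#'   within-genus protein-family cutoff).
#' @return A `similarity_graph`: list with `nodes`, `edges` (data.frame
#'   `from`, `to`, `weight`) and `min_identity`.
#' @export
build_graph <- function(proteins, min_identity = 0.50) {
  stopifnot(length(proteins) >= 1, !is.null(names(proteins)))
  ids <- names(proteins)
  from <- character(); to <- character(); w <- double()
  n <- length(ids)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- align_local(proteins[[i]], proteins[[j]])
        # local identity over a trivially short block is not family evidence;
        # require the aligned block to cover at least half the shorter protein
        cover <- (a$query_span[2] - a$query_span[1]) /
          min(nchar(proteins[[i]]), nchar(proteins[[j]]))
        if (a$identity >= min_identity && cover >= 0.5) {
          from <- c(from, ids[i]); to <- c(to, ids[j]); w <- c(w, a$identity)
        }
      }
    }
  }
  structure(list(nodes = ids,
                 edges = data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE),
                 min_identity = min_identity),
            class = "similarity_graph")
}

#' Markov clustering of a similarity graph
#'
#' Dense-matrix MCL: the column-stochastic transition matrix (self-loops set
#' to each node's maximum incident weight) is alternately expanded (squared)
#' and inflated (elementwise power, column renormalization, pruning below
#' `prune`) until the maximum column change drops below `tol`. Clusters are
#' the connected components of the limit matrix's support.
#'
#' @param graph a `similarity_graph` from [build_graph()], or a square
#'   numeric adjacency matrix with dimnames.
#' @param inflation inflation exponent (> 1; default 2.0).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the transition matrix.
#' @param prune entries below this are zeroed after inflation.
#' @return A `family_clustering`: list with `clusters` (named list
#'   cluster_id -> member ids), `membership` (named vector), `inflation`,
#'   `iterations`, `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 2.0, max_iter = 100L,
                        tol = 1e-6, prune = 1e-8) {
  stopifnot(inflation > 1)
  if (inherits(graph, "similarity_graph")) {
    ids <- graph$nodes
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(graph$edges)) {
      for (r in seq_len(nrow(graph$edges))) {
        A[graph$edges$from[r], graph$edges$to[r]] <- graph$edges$weight[r]
        A[graph$edges$to[r], graph$edges$from[r]] <- graph$edges$weight[r]
      }
    }
  } else {
    A <- as.matrix(graph)
    ids <- rownames(A)
  }
  if (!length(ids)) stopf("mcl_cluster: empty graph")
  n <- length(ids)
  diag(A) <- 0
  selfw <- apply(A, 2, max)
  selfw[selfw == 0] <- 1
  diag(A) <- selfw
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M          # expansion
    M2 <- M2^inflation     # inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warnf("MCL did not converge in %d iterations; interpreting current matrix",
          max_iter)
  }
  support <- (M > sqrt(prune)) | t(M > sqrt(prune))
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # deterministic cluster ids: order by smallest member id
  groups <- split(ids, comp[ids])
  groups <- groups[order(vapply(groups, min, ""))]
  names(groups) <- sprintf("fam%03d", seq_along(groups))
  membership <- setNames(rep(names(groups), lengths(groups)),
                         unlist(groups, use.names = FALSE))[ids]
  structure(list(clusters = groups, membership = membership,
                 inflation = inflation, iterations = it,
                 converged = converged),
            class = "family_clustering")
}

#' Cluster proteins into gene families
#'
#' Convenience wrapper: [build_graph()] then [mcl_cluster()].
#'
#' @inheritParams build_graph
#' @inheritParams mcl_cluster
#' @return A `family_clustering` (see [mcl_cluster()]).
#' @export
gene_families <- function(proteins, min_identity = 0.50, inflation = 2.0) {
  mcl_cluster(build_graph(proteins, min_identity), inflation = inflation)
}

#' @export
print.family_clustering <- function(x, ...) {
  cat(sprintf("family_clustering: %d cluster(s) over %d protein(s), inflation %.2f (%d iterations)\n",
              length(x$clusters), length(x$membership), x$inflation,
              x$iterations))
  invisible(x)
}
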