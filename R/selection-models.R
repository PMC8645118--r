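# Codon-model machinery for mode-of-evolution analysis: Nei-Gojobori (1986)
# counting with Jukes-Cantor correction, Goldman-Yang style codon models
# (one-ratio, omega-fixed-to-1, two-ratio branch models) fitted by maximum
# likelihood, likelihood-ratio tests, and a codon simulator sharing the same
# rate matrix.
#
# omega (dN/dS) < 1 indicates purifying selection, > 1 positive selection.
# Reported omega is capped at 999 when dS carries no information, matching
# the convention used in published tables.

OMEGA_CAP <- 999

#' Back-translate a protein alignment to a codon alignment
#'
#' @param protein_msa named character vector of aligned amino-acid rows.
#' @param cds named character vector of coding nucleotide sequences (terminal
#'   stop codons are stripped); each must translate to its ungapped row.
#' @return Named character vector of aligned CDS (class `codon_alignment`);
#'   an amino-acid gap becomes `---`.
#' @export
back_translate <- function(protein_msa, cds) {
  ids <- names(protein_msa)
  if (!all(ids %in% names(cds))) {
    stopf("missing CDS for: %s", paste(setdiff(ids, names(cds)), collapse = ", "))
  }
  out <- vapply(ids, function(id) {
    row <- protein_msa[[id]]
    aa <- strsplit(row, "")[[1]]
    seq <- toupper(cds[[id]])
    cod <- as_codons(seq)
    if (length(cod) && translate_codon(cod[length(cod)]) == "*") {
      cod <- cod[-length(cod)]
    }
    trans <- translate_codon(cod)
    unaligned <- aa[aa != "-"]
    if (length(trans) != length(unaligned)) {
      stopf("back_translate: %s CDS encodes %d aa but row has %d",
            id, length(trans), length(unaligned))
    }
    mism <- which(trans != unaligned & unaligned != "X" & trans != "X")
    if (length(mism)) {
      stopf("back_translate: %s translation mismatch at residue %d (%s vs %s)",
            id, mism[1], trans[mism[1]], unaligned[mism[1]])
    }
    res <- character(length(aa))
    j <- 0L
    for (k in seq_along(aa)) {
      if (aa[k] == "-") {
        res[k] <- "---"
      } else {
        j <- j + 1L
        res[k] <- cod[j]
      }
    }
    paste(res, collapse = "")
  }, "")
  names(out) <- ids
  class(out) <- "codon_alignment"
  out
}

# --- NG86 ------------------------------------------------------------------

# synonymous fraction of the 3 possible changes at each position of a codon
# (changes creating stop codons count as nonsynonymous)
ng86_site_counts <- function(codon) {
  tab <- codon_table()
  aa <- tab[[codon]]
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (tab[[mut]] != "*" && tab[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged (Sd, Nd) between two codons; pathways through stop codons
# are excluded (all-blocked pairs fall back to unweighted averaging)
ng86_pair_counts <- function(c1, c2) {
  tab <- codon_table()
  diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diff)) return(c(sd = 0, nd = 0))
  perms <- if (length(diff) == 1) list(diff)
  else if (length(diff) == 2) list(diff, rev(diff))
  else {
    idx <- list()
    for (a in 1:3) for (b in setdiff(1:3, a)) {
      idx[[length(idx) + 1L]] <- diff[c(a, b, setdiff(1:3, c(a, b)))]
    }
    idx
  }
  res <- list()
  for (path in perms) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (tab[[nxt]] == "*") { blocked <- TRUE }
      if (tab[[nxt]] == tab[[cur]] && tab[[cur]] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1L]] <- c(sd = sd, nd = nd, blocked = blocked)
  }
  m <- do.call(rbind, res)
  ok <- m[, "blocked"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
}

#' Nei-Gojobori (1986) dN/dS for an aligned codon pair
#'
#' Per-codon synonymous site counts, pathway-averaged substitution counts for
#' multi-hit codons (stop-codon pathways excluded), and Jukes-Cantor
#' correction. Codon sites with a gap, ambiguity or stop in either sequence
#' are skipped.
#'
#' @param seq1,seq2 aligned coding sequences of equal length.
#' @return List with `S`, `N` (site counts), `Sd`, `Nd`, `pS`, `pN`, `dS`,
#'   `dN`, `omega` (capped at 999 when `dS` is 0 and `dN` > 0; 0/0 gives
#'   `NaN`), `capped`.
#' @export
ng86 <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) stopf("ng86: sequences differ in length")
  if (nchar(seq1) %% 3 != 0) stopf("ng86: length is not a multiple of 3")
  c1 <- as_codons(toupper(seq1))
  c2 <- as_codons(toupper(seq2))
  tab <- codon_table()
  ok <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  ok[ok] <- tab[c1[ok]] != "*" & tab[c2[ok]] != "*"
  if (!any(ok)) stopf("ng86: no comparable codon sites")
  c1 <- c1[ok]; c2 <- c2[ok]
  s1 <- sum(vapply(c1, ng86_site_counts, 0))
  s2 <- sum(vapply(c2, ng86_site_counts, 0))
  S <- (s1 + s2) / 2
  N <- 3 * length(c1) - S
  cnt <- vapply(seq_along(c1), function(i) ng86_pair_counts(c1[i], c2[i]),
                c(sd = 0, nd = 0))
  Sd <- sum(cnt["sd", ]); Nd <- sum(cnt["nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p, what) {
    if (p >= 3 / 4) {
      stopf("ng86: %s proportion %.3f outside the Jukes-Cantor domain", what, p)
    }
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS, "synonymous")
  dN <- jc(pN, "nonsynonymous")
  capped <- FALSE
  omega <- if (dS > 0) dN / dS else if (dN > 0) { capped <- TRUE; OMEGA_CAP }
  else NaN
  if (is.finite(omega) && omega > OMEGA_CAP) { omega <- OMEGA_CAP; capped <- TRUE }
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
       omega = omega, capped = capped)
}

# --- codon alignment utilities --------------------------------------------

codon_index <- function(codons) {
  idx <- match(codons, sense_codons()) - 1L
  idx[is.na(idx)] <- -1L
  as.integer(idx)
}

#' F3x4 equilibrium codon frequencies from a codon alignment
#'
#' Positional nucleotide frequencies multiplied across the three codon
#' positions, restricted to sense codons and renormalized.
#'
#' @param aln a `codon_alignment`.
#' @return Numeric 61-vector (order of `sense_codons()`), floored at 1e-8.
#' @export
codon_freqs_f3x4 <- function(aln) {
  nts <- c("A", "C", "G", "T")
  pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, nts))
  for (s in aln) {
    cod <- as_codons(toupper(s))
    cod <- cod[!grepl("[^ACGT]", cod)]
    for (p in 1:3) {
      tabp <- table(factor(substr(cod, p, p), levels = nts))
      pos_freq[p, ] <- pos_freq[p, ] + tabp
    }
  }
  pos_freq <- pos_freq / rowSums(pos_freq)
  sc <- sense_codons()
  pi <- vapply(sc, function(cd) {
    pos_freq[1, substr(cd, 1, 1)] * pos_freq[2, substr(cd, 2, 2)] *
      pos_freq[3, substr(cd, 3, 3)]
  }, 0)
  pi <- pmax(pi, 1e-8)
  pi / sum(pi)
}

# site patterns: list(tips = ntip x npat int matrix (0-based, -1 missing),
# weights)
codon_patterns <- function(aln, tip_order) {
  mats <- lapply(aln[tip_order], function(s) codon_index(as_codons(toupper(s))))
  m <- do.call(rbind, mats)
  key <- apply(m, 2, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(uk, key)
  list(tips = m[, idx, drop = FALSE],
       weights = as.numeric(table(key)[uk]))
}

# postorder edge representation for the C++ pruning kernel
tree_postorder <- function(tree, tip_order) {
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  perm <- match(tr$tip.label, tip_order)
  stopifnot(!anyNA(perm))
  # relabel child tip ids so that tip i in C++ = row i of the pattern matrix
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  remap <- c(perm, seq.int(ntip + 1L, ntip + tr$Nnode))
  edge[] <- remap[edge]
  list(tree = tr, edge = edge - 1L, nnode = ntip + tr$Nnode, ntip = ntip)
}

foreground_edge_rows <- function(tree, foreground_edges) {
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  if (is.numeric(foreground_edges)) return(as.integer(foreground_edges))
  tips <- match(foreground_edges, tr$tip.label)
  if (anyNA(tips)) {
    stopf("foreground tips not in tree: %s",
          paste(foreground_edges[is.na(tips)], collapse = ", "))
  }
  # pendant edges of the named tips, plus internal edges whose descendant
  # tips are all foreground (the duplicate clade)
  ntip <- length(tr$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(node)
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  rows <- integer()
  for (r in seq_len(nrow(tr$edge))) {
    d <- desc(tr$edge[r, 2])
    if (all(d %in% tips)) rows <- c(rows, r)
  }
  rows
}

# --- model fitting ---------------------------------------------------------

#' Fit a Goldman-Yang codon model
#'
#' 61x61 codon rate matrix with transition/transversion ratio `kappa`, `omega`
#' multiplying nonsynonymous rates, and F3x4 equilibrium frequencies estimated
#' from the data. Branch lengths (expected substitutions per codon), `kappa`
#' and free `omega` parameters are optimized by L-BFGS-B on the log scale from
#' two starting points (omega 0.1 and 1.0); the likelihood is computed by the
#' pruning algorithm on the unrooted tree.
#'
#' @param aln a `codon_alignment` (ids must match the tree's tips).
#' @param tree a `phylo` tree.
#' @param model_tag `"one_ratio"`, `"one_ratio_fixed1"` or `"two_ratio"`.
#' @param foreground_edges for `two_ratio`: tip labels (their pendant edges
#'   plus any clade made entirely of them) or postorder edge-row indices.
#' @param fix_omega optional fixed omega (implied 1 for `one_ratio_fixed1`).
#' @param start optional `codon_fit` whose solution seeds an extra start
#'   (guarantees nesting chains numerically).
#' @param control list: `maxit` (default 200), `factr` (L-BFGS-B tolerance,
#'   default 1e8), `omega_start` (omega starting values, default
#'   `c(0.1, 1)`; a single value is appropriate inside simulation loops where
#'   the surface is unimodal and restarts only duplicate work).
#' @return A `codon_fit`: `model_tag`, `lnL`, `kappa`, `omega` (named vector),
#'   `branch_lengths` (postorder edges), `edge_class`, `tree`, `freqs`, `np`,
#'   `converged`.
#' @export
fit_codon_model <- function(aln, tree, model_tag = c("one_ratio",
                                                     "one_ratio_fixed1",
                                                     "two_ratio"),
                            foreground_edges = NULL, fix_omega = NULL,
                            start = NULL, control = list()) {
  model_tag <- match.arg(model_tag)
  ids <- names(aln)
  if (!setequal(ids, tree$tip.label)) {
    stopf("alignment ids and tree tips differ")
  }
  po <- tree_postorder(tree, ids)
  nedge <- nrow(po$edge)
  pat <- codon_patterns(aln, ids)
  if (all(apply(pat$tips, 2, function(x) length(unique(x[x >= 0])) <= 1))) {
    warnf("alignment has no variable codon sites; omega is inestimable")
  }
  pi <- codon_freqs_f3x4(aln)
  pairs <- codon_pairs()

  edge_class <- rep(0L, nedge)
  n_omega_free <- 1L
  if (model_tag == "two_ratio") {
    if (is.null(foreground_edges) || !length(foreground_edges)) {
      stopf("two_ratio requires foreground_edges")
    }
    rows <- foreground_edge_rows(tree, foreground_edges)
    if (!length(rows)) stopf("no foreground edges resolved")
    edge_class[rows] <- 1L
    n_omega_free <- 2L
  } else if (!is.null(foreground_edges)) {
    stopf("foreground_edges only apply to the two_ratio model")
  }
  if (model_tag == "one_ratio_fixed1") fix_omega <- 1
  fixed <- !is.null(fix_omega)
  if (fixed) n_omega_free <- 0L

  maxit <- control$maxit %||% 200L
  factr <- control$factr %||% 1e8
  nclass <- max(edge_class) + 1L

  lnL_fun <- function(par) {
    bl <- exp(par[seq_len(nedge)])
    kappa <- exp(par[nedge + 1L])
    omegas <- if (fixed) rep(fix_omega, nclass)
    else exp(par[nedge + 1L + seq_len(nclass)])
    cpp_codon_lnL(pat$tips, pat$weights, po$edge, po$nnode, bl,
                  edge_class, kappa, omegas, pi, pairs)
  }
  last <- new.env(parent = emptyenv())
  obj <- function(par) {
    v <- -lnL_fun(par)
    last$par <- par
    last$val <- v
    v
  }
  # forward-difference gradient (halves the per-iteration likelihood calls
  # relative to optim's central differences); f(par) is reused when optim
  # requests the gradient at the point it just evaluated
  grad <- function(par) {
    f0 <- if (!is.null(last$par) && isTRUE(all.equal(par, last$par))) last$val
    else -lnL_fun(par)
    h <- 1e-5
    vapply(seq_along(par), function(i) {
      p2 <- par
      p2[i] <- p2[i] + h
      (-lnL_fun(p2) - f0) / h
    }, 0)
  }

  # input trees usually carry aa-distance lengths; codon-scale lengths run
  # about 3x larger, and the optimizer only needs the right magnitude
  bl0 <- pmin(pmax(3 * (po$tree$edge.length %||% rep(0.03, nedge)), 1e-3), 3)
  if (!length(bl0) || length(bl0) != nedge) bl0 <- rep(0.1, nedge)
  starts <- list()
  if (fixed) {
    starts[[1]] <- c(log(bl0), log(2))
  } else {
    for (w0 in (control$omega_start %||% c(0.1, 1.0))) {
      starts[[length(starts) + 1L]] <- c(log(bl0), log(2), rep(log(w0), nclass))
    }
  }
  if (!is.null(start) && inherits(start, "codon_fit") &&
      length(start$branch_lengths) == nedge) {
    w_prev <- unname(start$omega[1])
    extra <- c(log(pmax(start$branch_lengths, 1e-6)), log(start$kappa))
    if (!fixed) extra <- c(extra, rep(log(max(w_prev, 1e-4)), nclass))
    starts[[length(starts) + 1L]] <- extra
  }

  lower <- c(rep(log(1e-6), nedge), log(0.01), rep(log(1e-4), n_omega_free))
  upper <- c(rep(log(20), nedge), log(100), rep(log(OMEGA_CAP), n_omega_free))

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, obj, gr = grad, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("codon model optimization failed")

  par <- best$par
  bl <- exp(par[seq_len(nedge)])
  kappa <- exp(par[nedge + 1L])
  omegas <- if (fixed) rep(fix_omega, nclass)
  else pmin(exp(par[nedge + 1L + seq_len(nclass)]), OMEGA_CAP)
  names(omegas) <- if (nclass == 2L) c("background", "foreground") else "omega"
  np <- nedge + 1L + n_omega_free
  structure(list(model_tag = model_tag, lnL = -best$value, kappa = kappa,
                 omega = omegas, branch_lengths = bl,
                 edge_class = edge_class, tree = po$tree, freqs = pi,
                 np = np, converged = best$convergence == 0),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("codon_fit [%s]: lnL = %.4f, kappa = %.3f, omega = %s%s\n",
              x$model_tag, x$lnL, x$kappa,
              paste(sprintf("%s=%.4f", names(x$omega), x$omega), collapse = ", "),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Likelihood-ratio test between nested codon models
#'
#' @param null_fit,alt_fit `codon_fit` objects (null nested in alternative).
#' @param df degrees of freedom; defaults to the parameter-count difference.
#' @return An `lrt_result`: `statistic` (2 * delta lnL, clamped at 0), `df`,
#'   `p_value` (chi-square upper tail), plus both fits.
#' @export
lrt <- function(null_fit, alt_fit, df = NULL) {
  stopifnot(inherits(null_fit, "codon_fit"), inherits(alt_fit, "codon_fit"))
  if (is.null(df)) df <- alt_fit$np - null_fit$np
  if (df < 1) stopf("lrt: models are not nested (df = %d)", df)
  stat <- 2 * (alt_fit$lnL - null_fit$lnL)
  if (stat < -0.02) {
    stopf("lrt: alternative lnL below null (delta = %.4f); optimization failure",
          stat / 2)
  }
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 null_fit = null_fit, alt_fit = alt_fit),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2dlnL = %.4f, df = %d, p = %.4g\n",
              x$alt_fit$model_tag, x$null_fit$model_tag, x$statistic, x$df,
              x$p_value))
  invisible(x)
}

#' Simulate codon sequences along a tree
#'
#' Evolves codons under the same scaled Goldman-Yang rate matrix used by
#' [fit_codon_model()]; branch lengths are expected substitutions per codon.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param omega background omega, or a vector of per-class omegas.
#' @param kappa transition/transversion ratio.
#' @param freqs 61-vector of codon frequencies (default uniform).
#' @param n_codons number of codons.
#' @param seed RNG seed.
#' @param foreground_edges optional foreground specification (as in
#'   [fit_codon_model()]) evolving under `omega[2]`.
#' @return A `codon_alignment` of the tip sequences.
#' @export
simulate_codons <- function(tree, omega, kappa = 2, freqs = NULL,
                            n_codons = 300L, seed = 1L,
                            foreground_edges = NULL) {
  stopifnot(n_codons >= 1)
  sc <- sense_codons()
  if (is.null(freqs)) freqs <- rep(1 / length(sc), length(sc))
  stopifnot(length(freqs) == length(sc))
  freqs <- freqs / sum(freqs)
  pairs <- codon_pairs()
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  nedge <- nrow(tr$edge)
  edge_class <- rep(1L, nedge)
  if (!is.null(foreground_edges)) {
    edge_class[foreground_edge_rows(tree, foreground_edges)] <- 2L
  }
  omegas <- if (length(omega) == 1) c(omega, omega) else omega
  ntip <- length(tr$tip.label)
  root <- tr$edge[nedge, 1]
  with_seed(seed, {
    seqs <- vector("list", ntip + tr$Nnode)
    seqs[[root]] <- sample.int(length(sc), n_codons, replace = TRUE,
                               prob = freqs)
    # preorder: reverse postorder guarantees parents are simulated first
    for (e in rev(seq_len(nedge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      P <- cpp_codon_pmat(kappa, omegas[edge_class[e]], freqs,
                          tr$edge.length[e], pairs)
      parent_seq <- seqs[[p]]
      child <- integer(n_codons)
      for (st in unique(parent_seq)) {
        at <- which(parent_seq == st)
        child[at] <- sample.int(length(sc), length(at), replace = TRUE,
                                prob = P[st, ])
      }
      seqs[[ch]] <- child
    }
    out <- vapply(seq_len(ntip), function(i) {
      paste(sc[seqs[[i]]], collapse = "")
    }, "")
    names(out) <- tr$tip.label
    class(out) <- "codon_alignment"
    out
  })
}
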