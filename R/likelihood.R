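## Felsenstein pruning likelihood under HKY/GTR with discrete-gamma rate
## mixing, with site-pattern compression, plus coordinate-wise Brent
## optimisation of branch lengths and a neighbor-joining wrapper.

## encode an alignment (named character vector) as an integer matrix
## (taxa x sites); 0 = gap/ambiguity (treated as missing data)
encode_alignment <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- alignment
  } else {
    if (length(unique(nchar(alignment))) != 1L)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
    rownames(m) <- names(alignment)
  }
  code <- match(m, DNA_BASES)
  code[is.na(code)] <- 0L
  matrix(code, nrow = nrow(m), dimnames = dimnames(m))
}

## compress to unique site patterns with weights
compress_patterns <- function(code) {
  key <- apply(code, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- code[, first, drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[first])))
  list(patterns = pat, weights = w)
}

#' Total log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over site patterns, mixing the discrete gamma
#' categories with equal weights.  Gaps and ambiguity codes are treated as
#' missing data.  The likelihood is invariant under re-rooting because the
#' model is reversible.
#'
#' @param tree `phylo` tree with branch lengths (substitutions/site);
#'   its tips must be a subset of the alignment's taxa.
#' @param alignment named character vector of aligned sequences.
#' @param model a [subst_model()].
#' @return total log-likelihood (single number).
#' @export
site_log_likelihood <- function(tree, alignment, model = subst_model()) {
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  miss <- setdiff(tree$tip.label, names(alignment))
  if (length(miss))
    stop("taxa missing from alignment: ", paste(miss, collapse = ", "))
  code <- encode_alignment(alignment[tree$tip.label])
  cp <- compress_patterns(code)
  sum(cp$weights * log(site_likelihoods(tree, cp$patterns, model)))
}

## per-pattern likelihoods (gamma-mixed); patterns: taxa x npat integer
site_likelihoods <- function(tree, patterns, model) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  npat <- ncol(patterns)
  po <- ape::reorder.phylo(tree, "postorder")
  ## tip partials: indicator, or 1s for missing
  tipL <- vector("list", n_tip)
  for (i in seq_len(n_tip)) {
    M <- matrix(0, 4, npat)
    s <- patterns[i, ]
    M[cbind(s[s > 0L], which(s > 0L))] <- 1
    M[, s == 0L] <- 1
    tipL[[i]] <- M
  }
  lik <- numeric(npat)
  for (g in seq_len(model$ncat)) {
    rate <- model$gamma_rates[g]
    partial <- vector("list", n_node)
    partial[seq_len(n_tip)] <- tipL
    prod_at <- vector("list", n_node)
    for (e in seq_len(nrow(po$edge))) {
      u <- po$edge[e, 1]; v <- po$edge[e, 2]
      if (v > n_tip) partial[[v]] <- prod_at[[v]]
      P <- prob_matrix(model, po$edge.length[e] * rate)
      contrib <- P %*% partial[[v]]
      prod_at[[u]] <- if (is.null(prod_at[[u]])) contrib
                      else prod_at[[u]] * contrib
    }
    root <- n_tip + 1L
    lik <- lik + as.vector(model$base_freq %*% prod_at[[root]]) / model$ncat
  }
  lik
}

#' Optimise branch lengths of a tree by coordinate-wise Brent search
#'
#' Each branch in turn is optimised with [stats::optimize()] while the
#' others are held fixed, sweeping until the log-likelihood improves by
#' less than `tol` (relative) or `max_passes` sweeps are done.
#'
#' @param tree `phylo` tree with starting branch lengths.
#' @param alignment named character vector of aligned sequences.
#' @param model a [subst_model()].
#' @param upper upper bound on a branch length.
#' @param tol relative convergence tolerance.
#' @param max_passes maximum number of sweeps.
#' @return list with `tree` (optimised branch lengths) and `loglik`.
#' @export
optimize_branch_lengths <- function(tree, alignment, model = subst_model(),
                                    upper = 5, tol = 1e-6, max_passes = 100L) {
  code <- encode_alignment(alignment[tree$tip.label])
  cp <- compress_patterns(code)
  ll <- function(tr) sum(cp$weights * log(site_likelihoods(tr, cp$patterns,
                                                           model)))
  cur <- ll(tree)
  for (pass in seq_len(max_passes)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        ll(tree)
      }
      opt <- optimize(f, c(1e-8, upper), maximum = TRUE, tol = 1e-6)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (abs(cur - prev) < tol * (abs(prev) + 1e-12)) break
  }
  list(tree = tree, loglik = cur)
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining on a symmetric distance matrix (via
#' `ape::nj`); negative branch lengths are clamped to zero.
#'
#' @param dist symmetric numeric matrix with zero diagonal (or a `p_dist`).
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (inherits(dist, "p_dist")) dist <- dist$values
  if (!isSymmetric(unname(as.matrix(dist)), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(dist))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
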