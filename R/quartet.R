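## Quartet likelihood mapping: for every 4-taxon subset the three resolved
## topologies are fitted by maximum likelihood, the likelihoods are turned
## into barycentric weights on the 2-simplex, and each quartet is assigned
## to one of the seven regions (3 corners = fully resolved, 3 edges =
## partly unresolved, 1 centre = fully unresolved).

## the three resolved quartet topologies on taxa (a, b, c, d)
quartet_topologies <- function(taxa) {
  mk <- function(x1, x2, x3, x4)
    ape::read.tree(text = sprintf("((%s:0.1,%s:0.1):0.1,%s:0.1,%s:0.1);",
                                  x1, x2, x3, x4))
  list(mk(taxa[1], taxa[2], taxa[3], taxa[4]),
       mk(taxa[1], taxa[3], taxa[2], taxa[4]),
       mk(taxa[1], taxa[4], taxa[2], taxa[3]))
}

#' Classify a quartet weight vector on the likelihood-mapping simplex
#'
#' Boundaries follow the 1/3 rule on pairwise-renormalised weights: the
#' best topology fully resolves the quartet when each competitor's
#' pairwise-renormalised weight `w_j / (w_i + w_j)` is below 1/3 (i.e. the
#' best weight at least doubles it); when the runner-up competes but the
#' third weight is dominated, the quartet is partly unresolved (edge
#' region); otherwise it is fully unresolved (centre).  Boundary ties go to
#' the less-resolved region.
#'
#' @param w numeric vector of three non-negative weights (normalised
#'   internally).
#' @return `"resolved"`, `"partly"` or `"unresolved"`.
#' @export
classify_quartet_weights <- function(w) {
  if (length(w) != 3L || any(w < 0)) stop("need three non-negative weights")
  w <- sort(w / sum(w), decreasing = TRUE)
  if (w[1] > 2 * w[2]) "resolved"
  else if (w[2] > 2 * w[3]) "partly"
  else "unresolved"
}

#' Quartet likelihood mapping of an alignment
#'
#' For each sampled quartet the three resolved topologies are fitted
#' (branch lengths optimised by [optimize_branch_lengths()]), the
#' likelihoods are converted to weights `w_i = L_i / sum(L)`, and the
#' weight vector is classified with [classify_quartet_weights()].
#'
#' @param alignment named character vector of aligned sequences (>= 4).
#' @param model a [subst_model()].
#' @param quartet_sample `"all"` for exhaustive enumeration (automatically
#'   capped: if `choose(n, 4)` exceeds `max_quartets` a seeded uniform
#'   sample of `max_quartets` is used), or a list `list(k =, seed =)`.
#' @param max_quartets cap for exhaustive enumeration.
#' @param ... passed to [optimize_branch_lengths()].
#' @return object of class `quartet_signal` with `n_quartets`,
#'   `pct_resolved`, `pct_partly`, `pct_unresolved` and the per-quartet
#'   classification table.
#' @export
quartet_map <- function(alignment, model = subst_model(),
                        quartet_sample = "all", max_quartets = 20000L, ...) {
  taxa <- names(alignment)
  n <- length(taxa)
  if (n < 4L) stop("quartet mapping needs at least 4 taxa")
  if (any(nchar(alignment) == 0L)) stop("empty alignment")
  all_q <- combn(n, 4L)
  if (identical(quartet_sample, "all")) {
    if (ncol(all_q) > max_quartets) {
      set.seed(0L)
      all_q <- all_q[, sample.int(ncol(all_q), max_quartets), drop = FALSE]
    }
  } else {
    set.seed(quartet_sample$seed %||% 0L)
    k <- min(quartet_sample$k, ncol(all_q))
    all_q <- all_q[, sample.int(ncol(all_q), k), drop = FALSE]
  }
  classes <- character(ncol(all_q))
  for (qi in seq_len(ncol(all_q))) {
    qt <- taxa[all_q[, qi]]
    sub <- alignment[qt]
    ## a quartet with no comparable signal (e.g. all-gap columns) still
    ## evaluates: equal likelihoods land it in the centre region
    logl <- vapply(quartet_topologies(qt), function(tp)
      optimize_branch_lengths(tp, sub, model, ...)$loglik, 0)
    w <- exp(logl - max(logl))
    classes[qi] <- classify_quartet_weights(w)
  }
  tab <- table(factor(classes, levels = c("resolved", "partly",
                                          "unresolved")))
  pct <- 100 * as.vector(tab) / length(classes)
  structure(list(
    n_quartets = length(classes),
    pct_resolved = pct[1], pct_partly = pct[2], pct_unresolved = pct[3],
    classes = classes, quartets = all_q, taxa = taxa),
    class = "quartet_signal")
}

#' @export
print.quartet_signal <- function(x, ...) {
  cat(sprintf(
    "quartet signal: %d quartets | %%QFR %.2f  %%QPU %.2f  %%QFU %.2f\n",
    x$n_quartets, x$pct_resolved, x$pct_partly, x$pct_unresolved))
  invisible(x)
}

#' Phylogenetic-signal report for a set of alignments
#'
#' One row per alignment with its length and the likelihood-mapping
#' percentages, mirroring the usual signal tables (ALN, length, %QFR,
#' %QPU, %QFU).
#'
#' @param alignments named list of alignments (named character vectors).
#' @param model a [subst_model()].
#' @param ... passed to [quartet_map()].
#' @return data frame of class `signal_report`.
#' @export
signal_report <- function(alignments, model = subst_model(), ...) {
  rows <- lapply(names(alignments), function(nm) {
    qs <- quartet_map(alignments[[nm]], model, ...)
    data.frame(ALN = nm, length = unique(nchar(alignments[[nm]]))[1],
               pct_QFR = qs$pct_resolved, pct_QPU = qs$pct_partly,
               pct_QFU = qs$pct_unresolved, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("signal_report", "data.frame")
  out
}
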