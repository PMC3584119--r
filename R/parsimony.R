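## Unordered-parsimony ancestral state reconstruction (Sankoff dynamic
## programming; equal to Fitch on binary trees under unit costs).  Reports
## the minimum tree length, per-node MPR state sets (union over all
## most-parsimonious reconstructions) and the branches that change state in
## every MPR.  Polytomies are handled natively (sum over children).

## generalized Sankoff machinery over an arbitrary cost matrix; used by
## parsimony_reconstruct (unit costs) and by the spacer gain/loss
## classification (gain-penalised costs).
sankoff_engine <- function(tree, states, state_space, cost) {
  k <- length(state_space)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label) &&
                  all(nzchar(tree$node.label))) tree$node.label
              else paste0("node", (n_tip + 1L):n_node))
  po <- ape::reorder.phylo(tree, "postorder")
  INF <- .Machine$double.xmax / 4

  D <- matrix(INF, n_node, k)
  for (i in seq_len(n_tip)) {
    s <- states[[tree$tip.label[i]]]
    if (is.na(s) || s == "?") D[i, ] <- 0
    else {
      j <- match(s, state_space)
      if (is.na(j)) stop("state '", s, "' not in declared state space")
      D[i, j] <- 0
    }
  }
  ## min_t(cost[s, t] + D[c, t]) for all s, for one child profile
  stepmin <- function(dc) {
    vapply(seq_len(k), function(s) min(cost[s, ] + dc), 0)
  }
  ## down-pass: postorder guarantees a child's edges all precede its
  ## parent's edge, so D[v] is final when edge (u, v) is reached
  Dstep <- vector("list", n_node)   # stepmin of each child's profile
  acc <- matrix(0, n_node, k)       # running child sums of internal nodes
  for (e in seq_len(nrow(po$edge))) {
    u <- po$edge[e, 1]; v <- po$edge[e, 2]
    if (v > n_tip) D[v, ] <- acc[v, ]
    sv <- stepmin(D[v, ])
    acc[u, ] <- acc[u, ] + sv
    Dstep[[v]] <- sv
  }
  root <- n_tip + 1L
  D[root, ] <- acc[root, ]
  L <- min(D[root, ])

  ## up-pass: U[v, s] = cost of the tree outside v's subtree with v = s
  U <- matrix(INF, n_node, k)
  U[root, ] <- 0
  rest <- vector("list", n_node)   # rest-of-tree profile at the parent
  for (e in rev(seq_len(nrow(po$edge)))) {
    u <- po$edge[e, 1]; v <- po$edge[e, 2]
    r <- U[u, ] + (D[u, ] - Dstep[[v]])   # exclude v's contribution
    rest[[v]] <- r
    U[v, ] <- vapply(seq_len(k), function(b) min(r + cost[, b]), 0)
  }

  list(D = D, U = U, rest = rest, L = L, labels = labels, n_tip = n_tip,
       k = k, state_space = state_space, cost = cost, po = po,
       root = root)
}

#' Parsimony ancestral reconstruction of one categorical character
#'
#' Sankoff dynamic programming with unit costs on a rooted tree (equivalent
#' to Fitch on binary trees).  Missing observations (`"?"` or `NA`) allow
#' any state at that leaf.
#'
#' @param tree rooted `phylo` tree (branch lengths ignored; polytomies
#'   allowed).
#' @param states named character vector of leaf states (names = tip
#'   labels); `"?"` marks missing data.
#' @param state_space character vector of allowed states; defaults to the
#'   observed states.
#' @return object of class `parsimony_reconstruction`: `length` (minimum
#'   number of changes), `node_states` (named list of MPR state sets, the
#'   union over all most-parsimonious reconstructions, for tips and
#'   internal nodes), and `changes` (data frame of branches that change in
#'   every MPR, with the `from`/`to` state sets over the optimal
#'   assignments of that branch).
#' @export
parsimony_reconstruct <- function(tree, states, state_space = NULL) {
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("no state for taxa: ", paste(miss, collapse = ", "))
  states <- states[tree$tip.label]
  obs <- setdiff(unique(states), c("?", NA))
  if (is.null(state_space)) state_space <- sort(obs)
  if (length(setdiff(obs, state_space)))
    stop("state '", setdiff(obs, state_space)[1], "' not in declared state space")
  if (length(obs) == 0L) stop("at least one non-missing state required")
  k <- length(state_space)
  cost <- 1 - diag(k)
  eng <- sankoff_engine(tree, as.list(states), state_space, cost)

  tol <- 1e-9
  n_node <- nrow(eng$D)
  node_states <- vector("list", n_node)
  total <- eng$D + eng$U
  for (v in seq_len(n_node))
    node_states[[v]] <- state_space[total[v, ] <= eng$L + tol]
  names(node_states) <- eng$labels

  ## branches changing in every MPR: no optimal reconstruction keeps the
  ## same state across the edge
  changes <- list()
  for (e in seq_len(nrow(eng$po$edge))) {
    u <- eng$po$edge[e, 1]; v <- eng$po$edge[e, 2]
    r <- eng$rest[[v]]
    same_best <- min(r + eng$D[v, ])          # best with equal states
    if (same_best > eng$L + tol) {
      ## enumerate optimal (a, b) pairs across the edge
      pair_cost <- outer(r, eng$D[v, ], "+") + eng$cost
      opt <- which(pair_cost <= eng$L + tol, arr.ind = TRUE)
      changes[[length(changes) + 1L]] <- data.frame(
        branch = eng$labels[v],
        from = paste(sort(unique(eng$state_space[opt[, 1]])), collapse = "|"),
        to = paste(sort(unique(eng$state_space[opt[, 2]])), collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes)
             else data.frame(branch = character(0), from = character(0),
                             to = character(0))
  structure(list(length = eng$L, state_space = state_space,
                 node_states = node_states, changes = changes,
                 labels = eng$labels, n_tip = eng$n_tip),
            class = "parsimony_reconstruction")
}

#' @export
print.parsimony_reconstruction <- function(x, ...) {
  cat(sprintf("parsimony reconstruction: length %d, %d unambiguous change(s)\n",
              as.integer(x$length), nrow(x$changes)))
  if (nrow(x$changes)) print(x$changes, row.names = FALSE)
  invisible(x)
}

#' Number of independent origins of a state
#'
#' Counts the branches that change state in every most-parsimonious
#' reconstruction and whose destination state set is exactly the given
#' state: a lower bound on independent origins of that state.
#'
#' @param rec a `parsimony_reconstruction`.
#' @param state the derived state of interest.
#' @return integer count.
#' @export
count_origins <- function(rec, state) {
  sum(rec$changes$to == state & rec$changes$from != state)
}

#' Reconstruct all traits of a matrix and flag convergence
#'
#' @param tree rooted `phylo` tree.
#' @param traits data frame with a `taxon` column and one column per
#'   categorical trait (`"?"` = missing).
#' @return list of class `trait_mapping`: `reconstructions` (per trait)
#'   and `summary` (trait, length, states, convergent: does any state
#'   arise on two or more branches in every MPR?).
#' @export
map_all_traits <- function(tree, traits) {
  if (!"taxon" %in% names(traits)) stop("trait matrix needs a 'taxon' column")
  trait_names <- setdiff(names(traits), "taxon")
  if (!length(trait_names)) stop("empty trait matrix")
  recs <- list(); rows <- list()
  for (tr in trait_names) {
    st <- setNames(as.character(traits[[tr]]), traits$taxon)
    rec <- parsimony_reconstruct(tree, st)
    recs[[tr]] <- rec
    origin_counts <- vapply(rec$state_space, function(s)
      count_origins(rec, s), 0L)
    rows[[tr]] <- data.frame(
      trait = tr, length = as.integer(rec$length),
      n_states = length(rec$state_space),
      max_origins = if (length(origin_counts)) max(origin_counts) else 0L,
      convergent_state = if (length(origin_counts) && max(origin_counts) >= 2L)
        names(origin_counts)[which.max(origin_counts)] else NA_character_,
      stringsAsFactors = FALSE)
  }
  structure(list(reconstructions = recs,
                 summary = do.call(rbind, c(rows, list(make.row.names = FALSE)))),
            class = "trait_mapping")
}

#' @export
print.trait_mapping <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Annotated Newick with MPR state sets
#'
#' Writes the tree with each node's MPR state set appended to its label as
#' `label{state1|state2}`.
#'
#' @param tree the tree used for the reconstruction.
#' @param rec a `parsimony_reconstruction`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_annotated_tree <- function(tree, rec, path) {
  t2 <- tree
  n_tip <- length(tree$tip.label)
  fmt <- function(lab) {
    ss <- rec$node_states[[lab]]
    paste0(lab, "{", paste(ss, collapse = "|"), "}")
  }
  t2$tip.label <- vapply(tree$tip.label, fmt, "")
  labs <- rec$labels[(n_tip + 1L):length(rec$labels)]
  t2$node.label <- vapply(labs, fmt, "")
  ape::write.tree(t2, file = path)
  invisible(path)
}
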