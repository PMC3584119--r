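## Independent brute-force oracles used to validate the dynamic-programming
## and pruning implementations.  These deliberately share no code with the
## package internals beyond trivial encodings.

## exhaustive unordered-parsimony: enumerate all internal labelings (and
## all states at missing leaves); returns minimum length and per-node MPR
## state sets
oracle_parsimony <- function(tree, states, state_space) {
  k <- length(state_space)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  fixed <- match(states[tree$tip.label], state_space)   # NA = missing
  free <- c(which(is.na(fixed)), (n_tip + 1L):n_node)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  lab <- matrix(rep(fixed, nrow(grid)), nrow = nrow(grid), byrow = TRUE)
  lab <- cbind(lab, matrix(0L, nrow(grid), tree$Nnode))
  lab[, free] <- grid
  cost <- rep(0L, nrow(grid))
  for (e in seq_len(nrow(tree$edge)))
    cost <- cost + (lab[, tree$edge[e, 1]] != lab[, tree$edge[e, 2]])
  L <- min(cost)
  opt <- lab[cost == L, , drop = FALSE]
  sets <- lapply(seq_len(n_node), function(v)
    sort(state_space[unique(opt[, v])]))
  list(length = L, node_sets = sets)
}

## brute-force pruning likelihood: sum over all internal state combinations
oracle_loglik <- function(tree, aln, model) {
  code <- do.call(rbind, strsplit(toupper(aln[tree$tip.label]), ""))
  code <- matrix(match(code, c("A", "C", "G", "T")), nrow = nrow(code))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internals <- (n_tip + 1L):n_node
  combos <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  total <- 0
  for (site in seq_len(ncol(code))) {
    lik <- 0
    for (g in seq_len(model$ncat)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
        mitosig:::prob_matrix(model,
                              tree$edge.length[e] * model$gamma_rates[g]))
      s <- 0
      for (r in seq_len(nrow(combos))) {
        st <- integer(n_node)
        st[internals] <- combos[r, ]
        st[seq_len(n_tip)] <- code[, site]
        p <- unname(model$base_freq[st[n_tip + 1L]])
        for (e in seq_len(nrow(tree$edge))) {
          a <- st[tree$edge[e, 1]]; b <- st[tree$edge[e, 2]]
          if (is.na(b)) next                       # missing tip: marginal
          p <- p * Ps[[e]][a, b]
        }
        s <- s + p
      }
      lik <- lik + s / model$ncat
    }
    total <- total + log(lik)
  }
  total
}

## random rooted tree with unit-independent branch lengths and tip labels
random_labelled_tree <- function(n, bl = 0.1) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr
}
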