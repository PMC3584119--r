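## Clade signatures from intergenic spacers and tRNA loops: group spacers
## by locus, classify their phyletic pattern on a tree by minimum-change
## (gain-averse) reconstruction, extract DHU/TPsiC loop motifs and find
## clade-diagnostic IUPAC consensi.

#' Group per-taxon spacers by locus
#'
#' One group per spacer locus that occurs (length >= 1 nt) in at least one
#' taxon; all other taxa are recorded as absent.  Present members are
#' aligned (structure-free progressive alignment) when the group has more
#' than one member.
#'
#' @param spacers data frame from [extract_spacers()] /
#'   [annotate_genomes()] with columns `taxon`, `locus`, `length`,
#'   `sequence`.
#' @param taxa full taxon set (defaults to the taxa seen in `spacers`).
#' @param align align present members with MAFFT.
#' @return named list of `spacer_group` objects (`locus`, `members`,
#'   `presence`, `aligned`).
#' @export
group_spacers <- function(spacers, taxa = NULL, align = TRUE) {
  if (is.null(taxa)) taxa <- unique(spacers$taxon)
  if (anyDuplicated(spacers[, c("taxon", "locus")]))
    stop("conflicting spacer records: duplicated taxon/locus keys")
  out <- list()
  for (loc in unique(spacers$locus)) {
    sub <- spacers[spacers$locus == loc & spacers$length > 0L, ]
    if (!nrow(sub)) next
    presence <- setNames(taxa %in% sub$taxon, taxa)
    members <- setNames(sub$sequence, sub$taxon)
    ## equal-length members are already columnwise comparable; progressive
    ## alignment is only needed for length variation
    aligned <- if (align && length(members) > 1L &&
                   length(unique(nchar(members))) > 1L)
      mafft_align(members, "nucleotide") else members
    out[[loc]] <- structure(list(locus = loc, members = members,
                                 presence = presence, aligned = aligned),
                            class = "spacer_group")
  }
  out
}

#' @export
print.spacer_group <- function(x, ...) {
  cat(sprintf("spacer %s: present in %d/%d taxa\n", x$locus,
              sum(x$presence), length(x$presence)))
  invisible(x)
}

## mean pairwise identity of aligned sequences (matches over columns where
## both rows have a base)
mean_pairwise_identity <- function(aln) {
  if (length(aln) < 2L) return(1)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  ids <- combn(nrow(m), 2L, function(ij) {
    a <- m[ij[1], ]; b <- m[ij[2], ]
    ok <- a != "-" & b != "-"
    if (!any(ok)) return(0)
    mean(a[ok] == b[ok])
  })
  mean(ids)
}

## strict IUPAC consensus over alignment columns; gap-containing columns
## become '-'
aligned_consensus <- function(aln) {
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  paste(vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == "-")) return("-")
    obs <- sort(unique(unlist(IUPAC_SETS[col], use.names = FALSE)))
    IUPAC_CODE[[paste(obs, collapse = "")]]
  }, ""), collapse = "")
}

#' Classify the phyletic pattern of a spacer group on a tree
#'
#' Minimum-change (unit-cost) reconstruction of presence/absence on the
#' tree, with ties between equally parsimonious solutions broken towards
#' fewer gains (independent identical gains being the less likely event).
#' The pattern class is `ubiquitous` (all taxa), `lineage_specific`
#' (exactly one taxon) or `clade_restricted` otherwise; the supporting
#' clade is the node whose leaf set equals the present set, when one
#' exists.
#'
#' @param group a `spacer_group`.
#' @param clades a [clade_model()] (or a rooted `phylo` tree).
#' @param identity_threshold minimum mean pairwise identity for reporting
#'   a shared consensus motif.
#' @return object of class `signature_pattern`: `locus`, `pattern_class`,
#'   `supporting_clade`, `gains`, `losses` (branch label vectors),
#'   `n_changes`, `shared_motif`.
#' @export
classify_pattern <- function(group, clades, identity_threshold = 0.6) {
  tree <- if (inherits(clades, "clade_model")) clades$tree else clades
  miss <- setdiff(tree$tip.label, names(group$presence))
  if (length(miss))
    stop("taxa without presence record: ", paste(miss, collapse = ", "))
  pres <- group$presence[tree$tip.label]

  states <- ifelse(pres, "present", "absent")
  space <- c("absent", "present")
  ## gain-averse costs: both change types cost ~1, gains epsilon more, so
  ## the minimum is taken over change count first, then gain count
  cost <- matrix(c(0, 1000, 1001, 0), 2, 2, byrow = TRUE,
                 dimnames = list(space, space))
  eng <- sankoff_engine(tree, as.list(states), space, cost)

  ## one canonical optimal labeling by greedy top-down backtracking
  ## (prefer the parent's state on ties, then absence)
  n_tip <- eng$n_tip
  po <- eng$po
  assign <- integer(nrow(eng$D))
  root_costs <- eng$D[eng$root, ]
  assign[eng$root] <- which(root_costs == min(root_costs))[1]
  for (e in rev(seq_len(nrow(po$edge)))) {
    u <- po$edge[e, 1]; v <- po$edge[e, 2]
    a <- assign[u]
    opts <- eng$cost[a, ] + eng$D[v, ]
    best <- which(opts == min(opts))
    assign[v] <- if (a %in% best) a else best[1]
  }
  gains <- character(0); losses <- character(0)
  for (e in seq_len(nrow(po$edge))) {
    u <- po$edge[e, 1]; v <- po$edge[e, 2]
    if (assign[u] == 1L && assign[v] == 2L)
      gains <- c(gains, eng$labels[v])
    if (assign[u] == 2L && assign[v] == 1L)
      losses <- c(losses, eng$labels[v])
  }

  pattern_class <- if (all(pres)) "ubiquitous"
                   else if (sum(pres) == 1L) "lineage_specific"
                   else "clade_restricted"
  supporting <- NA_character_
  if (sum(pres) >= 1L && !all(pres)) {
    present_set <- sort(names(pres)[pres])
    if (length(present_set) == 1L) supporting <- present_set
    else {
      for (nd in (n_tip + 1L):length(eng$labels)) {
        tips <- tree$tip.label[
          unlist(tips_below(tree, nd))]
        if (setequal(tips, present_set)) { supporting <- eng$labels[nd]; break }
      }
    }
  }
  shared_motif <- NA_character_
  if (length(group$members) == 1L) {
    shared_motif <- unname(group$members)
  } else if (mean_pairwise_identity(group$aligned) >= identity_threshold) {
    shared_motif <- aligned_consensus(group$aligned)
  }
  structure(list(locus = group$locus, pattern_class = pattern_class,
                 supporting_clade = supporting, gains = gains,
                 losses = losses, n_changes = length(gains) + length(losses),
                 shared_motif = shared_motif),
            class = "signature_pattern")
}

## tip numbers below a node (small-tree recursion; no phangorn dependency)
tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

#' @export
print.signature_pattern <- function(x, ...) {
  cat(sprintf("isp^%s: %s (%d gain(s), %d loss(es))%s\n", x$locus,
              x$pattern_class, length(x$gains), length(x$losses),
              if (!is.na(x$supporting_clade))
                paste0(" on ", x$supporting_clade) else ""))
  invisible(x)
}

#' Signature report for a set of spacer groups
#'
#' @param groups list of `spacer_group`s (from [group_spacers()]).
#' @param clades a [clade_model()].
#' @param ... passed to [classify_pattern()].
#' @return data frame: locus, class, clade, gains, losses, motif.
#' @export
signature_report <- function(groups, clades, ...) {
  rows <- lapply(groups, function(g) {
    p <- classify_pattern(g, clades, ...)
    data.frame(locus = p$locus, class = p$pattern_class,
               clade = p$supporting_clade,
               gains = paste(p$gains, collapse = ","),
               losses = paste(p$losses, collapse = ","),
               motif = p$shared_motif, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Extract DHU and TPsiC loop motifs from annotated cloverleafs
#'
#' @param cloverleafs nested list taxon -> tRNA -> cloverleaf (from
#'   [annotate_genomes()]).
#' @return data frame with `taxon`, `trna`, `loop`, `motif`.
#' @export
extract_loop_motifs <- function(cloverleafs) {
  rows <- list()
  for (tx in names(cloverleafs)) {
    for (tr in names(TRNA_ANTICODONS)) {
      cl <- cloverleafs[[tx]][[tr]]
      if (is.null(cl)) {
        warning("missing tRNA ", tr, " for ", tx, "; row omitted")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, trna = tr, loop = c("DHU", "TPsiC"),
        motif = c(cl$loops$DHU$seq, cl$loops$TPsiC$seq),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Clade-diagnostic loop motifs
#'
#' For each clade and each tRNA loop, the minimal IUPAC consensus of the
#' clade members' loops (position-wise union of observed bases) is
#' reported when it is diagnostic: every clade member matches it, no
#' non-member does, and it has at most `max_degeneracy` degenerate
#' positions.  Loops of unequal length within a clade admit no consensus.
#'
#' @param motif_table data frame from [extract_loop_motifs()].
#' @param clades a [clade_model()] (or named assignment vector).
#' @param max_degeneracy maximum number of degenerate (non-ACGT) consensus
#'   positions.
#' @param groups clade labels to test (default: all except `outgroup`).
#' @return data frame: clade, trna, loop, consensus.
#' @export
diagnostic_motifs <- function(motif_table, clades, max_degeneracy = 2L,
                              groups = NULL) {
  assignment <- if (inherits(clades, "clade_model")) clades$assignment
                else clades
  if (length(unique(assignment[unique(motif_table$taxon)])) < 2L)
    stop("diagnostic search needs at least two clades")
  if (is.null(groups))
    groups <- setdiff(sort(unique(assignment)), "outgroup")
  rows <- list()
  for (g in groups) {
    members <- names(assignment)[assignment == g]
    for (tr in unique(motif_table$trna)) for (lp in c("DHU", "TPsiC")) {
      sub <- motif_table[motif_table$trna == tr & motif_table$loop == lp, ]
      inm <- sub$motif[sub$taxon %in% members]
      outm <- sub$motif[!sub$taxon %in% members]
      if (length(inm) == 0L || length(inm) < length(members)) next
      cons <- iupac_consensus(inm)
      if (is.na(cons)) next
      if (iupac_degeneracy(cons) > max_degeneracy) next
      if (any(iupac_match(outm, cons))) next
      rows[[length(rows) + 1L]] <- data.frame(
        clade = g, trna = tr, loop = lp, consensus = cons,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(clade = character(0), trna = character(0),
                      loop = character(0), consensus = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
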