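## p-distance matrices and within/among-clade summaries.

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites per pair over their comparable sites.
#' Under pairwise deletion (default) a site is dropped for a pair when
#' either sequence carries a gap or any non-ACGT symbol; under complete
#' deletion such columns are dropped for all pairs first.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, or a character matrix (taxa x sites).
#' @param deletion `"pairwise"` or `"complete"`.
#' @return object of class `p_dist`: list with `taxa`, `values` (symmetric
#'   matrix, `NA` where a pair has no comparable site) and
#'   `comparable_sites` (per-pair counts).
#' @export
p_distance_matrix <- function(alignment, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- if (is.matrix(alignment)) alignment
       else {
         if (length(unique(nchar(alignment))) != 1L)
           stop("aligned sequences must have equal length")
         do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
       }
  if (is.null(rownames(m))) rownames(m) <- names(alignment)
  taxa <- rownames(m)
  good <- matrix(m %in% DNA_BASES, nrow = nrow(m))
  if (deletion == "complete") {
    keep <- colSums(good) == nrow(m)
    m <- m[, keep, drop = FALSE]
    good <- good[, keep, drop = FALSE]
  }
  n <- length(taxa)
  values <- matrix(0, n, n, dimnames = list(taxa, taxa))
  comp <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- good[i, ] & good[j, ]
    nc <- sum(ok)
    comp[i, j] <- comp[j, i] <- nc
    if (nc == 0L) {
      values[i, j] <- values[j, i] <- NA_real_
      warning("no comparable sites for pair ", taxa[i], " / ", taxa[j])
    } else {
      d <- sum(m[i, ok] != m[j, ok]) / nc
      values[i, j] <- values[j, i] <- d
    }
  }
  structure(list(taxa = taxa, values = values, comparable_sites = comp),
            class = "p_dist")
}

#' @export
print.p_dist <- function(x, digits = 3, ...) {
  cat("p-distance matrix (", length(x$taxa), " taxa)\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' Build a p_dist object from a precomputed matrix
#'
#' Used to analyse published distance tables directly.
#'
#' @param values symmetric numeric matrix with taxon dimnames.
#' @return a `p_dist` object (comparable-site counts unknown, set `NA`).
#' @export
as_p_dist <- function(values) {
  if (!isSymmetric(unname(values), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  structure(list(taxa = rownames(values), values = values,
                 comparable_sites = matrix(NA_integer_, nrow(values),
                                           ncol(values))),
            class = "p_dist")
}

#' Clade model: rooted tree plus taxon-to-clade assignment
#'
#' @param tree rooted `phylo` tree (or path to a Newick file).
#' @param assignment named character vector mapping taxa to clade labels
#'   (e.g. `"A"`, `"B"`, `"C"`, `"outgroup"`), or a path to a two-column
#'   TSV (`taxon`, `clade`).
#' @param check_monophyly verify that each non-outgroup clade is
#'   monophyletic on the tree.
#' @return object of class `clade_model`.
#' @export
clade_model <- function(tree, assignment, check_monophyly = TRUE) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.character(assignment) && length(assignment) == 1L) {
    df <- read_tsv(assignment)
    assignment <- setNames(df$clade, df$taxon)
  }
  missing <- setdiff(tree$tip.label, names(assignment))
  if (length(missing))
    stop("taxa without clade assignment: ", paste(missing, collapse = ", "))
  if (check_monophyly) {
    for (cl in setdiff(unique(assignment), "outgroup")) {
      tips <- intersect(names(assignment)[assignment == cl], tree$tip.label)
      if (length(tips) > 1L &&
          !ape::is.monophyletic(tree, tips))
        stop("clade ", cl, " is not monophyletic on the tree")
    }
  }
  structure(list(tree = tree, assignment = assignment),
            class = "clade_model")
}

#' @export
print.clade_model <- function(x, ...) {
  tab <- table(x$assignment)
  cat("clade_model:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = " "), "\n")
  invisible(x)
}

#' Within- and among-clade p-distance summaries
#'
#' Within-clade mean is the arithmetic mean over unordered pairs inside the
#' clade; among-clade means average all cross-clade pairs.  Outgroup taxa
#' are excluded from the summaries.  Values are reported at full precision
#' and rounded half-up to 3 decimals; dispersion is given both as the
#' sample SD over pairs and as a bootstrap SE over pairs (the published
#' "+/-" convention for such tables is ambiguous, so both are shown).
#'
#' @param dist a `p_dist` object.
#' @param clades a [clade_model()] (its tree is not needed here; a named
#'   assignment vector is also accepted).
#' @param n_boot bootstrap resamples for the SE.
#' @param seed seed for the bootstrap.
#' @return list of class `clade_summary` with data frames `within`
#'   (clade, n_pairs, mean, mean_3dp, sd, boot_se) and `among`
#'   (clade_a, clade_b, n_pairs, mean, mean_3dp).
#' @export
clade_summary <- function(dist, clades, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(dist, "p_dist"))
  assignment <- if (inherits(clades, "clade_model")) clades$assignment
                else clades
  taxa <- intersect(dist$taxa, names(assignment))
  cl <- assignment[taxa]
  groups <- setdiff(sort(unique(cl)), "outgroup")

  pair_values <- function(ta, tb) {
    v <- dist$values[ta, tb, drop = FALSE]
    if (identical(ta, tb)) v[upper.tri(v)] else as.vector(v)
  }
  set.seed(seed)
  within <- do.call(rbind, lapply(groups, function(g) {
    tg <- taxa[cl == g]
    if (length(tg) < 2L) {
      message("clade ", g, " has fewer than 2 taxa; within mean undefined")
      return(data.frame(clade = g, n_pairs = 0L, mean = NA_real_,
                        mean_3dp = NA_real_, sd = NA_real_,
                        boot_se = NA_real_))
    }
    v <- pair_values(tg, tg)
    boot <- vapply(seq_len(n_boot), function(i)
      mean(sample(v, replace = TRUE)), 0)
    data.frame(clade = g, n_pairs = length(v), mean = mean(v),
               mean_3dp = round_half_up(mean(v), 3L),
               sd = if (length(v) > 1L) sd(v) else 0,
               boot_se = sd(boot), stringsAsFactors = FALSE)
  }))
  pairs <- t(combn(groups, 2L))
  among <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    ta <- taxa[cl == pairs[k, 1]]; tb <- taxa[cl == pairs[k, 2]]
    v <- pair_values(ta, tb)
    data.frame(clade_a = pairs[k, 1], clade_b = pairs[k, 2],
               n_pairs = length(v), mean = mean(v),
               mean_3dp = round_half_up(mean(v), 3L),
               stringsAsFactors = FALSE)
  }))
  structure(list(within = within, among = among), class = "clade_summary")
}

#' @export
print.clade_summary <- function(x, ...) {
  cat("within-clade p-distances:\n")
  print(x$within, row.names = FALSE)
  cat("among-clade p-distances:\n")
  print(x$among, row.names = FALSE)
  invisible(x)
}

#' Read a printed lower-triangle distance table
#'
#' Parses a TSV whose first column holds taxon names and whose remaining
#' cells give the lower triangle of a distance matrix (empty above the
#' diagonal), as distance tables are usually typeset.
#'
#' @param path TSV file.
#' @return a `p_dist` object.
#' @export
read_pdist_table <- function(path) {
  df <- read_tsv(path)
  taxa <- df[[1]]
  n <- length(taxa)
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j >= i) next
    val <- suppressWarnings(as.numeric(df[i, j + 1L]))
    if (is.na(val)) stop("missing cell at row ", taxa[i], " col ", taxa[j])
    m[i, j] <- m[j, i] <- val
  }
  as_p_dist(m)
}

#' Write a p_dist object as TSV (full precision and 3-decimal copies)
#'
#' @param dist a `p_dist`.
#' @param path base path; a `_3dp` variant is written alongside.
#' @return invisibly, the paths written.
#' @export
write_pdist <- function(dist, path) {
  full <- data.frame(taxon = dist$taxa, dist$values, check.names = FALSE)
  write_tsv(full, path)
  p2 <- sub("(\\.[^.]+)$", "_3dp\\1", path)
  rd <- data.frame(taxon = dist$taxa, round_half_up(dist$values, 3L),
                   check.names = FALSE)
  write_tsv(rd, p2)
  invisible(c(path, p2))
}
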