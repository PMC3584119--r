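## Loaders for the packaged reference fixtures: the reference topology of
## the processionary-moth study system, its clade assignments, the printed
## pairwise p-distance tables, and a best-effort categorical trait matrix
## encoded from published life-history descriptions.

#' Path to a packaged fixture
#'
#' @param file file name under `extdata` (empty to list them).
#' @return file path.
#' @export
mitosig_extdata <- function(file = "") {
  if (!nzchar(file)) return(dir(system.file("extdata", package = "mitosig")))
  p <- system.file("extdata", file, package = "mitosig")
  if (!nzchar(p)) stop("no packaged file ", file)
  p
}

#' Reference tree of the study system
#'
#' Rooted topology with the three ingroup clades (A: Angiosperm feeders;
#' B: winter pine processionary moths; C: summer pine/cedar processionary
#' moths) and three outgroups.
#'
#' @return a `phylo` tree.
#' @export
load_reference_tree <- function() {
  ape::read.tree(mitosig_extdata("reference_tree.nwk"))
}

#' Reference clade model (tree + A/B/C/outgroup assignment)
#'
#' @return a [clade_model()].
#' @export
load_reference_clades <- function() {
  clade_model(load_reference_tree(), mitosig_extdata("clades.tsv"))
}

#' Published pairwise p-distance tables
#'
#' The printed lower-triangle p-distance matrices for the concatenated
#' mitochondrial protein-coding set (`mtpcg`) and the three-gene nuclear
#' set (`nuc3`).
#'
#' @param set `"mtpcg"` or `"nuc3"`.
#' @return a `p_dist` object.
#' @export
load_published_pdist <- function(set = c("mtpcg", "nuc3")) {
  set <- match.arg(set)
  read_pdist_table(mitosig_extdata(paste0("pdist_", set, ".tsv")))
}

#' Life-history trait matrix of the study taxa
#'
#' Categorical characters (host plant class, foliage age, foraging type,
#' tent, pupation site, overwintering stage, adult front, foreleg tibia
#' spine, egg-scale size, urticating setae) encoded from published
#' descriptions of the species; cells that could not be established are
#' `"?"`.
#'
#' @return data frame with a `taxon` column and one column per trait.
#' @export
load_reference_traits <- function() {
  read_tsv(mitosig_extdata("traits.tsv"))
}
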