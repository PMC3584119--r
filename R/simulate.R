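## Synthetic mitogenome generator.  Produces a rooted tree with three ingroup
## clades plus outgroups, evolves the three lepidopteran mitogenome segments
## and a set of nuclear CDS along it under an HKY/GTR+G model, applies
## branch-addressed intergenic-spacer and tRNA-loop events, and emits full
## ground truth (feature table, spacer presence, loop motifs, trait matrix
## and ancestral states) so downstream stages can be validated exactly.

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: a 3-clade ingroup
#' with outgroups, AT-rich insect mitochondrial base composition, gamma rate
#' heterogeneity, branch-specific spacer gains and clade-specific tRNA-loop
#' substitutions, and categorical traits with known ancestral assignments.
#'
#' Default events place: a spacer between `trnK` and `trnD` gained on the
#' ingroup stem (ubiquitous in the ingroup, absent in outgroups), a spacer
#' between `atp6` and `cox3` gained on the B+C stem, a `CT` spacer between
#' `cox1` and `trnL2` gained on the clade-A cherry, and a lineage-specific
#' spacer between `trnL1` and `rrnL` on the first outgroup; loop events mark
#' clade C (TPsiC loop of `trnD`), clade A (DHU loop of `trnD`) and one
#' clade-B terminal (TPsiC loop of `trnH`).
#'
#' @param clade_sizes integer vector of exactly three ingroup clade sizes.
#' @param n_outgroups number of outgroup taxa (>= 1).
#' @param seed integer seed; the whole truth bundle is reproducible from it.
#' @param model a [subst_model()].
#' @param branch_length_range range (substitutions/site) for branch lengths.
#' @param spacer_events list of spacer gain/loss events; each a list with
#'   `locus` (`"geneX-geneY"`), `branch` (tip or internal node label),
#'   `seq` (gained sequence) and optional `action` (`"gain"`/`"loss"`).
#' @param loop_events list of tRNA loop replacements; each a list with
#'   `trna`, `loop` (`"DHU"`/`"TPsiC"`), `branch`, `motif`.  The replaced
#'   loop is held fixed below the event branch so it stays a signature.
#' @param trait_spec list of traits; each a list with `name`, `states`,
#'   `root` and `events` (lists with `branch`, `to`).
#' @param stem_rate_scale branch-length multiplier for tRNA stem
#'   positions (pairing constraint; loops evolve at the full rate).
#' @param indel_rate per-site indel rate (per substitution unit of branch
#'   length) applied only to rRNA and control-region features.
#' @param nuclear named integer vector of nuclear CDS lengths (nt,
#'   divisible by 3).
#' @param nuclear_rate_scale branch-length multiplier for nuclear genes.
#' @param nuclear_missing named list: gene -> taxa without that gene.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(clade_sizes = c(3L, 3L, 4L),
                       n_outgroups = 3L,
                       seed = 1L,
                       model = subst_model(),
                       branch_length_range = c(0.01, 0.04),
                       stem_rate_scale = 0.1,
                       spacer_events = default_spacer_events(),
                       loop_events = default_loop_events(),
                       trait_spec = default_trait_spec(),
                       indel_rate = 0.02,
                       nuclear = c(EF1a = 999L, wng = 309L, pho = 651L),
                       nuclear_rate_scale = 0.3,
                       nuclear_missing = list(pho = c("OG2", "OG3"))) {
  if (length(clade_sizes) != 3L || any(clade_sizes < 1L))
    stop("configuration error: clade_sizes must be three integers >= 1")
  if (n_outgroups < 1L)
    stop("configuration error: n_outgroups must be >= 1")
  if (!inherits(model, "subst_model")) stop("model must be a subst_model")
  if (length(branch_length_range) != 2L || any(branch_length_range < 0) ||
      diff(branch_length_range) < 0)
    stop("configuration error: invalid branch_length_range")
  if (any(nuclear %% 3L != 0L)) stop("nuclear CDS lengths must be codons")
  structure(list(
    clade_sizes = as.integer(clade_sizes),
    n_ingroup_taxa = sum(as.integer(clade_sizes)),
    n_outgroups = as.integer(n_outgroups),
    seed = as.integer(seed), model = model,
    branch_length_range = branch_length_range,
    spacer_events = spacer_events, loop_events = loop_events,
    trait_spec = trait_spec, indel_rate = indel_rate,
    stem_rate_scale = stem_rate_scale,
    nuclear = nuclear, nuclear_rate_scale = nuclear_rate_scale,
    nuclear_missing = nuclear_missing), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d ingroup taxa in clades (%s) + %d outgroups, seed %d\n",
    x$n_ingroup_taxa, paste(x$clade_sizes, collapse = ","),
    x$n_outgroups, x$seed))
  cat(sprintf("  %d spacer events, %d loop events, %d traits\n",
              length(x$spacer_events), length(x$loop_events),
              length(x$trait_spec)))
  invisible(x)
}

#' @rdname sim_config
#' @export
default_spacer_events <- function() {
  list(
    list(locus = "trnK-trnD", branch = "ingroup", seq = "ATTTA"),
    ## C-heavy spacer: no single substitution can create a legitimate
    ## in-frame start codon upstream of the downstream gene
    list(locus = "atp6-cox3", branch = "cladeBC",
         seq = substr(strrep("CCT", 7L), 1L, 20L)),
    list(locus = "cox1-trnL2", branch = "cladeA_1", seq = "CT"),
    ## lineage-specific spacer on the first outgroup; placed between cob
    ## and trnS2 because a spacer flanking rrnL would be absorbed by the
    ## tRNA-delimited rRNA boundary rule at annotation time
    list(locus = "cob-trnS2", branch = "OG1",
         seq = "TTAATATTAATTTAAT"))
}

#' @rdname sim_config
#' @export
default_loop_events <- function() {
  list(
    list(trna = "trnD", loop = "TPsiC", branch = "cladeC", motif = "ATTTAAT"),
    list(trna = "trnD", loop = "DHU",   branch = "cladeA", motif = "ATATTAA"),
    list(trna = "trnH", loop = "TPsiC", branch = "B2",     motif = "ATGAAT"))
}

#' @rdname sim_config
#' @export
default_trait_spec <- function() {
  list(
    list(name = "host_class", states = c("Angiosperm", "Gymnosperm"),
         root = "Angiosperm",
         events = list(list(branch = "cladeBC", to = "Gymnosperm"))),
    list(name = "front", states = c("smooth", "crested"), root = "smooth",
         events = list(list(branch = "cladeBC", to = "crested"),
                       list(branch = "A2", to = "crested"))),
    list(name = "foraging",
         states = c("central_place", "patch_restricted", "nomadic"),
         root = "central_place",
         events = list(list(branch = "cladeC", to = "patch_restricted"),
                       list(branch = "A1", to = "patch_restricted"))))
}

## --------------------------------------------------------------------------
## Tree simulation

## caterpillar subtree newick for one clade: (X1,(X2,(X3,X4)X_2)X_1)cladeX
clade_newick <- function(letter, n, bl) {
  tips <- paste0(letter, seq_len(n))
  if (n == 1L) return(tips)
  node <- tips[n]
  for (i in rev(seq_len(n - 1L))) {
    lab <- if (i == 1L) paste0("clade", letter)
           else paste0("clade", letter, "_", i - 1L)
    node <- sprintf("(%s:%.8f,%s:%.8f)%s", tips[i], bl(), node, bl(), lab)
  }
  node
}

#' Simulate the study tree
#'
#' Rooted binary tree with a monophyletic ingroup split into three labelled
#' monophyletic clades (A, (B, C)), and outgroups attached as successive
#' sisters below the ingroup.  Internal nodes carry stable labels
#' (`cladeA`, `cladeB`, `cladeC`, `cladeBC`, `ingroup`, `cladeA_1`, ...,
#' `root_1`, ...) so that events can address branches; each branch is
#' identified by the label of its child node.  Branch lengths are drawn
#' uniformly from `branch_length_range`.
#'
#' @param cfg a [sim_config()].
#' @return an `ape::phylo` tree with node labels and branch lengths.
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rng <- cfg$branch_length_range
  bl <- function() runif(1L, rng[1], rng[2])
  a <- clade_newick("A", cfg$clade_sizes[1], bl)
  b <- clade_newick("B", cfg$clade_sizes[2], bl)
  c_ <- clade_newick("C", cfg$clade_sizes[3], bl)
  bc <- sprintf("(%s:%.8f,%s:%.8f)cladeBC", b, bl(), c_, bl())
  node <- sprintf("(%s:%.8f,%s:%.8f)ingroup", a, bl(), bc, bl())
  for (i in seq_len(cfg$n_outgroups)) {
    lab <- if (i == cfg$n_outgroups) "root" else paste0("root_", i)
    node <- sprintf("(%s:%.8f,OG%d:%.8f)%s", node, bl(), i, bl(), lab)
  }
  tree <- ape::read.tree(text = paste0(node, ";"))
  tree
}

## node label lookup (tips then internals, in ape numbering)
node_labels <- function(tree) c(tree$tip.label, tree$node.label)

## children edges of each node, in cladewise order for determinism
tree_children <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  split(seq_len(nrow(tree$edge)), tree$edge[, 1])
}

branch_labels <- function(tree) node_labels(tree)[tree$edge[, 2]]

## --------------------------------------------------------------------------
## Root genome construction.  A genome is a list of segments; each segment a
## list of features; each feature keeps its parts as integer state vectors in
## gene orientation, plus per-part gamma categories and protection flags.

LEGIT_START_INT <- t(vapply(LEGIT_STARTS, dna_to_int, integer(3)))
STOP_INT <- t(vapply(MITO_STOPS, dna_to_int, integer(3)))

codon_matches <- function(states, table) {
  any(apply(table, 1L, function(cod) all(states == cod)))
}

## random codons with no stop
draw_codons <- function(n, base_freq) {
  out <- integer(3L * n)
  for (i in seq_len(n)) {
    repeat {
      cod <- draw_bases(3L, base_freq)
      if (!codon_matches(cod, STOP_INT)) break
    }
    out[(3L * i - 2L):(3L * i)] <- cod
  }
  out
}

new_part <- function(states, ncat, protect = FALSE) {
  list(states = states,
       cats = sample.int(ncat, length(states), replace = TRUE),
       protect = protect)
}

make_pcg_feature <- function(name, strand, len, trunc, model) {
  rem_len <- nchar(trunc)
  ncod <- (len - rem_len) %/% 3L
  stopifnot((len - rem_len) %% 3L == 0L, ncod >= 3L)
  body <- if (rem_len > 0L) {
    c(dna_to_int("ATG"), draw_codons(ncod - 1L, model$base_freq))
  } else {
    c(dna_to_int("ATG"), draw_codons(ncod - 2L, model$base_freq),
      dna_to_int("TAA"))
  }
  ## canonical atp8/atp6 junction: atp8 ends ..CCA TGA TAA with atp6's
  ## ATG ATA A.. overlapping its last 7 nt; the 7 shared bases are held
  ## fixed on both features so the overlap stays annotatable.
  frozen <- integer(0)
  if (name == "atp8") {
    tail_seq <- dna_to_int("CCATGATAA")
    body[(length(body) - 8L):length(body)] <- tail_seq
    frozen <- (length(body) - 6L):length(body)
  } else if (name == "atp6") {
    body[1:7] <- dna_to_int("ATGATAA")
    frozen <- 1:7
  }
  parts <- list(cds = new_part(body, model$ncat))
  if (rem_len > 0L)
    parts$rem <- new_part(dna_to_int(trunc), model$ncat, protect = TRUE)
  list(feature = name, type = "PCG", strand = strand, parts = parts,
       frozen = frozen,
       overlap_prev = if (name == "atp6") ATP6_OVERLAP else 0L)
}

make_trna_feature <- function(name, strand, anticodon, model) {
  g <- CLOVERLEAF_GEOMETRY
  f <- model$base_freq
  stem <- function(n) draw_bases(n, f)
  comp <- function(s) rev(c(4L, 3L, 2L, 1L)[s])  # A<->T, C<->G on ints
  acc <- stem(g$acc); ds <- stem(g$dstem); as_ <- stem(g$acstem)
  ts <- stem(g$tstem)
  ## a tRNA that abuts a truncated-stop gene must not complete the T/TA
  ## remainder into a full TAA/TAG stop with its first acceptor bases,
  ## otherwise the truncation would be unannotatable by construction;
  ## those junction bases are constrained and held fixed
  freeze <- NULL
  if (name == "trnK") {          # follows the T remainder of cox2
    while (acc[1] == 1L && acc[2] %in% c(1L, 3L))
      acc[1:2] <- draw_bases(2L, f)
    freeze <- list(acc5 = 1:2)
  } else if (name == "trnH") {   # follows the TA remainder of nad4
    while (acc[1] %in% c(1L, 3L)) acc[1] <- draw_bases(1L, f)
    freeze <- list(acc5 = 1L)
  }
  parts <- list(
    acc5   = new_part(acc, model$ncat),
    dstem  = new_part(ds, model$ncat),
    dloop  = new_part(draw_bases(g$dloop, f), model$ncat),
    dstem2 = new_part(comp(ds), model$ncat),
    acstem = new_part(as_, model$ncat),
    acl1   = new_part(draw_bases((g$acloop - 3L) %/% 2L, f), model$ncat),
    anticodon = new_part(dna_to_int(anticodon), model$ncat, protect = TRUE),
    acl2   = new_part(draw_bases(g$acloop - 3L - (g$acloop - 3L) %/% 2L, f),
                      model$ncat),
    acstem2 = new_part(comp(as_), model$ncat),
    tstem  = new_part(ts, model$ncat),
    tloop  = new_part(draw_bases(g$tloop, f), model$ncat),
    tstem2 = new_part(comp(ts), model$ncat),
    acc3   = new_part(comp(acc), model$ncat))
  list(feature = name, type = "tRNA", strand = strand,
       parts = parts, freeze = freeze)
}

## random AT-biased block (rRNA / control region / spacers)
make_block_feature <- function(name, type, strand, len, model, at = 0.7) {
  f <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  list(feature = name, type = type, strand = strand,
       parts = list(seq = new_part(draw_bases(len, f), model$ncat)))
}

make_spacer_feature <- function(locus, seq, model) {
  list(feature = locus, type = "spacer", strand = "+",
       parts = list(seq = new_part(dna_to_int(seq), model$ncat)))
}

build_root_genome <- function(cfg) {
  model <- cfg$model
  g <- CLOVERLEAF_GEOMETRY
  canon <- c(g$dstem, g$dloop, (g$acloop - 3L) %/% 2L, g$tstem, g$tloop)
  genome <- lapply(segment_templates(), function(tpl) {
    feats <- list()
    for (i in seq_len(nrow(tpl$features))) {
      row <- tpl$features[i, ]
      feat <- switch(row$type,
        PCG = make_pcg_feature(row$feature, row$strand, row$len, row$trunc,
                               model),
        tRNA = make_trna_feature(row$feature, row$strand,
                                 TRNA_ANTICODONS[[row$feature]], model),
        rRNA = make_block_feature(row$feature, "rRNA", row$strand, row$len,
                                  model),
        control_region = make_block_feature(row$feature, "control_region",
                                            row$strand, row$len, model,
                                            at = 0.85))
      feats[[length(feats) + 1L]] <- feat
      ## root-level ubiquitous spacers
      locus_after <- names(ROOT_SPACERS)[
        vapply(names(ROOT_SPACERS),
               function(l) strsplit(l, "-")[[1]][1] == row$feature, NA)]
      for (l in locus_after) {
        sp <- make_block_feature(l, "spacer", "+", ROOT_SPACERS[[l]], model,
                                 at = 0.7)
        feats[[length(feats) + 1L]] <- sp
      }
    }
    seg <- list(segment_id = tpl$segment_id, features = feats)
    ## every root tRNA must fold into its intended cloverleaf *in segment
    ## context*, and robustly so: the canonical fold must beat any
    ## alternative-span fold by a clear margin, otherwise a couple of
    ## substitutions could make the fold boundaries ambiguous on some
    ## lineage.  tRNAs failing the check are redrawn (stems and loops).
    trna_idx <- which(vapply(seg$features, `[[`, "", "type") == "tRNA")
    for (idx in trna_idx) {
      name <- seg$features[[idx]]$feature
      for (try in 1:100) {
        em <- emit_segment(seg, "root")
        row <- em$features[em$features$feature == name, ]
        hit <- find_cloverleaf(
          em$sequence, name, TRNA_ANTICODONS[[name]], row$strand,
          window = c(max(0L, row$start - 120L),
                     min(nchar(em$sequence), row$end + 120L)),
          margin = TRUE)
        if (!is.null(hit) && hit$annotation$start == row$start &&
            hit$annotation$end == row$end &&
            identical(hit$cloverleaf$geometry, canon) &&
            hit$cloverleaf$margin >= 5)
          break
        seg$features[[idx]] <- make_trna_feature(
          name, seg$features[[idx]]$strand, TRNA_ANTICODONS[[name]], model)
      }
    }
    seg
  })
  genome
}

## --------------------------------------------------------------------------
## Evolution along a branch

## revert codons that break the reading frame (created stop, broken start,
## broken terminal stop) back to the parent codon
repair_cds <- function(child, parent, has_rem) {
  n <- length(child) %/% 3L
  idx <- function(i) (3L * i - 2L):(3L * i)
  if (!codon_matches(child[idx(1L)], LEGIT_START_INT))
    child[idx(1L)] <- parent[idx(1L)]
  last_internal <- if (has_rem) n else n - 1L
  for (i in seq_len(last_internal)[-1L]) {
    if (codon_matches(child[idx(i)], STOP_INT))
      child[idx(i)] <- parent[idx(i)]
  }
  if (!has_rem && !codon_matches(child[idx(n)], STOP_INT))
    child[idx(n)] <- parent[idx(n)]
  child
}

apply_indels <- function(part, t, rate, model) {
  len <- length(part$states)
  n_ev <- rpois(1L, rate * len * t)
  if (n_ev == 0L) return(part)
  for (ev in seq_len(n_ev)) {
    len <- length(part$states)
    if (len < 10L) break
    pos <- sample.int(len, 1L)
    size <- sample.int(4L, 1L)
    if (runif(1L) < 0.5) {     # deletion
      del <- pos:min(len, pos + size - 1L)
      part$states <- part$states[-del]
      part$cats <- part$cats[-del]
    } else {                   # insertion after pos
      ins <- draw_bases(size, model$base_freq)
      part$states <- append(part$states, ins, after = pos)
      part$cats <- append(part$cats,
                          sample.int(model$ncat, size, replace = TRUE),
                          after = pos)
    }
  }
  part
}

TRNA_STEM_PARTS <- c("acc5", "dstem", "dstem2", "acstem", "acstem2",
                     "tstem", "tstem2", "acc3")

evolve_feature <- function(feat, t, cfg) {
  model <- cfg$model
  parent_parts <- feat$parts
  for (p in names(feat$parts)) {
    part <- feat$parts[[p]]
    if (isTRUE(part$protect) || length(part$states) == 0L) next
    ## tRNA stems are under pairing (secondary-structure) constraint and
    ## evolve slower than the loops
    t_eff <- if (feat$type == "tRNA" && p %in% TRNA_STEM_PARTS)
      t * cfg$stem_rate_scale else t
    part$states <- evolve_states(part$states, part$cats, t_eff, model)
    feat$parts[[p]] <- part
  }
  if (feat$type == "PCG") {
    feat$parts$cds$states <- repair_cds(feat$parts$cds$states,
                                        parent_parts$cds$states,
                                        has_rem = !is.null(feat$parts$rem))
    if (length(feat$frozen))
      feat$parts$cds$states[feat$frozen] <-
        parent_parts$cds$states[feat$frozen]
  }
  if (feat$type %in% c("rRNA", "control_region") && cfg$indel_rate > 0) {
    feat$parts$seq <- apply_indels(feat$parts$seq, t, cfg$indel_rate, model)
  }
  if (!is.null(feat$freeze))
    for (p in names(feat$freeze))
      feat$parts[[p]]$states[feat$freeze[[p]]] <-
        parent_parts[[p]]$states[feat$freeze[[p]]]
  feat
}

evolve_genome_branch <- function(genome, t, cfg) {
  lapply(genome, function(seg) {
    seg$features <- lapply(seg$features, evolve_feature, t = t, cfg = cfg)
    seg
  })
}

## --------------------------------------------------------------------------
## Events

spacer_locus_parts <- function(locus) strsplit(locus, "-", fixed = TRUE)[[1]]

apply_spacer_event <- function(genome, ev, cfg) {
  pair <- spacer_locus_parts(ev$locus)
  action <- if (is.null(ev$action)) "gain" else ev$action
  for (s in seq_along(genome)) {
    feats <- genome[[s]]$features
    nms <- vapply(feats, `[[`, "", "feature")
    i <- match(pair[1], nms)
    if (is.na(i)) next
    j <- match(pair[2], nms)
    if (is.na(j) || j < i)
      stop("configuration error: spacer locus ", ev$locus,
           " does not flank adjacent features")
    have <- match(ev$locus, nms)
    if (action == "gain") {
      if (!is.na(have))
        stop("configuration error: spacer ", ev$locus, " already present")
      sp <- make_spacer_feature(ev$locus, ev$seq, cfg$model)
      genome[[s]]$features <- append(feats, list(sp), after = i)
    } else {
      if (is.na(have))
        stop("configuration error: spacer ", ev$locus, " not present to lose")
      genome[[s]]$features <- feats[-have]
    }
    return(genome)
  }
  stop("configuration error: unknown spacer locus ", ev$locus)
}

apply_loop_event <- function(genome, ev, cfg) {
  part <- switch(ev$loop, DHU = "dloop", TPsiC = "tloop",
                 stop("configuration error: loop must be DHU or TPsiC"))
  for (s in seq_along(genome)) {
    feats <- genome[[s]]$features
    nms <- vapply(feats, `[[`, "", "feature")
    i <- match(ev$trna, nms)
    if (is.na(i)) next
    states <- dna_to_int(ev$motif)
    genome[[s]]$features[[i]]$parts[[part]] <-
      list(states = states,
           cats = sample.int(cfg$model$ncat, length(states), replace = TRUE),
           protect = TRUE)
    return(genome)
  }
  stop("configuration error: unknown tRNA ", ev$trna)
}

## --------------------------------------------------------------------------
## Emission

feature_sequence <- function(feat) {
  s <- unlist(lapply(feat$parts, `[[`, "states"), use.names = FALSE)
  int_to_dna(s)
}

## build the plus-strand segment string and the 0-based feature table rows;
## a feature with `overlap_prev` shares its first bases with the previous
## feature (the atp8/atp6 junction) and they are emitted only once
emit_segment <- function(seg, taxon) {
  pos <- 0L
  rows <- list(); chunks <- character(0)
  for (feat in seg$features) {
    s <- feature_sequence(feat)
    if (feat$strand == "-") s <- revcomp(s)
    len <- nchar(s)
    ov <- feat$overlap_prev %||% 0L
    rows[[length(rows) + 1L]] <- data.frame(
      taxon = taxon, segment = seg$segment_id, feature = feat$feature,
      type = feat$type, start = pos - ov, end = pos - ov + len,
      strand = feat$strand, stringsAsFactors = FALSE)
    chunks <- c(chunks, substring(s, ov + 1L))
    pos <- pos + len - ov
  }
  list(sequence = paste(chunks, collapse = ""),
       features = do.call(rbind, rows))
}

emit_loops <- function(genome, taxon) {
  rows <- list()
  for (seg in genome) for (feat in seg$features) {
    if (feat$type != "tRNA") next
    rows[[length(rows) + 1L]] <- data.frame(
      taxon = taxon, trna = feat$feature,
      loop = c("DHU", "TPsiC"),
      motif = c(int_to_dna(feat$parts$dloop$states),
                int_to_dna(feat$parts$tloop$states)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## --------------------------------------------------------------------------
## Full genome + trait evolution

#' Evolve genomes, nuclear CDS and traits along a simulated tree
#'
#' Builds the root genome from the lepidopteran segment templates (valid ORFs
#' under the invertebrate mitochondrial code, perfect cloverleaf tRNAs,
#' AT-biased rRNA and control-region blocks), evolves it along the tree under
#' the configured substitution model with gamma rate heterogeneity (indels
#' confined to rRNA / control region), applies spacer and loop events on
#' their branches, and emits a truth bundle.
#'
#' @param tree tree from [simulate_tree()] (it is re-simulated from the
#'   config seed if omitted).
#' @param cfg a [sim_config()].
#' @return an object of class `truth_bundle`: list with `tree`, `segments`
#'   (taxon -> segment -> sequence), `features` (0-based half-open truth
#'   annotation table), `spacer_presence` (locus x taxon lengths), `loops`
#'   (taxon/trna/loop/motif), `traits` (taxon x trait data frame),
#'   `trait_ancestral` (node x trait), and `nuclear` (gene -> named
#'   character vector of CDS).
#' @export
evolve_genomes <- function(tree = NULL, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(tree)) tree <- simulate_tree(cfg)
  labels <- node_labels(tree)
  valid <- labels
  for (ev in cfg$spacer_events)
    if (!ev$branch %in% valid)
      stop("configuration error: spacer event on unknown branch ", ev$branch)
  for (ev in cfg$loop_events)
    if (!ev$branch %in% valid)
      stop("configuration error: loop event on unknown branch ", ev$branch)
  for (tr in cfg$trait_spec)
    for (ev in tr$events)
      if (!ev$branch %in% valid)
        stop("configuration error: trait event on unknown branch ", ev$branch)

  set.seed(cfg$seed + 1L)
  root_genome <- build_root_genome(cfg)
  model <- cfg$model

  ## nuclear root CDS
  nuclear_root <- lapply(cfg$nuclear, function(len) {
    list(feature = "nuc", type = "PCG", strand = "+",
         parts = list(cds = new_part(
           c(dna_to_int("ATG"), draw_codons(len %/% 3L - 2L, model$base_freq),
             dna_to_int("TAA")), model$ncat)))
  })

  root_traits <- setNames(
    vapply(cfg$trait_spec, `[[`, "", "root"),
    vapply(cfg$trait_spec, `[[`, "", "name"))

  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  kids <- split(seq_len(nrow(tree_cw$edge)), tree_cw$edge[, 1])

  segments <- list(); features <- list(); loops <- list()
  traits_rows <- list(); anc_rows <- list(); nuc_out <- list()
  spacer_rows <- list()

  record_node_traits <- function(label, traits) {
    anc_rows[[length(anc_rows) + 1L]] <<- data.frame(
      node = label, trait = names(traits), state = unname(traits),
      stringsAsFactors = FALSE)
  }

  recurse <- function(node, genome, nuclear, traits) {
    label <- labels[node]
    if (node <= n_tip) {
      for (seg in genome) {
        em <- emit_segment(seg, label)
        segments[[label]][[seg$segment_id]] <<- em$sequence
        features[[length(features) + 1L]] <<- em$features
      }
      loops[[length(loops) + 1L]] <<- emit_loops(genome, label)
      traits_rows[[length(traits_rows) + 1L]] <<- data.frame(
        taxon = label, t(traits), stringsAsFactors = FALSE)
      for (g in names(nuclear)) {
        if (label %in% (cfg$nuclear_missing[[g]] %||% character(0))) next
        nuc_out[[g]][label] <<- feature_sequence(nuclear[[g]])
      }
      for (seg in genome) for (feat in seg$features) {
        if (feat$type == "spacer")
          spacer_rows[[length(spacer_rows) + 1L]] <<- data.frame(
            taxon = label, locus = feat$feature,
            length = length(feat$parts$seq$states), stringsAsFactors = FALSE)
      }
      return(invisible(NULL))
    }
    record_node_traits(label, traits)
    for (e in kids[[as.character(node)]]) {
      child <- tree_cw$edge[e, 2]
      t_len <- tree_cw$edge.length[e]
      child_label <- labels[child]
      g2 <- evolve_genome_branch(genome, t_len, cfg)
      n2 <- lapply(nuclear, evolve_feature, t = t_len * cfg$nuclear_rate_scale,
                   cfg = cfg)
      tr2 <- traits
      for (ev in cfg$spacer_events)
        if (ev$branch == child_label) g2 <- apply_spacer_event(g2, ev, cfg)
      for (ev in cfg$loop_events)
        if (ev$branch == child_label) g2 <- apply_loop_event(g2, ev, cfg)
      for (tr in cfg$trait_spec)
        for (ev in tr$events)
          if (ev$branch == child_label) {
            if (!ev$to %in% tr$states)
              stop("configuration error: state ", ev$to,
                   " not in trait ", tr$name)
            tr2[[tr$name]] <- ev$to
          }
      recurse(child, g2, n2, tr2)
    }
  }
  recurse(root_node, root_genome, nuclear_root, root_traits)

  features <- do.call(rbind, features)
  rownames(features) <- NULL
  spacers <- do.call(rbind, spacer_rows)
  taxa <- tree$tip.label
  loci <- unique(spacers$locus)
  presence <- matrix(0L, length(loci), length(taxa),
                     dimnames = list(loci, taxa))
  for (i in seq_len(nrow(spacers)))
    presence[spacers$locus[i], spacers$taxon[i]] <- spacers$length[i]

  traits_df <- do.call(rbind, traits_rows)
  rownames(traits_df) <- NULL

  structure(list(
    tree = tree, config = cfg,
    segments = segments, features = features,
    spacer_presence = presence,
    loops = do.call(rbind, loops),
    traits = traits_df,
    trait_ancestral = do.call(rbind, anc_rows),
    nuclear = lapply(nuc_out, unlist)), class = "truth_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("truth_bundle: %d taxa, %d segments each, %d spacer loci, %d traits\n",
              length(x$segments), length(x$segments[[1]]),
              nrow(x$spacer_presence), ncol(x$traits) - 1L))
  invisible(x)
}

#' Simulate a plain alignment on a tree
#'
#' Gap-free alignment simulator under the same substitution engine; used for
#' phylogenetic-signal experiments where only site patterns matter.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param n_sites number of alignment columns.
#' @param model a [subst_model()].
#' @param seed integer seed.
#' @return named character vector of sequences (one per tip).
#' @export
simulate_alignment <- function(tree, n_sites, model = subst_model(),
                               seed = 1L) {
  set.seed(seed)
  labels <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  kids <- split(seq_len(nrow(tree_cw$edge)), tree_cw$edge[, 1])
  cats <- sample.int(model$ncat, n_sites, replace = TRUE)
  root <- draw_bases(n_sites, model$base_freq)
  out <- character(n_tip); names(out) <- tree$tip.label
  recurse <- function(node, states) {
    if (node <= n_tip) {
      out[labels[node]] <<- int_to_dna(states)
      return(invisible(NULL))
    }
    for (e in kids[[as.character(node)]]) {
      child <- tree_cw$edge[e, 2]
      recurse(child, evolve_states(states, cats, tree_cw$edge.length[e],
                                   model))
    }
  }
  recurse(n_tip + 1L, root)
  out
}

#' Write a truth bundle to plain-text files
#'
#' Emits `segments.fasta` (headers `taxon|segment`), `tree.nwk`,
#' `features.tsv` (0-based half-open), `spacer_presence.tsv`, `loops.tsv`,
#' `traits.tsv`, `trait_ancestral.tsv` and one FASTA per nuclear gene.
#'
#' @param bundle a `truth_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_truth_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- unlist(lapply(names(bundle$segments), function(tx)
    setNames(unlist(bundle$segments[[tx]]),
             paste0(tx, "|", names(bundle$segments[[tx]])))))
  files <- file.path(dir, c("segments.fasta", "tree.nwk", "features.tsv",
                            "spacer_presence.tsv", "loops.tsv", "traits.tsv",
                            "trait_ancestral.tsv"))
  write_fasta(seqs, files[1])
  ape::write.tree(bundle$tree, file = files[2])
  write_tsv(bundle$features, files[3])
  write_tsv(data.frame(locus = rownames(bundle$spacer_presence),
                       bundle$spacer_presence, check.names = FALSE),
            files[4])
  write_tsv(bundle$loops, files[5])
  write_tsv(bundle$traits, files[6])
  write_tsv(bundle$trait_ancestral, files[7])
  for (g in names(bundle$nuclear)) {
    f <- file.path(dir, paste0("nuclear_", g, ".fasta"))
    write_fasta(bundle$nuclear[[g]], f)
    files <- c(files, f)
  }
  invisible(files)
}

## minimal plain-text helpers used across modules
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path, width = 80L)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
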