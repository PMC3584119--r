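## Orchestration: run the stages (simulate -> annotate -> align ->
## signal / dist / signatures / traits) from a single seeded config and
## record a reproducible run manifest.

#' Clade model implied by a synthetic truth bundle
#'
#' Tips named `A*`/`B*`/`C*` form the three ingroup clades; `OG*` tips are
#' outgroups.
#'
#' @param bundle a `truth_bundle`.
#' @return a [clade_model()].
#' @export
bundle_clade_model <- function(bundle) {
  tips <- bundle$tree$tip.label
  assignment <- setNames(ifelse(grepl("^OG", tips), "outgroup",
                                substr(tips, 1L, 1L)), tips)
  clade_model(bundle$tree, assignment)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order from one config (a
#' list or a YAML file).  All randomness flows from the single top-level
#' `seed`.  Config fields: `seed`, `out_dir`, `stages` (subset of
#' `simulate`, `annotate`, `align`, `signal`, `dist`, `signatures`,
#' `traits`), optional `simulate` (arguments for [sim_config()]), optional
#' `inputs` (paths: `segments_fasta`, `tree`, `clades`, `traits`,
#' `distance_table`), optional `align` (`sets`).
#'
#' @param config list or path to a YAML file.
#' @return a `run_manifest` (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config needs an out_dir")
  stages <- config$stages %||%
    c("simulate", "annotate", "align", "signal", "dist", "signatures",
      "traits")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  emit <- function(stage, ...) outputs[[stage]] <<- c(outputs[[stage]], ...)

  bundle <- NULL; segments <- NULL; annotation <- NULL
  alignments <- list(); clades <- NULL; traits <- NULL; tree <- NULL

  need <- function(x, what, stage)
    if (is.null(x)) stop("stage '", stage, "' is missing its input: ", what)
    else x

  if ("simulate" %in% stages) {
    cfg <- do.call(sim_config, c(config$simulate %||% list(),
                                 list(seed = seed)))
    bundle <- evolve_genomes(cfg = cfg)
    d <- file.path(out_dir, "simulate")
    emit("simulate", write_truth_bundle(bundle, d))
    segments <- bundle$segments
    tree <- bundle$tree
  }
  if (!is.null(config$inputs$segments_fasta))
    segments <- config$inputs$segments_fasta
  if (!is.null(config$inputs$tree))
    tree <- ape::read.tree(config$inputs$tree)
  if (!is.null(config$inputs$clades) && !is.null(tree))
    clades <- clade_model(tree, config$inputs$clades)
  if (is.null(clades) && !is.null(bundle)) clades <- bundle_clade_model(bundle)

  if ("annotate" %in% stages) {
    annotation <- annotate_genomes(need(segments, "segments", "annotate"))
    if (is.character(segments)) {
      seqs <- read_fasta(segments)
      parts <- strsplit(names(seqs), "|", fixed = TRUE)
      segments <- list()
      for (i in seq_along(seqs))
        segments[[parts[[i]][1]]][[parts[[i]][2]]] <- unname(seqs[i])
    }
    d <- file.path(out_dir, "annotate")
    dir.create(d, showWarnings = FALSE)
    f1 <- file.path(d, "features.tsv")
    write_tsv(annotation$features, f1)
    f2 <- file.path(d, "spacers.tsv")
    write_tsv(annotation$spacers, f2)
    f3 <- write_gff3(annotation$features, file.path(d, "features.gff3"))
    emit("annotate", f1, f2, f3)
  }

  if ("align" %in% stages) {
    need(annotation, "annotation", "align")
    d <- file.path(out_dir, "align")
    dir.create(d, showWarnings = FALSE)
    genes <- extract_gene_sequences(annotation$features, segments)
    pcg_names <- unique(annotation$features$feature[
      annotation$features$type == "PCG"])
    per_gene <- list()
    for (g in pcg_names) {
      sub <- genes[genes$feature == g, ]
      ca <- codon_align(setNames(sub$sequence, sub$taxon))
      per_gene[[g]] <- ca$nt
      f <- file.path(d, paste0(g, "_nt.fasta"))
      write_fasta(ca$nt, f)
      emit("align", f)
    }
    mt <- concatenate(per_gene, "mtpcg", codon_blocks = names(per_gene))
    alignments$mtpcg <- mt$aln
    f <- file.path(d, "mtpcg.fasta"); write_fasta(mt$aln, f)
    fp <- write_raxml_partitions(mt$scheme, file.path(d, "mtpcg.partitions"))
    emit("align", f, fp)
    ## structure-guided tRNA alignments concatenated as one set
    trna_names <- unique(annotation$features$feature[
      annotation$features$type == "tRNA"])
    per_trna <- list()
    for (tr in trna_names) {
      sub <- genes[genes$feature == tr, ]
      seqs <- setNames(sub$sequence, sub$taxon)
      ref <- names(seqs)[which(nchar(seqs) == trna_template_length())[1]]
      per_trna[[tr]] <- if (!is.na(ref) && length(seqs) > 1L)
        structure_align(seqs, list(ref = ref,
                                   track = trna_template_track()))$aln
      else mafft_align(seqs, "nucleotide")
    }
    if (length(per_trna)) {
      tj <- concatenate(per_trna, "7trnas")
      alignments[["7trnas"]] <- tj$aln
      f <- file.path(d, "7trnas.fasta"); write_fasta(tj$aln, f)
      emit("align", f)
    }
    ## nuclear sets when the generator provided them
    if (!is.null(bundle) && length(bundle$nuclear)) {
      per_nuc <- lapply(bundle$nuclear, function(s) codon_align(s)$nt)
      n2 <- concatenate(per_nuc[intersect(names(per_nuc),
                                          c("EF1a", "wng"))], "nuc2",
                        codon_blocks = intersect(names(per_nuc),
                                                 c("EF1a", "wng")))
      alignments$nuc2 <- n2$aln
      n3 <- concatenate(per_nuc, "nuc3", codon_blocks = names(per_nuc))
      alignments$nuc3 <- n3$aln
      f2 <- file.path(d, "nuc2.fasta"); write_fasta(n2$aln, f2)
      f3 <- file.path(d, "nuc3.fasta"); write_fasta(n3$aln, f3)
      emit("align", f2, f3)
    }
  }

  if ("signal" %in% stages) {
    if (!length(alignments))
      stop("stage 'signal' is missing its input: alignments")
    d <- file.path(out_dir, "signal")
    dir.create(d, showWarnings = FALSE)
    rep <- signal_report(alignments)
    f <- file.path(d, "signal.tsv"); write_tsv(rep, f)
    emit("signal", f)
  }

  if ("dist" %in% stages) {
    d <- file.path(out_dir, "dist")
    dir.create(d, showWarnings = FALSE)
    dm <- if (!is.null(config$inputs$distance_table))
      read_pdist_table(config$inputs$distance_table)
    else p_distance_matrix(need(alignments$mtpcg, "mtpcg alignment", "dist"))
    cm <- need(clades, "clade model", "dist")
    cs <- clade_summary(dm, cm, seed = seed)
    f0 <- write_pdist(dm, file.path(d, "pdist.tsv"))
    f1 <- file.path(d, "within_clades.tsv"); write_tsv(cs$within, f1)
    f2 <- file.path(d, "among_clades.tsv"); write_tsv(cs$among, f2)
    emit("dist", f0, f1, f2)
  }

  if ("signatures" %in% stages) {
    need(annotation, "annotation", "signatures")
    cm <- need(clades, "clade model", "signatures")
    d <- file.path(out_dir, "signatures")
    dir.create(d, showWarnings = FALSE)
    groups <- group_spacers(annotation$spacers,
                            taxa = cm$tree$tip.label)
    rep <- signature_report(groups, cm)
    f1 <- file.path(d, "spacer_signatures.tsv"); write_tsv(rep, f1)
    motifs <- extract_loop_motifs(annotation$cloverleafs)
    f2 <- file.path(d, "loop_motifs.tsv"); write_tsv(motifs, f2)
    diag <- diagnostic_motifs(motifs, cm)
    f3 <- file.path(d, "diagnostic_motifs.tsv"); write_tsv(diag, f3)
    emit("signatures", f1, f2, f3)
    for (g in names(groups)) {
      if (length(groups[[g]]$aligned) < 2L) next
      f <- file.path(d, paste0("isp_", gsub("[^A-Za-z0-9]", "_", g),
                               ".fasta"))
      write_fasta(groups[[g]]$aligned, f)
      emit("signatures", f)
    }
  }

  if ("traits" %in% stages) {
    tr_df <- if (!is.null(config$inputs$traits))
      read_tsv(config$inputs$traits)
    else if (!is.null(bundle)) bundle$traits
    tr_df <- need(tr_df, "trait matrix", "traits")
    tr_tree <- need(tree, "tree", "traits")
    d <- file.path(out_dir, "traits")
    dir.create(d, showWarnings = FALSE)
    tm <- map_all_traits(tr_tree, tr_df)
    f1 <- file.path(d, "trait_summary.tsv"); write_tsv(tm$summary, f1)
    emit("traits", f1)
    for (tr in names(tm$reconstructions)) {
      f <- file.path(d, paste0("changes_", tr, ".tsv"))
      write_tsv(tm$reconstructions[[tr]]$changes, f)
      ft <- write_annotated_tree(tr_tree, tm$reconstructions[[tr]],
                                 file.path(d, paste0("mpr_", tr, ".nwk")))
      emit("traits", f, ft)
    }
  }

  manifest <- structure(list(
    tool = "mitosig",
    version = as.character(utils::packageVersion("mitosig")),
    seed = seed, stages = stages, config = config,
    outputs = lapply(outputs, function(fs) {
      fs <- unlist(fs)
      data.frame(file = fs, md5 = unname(tools::md5sum(fs)),
                 stringsAsFactors = FALSE)
    })), class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("mitosig run (seed %d): stages %s\n", x$seed,
              paste(x$stages, collapse = ", ")))
  for (s in names(x$outputs))
    cat(sprintf("  %s: %d file(s)\n", s, nrow(x$outputs[[s]])))
  invisible(x)
}
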