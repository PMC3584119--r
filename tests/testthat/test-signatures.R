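test_that("spacer grouping records presence and absence per locus", {
  sp <- data.frame(
    taxon = c("a", "b", "c", "a"),
    locus = c("g1-g2", "g1-g2", "g1-g2", "g2-g3"),
    length = c(5L, 5L, 0L, 3L),
    sequence = c("AATTA", "AATTT", "", "CCC"),
    stringsAsFactors = FALSE)
  gr <- group_spacers(sp, taxa = c("a", "b", "c"))
  expect_setequal(names(gr), c("g1-g2", "g2-g3"))
  expect_equal(unname(gr[["g1-g2"]]$presence), c(TRUE, TRUE, FALSE))
  expect_identical(names(gr[["g2-g3"]]$members), "a")

  ## no spacers anywhere: empty group list
  empty <- sp[0, ]
  expect_length(group_spacers(empty, taxa = "a"), 0L)

  dup <- rbind(sp, sp[1, ])
  expect_error(group_spacers(dup), "conflicting")
})

test_that("phyletic patterns classify with gain-averse minimum change", {
  tree <- load_reference_tree()
  taxa <- tree$tip.label
  cm <- load_reference_clades()
  mk_group <- function(present, seqs = NULL) {
    structure(list(
      locus = "x-y",
      members = setNames(seqs %||% rep("AATT", length(present)), present),
      presence = setNames(taxa %in% present, taxa),
      aligned = setNames(seqs %||% rep("AATT", length(present)), present)),
      class = "spacer_group")
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  ## present in the whole ingroup + nearest outgroup, absent in the two
  ## distant outgroups: one gain on the subfamily stem
  thaum <- setdiff(taxa, c("H_cunea", "L_dispar"))
  p <- classify_pattern(mk_group(thaum), cm)
  expect_identical(p$pattern_class, "clade_restricted")
  expect_equal(length(p$gains), 1L)
  expect_length(p$losses, 0L)

  ## exactly one taxon
  p1 <- classify_pattern(mk_group("O_lunifer"), cm)
  expect_identical(p1$pattern_class, "lineage_specific")
  expect_identical(p1$supporting_clade, "O_lunifer")

  ## everywhere: ubiquitous, no gains or losses beyond the root state
  pu <- classify_pattern(mk_group(taxa), cm)
  expect_identical(pu$pattern_class, "ubiquitous")
  expect_length(pu$gains, 0L)
  expect_length(pu$losses, 0L)
})

test_that("minimum-change classification equals exhaustive search", {
  set.seed(77)
  for (case in 1:25) {
    n <- sample(4:8, 1L)
    tr <- random_labelled_tree(n)
    present <- sample(tr$tip.label, sample(seq_len(n), 1L))
    gr <- structure(list(
      locus = "x-y", members = setNames(rep("AA", length(present)), present),
      presence = setNames(tr$tip.label %in% present, tr$tip.label),
      aligned = setNames(rep("AA", length(present)), present)),
      class = "spacer_group")
    p <- classify_pattern(gr, tr)
    states <- setNames(ifelse(tr$tip.label %in% present, "p", "a"),
                       tr$tip.label)
    ora <- oracle_parsimony(tr, states, c("a", "p"))
    expect_equal(p$n_changes, ora$length, label = paste("case", case))
  }
})

test_that("diagnostic motifs are exclusive by construction", {
  tab <- data.frame(
    taxon = c("a1", "a2", "b1", "b2"),
    trna = "trnD", loop = "DHU",
    motif = c("ATTA", "ATTT", "GCCG", "GCCG"),
    stringsAsFactors = FALSE)
  cl <- setNames(c("A", "A", "B", "B"), c("a1", "a2", "b1", "b2"))
  dg <- diagnostic_motifs(tab, cl, max_degeneracy = 2L,
                          groups = c("A", "B"))
  expect_identical(dg$consensus[dg$clade == "A" & dg$loop == "DHU"], "ATTW")
  expect_identical(dg$consensus[dg$clade == "B" & dg$loop == "DHU"], "GCCG")

  ## oracle: exhaustive enumeration over all IUPAC strings of length 4
  codes <- names(mitosig:::IUPAC_SETS)
  grid <- expand.grid(codes, codes, codes, codes, stringsAsFactors = FALSE)
  all_cons <- apply(grid, 1L, paste, collapse = "")
  diag_a <- all_cons[vapply(all_cons, function(cons) {
    all(iupac_match(c("ATTA", "ATTT"), cons)) &&
      !any(iupac_match(c("GCCG", "GCCG"), cons)) &&
      mitosig:::iupac_degeneracy(cons) <= 2L
  }, NA)]
  ## the reported motif is the minimal (position-wise union) of those
  expect_true("ATTW" %in% diag_a)
  expect_true(all(vapply(diag_a, function(cons)
    all(iupac_match(c("ATTA", "ATTT"), cons)), NA)))

  ## a loop shared by everyone is never diagnostic
  tab2 <- tab; tab2$motif <- "AAAA"
  expect_equal(nrow(diagnostic_motifs(tab2, cl, groups = c("A", "B"))), 0L)
})

test_that("injected clade signatures are recovered from annotations", {
  b <- shared_bundle()
  ann <- shared_annotation()
  cm <- bundle_clade_model(b)
  groups <- group_spacers(ann$spacers, taxa = cm$tree$tip.label)
  rep <- signature_report(groups, cm)

  expect_identical(rep$class[rep$locus == "trnS2-nad1"], "ubiquitous")
  expect_identical(rep$gains[rep$locus == "trnK-trnD"], "ingroup")
  expect_identical(rep$gains[rep$locus == "atp6-cox3"], "cladeBC")
  expect_identical(rep$gains[rep$locus == "cox1-trnL2"], "cladeA_1")
  expect_identical(rep$class[rep$locus == "cob-trnS2"], "lineage_specific")
  expect_identical(rep$clade[rep$locus == "cob-trnS2"], "OG1")

  motifs <- extract_loop_motifs(ann$cloverleafs)
  truth <- b$loops
  m <- merge(motifs, truth, by = c("taxon", "trna", "loop"))
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$motif.x == m$motif.y))

  ## injected clade-diagnostic loops are found, and every reported
  ## consensus re-matches exactly its clade (no false positives)
  dg <- diagnostic_motifs(motifs, cm)
  expect_true(any(dg$clade == "C" & dg$trna == "trnD" & dg$loop == "TPsiC" &
                  dg$consensus == "ATTTAAT"))
  expect_true(any(dg$clade == "A" & dg$trna == "trnD" & dg$loop == "DHU"))
  assignment <- cm$assignment
  for (i in seq_len(nrow(dg))) {
    sub <- motifs[motifs$trna == dg$trna[i] & motifs$loop == dg$loop[i], ]
    hits <- sub$taxon[iupac_match(sub$motif, dg$consensus[i])]
    members <- names(assignment)[assignment == dg$clade[i]]
    expect_setequal(hits, members)
  }
})
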