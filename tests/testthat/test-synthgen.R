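test_that("simulated trees have the required clade structure and are deterministic", {
  cfg <- sim_config(seed = 3L)
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 13L)
  expect_true(ape::is.monophyletic(tr, c("A1", "A2", "A3")))
  expect_true(ape::is.monophyletic(tr, c("B1", "B2", "B3")))
  expect_true(ape::is.monophyletic(tr, paste0("C", 1:4)))
  expect_true(ape::is.monophyletic(tr, c(paste0("A", 1:3), paste0("B", 1:3),
                                         paste0("C", 1:4))))
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(cfg)))

  quartet <- sim_config(clade_sizes = c(1L, 1L, 1L), n_outgroups = 1L,
                        seed = 2L, spacer_events = list(),
                        loop_events = list(), trait_spec = list())
  expect_equal(length(simulate_tree(quartet)$tip.label), 4L)
  expect_error(sim_config(clade_sizes = c(2L, 2L)), "clade_sizes")
  expect_error(sim_config(clade_sizes = c(0L, 1L, 1L)), "clade_sizes")
  expect_error(sim_config(n_outgroups = 0L), "n_outgroups")
})

test_that("truth bundles are reproducible from config and seed", {
  cfg <- small_cfg(seed = 9L)
  b1 <- evolve_genomes(cfg = cfg)
  b2 <- evolve_genomes(cfg = cfg)
  expect_identical(b1$segments, b2$segments)
  expect_identical(b1$features, b2$features)
  expect_identical(b1$spacer_presence, b2$spacer_presence)
  expect_identical(b1$nuclear, b2$nuclear)
})

test_that("zero-length branches produce identical leaf genomes", {
  cfg <- small_cfg(seed = 4L, branch_length_range = c(0, 0), indel_rate = 0)
  cfg$spacer_events <- list(); cfg$loop_events <- list()
  b <- evolve_genomes(cfg = cfg)
  ref <- b$segments[[1]]
  for (tx in names(b$segments))
    expect_identical(b$segments[[tx]], ref, label = tx)
})

test_that("every truth PCG translates without internal stops (table 5)", {
  b <- shared_bundle()
  pcg <- b$features[b$features$type == "PCG", ]
  genes <- extract_gene_sequences(pcg, b$segments)
  for (i in seq_len(nrow(genes))) {
    aa <- translate_mito(genes$sequence[i])
    internal <- substr(aa, 1L, nchar(aa) - 1L)
    expect_false(grepl("*", internal, fixed = TRUE),
                 label = paste(genes$taxon[i], genes$feature[i]))
  }
})

test_that("spacer and loop events shape the truth tables as injected", {
  b <- shared_bundle()
  pres <- b$spacer_presence > 0L
  ingroup <- c(paste0("A", 1:3), paste0("B", 1:3), paste0("C", 1:4))
  expect_true(all(pres["trnK-trnD", ingroup]))
  expect_false(any(pres["trnK-trnD", paste0("OG", 1:3)]))
  expect_true(all(pres["atp6-cox3", c(paste0("B", 1:3), paste0("C", 1:4))]))
  expect_false(any(pres["atp6-cox3", c(paste0("A", 1:3), paste0("OG", 1:3))]))
  expect_identical(sort(colnames(pres)[pres["cox1-trnL2", ]]),
                   c("A2", "A3"))
  expect_identical(colnames(pres)[pres["cob-trnS2", ]], "OG1")
  expect_true(all(pres["trnS2-nad1", ]))

  loops <- b$loops
  b2_tpsic <- loops$motif[loops$taxon == "B2" & loops$trna == "trnH" &
                          loops$loop == "TPsiC"]
  expect_identical(b2_tpsic, "ATGAAT")
  c_tpsic <- loops$motif[loops$taxon %in% paste0("C", 1:4) &
                         loops$trna == "trnD" & loops$loop == "TPsiC"]
  expect_identical(unique(c_tpsic), "ATTTAAT")

  bad <- small_cfg(seed = 1L)
  bad$spacer_events <- list(list(locus = "trnK-trnD", branch = "no_branch",
                                 seq = "AT"))
  expect_error(evolve_genomes(cfg = bad), "configuration error")
})

test_that("truth ancestral trait states follow the event propagation", {
  b <- shared_bundle()
  anc <- b$trait_ancestral
  expect_identical(
    anc$state[anc$node == "cladeBC" & anc$trait == "host_class"],
    "Gymnosperm")
  expect_identical(
    anc$state[anc$node == "ingroup" & anc$trait == "host_class"],
    "Angiosperm")
  tr <- b$traits
  expect_identical(unique(tr$host_class[grepl("^[BC]", tr$taxon)]),
                   "Gymnosperm")
  expect_identical(unique(tr$host_class[grepl("^(A|OG)", tr$taxon)]),
                   "Angiosperm")
})

test_that("plain alignment simulation is seed-stable and tracks the tree", {
  tr <- ape::read.tree(text = "((a:0.02,b:0.02):0.3,(c:0.02,d:0.02):0.3);")
  a1 <- simulate_alignment(tr, 500L, seed = 3L)
  a2 <- simulate_alignment(tr, 500L, seed = 3L)
  expect_identical(a1, a2)
  d <- p_distance_matrix(a1)$values
  ## within-cherry distances smaller than across the long internal branch
  expect_lt(d["a", "b"], d["a", "c"])
  expect_lt(d["c", "d"], d["b", "d"])
})
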