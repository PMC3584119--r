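test_that("textbook Fitch cases reconstruct as expected", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rec <- parsimony_reconstruct(tr, c(A = "0", B = "0", C = "1", D = "1"))
  expect_equal(rec$length, 1)
  root_set <- rec$node_states[[length(tr$tip.label) + 1L]]
  expect_setequal(root_set, c("0", "1"))

  ## all leaves in one state: zero changes, every node that state
  rec0 <- parsimony_reconstruct(tr, c(A = "x", B = "x", C = "x", D = "x"),
                                state_space = c("x", "y"))
  expect_equal(rec0$length, 0)
  for (s in rec0$node_states) expect_identical(s, "x")
  expect_equal(nrow(rec0$changes), 0L)

  expect_error(parsimony_reconstruct(tr, c(A = "0", B = "0", C = "1",
                                           D = "z"),
                                     state_space = c("0", "1")),
               "not in declared state space")
  expect_error(parsimony_reconstruct(tr, c(A = "0", B = "0", C = "1")),
               "no state for taxa")
})

test_that("Sankoff equals exhaustive enumeration on random trees", {
  set.seed(99)
  for (case in 1:40) {
    n <- sample(4:8, 1L)
    k <- sample(2:4, 1L)
    tr <- random_labelled_tree(n)
    space <- letters[seq_len(k)]
    states <- setNames(sample(space, n, replace = TRUE), tr$tip.label)
    if (case %% 5L == 0L) states[sample(n, 1L)] <- "?"
    if (length(setdiff(unique(states), "?")) == 0L) next
    rec <- parsimony_reconstruct(tr, states, state_space = space)
    ora <- oracle_parsimony(tr, states, space)
    expect_equal(rec$length, ora$length, label = paste("length case", case))
    for (v in seq_len(n + tr$Nnode))
      expect_setequal(rec$node_states[[v]], ora$node_sets[[v]])
  }
})

test_that("missing leaves never increase the tree length", {
  set.seed(12)
  for (case in 1:10) {
    n <- sample(5:8, 1L)
    tr <- random_labelled_tree(n)
    space <- c("0", "1", "2")
    states <- setNames(sample(space, n, replace = TRUE), tr$tip.label)
    full <- parsimony_reconstruct(tr, states, space)$length
    states[sample(n, 1L)] <- "?"
    miss <- parsimony_reconstruct(tr, states, space)$length
    expect_lte(miss, full)
  }
})

test_that("length is invariant under state relabeling", {
  set.seed(21)
  tr <- random_labelled_tree(7)
  states <- setNames(sample(c("a", "b", "c"), 7, replace = TRUE),
                     tr$tip.label)
  l1 <- parsimony_reconstruct(tr, states, c("a", "b", "c"))$length
  relab <- c(a = "c", b = "a", c = "b")[states]
  names(relab) <- names(states)
  l2 <- parsimony_reconstruct(tr, relab, c("a", "b", "c"))$length
  expect_equal(l1, l2)
})

test_that("polytomies are handled natively", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,(D:1,E:1):1);")
  rec <- parsimony_reconstruct(tr, c(A = "0", B = "0", C = "1", D = "1",
                                     E = "1"))
  ora <- oracle_parsimony(tr, c(A = "0", B = "0", C = "1", D = "1",
                                E = "1"), c("0", "1"))
  expect_equal(rec$length, ora$length)
})

test_that("trait mapping flags convergent states and matches single runs", {
  tree <- load_reference_tree()
  traits <- load_reference_traits()
  tm <- map_all_traits(tree, traits)
  s <- tm$summary
  expect_identical(s$convergent_state[s$trait == "adult_front"], "crested")
  expect_identical(s$convergent_state[s$trait == "tibia_spine"], "present")
  expect_equal(s$max_origins[s$trait == "foraging_type"], 2L)
  expect_equal(s$length[s$trait == "host_class"], 1L)

  one <- map_all_traits(tree, traits[, c("taxon", "adult_front")])
  direct <- parsimony_reconstruct(
    tree, setNames(traits$adult_front, traits$taxon))
  expect_equal(one$reconstructions$adult_front$length, direct$length)
  expect_identical(one$reconstructions$adult_front$changes, direct$changes)
  expect_error(map_all_traits(tree, traits["taxon"]), "empty")
})

test_that("annotated MPR trees serialise the state sets", {
  tree <- load_reference_tree()
  traits <- load_reference_traits()
  rec <- parsimony_reconstruct(tree,
                               setNames(traits$host_class, traits$taxon))
  tmp <- tempfile(fileext = ".nwk")
  write_annotated_tree(tree, rec, tmp)
  txt <- readLines(tmp)
  expect_match(txt, "T_pityocampa\\{Gymnosperm\\}")
  expect_match(txt, "T_solitaria\\{Angiosperm\\}")
})
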