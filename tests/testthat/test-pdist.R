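test_that("p-distances count mismatches over comparable sites", {
  d <- p_distance_matrix(c(a = "ACGT", b = "ACGT"))
  expect_equal(d$values["a", "b"], 0)
  d2 <- p_distance_matrix(c(a = "ACGT", b = "ACGA"))
  expect_equal(d2$values["a", "b"], 0.25)
  ## pairwise deletion: the gapped site is excluded for the pair
  d3 <- p_distance_matrix(c(a = "AC-T", b = "ACGT"))
  expect_equal(d3$values["a", "b"], 0)
  expect_equal(d3$comparable_sites["a", "b"], 3L)
  ## ambiguity codes are excluded like gaps
  d4 <- p_distance_matrix(c(a = "ACNT", b = "ACGA"))
  expect_equal(d4$values["a", "b"], 1 / 3)
  ## complete deletion equals pairwise deletion without gaps/ambiguities
  aln <- c(a = "ACGTACGT", b = "ACGAACGA", c = "TCGTACGA")
  expect_equal(p_distance_matrix(aln, "complete")$values,
               p_distance_matrix(aln, "pairwise")$values)
  expect_warning(p_distance_matrix(c(a = "--", b = "AC")), "no comparable")
  ## cross-check against the standard raw-distance implementation
  db <- ape::dist.dna(ape::as.DNAbin(do.call(rbind, strsplit(aln, ""))),
                      model = "raw", pairwise.deletion = TRUE)
  expect_equal(as.vector(as.dist(p_distance_matrix(aln)$values)),
               as.vector(db), tolerance = 1e-12)
})

test_that("clade summaries average the right pairs and ignore taxon order", {
  vals <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(vals) <- 0
  dm <- as_p_dist(vals)
  cl <- setNames(c("A", "A", "B", "B"), letters[1:4])
  cs <- clade_summary(dm, cl)
  expect_equal(cs$within$mean, c(0.1, 0.1))
  expect_equal(cs$within$sd, c(0, 0))
  expect_equal(cs$among$mean, 0.1)

  ## permuting taxa leaves the summaries unchanged
  perm <- c(3, 1, 4, 2)
  dm2 <- as_p_dist(vals[perm, perm])
  cs2 <- clade_summary(dm2, cl)
  expect_equal(cs2$within$mean, cs$within$mean)
  expect_equal(cs2$among$mean, cs$among$mean)

  ## singleton clade: within mean undefined, reported as NA
  cl3 <- setNames(c("A", "B", "B", "B"), letters[1:4])
  expect_message(cs3 <- clade_summary(dm, cl3), "fewer than 2")
  expect_true(is.na(cs3$within$mean[cs3$within$clade == "A"]))
})

test_that("printed distance tables are parsed into symmetric matrices", {
  dm <- load_published_pdist("mtpcg")
  expect_equal(dim(dm$values), c(11L, 11L))
  expect_true(isSymmetric(unname(dm$values)))
  expect_equal(dm$values["T_pityocampa", "T_pityocampa_ENA"], 0.074)
  expect_equal(dm$values["T_ispartaensis", "T_libanotica"], 0.042)
  dn <- load_published_pdist("nuc3")
  expect_equal(dn$values["T_ispartaensis", "T_libanotica"], 0.002)
})

test_that("rounding is half-up at the third decimal", {
  expect_equal(mitosig:::round_half_up(0.0795, 3), 0.080)
  expect_equal(mitosig:::round_half_up(0.1215, 3), 0.122)
  expect_equal(mitosig:::round_half_up(-0.0005, 3), -0.001)
})
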