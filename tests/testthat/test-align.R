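test_that("codon alignment preserves codons and completes truncated stops", {
  ## identical sequences: no gaps, identity columns
  ca0 <- codon_align(c(x = "ATGAAATTTTAA", y = "ATGAAATTTTAA"))
  expect_identical(unname(ca0$nt["x"]), unname(ca0$nt["y"]))
  expect_false(any(grepl("-", ca0$nt, fixed = TRUE)))

  ## one internal codon deletion: a single 3-column gap, never splitting a
  ## codon (hand alignment: MKFP vs MK-P)
  ca <- codon_align(c(a = "ATGAAATTTCCCTAA", b = "ATGAAACCCTAA"))
  expect_identical(unname(ca$nt["a"]), "ATGAAATTTCCC")
  expect_identical(unname(ca$nt["b"]), "ATGAAA---CCC")
  expect_identical(unname(ca$protein["b"]), "MK-P")

  ## truncated stop completed by polyadenylation before translation
  ca2 <- codon_align(c(p = "ATGAAATTTT", q = "ATGAAATTTTAA"))
  expect_identical(unname(ca2$nt["p"]), unname(ca2$nt["q"]))

  expect_error(codon_align(c(z = "ATGTAAAAATAA")), "internal stop")

  ## degap round-trip (terminal stop removed, as documented)
  expect_identical(unname(degap(ca$nt["b"])), "ATGAAACCC")
})

test_that("codon integrity holds on synthetic nuclear genes", {
  b <- shared_bundle()
  ca <- codon_align(b$nuclear$EF1a)
  widths <- unique(nchar(ca$nt))
  expect_length(widths, 1L)
  expect_equal(widths %% 3L, 0L)
  ## degapped rows equal the inputs minus their terminal stop
  for (tx in names(ca$nt)) {
    inp <- b$nuclear$EF1a[[tx]]
    expect_identical(unname(degap(ca$nt[tx])),
                     substr(inp, 1L, nchar(inp) - 3L), label = tx)
  }
  ## gap runs are codon-sized and codon-aligned
  for (row in ca$nt) {
    r <- gregexpr("-+", row)[[1]]
    if (r[1] == -1L) next
    len <- attr(r, "match.length")
    expect_true(all(len %% 3L == 0L))
    expect_true(all((as.integer(r) - 1L) %% 3L == 0L))
  }
})

test_that("structure correction moves stem gaps into loops", {
  ## identical stems, loops differing by 2 nt; gaps forced into the stem
  ## must relocate into loop columns with the stems realigned
  track <- c(rep("stem", 4L), rep("loop", 7L), rep("stem", 4L))
  r1 <- "ACGTAAAAAAAACGT"          # full-length reference
  aln <- c(r1 = r1,
           r2 = "AC-GTAAAAAAACGT")  # gap in stem col 3; true loop is 6 nt
  fixed <- structure_correct(aln, track)
  gap_cols <- which(strsplit(fixed[["r2"]], "")[[1]] == "-")
  expect_length(gap_cols, 1L)
  expect_true(all(track[gap_cols] == "loop"))
  ## correction only moves gaps, never loses characters
  expect_identical(gsub("-", "", fixed[["r2"]]),
                   gsub("-", "", aln[["r2"]]))
  ## the realigned stem now matches the reference stem columns
  expect_identical(substr(fixed[["r2"]], 1L, 4L), substr(r1, 1L, 4L))

  ## oracle: of all placements of one gap in r2, the corrected one is
  ## among the best-scoring against the reference (score = matches to r1)
  degapped <- gsub("-", "", aln[["r2"]])
  scores <- vapply(seq_len(nchar(r1)), function(pos) {
    cand <- paste0(substr(degapped, 1, pos - 1L), "-",
                   substr(degapped, pos, nchar(degapped)))
    sum(strsplit(cand, "")[[1]] == strsplit(r1, "")[[1]])
  }, 0)
  fixed_pos <- gap_cols
  expect_equal(scores[fixed_pos], max(scores))

  ## identical sequences: correction is a no-op
  seqs <- setNames(rep(strrep("ACGT", 4L), 3L), c("a", "b", "c"))
  tr <- rep(c("stem", "loop"), each = 8L)
  expect_identical(structure_correct(seqs, tr), seqs)
})

test_that("structure-guided alignment uses the template track", {
  set.seed(11)
  f <- mitosig:::make_trna_feature("trnV", "+", "TAC", subst_model())
  s <- mitosig:::feature_sequence(f)
  seqs <- c(ref = s, other = s)
  out <- structure_align(seqs, list(ref = "ref",
                                    track = trna_template_track()))
  expect_identical(unname(out$aln["ref"]), unname(out$aln["other"]))
  expect_equal(sum(out$column_track == "stem"),
               sum(trna_template_track() == "stem"))
  expect_error(structure_align(seqs, list(ref = "ref", track = "stem")),
               "structural error")
  expect_error(structure_align(seqs, list(ref = "zz",
                                          track = trna_template_track())),
               "not among")
})

test_that("concatenation builds disjoint covering partitions", {
  a1 <- c(t1 = "AAATTT", t2 = "AAATTT")
  a2 <- c(t1 = "CCCGGG", t2 = "CCCGGG")
  cc <- concatenate(list(g1 = a1, g2 = a2), "toy")
  expect_equal(nchar(cc$aln[["t1"]]), 12L)
  expect_length(cc$scheme$blocks, 2L)
  expect_true(validate_partition_scheme(cc$scheme))

  ## p1/p2/p3 split: three interleaved partitions whose union is the block
  cc3 <- concatenate(list(g1 = a1), "toy3", codon_blocks = "g1")
  expect_length(cc3$scheme$blocks, 3L)
  expect_identical(cc3$scheme$blocks$g1_p1$cols, c(1L, 4L))
  expect_setequal(unlist(lapply(cc3$scheme$blocks, `[[`, "cols")), 1:6)

  ## taxa missing from a block are dropped (or gap-filled on request)
  a3 <- c(t1 = "GG")
  expect_error(concatenate(list(g1 = c(t1 = "AA", t1 = "CC")), "dup"),
               "duplicate")
  keep <- concatenate(list(g1 = a1, g3 = a3), "drop_set")
  expect_identical(names(keep$aln), "t1")
  fill <- concatenate(list(g1 = a1, g3 = a3), "fill_set",
                      missing = "gapfill")
  expect_identical(unname(fill$aln["t2"]), "AAATTT--")

  tmp <- tempfile()
  write_raxml_partitions(cc3$scheme, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1], "DNA, g1_p1 = 1-4\\\\3", fixed = FALSE)
})

test_that("phylip writer emits a parseable relaxed header", {
  aln <- c(a = "ACGT", b = "AGGT")
  tmp <- tempfile()
  write_phylip(aln, tmp)
  lines <- readLines(tmp)
  expect_identical(lines[1], "2 4")
  expect_match(lines[2], "^a\\s+ACGT$")
})
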