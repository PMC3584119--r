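test_that("PCG boundaries follow the legitimate-start and stop rules", {
  ## upstream gene ends TAG; the gene starts at the first legitimate start
  ## not inside it and ends at the first in-frame stop
  seg <- paste0("ATGAAATAG", "ATGAAATTTTAA", "CCCCCC")
  up <- list(gene = "up", start = 0L, end = 9L, strand = "+")
  a <- annotate_pcg(seg, "toy", c(0L, nchar(seg)), "+",
                    upstream_feature = up, min_orf = 9L)
  expect_equal(c(a$start, a$end), c(9L, 21L))
  expect_identical(a$start_codon, "ATG")
  expect_identical(a$stop_codon, "TAA")
  expect_identical(a$completeness, "complete")

  ## independent oracle: enumerate every legitimate start downstream of the
  ## upstream gene and extend to the first in-frame stop
  starts <- c("ATA", "ATC", "ATG", "ATT", "GTG", "TTG", "GTT")
  cand <- integer(0)
  for (p in 9:(nchar(seg) - 3L)) {
    cod <- substr(seg, p + 1L, p + 3L)
    if (!cod %in% starts) next
    q <- p + 3L
    while (q + 3L <= nchar(seg) &&
           !substr(seg, q + 1L, q + 3L) %in% c("TAA", "TAG")) q <- q + 3L
    if (q + 3L - p >= 9L) { cand <- p; break }
  }
  expect_equal(a$start, cand)

  ## in-frame stop that begins 1 nt before the downstream tRNA: truncated T
  seg2 <- paste0("ATGAAA", "T", "AAGGGTTTAAGGGTTT")
  dn <- list(gene = "trnX", start = 7L, end = 20L, strand = "+")
  a2 <- annotate_pcg(seg2, "toy2", c(0L, 7L), "+", downstream_feature = dn,
                     min_orf = 6L)
  expect_equal(c(a2$start, a2$end), c(0L, 7L))
  expect_identical(a2$stop_codon, "T_trunc")

  ## TA truncation on the minus strand
  plus <- revcomp(paste0("ATGAAAAAC", "TA"))
  seg3 <- paste0("GGGGGGGGGGGG", plus)
  dn3 <- list(gene = "trnY", start = 10L, end = 12L, strand = "-")
  a3 <- annotate_pcg(seg3, "toy3", c(12L, nchar(seg3)), "-",
                     downstream_feature = dn3, min_orf = 9L)
  expect_identical(a3$stop_codon, "TA_trunc")
  expect_equal(a3$start, 12L)
  expect_equal(a3$end, nchar(seg3))

  expect_warning(
    expect_null(annotate_pcg("CCCCCCCCCCCC", "none", c(0L, 12L), "+",
                             min_orf = 9L)),
    "no ORF")
})

test_that("cloverleaf search round-trips templates, strands and scores", {
  set.seed(42)
  f <- mitosig:::make_trna_feature("trnH", "+", "GTG", subst_model())
  s <- mitosig:::feature_sequence(f)
  hit <- find_cloverleaf(s, "trnH", "GTG", "+")
  expect_equal(c(hit$annotation$start, hit$annotation$end), c(0L, nchar(s)))
  expect_identical(hit$cloverleaf$anticodon, "GTG")
  expect_equal(hit$cloverleaf$n_match, hit$cloverleaf$n_pairable)
  expect_identical(hit$cloverleaf$loops$DHU$seq,
                   mitosig:::int_to_dna(f$parts$dloop$states))
  expect_identical(hit$cloverleaf$loops$TPsiC$seq,
                   mitosig:::int_to_dna(f$parts$tloop$states))

  ## strand symmetry: the reverse complement annotated as minus strand
  ## yields identical gene-orientation loops and mirrored coordinates
  hit_m <- find_cloverleaf(revcomp(s), "trnH", "GTG", "-")
  expect_identical(hit_m$cloverleaf$loops$DHU$seq,
                   hit$cloverleaf$loops$DHU$seq)
  expect_identical(hit_m$cloverleaf$loops$TPsiC$seq,
                   hit$cloverleaf$loops$TPsiC$seq)
  expect_equal(c(hit_m$annotation$start, hit_m$annotation$end),
               c(0L, nchar(s)))

  ## break one acceptor-stem pair: by hand, matches drop from 21 to 20, so
  ## score = matches - penalty * mismatches = 20 - penalty
  sm <- s
  first <- substr(s, 1L, 1L)
  flip <- c(A = "C", C = "A", G = "A", T = "G")[[first]]
  substr(sm, 1L, 1L) <- flip
  hit1 <- find_cloverleaf(sm, "trnH", "GTG", "+", penalty = 1)
  expect_equal(hit1$cloverleaf$n_match, 20)
  expect_equal(hit1$cloverleaf$score, 19)
  hit2 <- find_cloverleaf(sm, "trnH", "GTG", "+", penalty = 2)
  expect_equal(hit2$cloverleaf$score, 18)
})

test_that("rRNA boundaries are forced by the flanking tRNAs", {
  mk <- function(gene, s, e) structure(
    list(gene = gene, type = "tRNA", start = s, end = e, strand = "-",
         start_codon = NA, stop_codon = NA, completeness = "complete"),
    class = "gene_annotation")
  feats <- list(trnL1 = mk("trnL1", 100L, 172L), trnV = mk("trnV", 1500L, 1571L))
  rr <- assign_rrna_boundaries(feats, 2500L, rrns_length = 780L)
  expect_equal(c(rr$rrnL$start, rr$rrnL$end), c(172L, 1500L))
  expect_equal(c(rr$rrnS$start, rr$rrnS$end), c(1571L, 2351L))
  w <- capture_warnings(rr2 <- assign_rrna_boundaries(feats["trnL1"], 2500L))
  expect_match(w, "missing", all = TRUE)
  expect_identical(rr2$rrnL$completeness, "partial3")
})

test_that("spacer extraction keeps zero-length records and validates overlap", {
  mk <- function(gene, s, e, type = "PCG") structure(
    list(gene = gene, type = type, start = s, end = e, strand = "+",
         start_codon = NA, stop_codon = NA, completeness = "complete"),
    class = "gene_annotation")
  seg <- strrep("ACGT", 30L)
  sp <- extract_spacers(list(mk("g1", 0L, 30L), mk("g2", 30L, 60L),
                             mk("g3", 70L, 100L)), seg, taxon = "t")
  expect_equal(sp$length, c(0L, 10L))
  expect_identical(sp$locus, c("g1-g2", "g2-g3"))
  expect_identical(sp$sequence[2], substr(seg, 61L, 70L))
  expect_error(
    extract_spacers(list(mk("g1", 0L, 30L), mk("g2", 25L, 60L)), seg),
    "structural error")
  ## the canonical atp8/atp6 overlap is allowed
  ok <- extract_spacers(list(mk("atp8", 0L, 30L), mk("atp6", 23L, 60L)), seg)
  expect_equal(ok$length, 0L)
})

test_that("synthetic genomes annotate back to their truth tables", {
  b <- shared_bundle()
  ann <- shared_annotation()

  pcg_t <- b$features[b$features$type == "PCG", ]
  m <- merge(pcg_t, ann$features[ann$features$type == "PCG", ],
             by = c("taxon", "feature"))
  expect_equal(nrow(m), nrow(pcg_t))
  exact <- m$start.x == m$start.y & m$end.x == m$end.y
  expect_gte(mean(exact), 0.95)

  ## every injected truncated-stop gene is recovered with its truncation
  trunc <- m[m$feature %in% c("cox2", "nad4"), ]
  expect_true(all(trunc$stop_codon %in% c("T_trunc", "TA_trunc")))
  expect_true(all(trunc$start.x == trunc$start.y &
                  trunc$end.x == trunc$end.y))

  ## all tRNAs found with the correct anticodon
  for (tx in names(ann$cloverleafs))
    for (tr in names(TRNA_ANTICODONS))
      expect_identical(ann$cloverleafs[[tx]][[tr]]$anticodon,
                       unname(TRNA_ANTICODONS[[tr]]),
                       label = paste(tx, tr))

  ## every spacer's sequence equals the segment substring between its
  ## flanking features
  sp <- ann$spacers[ann$spacers$length > 0L, ]
  for (i in seq_len(nrow(sp))) {
    seg_id <- mitosig:::segment_of_gene(strsplit(sp$locus[i], "-")[[1]][1])
    expect_identical(
      sp$sequence[i],
      substr(b$segments[[sp$taxon[i]]][[seg_id]], sp$start[i] + 1L,
             sp$end[i]),
      label = paste(sp$taxon[i], sp$locus[i]))
  }
})

test_that("rRNA truth coordinates round-trip when lengths are stable", {
  cfg <- small_cfg(seed = 21L, indel_rate = 0)
  b <- evolve_genomes(cfg = cfg)
  ann <- suppressWarnings(annotate_genomes(b$segments))
  rr_t <- b$features[b$features$type == "rRNA", ]
  m <- merge(rr_t, ann$features[ann$features$type == "rRNA", ],
             by = c("taxon", "feature"))
  expect_equal(nrow(m), nrow(rr_t))
  expect_true(all(m$start.x == m$start.y & m$end.x == m$end.y))
})
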