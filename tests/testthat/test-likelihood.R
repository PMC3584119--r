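test_that("single-column closed forms and re-rooting invariance hold", {
  m <- subst_model()
  ## two identical taxa joined by zero-length branches: the likelihood of
  ## one column is just the stationary frequency of the observed base
  tr <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(site_log_likelihood(tr, c(a = "G", b = "G"), m),
               log(m$base_freq[["G"]]))
  expect_equal(site_log_likelihood(tr, c(a = "T", b = "T"), m),
               log(m$base_freq[["T"]]))

  ## reversibility: the likelihood does not depend on the root position
  set.seed(8)
  tr5 <- random_labelled_tree(5, bl = 0.15)
  aln <- simulate_alignment(tr5, 40L, m, seed = 2L)
  l0 <- site_log_likelihood(tr5, aln, m)
  for (og in c("t2", "t4")) {
    tr_re <- ape::root(ape::unroot(tr5), outgroup = og, resolve.root = TRUE)
    expect_equal(site_log_likelihood(tr_re, aln, m), l0, tolerance = 1e-10)
  }

  expect_error(site_log_likelihood(tr5, aln[1:3], m), "missing")
  tr_neg <- tr5; tr_neg$edge.length[1] <- -0.1
  expect_error(site_log_likelihood(tr_neg, aln, m), "negative")
})

test_that("pruning equals brute-force enumeration on small instances", {
  m <- subst_model(alpha = 0.6)
  set.seed(31)
  for (case in 1:12) {
    n <- sample(3:5, 1L)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    aln <- simulate_alignment(tr, sample(3:10, 1L), m, seed = case)
    expect_equal(site_log_likelihood(tr, aln, m),
                 oracle_loglik(tr, aln, m), tolerance = 1e-9,
                 label = paste("case", case))
  }
})

test_that("likelihood matches an independent implementation (phangorn)", {
  library(phangorn)
  m <- subst_model(alpha = 0.5)
  set.seed(5)
  tr <- random_labelled_tree(6, bl = 0.12)
  aln <- simulate_alignment(tr, 300L, m, seed = 9L)
  dat <- phyDat(do.call(rbind, strsplit(aln, "")))
  fit <- pml(ape::unroot(tr), dat, bf = m$base_freq,
             Q = c(1, m$kappa, 1, 1, m$kappa, 1), k = 4L, shape = m$alpha)
  expect_equal(site_log_likelihood(tr, aln, m), fit$logLik,
               tolerance = 1e-6)
})

test_that("gamma discretisation has unit mean and sensible ordering", {
  for (a in c(0.2, 0.5, 1, 5)) {
    r <- discrete_gamma_rates(a, 4L)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(discrete_gamma_rates(0.5, 1L), 1)
})

test_that("branch-length optimisation improves the likelihood", {
  m <- subst_model()
  tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,(c:0.5,d:0.5):0.5);")
  truth <- ape::read.tree(text = "((a:0.05,b:0.05):0.2,(c:0.05,d:0.05):0.2);")
  aln <- simulate_alignment(truth, 1000L, m, seed = 4L)
  before <- site_log_likelihood(tr, aln, m)
  opt <- optimize_branch_lengths(tr, aln, m)
  expect_gt(opt$loglik, before)
  expect_true(all(opt$tree$edge.length < 0.5))
})

test_that("neighbor joining recovers additive trees exactly", {
  truth <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.1):0.07);")
  D <- ape::cophenetic.phylo(truth)
  nj <- nj_tree(D[order(rownames(D)), order(colnames(D))])
  expect_equal(ape::dist.topo(ape::unroot(truth), nj), 0,
               ignore_attr = TRUE)
  ## branch lengths reproduced (additivity)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)

  ## three taxa: closed-form star branches
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  nj3 <- nj_tree(D3)
  expect_equal(sort(nj3$edge.length), c(1, 2, 3))

  bad <- D3; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("distance trees recover the generating topology from sequences", {
  b <- evolve_genomes(cfg = small_cfg(seed = 13L))
  aln <- codon_align(b$nuclear$EF1a)$nt
  d <- p_distance_matrix(aln)
  nj <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(b$tree), nj), 0,
               ignore_attr = TRUE)
})
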