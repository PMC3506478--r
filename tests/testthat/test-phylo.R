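test_that("pruning equals exhaustive enumeration (oracle, 20 instances)", {
  ## random trees with <= 3 internal nodes, 4-state models, gappy data
  shapes <- c("(A:0.2,B:0.3);",
              "(A:0.1,B:0.2,C:0.3);",
              "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.2);",
              "(((A:0.1,B:0.2):0.1,C:0.3):0.15,D:0.1,E:0.4);")
  for (i in 1:20) {
    mod <- toy_model(4, seed = 100 + i)
    ## nucleotide-labelled states so msa validation accepts them
    mod$states <- c("A", "C", "G", "T")
    tree <- ape::read.tree(text = shapes[(i %% 4) + 1])
    aln <- random_alignment(mod, length(tree$tip.label), 6, seed = 200 + i)
    rownames(aln) <- tree$tip.label
    got <- site_log_likelihoods(tree, aln, mod)
    want <- brute_site_logliks(tree, allowed_states(aln, mod), mod)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("C++ kernel matches the pure-R reference pass", {
  mod <- jtt_model()
  tree <- simulate_tree(8, 1, seed = 3)
  aln <- simulate_protein(tree, 40, alpha = 0.8, seed = 4)
  tp <- sitesel:::.tip_partials(aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  expect_equal(sitesel:::.prune_loglik(tr, tp, mod, 1.3),
               sitesel:::.prune_loglik_r(tr, tp, mod, 1.3),
               tolerance = 1e-10)
})

test_that("pruning limit cases", {
  mod <- gtr_model(freq = c(0.1, 0.2, 0.3, 0.4))
  ## identical leaves, zero-length branches: log(freq_state)
  tree <- ape::read.tree(text = "(A:0,B:0);")
  aln <- msa(c("A", "B"), c("G", "G"), "nucleotide")
  expect_equal(site_log_likelihoods(tree, aln, mod), log(0.3),
               tolerance = 1e-10)
  ## two-taxon closed form with independent expm
  tree2 <- ape::read.tree(text = "(A:0.12,B:0.31);")
  aln2 <- msa(c("A", "B"), c("C", "T"), "nucleotide")
  P <- expm_oracle(mod$Q, 0.43)
  expect_equal(site_log_likelihoods(tree2, aln2, mod),
               log(0.2 * P[2, 4]), tolerance = 1e-8)
  ## all-gap column has log-likelihood 0
  aln3 <- msa(c("A", "B"), c("-A", "-C"), "nucleotide")
  expect_equal(site_log_likelihoods(tree2, aln3, mod)[1], 0,
               tolerance = 1e-12)
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  mod <- toy_model(4, seed = 9)
  mod$states <- c("A", "C", "G", "T")
  tree <- ape::read.tree(
    text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.2,E:0.4);")
  aln <- random_alignment(mod, 5, 20, seed = 77)
  rownames(aln) <- tree$tip.label
  base <- sum(site_log_likelihoods(tree, aln, mod))
  for (node in c("A", "D")) {
    rooted <- ape::root(tree, outgroup = node, resolve.root = TRUE)
    expect_equal(sum(site_log_likelihoods(rooted, aln, mod)), base,
                 tolerance = 1e-8)
  }
})

test_that("JTT is a valid normalized reversible model", {
  m <- jtt_model()
  expect_lt(max(abs(m$freq %*% m$Q)), 1e-10)          # stationarity
  expect_lt(max(abs(rowSums(m$Q))), 1e-10)
  expect_equal(-sum(m$freq * diag(m$Q)), 1, tolerance = 1e-12)
  db <- m$freq * m$Q - t(m$freq * m$Q)                # detailed balance
  expect_lt(max(abs(db)), 1e-12)
})

test_that("ml_distance: identity, consistency, saturation", {
  m <- jtt_model()
  s <- paste(sample(AMINO_ACIDS, 50, replace = TRUE), collapse = "")
  expect_equal(ml_distance(s, s, m), 0)

  ## simulation consistency at true distance 0.3 (5,000 sites)
  tree <- ape::read.tree(text = "(A:0.15,B:0.15);")
  aln <- simulate_protein(tree, 5000, alpha = 1, seed = 11,
                          rates = rep(1, 5000))
  d <- ml_distance(msa_strings_for_test(aln)[1],
                   msa_strings_for_test(aln)[2], m)
  ## 3 SE for a JTT distance at d=0.3, n=5000 is ~ 0.03
  expect_lt(abs(d - 0.3), 0.05)

  ## saturated random pair is capped with a warning
  set.seed(5)
  r1 <- paste(sample(AMINO_ACIDS, 300, TRUE), collapse = "")
  r2 <- paste(sample(AMINO_ACIDS, 300, TRUE), collapse = "")
  expect_warning(dcap <- ml_distance(r1, r2, m, d_max = 3), "saturated")
  expect_equal(dcap, 3)

  expect_error(ml_distance("A-", "-A", m), "no comparable")
})

test_that("BIONJ: three-point formulas and additive exactness", {
  d <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- bionj(d)
  bl <- tr$edge.length[order(tr$edge[, 2])]
  expect_equal(sort(bl), c(0.1, 0.2, 0.3))

  ## additive metric from a known 5-taxon tree is recovered exactly
  gen <- ape::read.tree(
    text = "((A:0.11,B:0.23):0.07,(C:0.16,D:0.09):0.12,E:0.3);")
  dm <- ape::cophenetic.phylo(gen)
  rec <- bionj(dm)
  expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(rec)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)],
               dm, tolerance = 1e-6)

  expect_error(bionj(matrix(c(0, 1, 2, 0), 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
  dbad <- d; dbad[1, 2] <- 9
  expect_error(bionj(dbad), "non-symmetric")
})

test_that("branch-length optimization is monotone and respects optima", {
  mod <- gtr_model(freq = c(.1, .2, .3, .4))
  tree <- simulate_tree(6, 0.8, seed = 21)
  sim <- simulate_codons(tree, simulation_spec(1, 1, matrix(1), 60),
                         seed = 22)
  aln <- sim$alignment$base
  start <- sum(site_log_likelihoods(tree, aln, mod))
  pert <- tree
  set.seed(23)
  pert$edge.length <- pert$edge.length * stats::runif(length(pert$edge.length), 0.3, 3)
  ll0 <- sum(site_log_likelihoods(pert, aln, mod))
  opt <- optimize_branch_lengths(pert, aln, mod)
  expect_gte(attr(opt, "loglik"), ll0)
  expect_gte(attr(opt, "loglik"), start - 1e-6)
  expect_true(all(opt$edge.length >= 0))
  ## fixed point: optimizing again changes little
  opt2 <- optimize_branch_lengths(opt, aln, mod)
  expect_equal(attr(opt2, "loglik"), attr(opt, "loglik"), tolerance = 1e-4)
})

test_that("bootstrap support behaves at the extremes and is seeded", {
  ## every column identically partitions {A,B} vs {C,D}
  aln <- msa(c("A", "B", "C", "D"),
             c("AAAA", "AAAA", "CCCC", "CCCC"), "nucleotide")
  ## the toy alignment's fully divergent pairs saturate the ML distance
  ## by construction, so the cap warnings are expected here
  builder <- function(a)
    suppressWarnings(build_bionj_tree(a, gtr_model(), d_max = 5))
  bs <- bootstrap_support(aln, builder, n_replicates = 10, seed = 1)
  expect_true(all(bs$support[!is.na(bs$support)] == 1))
  bs1 <- bootstrap_support(aln, builder, n_replicates = 1, seed = 2)
  expect_true(all(bs1$support[!is.na(bs1$support)] %in% c(0, 1)))
  ## determinism
  b2 <- bootstrap_support(aln, builder, n_replicates = 5, seed = 9)
  b3 <- bootstrap_support(aln, builder, n_replicates = 5, seed = 9)
  expect_identical(b2$support, b3$support)
})
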