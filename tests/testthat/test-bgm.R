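neutral_codon_model <- function()
  build_codon_model(c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1, GT = 1),
                    rep(1 / 61, 61), 0.5, 0.5)

test_that("joint ancestral reconstruction: basics and enumeration oracle", {
  mod <- neutral_codon_model()
  ## invariant site: every internal node gets the shared codon
  tree <- tree4()
  aln <- as_codon_alignment(msa(c("A", "B", "C", "D"),
                                rep("ATGGCC", 4), "nucleotide"))
  anc <- joint_ancestral_codons(tree, aln, mod)
  expect_true(all(anc[, 1] == "ATG"))
  expect_true(all(anc[, 2] == "GCC"))

  ## 3-taxon star, short branches, majority codon wins at the root
  star <- ape::read.tree(text = "(A:0.05,B:0.05,C:0.05);")
  aln3 <- as_codon_alignment(msa(c("A", "B", "C"),
                                 c("AAA", "AAA", "AAG"), "nucleotide"))
  anc3 <- joint_ancestral_codons(star, aln3, mod)
  expect_equal(unname(anc3[1, 1]), "AAA")
  ## brute force over all 61 root states using an independent expm
  P <- lapply(c(0.05, 0.05, 0.05), function(t) expm_oracle(mod$Q, t))
  leaf_idx <- match(c("AAA", "AAA", "AAG"), SENSE_CODONS)
  score <- sapply(seq_len(61), function(r)
    log(mod$freq[r]) + log(P[[1]][r, leaf_idx[1]]) +
      log(P[[2]][r, leaf_idx[2]]) + log(P[[3]][r, leaf_idx[3]]))
  expect_equal(match(anc3[1, 1], SENSE_CODONS), which.max(score))

  ## exhaustive-argmax oracle on a 2-internal-node tree, several sites
  t2 <- ape::read.tree(text = "((A:0.3,B:0.6):0.25,C:0.4,D:0.9);")
  set.seed(71)
  rows <- replicate(4, paste(sample(SENSE_CODONS, 5, TRUE), collapse = ""))
  aln2 <- as_codon_alignment(msa(c("A", "B", "C", "D"), rows, "nucleotide"))
  anc2 <- joint_ancestral_codons(t2, aln2, mod)
  tr <- attr(anc2, "tree")
  Ps <- lapply(tr$edge.length, function(t) expm_oracle(mod$Q, t))
  for (s in 1:5) {
    li <- match(aln2$codons[tr$tip.label, s], SENSE_CODONS)
    best <- -Inf; arg <- NULL
    for (r in seq_len(61)) for (v in seq_len(61)) {
      st <- c(li, r, v)   # nodes 1..4 tips, 5 root, 6 internal
      lp <- log(mod$freq[r])
      for (e in seq_len(nrow(tr$edge)))
        lp <- lp + log(Ps[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]])
      if (lp > best) { best <- lp; arg <- c(r, v) }
    }
    got <- match(anc2[, s], SENSE_CODONS)
    ## joint reconstruction attains the exhaustive maximum
    lp_got <- log(mod$freq[got[1]])
    st <- c(li, got)
    for (e in seq_len(nrow(tr$edge)))
      lp_got <- lp_got + log(Ps[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]])
    expect_equal(lp_got, best, tolerance = 1e-9)
  }
})

test_that("substitution maps count amino-acid-changing branches", {
  mod <- neutral_codon_model()
  tree <- tree4()
  ## identical leaves: all-zero matrix
  aln <- as_codon_alignment(msa(c("A", "B", "C", "D"),
                                rep("ATGGCC", 4), "nucleotide"))
  anc <- joint_ancestral_codons(tree, aln, mod)
  m <- substitution_map(tree, aln, anc)
  expect_true(all(m$matrix == 0))
  ## one leaf differs non-synonymously (AAA Lys -> GAA Glu): exactly one
  ## event, on that terminal branch
  star <- ape::read.tree(text = "(A:0.05,B:0.05,C:0.05);")
  aln1 <- as_codon_alignment(msa(c("A", "B", "C"),
                                 c("AAA", "AAA", "GAA"), "nucleotide"))
  anc1 <- joint_ancestral_codons(star, aln1, mod)
  m1 <- substitution_map(star, aln1, anc1)
  expect_equal(sum(m1$matrix), 1)
  expect_equal(m1$branches[which(m1$matrix[1, ] == 1)], "4->C")
  ## synonymous-only variation (AAA/AAG both Lys): all-zero row
  aln2 <- as_codon_alignment(msa(c("A", "B", "C"),
                                 c("AAA", "AAG", "AAA"), "nucleotide"))
  anc2 <- joint_ancestral_codons(star, aln2, mod)
  expect_true(all(substitution_map(star, aln2, anc2)$matrix == 0))
})

test_that("filter_sites thresholds and idempotence", {
  fake <- structure(list(
    matrix = rbind(rep(0L, 6), c(1L, 1L, 0L, 0L, 0L, 0L),
                   c(1L, 1L, 1L, 0L, 0L, 0L),
                   c(1L, 1L, 1L, 1L, 1L, 0L)),
    branch_count = c(0, 2, 3, 5),
    positions = c(10L, 20L, 30L, 40L),
    branches = paste0("b", 1:6)), class = "subst_map")
  f3 <- filter_sites(fake, 3)
  expect_equal(f3$positions, c(30L, 40L))   # boundary inclusive
  expect_equal(filter_sites(fake, 0)$positions, fake$positions)
  expect_identical(filter_sites(f3, 3), f3) # idempotent
})

test_that("bgm_fit finds planted dependence and is seed-deterministic", {
  set.seed(81)
  col <- rbinom(24, 1, 0.4)
  while (sum(col) < 3) col <- rbinom(24, 1, 0.4)
  X <- rbind(col, col,
             matrix(rbinom(24 * 4, 1, 0.3), 4, 24))
  map <- structure(list(matrix = X, branch_count = rowSums(X),
                        positions = 1:6, branches = paste0("b", 1:24)),
                   class = "subst_map")
  net <- bgm_fit(map, chain_length = 20000, burn_in = 2000, seed = 5)
  top <- net$edge_posterior[1, ]
  expect_equal(sort(c(top$site1, top$site2)), c(1, 2))
  expect_gte(top$posterior, 0.9)
  ## bit-for-bit reproducibility
  net2 <- bgm_fit(map, chain_length = 20000, burn_in = 2000, seed = 5)
  expect_identical(net$edge_posterior, net2$edge_posterior)
  expect_identical(net$posterior_matrix, net2$posterior_matrix)
  ## degenerate inputs
  one <- structure(list(matrix = X[1, , drop = FALSE], branch_count = 9,
                        positions = 1L, branches = map$branches),
                   class = "subst_map")
  expect_error(bgm_fit(one), "at least 2")
  bad <- map; bad$matrix[1, 1] <- 2L
  expect_error(bgm_fit(bad, chain_length = 10, burn_in = 1), "binary")
})

test_that("co-evolving pair calling and connected-component grouping", {
  ## the five-pair configuration reduces to four groups
  pairs <- data.frame(site1 = c(142, 152, 188, 199, 203),
                      site2 = c(144, 200, 200, 325, 310),
                      posterior = c(0.85, 0.59, 0.55, 0.58, 0.68))
  called <- call_coevolving(pairs, 0.5)
  expect_equal(nrow(called$pairs), 5)
  expect_length(called$groups, 4)
  expect_setequal_groups <- function(groups, want)
    expect_true(all(vapply(want, function(g)
      any(vapply(groups, function(h) setequal(h, g), logical(1))),
      logical(1))))
  expect_setequal_groups(called$groups,
                         list(c(142, 144), c(152, 188, 200),
                              c(199, 325), c(203, 310)))
  ## raising the threshold shrinks the called set
  expect_length(call_coevolving(pairs, 0.8)$groups, 1)   # only 142-144
  none <- call_coevolving(pairs, 0.99)
  expect_equal(nrow(none$pairs), 0)
  expect_length(none$groups, 0)
  chain <- data.frame(site1 = c(1, 2, 3), site2 = c(2, 3, 4),
                      posterior = rep(0.8, 3))
  expect_equal(call_coevolving(chain, 0.5)$groups[[1]], c(1, 2, 3, 4))
})
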