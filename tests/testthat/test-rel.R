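test_that("constraint presets encode the published reductions", {
  chij <- nucleotide_constraints("chiJ")
  expect_length(chij$params, 2)          # RAC shared by AC/CT, RAT by AT/GT
  v <- sitesel:::.expand_exch(chij, c(RAC = 2.5, RAT = 0.4))
  expect_equal(unname(v[c("AG", "CG")]), c(1, 1))
  expect_equal(unname(v["CT"]), unname(v["AC"]))
  expect_equal(unname(v["GT"]), unname(v["AT"]))

  reca <- nucleotide_constraints("recA")
  expect_length(reca$params, 3)
  expect_equal(unname(reca$mapping[c("AC", "AT")]), c("ref", "ref"))

  dnan <- nucleotide_constraints("dnaN")
  expect_length(dnan$params, 2)          # RCG + the flagged free RCT
  expect_match(dnan$note, "CT")
  expect_error(nucleotide_constraints("custom"), "mapping")
})

test_that("codon rate matrix construction obeys its contracts", {
  exch <- c(AC = 0.7, AG = 1, AT = 0.3, CG = 1.4, CT = 2.2, GT = 0.5)
  freqs <- estimate_codon_frequencies(
    as_codon_alignment(msa(c("a", "b"), c("ATGGCTAAA", "ATGGCAAAG"),
                           "nucleotide")), "F61")
  mod <- build_codon_model(exch, freqs, dn = 0.8, ds = 1.7)
  Q <- mod$Q
  ## multi-nucleotide changes have rate exactly 0 (exhaustive 61x61)
  s <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  ndiff <- outer(seq_len(61), seq_len(61),
                 Vectorize(function(i, j) sum(s[i, ] != s[j, ])))
  expect_true(all(Q[ndiff > 1] == 0))
  ## dn = 0 kills all non-synonymous rates
  mod0 <- build_codon_model(exch, freqs, dn = 0, ds = 1)
  aa <- translate_codons(SENSE_CODONS)
  nonsyn <- outer(aa, aa, "!=") & ndiff == 1
  expect_true(all(mod0$Q[nonsyn] == 0))
  expect_true(any(mod0$Q[!nonsyn & ndiff == 1] > 0))
  ## neutral limit: Q(d, d) = d * Q(1, 1)
  expect_equal(build_codon_model(exch, freqs, 0.6, 0.6)$Q,
               0.6 * build_codon_model(exch, freqs, 1, 1)$Q,
               tolerance = 1e-12)
  ## detailed balance w.r.t. the codon frequencies
  F <- freqs * Q
  expect_lt(max(abs(F - t(F))), 1e-12)
  expect_lt(max(abs(rowSums(Q))), 1e-10)
})

test_that("codon frequency estimators", {
  one <- as_codon_alignment(msa("x", "ATGATGATG", "nucleotide"))
  f61 <- estimate_codon_frequencies(one, "F61", pseudocount = 0)
  expect_equal(unname(f61["ATG"]), 1)
  ## uniform nucleotide composition -> approximately uniform sense codons
  aln <- as_codon_alignment(msa(c("a", "b"),
                                c("ACGTACGTACGT", "CAGTTGCAAGTC"),
                                "nucleotide"))
  f34 <- estimate_codon_frequencies(aln, "F3x4")
  expect_equal(sum(f34), 1, tolerance = 1e-12)
  expect_lt(max(f34) / min(f34), 30)   # no degenerate spikes
  ## F3x4 equals position-frequency products renormalized (hand check)
  cds <- as.vector(aln$codons)
  pos <- do.call(rbind, strsplit(cds, ""))
  pf <- apply(pos, 2, function(c0) table(factor(c0, c("A","C","G","T"))) /
                length(c0))
  want <- sapply(SENSE_CODONS, function(cd) {
    b <- strsplit(cd, "")[[1]]
    pf[b[1], 1] * pf[b[2], 2] * pf[b[3], 3]
  })
  expect_equal(as.numeric(f34), as.numeric(want / sum(want)),
               tolerance = 1e-12)
})

test_that("mixture likelihood identity and weight profiling", {
  tree <- simulate_tree(6, 1, seed = 51)
  sim <- simulate_codons(tree,
                         simulation_spec(c(0.2, 1), c(0.5, 1.5),
                                         matrix(0.25, 2, 2), 40),
                         seed = 52)
  tp <- sitesel:::.tip_partials(sim$alignment)
  tr <- ape::reorder.phylo(tree, "postorder")
  exch <- c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1, GT = 1)
  cf <- estimate_codon_frequencies(sim$alignment)
  M <- sitesel:::.rel_class_logliks(tp, tr, exch, cf,
                                    c(0.2, 1), c(0.5, 1.5))
  w <- c(0.1, 0.2, 0.3, 0.4)
  ## definitional identity: mixture site likelihood = weighted sum
  mix <- log(exp(M) %*% w)
  direct <- sapply(seq_len(nrow(M)), function(s)
    log(sum(w * exp(M[s, ]))))
  expect_equal(as.vector(mix), direct, tolerance = 1e-10)
  ## EM-profiled weights never fall below the uniform-weight likelihood
  pw <- sitesel:::.profile_weights(M)
  expect_gte(pw$loglik, sum(log(exp(M) %*% rep(0.25, 4))))
  expect_equal(sum(pw$w), 1, tolerance = 1e-9)
})

test_that("site posteriors and Bayes factors: closed forms and oracle", {
  ## engineered fit: 2x2 grid, known weights and site likelihoods
  dn <- c(0.5, 2); ds <- c(1, 1.2)
  W <- matrix(c(0.5, 0.2, 0.2, 0.1), 2, 2, byrow = TRUE)
  M <- log(matrix(c(1, 1, 1, 1,          # uninformative site
                    0.1, 0.2, 0.4, 0.8,  # likes the positive classes
                    8, 4, 1, 0.5), 3, 4, byrow = TRUE))
  fit <- fake_rel_fit(dn, ds, W, M)
  post <- site_posteriors(fit)
  expect_equal(rowSums(post), rep(1, 3), tolerance = 1e-12)
  ## brute-force oracle over the 4 classes
  wvec <- as.vector(t(W))
  for (s in 1:3) {
    want <- wvec * exp(M[s, ]); want <- want / sum(want)
    expect_equal(post[s, ], want, tolerance = 1e-12)
  }
  ## uninformative site: posterior equals prior; BF = 1
  bf <- bayes_factor_positive(fit)
  expect_equal(bf$posterior[1], fit$prior_positive, tolerance = 1e-12)
  expect_equal(bf$bayes_factor[1], 1, tolerance = 1e-12)
  ## closed form: prior 0.1, post 0.5 -> BF 9
  W2 <- matrix(c(0.9, 0, 0.1, 0), 2, 2, byrow = TRUE)   # prior pos = 0.1
  M2 <- log(matrix(c(1, 1, 9, 1), 1, 4, byrow = TRUE))  # post = 0.5
  fit2 <- fake_rel_fit(dn, ds, W2, M2)
  bf2 <- bayes_factor_positive(fit2)
  expect_equal(bf2$posterior[1], 0.5, tolerance = 1e-12)
  expect_equal(bf2$bayes_factor[1], 9, tolerance = 1e-9)
  ## posterior 1 with prior < 1 -> infinite BF
  W3 <- matrix(c(0.5, 0, 0.5, 0), 2, 2, byrow = TRUE)
  M3 <- matrix(c(-1e6, -1e6, 0, -1e6), 1, 4)
  expect_equal(bayes_factor_positive(fake_rel_fit(dn, ds, W3, M3))$bayes_factor,
               Inf)
  ## weight-1 class: posterior 1 for that class everywhere
  W4 <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  post4 <- site_posteriors(fake_rel_fit(dn, ds, W4, M))
  expect_equal(post4[, 1], rep(1, 3), tolerance = 1e-12)
})

test_that("classification thresholds are inclusive at the boundaries", {
  dn <- c(0.5, 2); ds <- c(1, 1.2)
  W <- matrix(c(0.45, 0.45, 0.05, 0.05), 2, 2, byrow = TRUE)
  prior <- 0.1
  ## craft site likelihood rows giving exact target Bayes factors
  bf_to_post <- function(bf) {
    po <- bf * prior / (1 - prior)
    po / (1 + po)
  }
  row_for <- function(post) {
    ## likelihood ratio between positive block and the rest
    lr <- (post / 0.1) / ((1 - post) / 0.9)
    log(c(1, 1, lr, lr))
  }
  ## nudge the boundary targets by 1e-9 so float round-trips through
  ## exp/log cannot flip the inclusive comparison being tested
  targets <- c(197, 50 * (1 + 1e-9), 49.9, 10 * (1 + 1e-9), 9.99)
  M <- do.call(rbind, lapply(targets, function(b) row_for(bf_to_post(b))))
  fit <- fake_rel_fit(dn, ds, W, M)
  cls <- classify_sites(fit)
  expect_equal(cls$bayes_factor, targets, tolerance = 1e-6)
  expect_equal(cls$category,
               c("strong", "strong", "weak", "weak", "none"))
})

test_that("fit_rel: nesting, posteriors sum to 1, negative control flag", {
  tree <- simulate_tree(8, 1, seed = 61)
  spec <- simulation_spec(c(0.3, 1, 1.0001), c(0.3, 1, 1.0001),
                          diag(3) / 3, 120)
  sim <- simulate_codons(tree, spec, seed = 62)
  fit <- fit_rel(sim$alignment, tree, n_starts = 2, maxit = 200)
  expect_s3_class(fit, "rel_fit")
  post <- site_posteriors(fit)
  expect_equal(rowSums(post), rep(1, 120), tolerance = 1e-9)
  ## nesting: 3x3 fit is at least as good as the ML single neutral class
  tp <- sitesel:::.tip_partials(sim$alignment)
  one_ll <- function(lc) sum(sitesel:::.rel_class_logliks(
    tp, fit$tree, fit$nucleotide$exch, fit$codon_freqs,
    exp(lc), exp(lc)))
  best1 <- stats::optimize(one_ll, c(-6, 4), maximum = TRUE)$objective
  expect_gte(fit$loglik, best1 - 0.5)
  ## scaled reporting convention: weighted mean of scaled ds is 1
  u <- colSums(fit$grid$weights)
  expect_equal(sum(u * fit$grid$ds_scaled), 1, tolerance = 1e-9)
  ## ratio grid is scale-invariant
  expect_equal(outer(fit$grid$dn_scaled, fit$grid$ds_scaled, "/"),
               fit$grid$ratio, tolerance = 1e-12)
  ## TSV writer produces one row per site
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rel_tsv(fit, f)
  expect_equal(nrow(utils::read.delim(f)), 120)
})
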