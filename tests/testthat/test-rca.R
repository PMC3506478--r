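test_that("discrete gamma category rates have mean 1 and match phangorn", {
  for (alpha in c(0.2, 0.5, 1, 3)) {
    r <- discrete_gamma_rates(alpha, 16)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
    expect_equal(r, as.vector(phangorn::discrete.gamma(alpha, 16)),
                 tolerance = 1e-6)
  }
  expect_equal(discrete_gamma_rates(0.7, 1), 1)
})

test_that("normalize_s is an exact z-transform", {
  expect_equal(normalize_s(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(normalize_s(rep(4, 10)), rep(0, 10))
  set.seed(8)
  for (i in 1:5) {
    x <- stats::rgamma(50, 1)
    s <- normalize_s(x)
    expect_equal(mean(s), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(s^2)), 1, tolerance = 1e-9)
  }
})

test_that("window_mean truncates at termini and matches a loop oracle", {
  expect_equal(window_mean(c(3, 1, 4), 1), c(3, 1, 4))
  expect_equal(window_mean(rep(2.5, 9), 7), rep(2.5, 9))
  s <- c(0, 0, 7, 0, 0, 0, 0, 0, 0)
  w <- window_mean(s, 7)
  expect_equal(w[3], 7 / 6)
  expect_equal(w[4], 1)
  ## loop oracle on random input
  set.seed(3)
  x <- stats::rnorm(40)
  for (n in c(1, 3, 7, 11)) {
    want <- sapply(seq_along(x), function(c) {
      h <- (n - 1) / 2
      mean(x[max(1, c - h):min(length(x), c + h)])
    })
    expect_equal(window_mean(x, n), want, tolerance = 1e-12)
  }
  expect_error(window_mean(x, 4), "n")
})

test_that("posterior rates: missing data, ordering, quadrature oracle", {
  tree <- tree4()
  mod <- jtt_model()
  aln <- msa(c("A", "B", "C", "D"),
             c("-AMW", "-AMC", "-AWV", "-AHD"), "protein")
  r <- site_posterior_rates(aln, tree, mod, alpha = 0.5, K = 16)
  expect_equal(r[1], 1, tolerance = 1e-9)   # all-gap: prior mean
  expect_lt(r[2], r[3])                     # invariant < variable
  expect_lt(r[3], r[4])                     # 2 states < 4 distinct states
  ## K=16 vs fine-quadrature (K=1024) oracle within 2% (moderate
  ## columns; at small alpha the top-category tail dominates and the
  ## K=16 discretization error is intrinsically larger)
  aln2 <- msa(c("A", "B", "C", "D"),
              c("-AMWK", "-AMWK", "-AMCK", "-AHCK"), "protein")
  r16 <- site_posterior_rates(aln2, tree, mod, alpha = 1, K = 16)
  r1024 <- site_posterior_rates(aln2, tree, mod, alpha = 1, K = 1024)
  expect_lt(max(abs(r16 - r1024) / r1024), 0.02)
})

test_that("gamma shape: boundary behaviour and parameter recovery", {
  tree <- tree4()
  cons <- msa(c("A", "B", "C", "D"),
              c("MKVL", "MKVL", "MKVL", "MKVL"), "protein")
  ## a perfectly conserved alignment is best explained by near-zero
  ## rates (most categories ~0 at tiny alpha), so the ML shape pins at
  ## the LOWER bound, not the upper one
  expect_warning(fit <- fit_gamma_shape(cons, tree), "lower bound")
  expect_equal(fit$alpha, 0.02)
  expect_true(fit$at_bound)

  ## recovery: alpha = 0.5, 8 taxa, 1,000 sites
  tr <- simulate_tree(8, 1, seed = 31)
  aln <- simulate_protein(tr, 1000, alpha = 0.5, seed = 32)
  est <- fit_gamma_shape(aln, tr)
  expect_gt(est$alpha, 0.35)
  expect_lt(est$alpha, 0.7)

  ## finer discretization never loses likelihood (up to optimizer slack)
  aln2 <- simulate_protein(tr, 200, alpha = 0.5, seed = 33)
  f2 <- fit_gamma_shape(aln2, tr, K = 2)
  f16 <- fit_gamma_shape(aln2, tr, K = 16)
  expect_gte(f16$loglik, f2$loglik - 0.5)
})

test_that("call_regions: construction, boundaries, reference mapping", {
  expect_equal(nrow(call_regions(rep(0.2, 30), 0.5)), 0)
  w <- rep(-1, 50); w[10:14] <- 0.8; w[30] <- 0.5   # tie at threshold
  reg <- call_regions(w, 0.5)
  expect_equal(reg$start, c(10, 30))
  expect_equal(reg$end, c(14, 30))
  ## offset shifts reported coordinates
  reg_off <- call_regions(w, 0.5, offset = 36)
  expect_equal(reg_off$start, c(46, 66))
  ## reference map: gaps in the reference re-number the bounds
  aln <- msa(c("r", "q"), c("AA--AAAAAA", "AAAAAAAAAA"), "protein")
  rm <- build_reference_map(aln, "r")
  w2 <- rep(-1, 10); w2[2:5] <- 1
  reg2 <- call_regions(w2, 0.5, ref_map = rm)
  expect_equal(reg2$start, 2)   # columns 3,4 are reference gaps
  expect_equal(reg2$end, 3)
})

test_that("region calling is idempotent and threshold-monotone", {
  set.seed(12)
  w <- window_mean(normalize_s(stats::rgamma(120, 0.6)), 7)
  r1 <- call_regions(w, 0.5)
  covered <- function(reg) {
    if (!nrow(reg)) return(integer(0))
    unlist(Map(seq, reg$start_col, reg$end_col))
  }
  for (thr in c(0.7, 1.0, 1.5)) {
    r2 <- call_regions(w, thr)
    expect_true(all(covered(r2) %in% covered(r1)))
    expect_lte(nrow(r2) == 0, TRUE)
  }
  ## every in-region position really has w >= threshold, and maximality
  expect_true(all(w[covered(r1)] >= 0.5))
  outside <- setdiff(seq_along(w), covered(r1))
  expect_true(all(w[outside] < 0.5))
})

test_that("rca_profile wires the stages together", {
  tr <- simulate_tree(8, 1.2, seed = 41)
  rates <- rep(0.3, 100); rates[40:59] <- 1.5   # planted fast block
  aln <- simulate_protein(tr, 100, alpha = 1, seed = 42, rates = rates)
  prof <- rca_profile(aln, tr, reference_id = "t1")
  expect_s3_class(prof, "conservation_profile")
  expect_equal(length(prof$s_scores), 100)
  expect_equal(mean(prof$s_scores), 0, tolerance = 1e-9)
  expect_true(nrow(prof$regions) >= 1)
  ## the top-scoring region overlaps the planted block
  top <- prof$regions[which.max(prof$regions$end_col -
                                  prof$regions$start_col), ]
  expect_true(top$start_col <= 59 && top$end_col >= 40)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rca_tsv(prof, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 100)
  expect_true(any(tab$in_region))
})
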