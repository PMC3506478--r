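## Self-contained recovery/false-positive audits on synthetic data.
## These functions define the package's statistical acceptance surface:
## each simulates data from a stated world with known truth and measures
## how well the corresponding analysis stage recovers it.  They are used
## by the test suite and by scripts/acceptance.R.

#' RCA planted-block recovery audit
#'
#' Simulates protein alignments with a planted block of fast-evolving
#' columns (rate x5, default 20 consecutive columns among 300; 10 taxa)
#' and asks whether a region called at the 0.5 SD threshold overlaps the
#' planted block.
#'
#' @param n_reps number of seeded replicates.
#' @param seed base seed.
#' @param n_taxa,n_sites,block,fast_rate world parameters: taxon count,
#'   column count, planted block positions, rate multiplier.
#' @return list with `recovered` (logical per replicate) and `rate`.
#' @export
audit_rca_recovery <- function(n_reps = 50, seed = 1, n_taxa = 10,
                               n_sites = 300, block = 141:160,
                               fast_rate = 5) {
  recovered <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    s <- seed + 7 * r
    tree <- simulate_tree(n_taxa, 1, seed = s)
    rates <- rep(1, n_sites)
    rates[block] <- fast_rate
    aln <- simulate_protein(tree, n_sites, alpha = 1, seed = s + 1,
                            rates = rates)
    fit <- suppressWarnings(fit_gamma_shape(aln, tree))
    pr <- site_posterior_rates(aln, tree, alpha = fit$alpha)
    reg <- call_regions(window_mean(normalize_s(pr)), 0.5)
    recovered[r] <- any(reg$start_col <= max(block) &
                          reg$end_col >= min(block))
  }
  list(recovered = recovered, rate = mean(recovered))
}

## shared REL audit runner
.rel_audit_rep <- function(seed, n_taxa, n_sites, dn, ds, assignment,
                           n_starts, maxit) {
  tree <- simulate_tree(n_taxa, 1, seed = seed)
  k <- nrow(assignment)
  spec <- simulation_spec(dn, ds,
                          matrix(1 / (length(dn) * length(ds)),
                                 length(dn), length(ds)),
                          n_sites, class_assignment = assignment)
  sim <- simulate_codons(tree, spec, seed = seed + 500)
  fit <- fit_rel(sim$alignment, tree, n_starts = n_starts, maxit = maxit)
  list(fit = fit, sites = classify_sites(fit), truth = sim$truth)
}

#' REL type-I (false positive) audit
#'
#' All-neutral simulation: every site evolves with dn = ds = 1 (strict
#' neutrality, no selection signal).  Records, per replicate, whether
#' any site reaches the strong Bayes-factor threshold, plus the fitted
#' prior mass on dN > dS classes.
#'
#' @param n_reps seeded replicates.
#' @param seed base seed.
#' @param n_taxa,n_sites world size (default 12 taxa, 300 codons).
#' @param n_starts,maxit optimizer effort per fit.
#' @return list with `n_bf50` (count of sites at BF >= 50 per
#'   replicate), `violations` (replicates with any such site),
#'   `positive_weight` (fitted prior mass on dN > dS per replicate).
#' @export
audit_rel_type1 <- function(n_reps = 50, seed = 1, n_taxa = 12,
                            n_sites = 300, n_starts = 2, maxit = 200) {
  n_bf50 <- integer(n_reps)
  posw <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- seed + 1000 * r
    rep_res <- .rel_audit_rep(s, n_taxa, n_sites,
                              dn = 1, ds = 1,
                              assignment = cbind(rep(1, n_sites), 1),
                              n_starts, maxit)
    n_bf50[r] <- sum(rep_res$sites$category == "strong")
    posw[r] <- rep_res$fit$prior_positive
  }
  list(n_bf50 = n_bf50, violations = sum(n_bf50 > 0),
       positive_weight = posw)
}

#' REL power and parameter-recovery audit
#'
#' 10% of sites evolve at dN/dS = 4, the rest under purifying selection.
#' Measures, per replicate: presence of a fitted class with ratio > 1,
#' the fraction of planted sites flagged at BF >= 10, and whether the
#' best fitted positive ratio is within a factor 2 of the truth.
#'
#' @inheritParams audit_rel_type1
#' @param true_ratio planted dN/dS (default 4).
#' @return list with per-replicate vectors `has_positive`,
#'   `flagged_frac`, `ratio_ok`, `fitted_ratio`, and the aggregate
#'   `flagged_overall` (fraction of all planted sites flagged).
#' @export
audit_rel_power <- function(n_reps = 50, seed = 1, n_taxa = 12,
                            n_sites = 300, true_ratio = 4,
                            n_starts = 2, maxit = 200) {
  n_pos <- round(0.1 * n_sites)
  has_positive <- logical(n_reps)
  flagged_frac <- numeric(n_reps)
  fitted_ratio <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- seed + 2000 * r
    ## 45% ratio 0.1, 45% ratio 0.5, 10% ratio = true_ratio
    n1 <- round(0.45 * n_sites); n2 <- round(0.45 * n_sites)
    assignment <- cbind(c(rep(1, n1), rep(2, n2),
                          rep(3, n_sites - n1 - n2)), 2)
    assignment[, 2] <- 2
    rep_res <- .rel_audit_rep(
      s, n_taxa, n_sites,
      dn = c(0.1, 0.5, true_ratio), ds = c(0.8, 1, 1.25),
      assignment = assignment, n_starts, maxit)
    planted <- which(rep_res$truth$dn_class == 3)
    flagged_frac[r] <- mean(rep_res$sites$category[planted] %in%
                              c("strong", "weak"))
    pos <- rel_positive_class(rep_res$fit, min_weight = 0.01)
    has_positive[r] <- pos$any_positive
    fitted_ratio[r] <- pos$best_ratio
  }
  list(has_positive = has_positive, flagged_frac = flagged_frac,
       fitted_ratio = fitted_ratio,
       ratio_ok = has_positive & fitted_ratio >= true_ratio / 2 &
         fitted_ratio <= true_ratio * 2,
       flagged_overall = mean(flagged_frac))
}

#' BGM null (false positive) audit
#'
#' Independent binary site columns (per-branch Bernoulli(0.3), 20
#' branches, 10 sites) fed directly to the network MCMC; a run is clean
#' when no edge posterior reaches 0.5.
#'
#' @param n_reps seeded runs.
#' @param seed base seed.
#' @param n_sites,n_branches,p world parameters.
#' @param chain_length,burn_in MCMC settings.
#' @return list with `clean` (logical per run) and `max_posterior`.
#' @export
audit_bgm_null <- function(n_reps = 20, seed = 1, n_sites = 10,
                           n_branches = 20, p = 0.3,
                           chain_length = 20000, burn_in = 2000) {
  clean <- logical(n_reps)
  maxp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + 10 * r)
    X <- matrix(stats::rbinom(n_sites * n_branches, 1, p),
                n_sites, n_branches)
    map <- structure(list(matrix = X, branch_count = rowSums(X),
                          positions = seq_len(n_sites),
                          branches = paste0("b", seq_len(n_branches))),
                     class = "subst_map")
    net <- bgm_fit(map, chain_length = chain_length, burn_in = burn_in,
                   seed = seed + 10 * r + 1)
    maxp[r] <- max(net$edge_posterior$posterior)
    clean[r] <- maxp[r] < 0.5
  }
  list(clean = clean, max_posterior = maxp, rate = mean(clean))
}

#' BGM co-evolution recovery audit
#'
#' A coupled pair (rho = 0.9) planted among 8 independent sites on a
#' 20-taxon tree.  Two detection paths are audited:
#' `map_source = "truth"` feeds the simulator's own branch-level
#' non-synonymous event map to the network MCMC (tests the detector and
#' the generator's dependence structure directly);
#' `map_source = "reconstruction"` runs the full pipeline — joint
#' ancestral reconstruction under the neutral fallback model (branch
#' lengths in substitution units), substitution map, >= 3 count filter —
#' before the MCMC.  Divergence (depth 0.6) and class rates (coupled dN
#' 1.8, independent dN 0.6, dS 0.5) are chosen so coupled sites accrue
#' roughly five informative events without saturating the
#' reconstruction; the reconstruction path is intrinsically noisier and
#' its recovery rate is seed-set sensitive (see the methods vignette).
#'
#' @param n_reps seeded replicates.
#' @param seed base seed.
#' @param rho coupling strength.
#' @param map_source `"truth"` or `"reconstruction"`.
#' @param chain_length,burn_in MCMC settings.
#' @return list with `recovered` (logical; filtered-out pairs count as
#'   failures) and `rate`.
#' @export
audit_bgm_recovery <- function(n_reps = 20, seed = 1, rho = 0.9,
                               map_source = c("truth", "reconstruction"),
                               chain_length = 30000, burn_in = 3000) {
  map_source <- match.arg(map_source)
  recovered <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    s <- seed + 100 * r
    tree <- simulate_tree(20, 0.6, seed = s)
    assignment <- cbind(c(2, 2, rep(1, 8)), rep(1, 10))
    spec <- simulation_spec(
      c(0.6, 1.8), c(0.5, 1), matrix(0.25, 2, 2), 10,
      class_assignment = assignment,
      coupling_pairs = data.frame(leader = 1, follower = 2, rho = rho))
    sim <- simulate_coevolution(tree, spec, seed = s + 1)
    if (map_source == "truth") {
      smap <- structure(list(matrix = sim$nonsyn_map,
                             branch_count = rowSums(sim$nonsyn_map),
                             positions = seq_len(nrow(sim$nonsyn_map)),
                             branches = paste0("b", seq_len(ncol(sim$nonsyn_map)))),
                        class = "subst_map")
    } else {
      mod <- build_codon_model(c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1,
                                 GT = 1), rep(1 / 61, 61), 1, 1)
      mu <- -sum(mod$freq * diag(mod$Q))
      tr <- sim$tree
      tr$edge.length <- tr$edge.length / mu
      anc <- joint_ancestral_codons(tr, sim$alignment, mod)
      smap <- substitution_map(tr, sim$alignment, anc)
    }
    fmap <- filter_sites(smap, 3)
    if (!all(c(1, 2) %in% fmap$positions)) {
      recovered[r] <- FALSE
      next
    }
    net <- bgm_fit(fmap, chain_length = chain_length, burn_in = burn_in,
                   seed = s + 2)
    pairs <- call_coevolving(net, 0.5)$pairs
    recovered[r] <- nrow(pairs) > 0 &&
      any(pairs$site1 + pairs$site2 == 3 & pmin(pairs$site1, pairs$site2) == 1)
  }
  list(recovered = recovered, rate = mean(recovered))
}
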