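## Seeded simulators for trees, protein alignments (JTT + gamma rates),
## codon alignments with site-specific (dN, dS) classes, and coupled
## co-evolving site pairs.  Truth tables are first-class outputs so
## recovery tests are self-contained.

#' Simulate a Yule tree
#'
#' Pure-birth topology with branch lengths rescaled so the mean
#' root-to-tip path length equals `depth`.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param depth target mean root-to-tip length (expected substitutions
#'   per site).
#' @param seed integer seed (mandatory; same seed, same tree).
#' @return rooted binary `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, depth = 1, seed) {
  stopifnot(n_taxa >= 3, depth > 0)
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tip_depths <- ape::node.depth.edgelength(tr)[seq_len(n_taxa)]
  tr$edge.length <- tr$edge.length * depth / mean(tip_depths)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}

## Gillespie simulation of one site down one branch; returns final state
## and the ordered list of (from, to) jumps.
.evolve_branch <- function(state, Q, t) {
  jumps_from <- integer(0); jumps_to <- integer(0)
  repeat {
    rate <- -Q[state, state]
    if (rate <= 0) break
    wait <- stats::rexp(1, rate)
    if (wait >= t) break
    t <- t - wait
    p <- Q[state, ]; p[state] <- 0
    new <- sample.int(length(p), 1, prob = p)
    jumps_from <- c(jumps_from, state); jumps_to <- c(jumps_to, new)
    state <- new
  }
  list(state = state, from = jumps_from, to = jumps_to)
}

## Simulate all sites over a tree for per-site Q matrices.  Returns
## tip-state matrix, per-site substitution counts, and (optionally) a
## per-site x per-edge matrix of non-synonymous event indicators when
## `aa` (per-state amino acid) is given.
.simulate_sites <- function(tree, Qs, root_probs, aa = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  pre <- rev(seq_len(nrow(edge)))              # preorder edge sweep
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  nsites <- length(Qs)
  ns <- nrow(Qs[[1]])
  root <- edge[nrow(edge), 1]
  states <- matrix(0L, nnode, nsites)
  counts <- integer(nsites)
  nonsyn <- matrix(0L, nsites, nrow(edge))
  for (s in seq_len(nsites)) {
    states[root, s] <- sample.int(ns, 1, prob = root_probs)
    for (k in pre) {
      res <- .evolve_branch(states[edge[k, 1], s], Qs[[s]],
                            tr$edge.length[k])
      states[edge[k, 2], s] <- res$state
      counts[s] <- counts[s] + length(res$from)
      if (!is.null(aa) && length(res$from) &&
          any(aa[res$from] != aa[res$to]))
        nonsyn[s, k] <- 1L
    }
  }
  list(tree = tr, states = states, counts = counts, nonsyn = nonsyn,
       edge = edge, ntip = ntip)
}

#' Simulate a protein alignment with gamma rate heterogeneity
#'
#' Per-site rates are drawn from Gamma(shape = `alpha`, mean 1); root
#' states from the model equilibrium; substitution histories are
#' simulated exactly (Gillespie) down each branch.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_sites number of columns.
#' @param alpha gamma shape (> 0).
#' @param seed integer seed.
#' @param model amino-acid model (default JTT).
#' @param rates optional fixed per-site rate vector overriding the
#'   gamma draw (e.g. to plant a block of fast sites).
#' @return protein [msa()] with attributes `true_rates` and
#'   `subst_counts`.
#' @export
simulate_protein <- function(tree, n_sites, alpha = 1, seed, model = jtt_model(),
                             rates = NULL) {
  stopifnot(alpha > 0)
  set.seed(seed)
  if (is.null(rates)) rates <- stats::rgamma(n_sites, alpha, alpha)
  stopifnot(length(rates) == n_sites)
  Qs <- lapply(rates, function(r) model$Q * r)
  sim <- .simulate_sites(tree, Qs, model$freq)
  tipm <- matrix(model$states[sim$states[seq_len(sim$ntip), , drop = FALSE]],
                 sim$ntip, n_sites)
  out <- msa(sim$tree$tip.label, apply(tipm, 1, paste, collapse = ""),
             "protein")
  attr(out, "true_rates") <- rates
  attr(out, "subst_counts") <- sim$counts
  out
}

#' Specification for codon-alignment simulation
#'
#' @param dn_values,ds_values the 3 (or k) grid values.
#' @param weights class weight matrix (rows dN, cols dS), summing to 1.
#' @param n_sites number of codon sites.
#' @param class_assignment optional explicit per-site class index matrix
#'   rows `(i, j)`; default: drawn from `weights`.
#' @param coupling_pairs data.frame with columns `leader`, `follower`,
#'   `rho` for co-evolution simulation (sites must not be reused across
#'   pairs).
#' @return list of class `sim_spec`.
#' @export
simulation_spec <- function(dn_values, ds_values, weights, n_sites,
                            class_assignment = NULL, coupling_pairs = NULL) {
  weights <- as.matrix(weights)
  stopifnot(length(dn_values) == nrow(weights),
            length(ds_values) == ncol(weights),
            abs(sum(weights) - 1) < 1e-9, all(weights >= 0))
  if (!is.null(coupling_pairs)) {
    mem <- c(coupling_pairs$leader, coupling_pairs$follower)
    if (anyDuplicated(mem)) stop("overlapping pair membership")
    if (any(coupling_pairs$rho < 0 | coupling_pairs$rho > 1))
      stop("rho must be in [0,1]")
  }
  structure(list(dn_values = dn_values, ds_values = ds_values,
                 weights = weights, n_sites = n_sites,
                 class_assignment = class_assignment,
                 coupling_pairs = coupling_pairs),
            class = "sim_spec")
}

#' Simulate a codon alignment under a (dN, dS) class grid
#'
#' Each site evolves under the codon model for its assigned class.
#'
#' @param tree `phylo` with branch lengths.
#' @param spec a [simulation_spec()].
#' @param seed integer seed.
#' @param exch nucleotide exchangeabilities (default equal rates).
#' @param codon_freqs equilibrium codon frequencies (default uniform
#'   over the 61 sense codons).
#' @return list with `alignment` (codon alignment), `truth` (data.frame
#'   site, dn_class, ds_class, dn, ds, positive) and `nonsyn_map`
#'   (sites x branches event indicator, postorder edge order).
#' @export
simulate_codons <- function(tree, spec, seed,
                            exch = c(AC = 1, AG = 1, AT = 1, CG = 1,
                                     CT = 1, GT = 1),
                            codon_freqs = rep(1 / 61, 61)) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(seed)
  nd <- length(spec$dn_values); ns_ <- length(spec$ds_values)
  if (is.null(spec$class_assignment)) {
    flat <- sample.int(nd * ns_, spec$n_sites, replace = TRUE,
                       prob = as.vector(t(spec$weights)))
    ij <- cbind((flat - 1) %/% ns_ + 1, (flat - 1) %% ns_ + 1)
  } else {
    ij <- spec$class_assignment
  }
  models <- list()
  key <- function(i, j) paste0(i, ",", j)
  for (i in seq_len(nd)) for (j in seq_len(ns_)) {
    models[[key(i, j)]] <- build_codon_model(exch, codon_freqs,
                                             spec$dn_values[i],
                                             spec$ds_values[j])
  }
  Qs <- lapply(seq_len(spec$n_sites), function(s)
    models[[key(ij[s, 1], ij[s, 2])]]$Q)
  ## common normalization so branch lengths are expected substitutions
  ## per codon site averaged over the realized class assignment: dn/ds
  ## values act as relative rates, tree depth sets the divergence
  mu <- mean(vapply(Qs, function(Q) -sum(codon_freqs * diag(Q)),
                    numeric(1)))
  if (mu <= 0) mu <- 1
  Qs <- lapply(Qs, function(Q) Q / mu)
  aa <- translate_codons(SENSE_CODONS)
  sim <- .simulate_sites(tree, Qs, codon_freqs, aa = aa)
  tipcd <- matrix(SENSE_CODONS[sim$states[seq_len(sim$ntip), , drop = FALSE]],
                  sim$ntip, spec$n_sites)
  aln <- as_codon_alignment(msa(sim$tree$tip.label,
                                apply(tipcd, 1, paste, collapse = ""),
                                "nucleotide"))
  truth <- data.frame(site = seq_len(spec$n_sites),
                      dn_class = ij[, 1], ds_class = ij[, 2],
                      dn = spec$dn_values[ij[, 1]],
                      ds = spec$ds_values[ij[, 2]])
  truth$positive <- truth$dn > truth$ds
  list(alignment = aln, truth = truth, nonsyn_map = sim$nonsyn,
       tree = sim$tree, rate_scale = 1 / mu)
}

#' Simulate coupled (co-evolving) codon sites
#'
#' Leader sites of each coupled pair evolve under their assigned class;
#' for every branch on which a leader shows a non-synonymous event, the
#' follower receives a forced non-synonymous substitution on the same
#' branch with probability `rho`, and on a uniformly random branch
#' otherwise.  Followers otherwise evolve synonymously; uncoupled sites
#' are independent [simulate_codons()] sites.
#'
#' @inheritParams simulate_codons
#' @return as [simulate_codons()], plus `truth$coupled_with` and
#'   `truth$rho`.
#' @export
simulate_coevolution <- function(tree, spec, seed,
                                 exch = c(AC = 1, AG = 1, AT = 1, CG = 1,
                                          CT = 1, GT = 1),
                                 codon_freqs = rep(1 / 61, 61)) {
  stopifnot(inherits(spec, "sim_spec"), !is.null(spec$coupling_pairs))
  base <- simulate_codons(tree, spec, seed, exch, codon_freqs)
  tr <- base$tree
  edge <- tr$edge
  pre <- rev(seq_len(nrow(edge)))
  ntip <- length(tr$tip.label)
  aa <- translate_codons(SENSE_CODONS)
  cp <- spec$coupling_pairs
  ## synonymous-only model for follower background evolution
  ds_bg <- max(mean(spec$ds_values), 1e-3)
  syn_Q <- build_codon_model(exch, codon_freqs, 0, ds_bg)$Q * base$rate_scale
  ## nonsynonymous jump kernel (row-normalized nonsyn rates)
  full_Q <- build_codon_model(exch, codon_freqs, 1, 0)$Q
  diag(full_Q) <- 0
  tipcd <- base$alignment$codons
  for (r in seq_len(nrow(cp))) {
    leader <- cp$leader[r]; follower <- cp$follower[r]; rho <- cp$rho[r]
    lead_branches <- which(base$nonsyn_map[leader, ] == 1L)
    forced <- integer(0)
    for (b in lead_branches) {
      forced <- c(forced,
                  if (stats::runif(1) < rho) b
                  else sample.int(nrow(edge), 1))
    }
    ## re-evolve the follower with forced events
    state <- sample.int(61, 1, prob = codon_freqs)
    st <- integer(ntip + tr$Nnode)
    st[edge[nrow(edge), 1]] <- state
    base$nonsyn_map[follower, ] <- 0L
    for (k in pre) {
      s0 <- st[edge[k, 1]]
      res <- .evolve_branch(s0, syn_Q, tr$edge.length[k])
      s1 <- res$state
      n_forced <- sum(forced == k)
      for (f in seq_len(n_forced)) {
        p <- full_Q[s1, ]
        if (sum(p) > 0) s1 <- sample.int(61, 1, prob = p)
      }
      if (n_forced > 0) base$nonsyn_map[follower, k] <- 1L
      st[edge[k, 2]] <- s1
    }
    tipcd[, follower] <- SENSE_CODONS[st[seq_len(ntip)]]
  }
  aln <- as_codon_alignment(msa(rownames(tipcd),
                                apply(tipcd, 1, paste, collapse = ""),
                                "nucleotide"))
  base$alignment <- aln
  base$truth$coupled_with <- NA_integer_
  base$truth$rho <- NA_real_
  for (r in seq_len(nrow(cp))) {
    base$truth$coupled_with[cp$leader[r]] <- cp$follower[r]
    base$truth$coupled_with[cp$follower[r]] <- cp$leader[r]
    base$truth$rho[c(cp$leader[r], cp$follower[r])] <- cp$rho[r]
  }
  base
}
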