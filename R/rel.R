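## Random-effects-likelihood (REL) site-specific selection analysis.
##
## A codon model separates synonymous (dS) and non-synonymous (dN)
## substitution rates; dN and dS each take one of three discrete values,
## giving a 3x3 grid of (dN, dS) classes whose values and weights are
## estimated by maximum likelihood.  Per-site inference is empirical
## Bayes; evidence for dN > dS at a site is summarized by a Bayes
## factor, with >= 50 read as strong and [10, 50) as weak support for
## positive selection.

#' Constrained nucleotide exchangeability sets
#'
#' Encodes reductions of the general reversible nucleotide model.  Each
#' of the five relative exchangeabilities (AC, AT, CG, CT, GT; AG is the
#' reference, fixed at 1) is either tied to the reference (`"ref"`) or
#' assigned a named free parameter; exchangeabilities sharing a name
#' share one parameter.
#'
#' Shipped presets (gene-specific reduced models for the chitinase
#' analysis and its two negative-control genes):
#' * `"chiJ"`: CG tied to the reference; CT shares the AC parameter;
#'   GT shares the AT parameter (2 free parameters).
#' * `"recA"`: AC and AT tied to the reference; CG, CT, GT free
#'   (3 free parameters).
#' * `"dnaN"`: AC, AT and GT tied to the reference; CG free; CT is kept
#'   as its own free parameter (its constraint is not specified by the
#'   published set, so the most general consistent reading is used and
#'   flagged).
#'
#' @param preset one of `"chiJ"`, `"recA"`, `"dnaN"`, `"GTR"`, or
#'   `"custom"` with `mapping` supplied.
#' @param mapping for `"custom"`: named character vector over
#'   `c("AC","AT","CG","CT","GT")` with values `"ref"` or parameter
#'   names.
#' @return object of class `nuc_constraints`: list with `mapping`,
#'   `params` (free parameter names) and `note`.
#' @export
nucleotide_constraints <- function(preset = c("GTR", "chiJ", "recA", "dnaN",
                                              "custom"),
                                   mapping = NULL) {
  preset <- match.arg(preset)
  note <- NULL
  mapping <- switch(preset,
    GTR  = c(AC = "RAC", AT = "RAT", CG = "RCG", CT = "RCT", GT = "RGT"),
    chiJ = c(AC = "RAC", AT = "RAT", CG = "ref", CT = "RAC", GT = "RAT"),
    recA = c(AC = "ref", AT = "ref", CG = "RCG", CT = "RCT", GT = "RGT"),
    dnaN = {
      note <- paste("CT exchangeability unspecified in the published",
                    "constraint set; kept as its own free parameter")
      c(AC = "ref", AT = "ref", CG = "RCG", CT = "RCT", GT = "ref")
    },
    custom = {
      if (is.null(mapping)) stop("custom constraints need 'mapping'")
      mapping
    })
  need <- c("AC", "AT", "CG", "CT", "GT")
  if (!all(need %in% names(mapping)))
    stop("mapping must cover: ", paste(need, collapse = ", "))
  mapping <- mapping[need]
  params <- unique(unname(mapping[mapping != "ref"]))
  structure(list(preset = preset, mapping = mapping, params = params,
                 note = note),
            class = "nuc_constraints")
}

#' @export
print.nuc_constraints <- function(x, ...) {
  cat(sprintf("Nucleotide constraints [%s]: AG=ref, %s (%d free parameter(s))\n",
              x$preset,
              paste(names(x$mapping), "=", x$mapping, collapse = ", "),
              length(x$params)))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

## Expand constraint parameters into the 6 exchangeabilities (AG = 1).
.expand_exch <- function(constraints, par) {
  v <- c(AG = 1, vapply(constraints$mapping, function(slot) {
    if (slot == "ref") 1 else unname(par[slot])
  }, numeric(1)))
  v[c("AC", "AG", "AT", "CG", "CT", "GT")]
}

#' Fit a constrained reversible nucleotide model
#'
#' Stage-1 fit of the REL pipeline: empirical base frequencies, ML
#' estimates of the free exchangeability parameters and ML branch
#' lengths on the fixed topology.
#'
#' @param aln nucleotide [msa()].
#' @param tree `phylo`; branch lengths (if absent, initialized at 0.1)
#'   are re-optimized.
#' @param constraints a [nucleotide_constraints()] object.
#' @param rounds alternations of exchangeability and branch-length
#'   optimization.
#' @return list with `exch` (named 6-vector, AG = 1), `freq`, `tree`
#'   (ML branch lengths), `loglik`, `constraints`.
#' @export
fit_nucleotide <- function(aln, tree, constraints = nucleotide_constraints("GTR"),
                           rounds = 3) {
  check_tree_alignment(tree, aln)
  m <- unclass(aln)
  counts <- table(factor(m, NUCLEOTIDES))
  freq <- as.numeric(counts) / sum(counts)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tp <- .tip_partials(aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  par <- stats::setNames(rep(1, length(constraints$params)),
                         constraints$params)
  model_of <- function(par) gtr_model(.expand_exch(constraints, par), freq)
  ll <- -Inf
  for (r in seq_len(rounds)) {
    if (length(par)) {
      f <- function(lp) {
        -sum(.prune_loglik(tr, tp, model_of(exp(stats::setNames(lp, names(par)))),
                           1))
      }
      opt <- if (length(par) == 1) {
        o <- stats::optimize(f, c(-5, 5), tol = 1e-6)
        list(par = o$minimum, value = o$objective)
      } else {
        stats::optim(log(par), f, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-9))
      }
      par <- exp(stats::setNames(opt$par, names(par)))
    }
    tr <- optimize_branch_lengths(tr, aln, model_of(par))
    new_ll <- attr(tr, "loglik")
    if (new_ll - ll < 1e-6 && r > 1) { ll <- new_ll; break }
    ll <- new_ll
  }
  list(exch = .expand_exch(constraints, par), freq = freq, tree = tr,
       loglik = ll, constraints = constraints)
}

#' Codon substitution model with separate dN and dS
#'
#' Rate between codons differing at exactly one nucleotide position is
#' (nucleotide exchangeability for that change) x (equilibrium frequency
#' of the target codon) x (dS if the change is synonymous, dN if it
#' changes the amino acid).  Codon pairs differing at more than one
#' position have rate 0.
#'
#' @param exch named 6-vector of nucleotide exchangeabilities
#'   (AC, AG, AT, CG, CT, GT), or a [nucleotide_constraints()] expansion.
#' @param codon_freqs equilibrium frequencies over the 61 sense codons.
#' @param dn non-synonymous rate multiplier.
#' @param ds synonymous rate multiplier.
#' @return unnormalized `subst_model` over the 61 sense codons (the
#'   absolute scale of `dn`/`ds` carries the rate information).
#' @export
build_codon_model <- function(exch, codon_freqs, dn, ds) {
  if (length(codon_freqs) != 61 || any(codon_freqs < 0) ||
      abs(sum(codon_freqs) - 1) > 1e-6)
    stop("codon_freqs must be a probability vector over 61 sense codons")
  if (dn < 0 || ds < 0) stop("dn and ds must be >= 0")
  info <- .codon_pair_info()
  R <- matrix(0, 61, 61, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  rates <- exch[info$pair] * ifelse(info$syn, ds, dn)
  R[info$idx] <- rates
  R <- R + t(R)
  substitution_model(SENSE_CODONS, R, codon_freqs, normalize = FALSE)
}

## Single-nucleotide-difference codon pairs: upper-triangle index matrix,
## the nucleotide pair label (e.g. "AG"), and synonymy flag.  Cached.
.codon_env <- new.env(parent = emptyenv())
.codon_pair_info <- function() {
  if (!is.null(.codon_env$info)) return(.codon_env$info)
  s <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  aa <- translate_codons(SENSE_CODONS)
  idx <- NULL; pair <- NULL; syn <- NULL
  for (i in 1:60) for (j in (i + 1):61) {
    diff <- which(s[i, ] != s[j, ])
    if (length(diff) == 1) {
      idx <- rbind(idx, c(i, j))
      pair <- c(pair, paste(sort(c(s[i, diff], s[j, diff])), collapse = ""))
      syn <- c(syn, aa[i] == aa[j])
    }
  }
  .codon_env$info <- list(idx = idx, pair = pair, syn = syn)
  .codon_env$info
}

#' Equilibrium codon frequencies from an alignment
#'
#' @param codon_aln a codon alignment.
#' @param method `"F3x4"` (products of position-specific nucleotide
#'   frequencies, renormalized over sense codons; default) or `"F61"`
#'   (observed codon counts).
#' @param pseudocount added to each sense-codon count under `"F61"`.
#' @return frequency vector over the 61 sense codons.
#' @export
estimate_codon_frequencies <- function(codon_aln, method = c("F3x4", "F61"),
                                       pseudocount = 0.5) {
  method <- match.arg(method)
  codons <- as.vector(codon_aln$codons)
  codons <- codons[codons %in% SENSE_CODONS]
  if (!length(codons)) stop("empty codon alignment")
  if (method == "F61") {
    cnt <- table(factor(codons, SENSE_CODONS)) + pseudocount
    return(stats::setNames(as.numeric(cnt) / sum(cnt), SENSE_CODONS))
  }
  chars <- do.call(rbind, strsplit(codons, ""))
  posfreq <- apply(chars, 2, function(col)
    as.numeric(table(factor(col, NUCLEOTIDES))) / length(col))
  s <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  f <- posfreq[match(s[, 1], NUCLEOTIDES), 1] *
       posfreq[match(s[, 2], NUCLEOTIDES), 2] *
       posfreq[match(s[, 3], NUCLEOTIDES), 3]
  stats::setNames(f / sum(f), SENSE_CODONS)
}

## Per-class site log-likelihood matrix (sites x 9) for a (dn, ds) grid.
.rel_class_logliks <- function(tp, tree, exch, codon_freqs, dn, ds) {
  nsites <- ncol(tp[[1]])
  out <- matrix(0, nsites, length(dn) * length(ds))
  k <- 0
  for (i in seq_along(dn)) for (j in seq_along(ds)) {
    k <- k + 1
    mod <- build_codon_model(exch, codon_freqs, dn[i], ds[j])
    out[, k] <- .prune_loglik(tree, tp, mod, 1)
  }
  out
}

## EM profile of mixture weights for a fixed site x class log-lik
## matrix.  The dN and dS site-to-site distributions are independent
## (the REL convention): the 3x3 class weights are the outer product of
## a dN marginal and a dS marginal, each updated in closed form from the
## class posteriors.  Class order is dN-major: k = (i-1)*n_ds + j.
.profile_weights <- function(M, counts = NULL, n_dn = NULL, tol = 1e-9,
                             max_iter = 500) {
  K <- ncol(M)
  if (is.null(counts)) counts <- rep(1, nrow(M))
  if (is.null(n_dn)) n_dn <- round(sqrt(K))
  n_ds <- K / n_dn
  dn_of <- rep(seq_len(n_dn), each = n_ds)
  ds_of <- rep(seq_len(n_ds), times = n_dn)
  mx <- apply(M, 1, max)
  L <- exp(M - mx)                      # site patterns x K, scaled
  w_dn <- rep(1 / n_dn, n_dn); w_ds <- rep(1 / n_ds, n_ds)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    w <- w_dn[dn_of] * w_ds[ds_of]
    denom <- as.vector(L %*% w)
    ll <- sum(counts * (log(denom) + mx))
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
    post <- L * rep(w, each = nrow(L)) / denom
    cw <- matrix(colSums(counts * post) / sum(counts), n_ds, n_dn)
    w_dn <- colSums(cw)
    w_ds <- rowSums(cw)
  }
  list(w = w_dn[dn_of] * w_ds[ds_of], w_dn = w_dn, w_ds = w_ds,
       loglik = ll)
}

#' Fit the 3x3 REL codon model
#'
#' Two-stage fit: (1) branch lengths and constrained nucleotide
#' exchangeabilities under the nucleotide model; (2) with relative
#' branch lengths fixed, the three dN values, three dS values and the
#' 3x3 class weight matrix by maximizing the per-site mixture
#' log-likelihood (weights profiled out by EM at every evaluation; dN/dS
#' values absorb the global branch scale, so a separate scale parameter
#' is redundant and not fitted).  Deterministic multi-starts reduce the
#' risk of local optima.
#'
#' @param codon_aln a codon alignment.
#' @param tree `phylo` over (a subset of) the alignment sequences.
#' @param constraints a [nucleotide_constraints()] object.
#' @param n_classes number of dN (and dS) values (default 3).
#' @param freq_method passed to [estimate_codon_frequencies()].
#' @param n_starts number of deterministic multi-starts (1-5).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param ref_positions optional vector of reference residue numbers per
#'   codon site (default: site index + codon offset).
#' @return object of class `rel_fit`; see [site_posteriors()],
#'   [bayes_factor_positive()], [classify_sites()].
#' @export
fit_rel <- function(codon_aln, tree, constraints = nucleotide_constraints("GTR"),
                    n_classes = 3, freq_method = "F3x4", n_starts = 3,
                    maxit = 300, ref_positions = NULL) {
  stopifnot(inherits(codon_aln, "codon_msa"))
  if (nrow(codon_aln$codons) < 3) stop("need at least 3 sequences")
  stage1 <- fit_nucleotide(codon_aln$base, tree, constraints)
  codon_freqs <- estimate_codon_frequencies(codon_aln, freq_method)
  tp <- .tip_partials(codon_aln)
  tr <- stage1$tree

  ## site-pattern compression: identical codon columns share one
  ## likelihood evaluation
  pat_key <- apply(codon_aln$codons, 2, paste, collapse = "\r")
  pat_id <- match(pat_key, unique(pat_key))
  uniq <- which(!duplicated(pat_key))
  counts <- tabulate(pat_id, nbins = length(uniq))
  tp_u <- lapply(tp, function(p) {
    q <- p[, uniq, drop = FALSE]
    attr(q, "state_idx") <- attr(p, "state_idx")[uniq]
    q
  })
  names(tp_u) <- names(tp)

  ## crude global scale: single-class neutral fit (dn = ds = c)
  scale_ll <- function(lc) {
    mod <- build_codon_model(stage1$exch, codon_freqs, exp(lc), exp(lc))
    sum(counts * .prune_loglik(tr, tp_u, mod, 1))
  }
  c0 <- exp(stats::optimize(scale_ll, c(-6, 8), maximum = TRUE,
                            tol = 1e-3)$maximum)

  ## deterministic multi-start presets (relative grids, scaled by c0)
  presets <- list(
    neutral   = list(dn = c(0.5, 1, 2),    ds = c(0.5, 1, 2)),
    purifying = list(dn = c(0.05, 0.3, 1), ds = c(0.5, 1, 2)),
    positive  = list(dn = c(0.2, 1, 4),    ds = c(0.4, 1, 1.6)),
    mixed_a   = list(dn = c(0.1, 0.5, 2),  ds = c(0.7, 1, 1.5)),
    mixed_b   = list(dn = c(0.05, 1, 3),   ds = c(0.6, 1, 1.8))
  )[seq_len(max(1, min(n_starts, 5)))]

  nd <- n_classes
  objective <- function(lp) {
    dn <- exp(lp[seq_len(nd)]); ds <- exp(lp[nd + seq_len(nd)])
    M <- .rel_class_logliks(tp_u, tr, stage1$exch, codon_freqs, dn, ds)
    -.profile_weights(M, counts)$loglik
  }
  starts_log <- list()
  best <- NULL
  for (nm in names(presets)) {
    p0 <- presets[[nm]]
    lp0 <- log(c0 * c(rep_len(p0$dn, nd), rep_len(p0$ds, nd)))
    opt <- stats::optim(lp0, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9))
    starts_log[[nm]] <- list(loglik = -opt$value,
                             converged = opt$convergence == 0)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  dn <- exp(best$par[seq_len(nd)]); ds <- exp(best$par[nd + seq_len(nd)])
  ## canonical order within each axis
  dn <- sort(dn); ds <- sort(ds)
  M_u <- .rel_class_logliks(tp_u, tr, stage1$exch, codon_freqs, dn, ds)
  pw <- .profile_weights(M_u, counts)
  M <- M_u[pat_id, , drop = FALSE]

  ## neutral-constrained submodel (each site dn = ds = r, r a 3-value
  ## discrete distribution): the LRT against it gates site-level
  ## positive-selection calls (see classify_sites)
  neut_class_logliks <- function(r) {
    out <- matrix(0, length(counts), length(r))
    for (i in seq_along(r)) {
      mod <- build_codon_model(stage1$exch, codon_freqs, r[i], r[i])
      out[, i] <- .prune_loglik(tr, tp_u, mod, 1)
    }
    out
  }
  neut_negll <- function(lr) {
    -.profile_weights(neut_class_logliks(exp(lr)), counts, n_dn = 1)$loglik
  }
  nopt <- stats::optim(log(c0 * c(0.5, 1, 2)), neut_negll,
                       method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-8))
  neutral_loglik <- -nopt$value
  lrt <- 2 * (pw$loglik - neutral_loglik)
  ## df: (6 values + 2+2 marginal weights) - (3 values + 2 weights)
  positive_supported <- lrt >= stats::qchisq(0.95, df = 5)
  W <- matrix(pw$w, nd, nd, byrow = TRUE)   # rows dn classes, cols ds
  ## reporting normalization: ds-marginal-weighted mean of ds = 1
  u <- colSums(W)
  f <- sum(u * ds)
  positive <- outer(dn, ds, ">")
  nsites <- nrow(M)
  offset <- codon_aln$offset_codons
  if (is.null(ref_positions)) ref_positions <- seq_len(nsites) + offset
  fit <- structure(list(
    grid = list(dn = dn, ds = ds, weights = W,
                ratio = outer(dn, ds, "/"),
                dn_scaled = dn / f, ds_scaled = ds / f, branch_scale = f),
    positive_classes = positive,
    prior_positive = sum(W[positive]),
    nucleotide = stage1, codon_freqs = codon_freqs, tree = tr,
    loglik = pw$loglik, site_logliks = M,
    neutral_loglik = neutral_loglik, lrt = lrt,
    positive_supported = positive_supported,
    positions = ref_positions,
    converged = best$convergence == 0, starts = starts_log,
    n_classes = nd
  ), class = "rel_fit")
  fit
}

#' @export
print.rel_fit <- function(x, ...) {
  cat(sprintf("REL fit: %dx%d (dN, dS) classes, logLik = %.3f%s\n",
              x$n_classes, x$n_classes, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  r <- x$grid$ratio
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
    cat(sprintf("  class (dN=%.4g, dS=%.4g): dN/dS = %.3f, weight = %.3f\n",
                x$grid$dn_scaled[i], x$grid$ds_scaled[j], r[i, j],
                x$grid$weights[i, j]))
  }
  cat(sprintf("  prior P(dN > dS) = %.4f\n", x$prior_positive))
  if (!is.null(x$lrt))
    cat(sprintf("  LRT vs neutral submodel: %.2f (positive class %s)\n",
                x$lrt,
                if (x$positive_supported) "supported" else "not supported"))
  invisible(x)
}

#' Empirical-Bayes per-site class posteriors
#'
#' `P(class (i,j) | site) \propto w_ij P(site | dN_i, dS_j)`.
#'
#' @param fit a [fit_rel()] result.
#' @return matrix (sites x 9) of class posteriors, rows summing to 1;
#'   columns ordered (dN_1,dS_1), (dN_1,dS_2), ..., (dN_3,dS_3).
#' @export
site_posteriors <- function(fit) {
  M <- fit$site_logliks
  w <- as.vector(t(fit$grid$weights))
  mx <- apply(M, 1, max)
  L <- exp(M - mx) * rep(w, each = nrow(M))
  L / rowSums(L)
}

#' Bayes factor for positive selection at a site
#'
#' `BF = [post/(1-post)] / [prior/(1-prior)]` with `post` the posterior
#' and `prior` the prior probability mass on classes with dN > dS.
#'
#' @param fit a [fit_rel()] result.
#' @param site site index (row of the alignment) or `NULL` for all.
#' @return named list with `posterior` and `bayes_factor` vectors
#'   (`Inf` when the posterior is 1; `NaN` when the prior is 0 or 1).
#' @export
bayes_factor_positive <- function(fit, site = NULL) {
  post <- site_posteriors(fit)
  pos <- as.vector(t(fit$positive_classes))
  p_site <- rowSums(post[, pos, drop = FALSE])
  prior <- fit$prior_positive
  if (prior <= 0 || prior >= 1) {
    bf <- rep(NaN, length(p_site))
  } else {
    prior_odds <- prior / (1 - prior)
    bf <- (p_site / (1 - p_site)) / prior_odds
    bf[p_site >= 1] <- Inf
  }
  idx <- if (is.null(site)) seq_along(p_site) else site
  list(posterior = p_site[idx], bayes_factor = bf[idx])
}

#' Classify sites by Bayes-factor evidence for positive selection
#'
#' `strong` if BF >= `strong_threshold`, `weak` if `weak_threshold` <=
#' BF < `strong_threshold`; otherwise `negative` when the posterior
#' mass on dN < dS classes exceeds 0.5, else `none`.
#'
#' By default site-level positive calls are gated on the model-level
#' likelihood-ratio test against the neutral-constrained submodel
#' (dn = ds at every site; `fit$positive_supported`).  On data without a
#' genuine positive class the fitted value vectors land arbitrarily on
#' either side of the dn = ds boundary, and ungated per-site Bayes
#' factors then manufacture spurious strong calls — the same reason
#' codeml interprets BEB sites only under a significant M1a/M2a test.
#'
#' @param fit a [fit_rel()] result.
#' @param strong_threshold Bayes-factor threshold for strong support
#'   (default 50; boundary inclusive).
#' @param weak_threshold lower Bayes-factor threshold for weak support
#'   (default 10; boundary inclusive).
#' @param lrt_gate if `TRUE` (default), suppress strong/weak categories
#'   when the model-level LRT does not support a positive class; Bayes
#'   factors are still reported.
#' @return data.frame: `site` (reference numbering), `posterior`
#'   (posterior probability of dN > dS), `bayes_factor`, `category`.
#' @export
classify_sites <- function(fit, strong_threshold = 50, weak_threshold = 10,
                           lrt_gate = TRUE) {
  bf <- bayes_factor_positive(fit)
  post <- site_posteriors(fit)
  neg <- as.vector(t(outer(fit$grid$dn, fit$grid$ds, "<")))
  p_neg <- rowSums(post[, neg, drop = FALSE])
  gate_open <- !lrt_gate || is.null(fit$positive_supported) ||
    isTRUE(fit$positive_supported)
  category <- rep("none", length(bf$bayes_factor))
  if (gate_open) {
    category[!is.nan(bf$bayes_factor) &
             bf$bayes_factor >= weak_threshold] <- "weak"
    category[!is.nan(bf$bayes_factor) &
             bf$bayes_factor >= strong_threshold] <- "strong"
  }
  category[category == "none" & p_neg > 0.5] <- "negative"
  data.frame(site = fit$positions,
             posterior = bf$posterior,
             bayes_factor = bf$bayes_factor,
             category = category)
}

#' Does any fitted class show dN/dS > 1?
#'
#' Mirrors the negative-control check: report whether the fitted grid
#' contains a class with ratio above 1 and its weight.
#'
#' @param fit a [fit_rel()] result.
#' @param min_weight ignore classes with weight below this.
#' @return list with `any_positive`, `best_ratio`, `weight`.
#' @export
rel_positive_class <- function(fit, min_weight = 1e-4) {
  r <- fit$grid$ratio; w <- fit$grid$weights
  ok <- r > 1 & w >= min_weight
  if (!any(ok)) return(list(any_positive = FALSE, best_ratio = max(r),
                            weight = 0))
  i <- which(ok & r == max(r[ok]), arr.ind = TRUE)[1, ]
  list(any_positive = TRUE, best_ratio = r[i[1], i[2]],
       weight = w[i[1], i[2]])
}

#' Write the per-site REL table as TSV
#'
#' Columns mirror a per-site selection table: position, posterior
#' probability of positive selection, Bayes factor, category.
#' @param fit a [fit_rel()] result.
#' @param path output file.
#' @param ... passed to [classify_sites()].
#' @export
write_rel_tsv <- function(fit, path, ...) {
  df <- classify_sites(fit, ...)
  df$posterior <- round(df$posterior, 4)
  df$bayes_factor <- ifelse(is.infinite(df$bayes_factor), "inf",
                            round(df$bayes_factor, 3))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
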