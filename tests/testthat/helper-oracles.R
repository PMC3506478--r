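## Independent oracles and small fixture builders.  Everything here
## deliberately avoids the package's pruning/eigendecomposition code
## paths: matrix exponentials come from Matrix::expm, likelihoods from
## exhaustive enumeration over internal-node states.

## random reversible k-state model (via the public constructor, but the
## oracles below never use its eigen machinery)
toy_model <- function(k = 4, seed = 1) {
  set.seed(seed)
  R <- matrix(0, k, k)
  R[upper.tri(R)] <- stats::runif(k * (k - 1) / 2, 0.2, 2)
  R <- R + t(R)
  f <- stats::runif(k, 0.5, 2)
  states <- LETTERS[seq_len(k)]
  dimnames(R) <- list(states, states)
  substitution_model(states, R, f / sum(f))
}

## transition matrix by series expm (independent of the package's
## symmetric-eigendecomposition route)
expm_oracle <- function(Q, t) as.matrix(Matrix::expm(Q * t))

## exhaustive-enumeration site log-likelihoods; `allowed` is a list
## (per tree tip label) of per-site lists of allowed state indices
brute_site_logliks <- function(tree, allowed, model, rate = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  k <- length(model$states)
  Ps <- lapply(seq_len(nrow(edge)), function(e)
    expm_oracle(model$Q, rate * tr$edge.length[e]))
  root <- edge[nrow(edge), 1]
  nsites <- length(allowed[[1]])
  sapply(seq_len(nsites), function(s) {
    grids <- lapply(seq_len(nnode), function(v) {
      if (v <= ntip) allowed[[tr$tip.label[v]]][[s]] else seq_len(k)
    })
    combos <- as.matrix(expand.grid(grids))
    lik <- 0
    for (r in seq_len(nrow(combos))) {
      st <- combos[r, ]
      p <- model$freq[st[root]]
      for (e in seq_len(nrow(edge)))
        p <- p * Ps[[e]][st[edge[e, 1]], st[edge[e, 2]]]
      lik <- lik + p
    }
    log(lik)
  })
}

## allowed-state lists from an msa (protein/nucleotide): gap/ambiguity
## symbols allow every state
allowed_states <- function(aln, model) {
  m <- unclass(aln)
  out <- lapply(rownames(m), function(id) {
    lapply(seq_len(ncol(m)), function(s) {
      i <- match(m[id, s], model$states)
      if (is.na(i)) seq_along(model$states) else i
    })
  })
  names(out) <- rownames(m)
  out
}

## random gappy alignment over a model's states
random_alignment <- function(model, ntaxa, nsites, seed,
                             alphabet = "nucleotide", gap_p = 0.1) {
  set.seed(seed)
  rows <- replicate(ntaxa, {
    x <- sample(model$states, nsites, replace = TRUE, prob = model$freq)
    x[stats::runif(nsites) < gap_p] <- "-"
    paste(x, collapse = "")
  })
  msa(paste0("t", seq_len(ntaxa)), rows, alphabet)
}

## minimal rel_fit stand-in for posterior/Bayes-factor arithmetic tests
fake_rel_fit <- function(dn, ds, W, M, positions = seq_len(nrow(M))) {
  structure(list(
    grid = list(dn = dn, ds = ds, weights = W, ratio = outer(dn, ds, "/")),
    positive_classes = outer(dn, ds, ">"),
    prior_positive = sum(W[outer(dn, ds, ">")]),
    site_logliks = M, positions = positions,
    n_classes = length(dn)
  ), class = "rel_fit")
}

msa_strings_for_test <- function(aln)
  apply(unclass(aln), 1, paste, collapse = "")

## small fixed trees
tree4 <- function() ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.2);")
tree3 <- function() ape::read.tree(text = "(A:0.1,B:0.2,C:0.3);")
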