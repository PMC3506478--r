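## Felsenstein pruning over arbitrary finite state spaces, plus
## distance-based tree scaffolding (ML pairwise distances, BIONJ,
## branch-length optimization, bootstrap support).

## Tip partial likelihoods.  Gaps and ambiguity symbols contribute
## all-ones partials ("treated as unknown characters"); partially
## ambiguous codons (e.g. an N at one position) get uniform support over
## all compatible sense codons.
.tip_partials <- function(aln) {
  if (inherits(aln, "codon_msa")) {
    states <- SENSE_CODONS
    codons <- aln$codons
    uniq <- unique(as.vector(codons))
    lut <- lapply(uniq, function(cd) {
      if (cd %in% states) {
        v <- numeric(61); v[match(cd, states)] <- 1; v
      } else if (cd == "---") {
        rep(1, 61)
      } else {
        pat <- chartr("N", ".", cd)
        as.numeric(grepl(paste0("^", pat, "$"), states))
      }
    })
    names(lut) <- uniq
    out <- lapply(rownames(codons), function(id) {
      m <- vapply(codons[id, ], function(cd) lut[[cd]], numeric(61))
      dim(m) <- c(61L, ncol(codons)); m
    })
    names(out) <- rownames(codons)
    for (id in names(out)) {
      ## definite-state index per site (NA when ambiguous/gap): enables
      ## a fast column-indexing path in the pruning loop
      attr(out[[id]], "state_idx") <- match(codons[id, ], SENSE_CODONS)
    }
    attr(out, "n_states") <- 61L
    return(out)
  }
  stopifnot(inherits(aln, "msa"))
  states <- if (attr(aln, "alphabet") == "protein") AMINO_ACIDS else NUCLEOTIDES
  ns <- length(states)
  m <- unclass(aln)
  out <- lapply(rownames(m), function(id) {
    idx <- match(m[id, ], states)
    p <- matrix(0, ns, ncol(m))
    known <- !is.na(idx)
    p[cbind(idx[known], which(known))] <- 1
    p[, !known] <- 1
    attr(p, "state_idx") <- idx
    p
  })
  names(out) <- rownames(m)
  attr(out, "n_states") <- ns
  out
}

## Core pruning pass (C++ kernel).  `tp` is the tip-partial list;
## returns the per-site log-likelihood vector.
.prune_loglik <- function(tree, tp, model, rate = 1, edge_lengths = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  el <- if (is.null(edge_lengths)) tr$edge.length else edge_lengths
  if (is.null(el)) stop("tree has no branch lengths")
  ntip <- length(tr$tip.label)
  ord <- tr$tip.label
  if (!all(ord %in% names(tp)))
    stop("tree leaf absent from alignment: ",
         paste(setdiff(ord, names(tp)), collapse = ", "))
  tip_parts <- tp[ord]
  nsites <- ncol(tip_parts[[1]])
  tip_idx <- do.call(rbind, lapply(tip_parts, function(p) {
    i <- attr(p, "state_idx")
    if (is.null(i)) i <- rep(NA_integer_, nsites)
    ifelse(is.na(i), 0L, i)
  }))
  prune_loglik_cpp(tr$edge, el, ntip, ntip + tr$Nnode, tip_parts,
                   tip_idx, model$U, model$Uinv, model$eval, model$freq,
                   rate)
}

## Pure-R reference implementation of the same pass (kept as an
## independent cross-check; see the test suite).
.prune_loglik_r <- function(tree, tp, model, rate = 1,
                            edge_lengths = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  el <- if (is.null(edge_lengths)) tr$edge.length else edge_lengths
  if (is.null(el)) stop("tree has no branch lengths")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  nsites <- ncol(tp[[1]])
  parts <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    p <- tp[[tr$tip.label[i]]]
    if (is.null(p)) stop("tree leaf absent from alignment: ", tr$tip.label[i])
    parts[[i]] <- p
  }
  logscale <- numeric(nsites)
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    bl <- rate * el[k]
    if (!is.finite(bl)) stop("non-finite branch length")
    P <- transition_matrix(model, bl)
    chp <- parts[[ch]]
    idx <- attr(chp, "state_idx")
    contrib <- if (!is.null(idx) && !anyNA(idx)) {
      P[, idx, drop = FALSE]      # definite tip states: column gather
    } else if (!is.null(idx)) {
      cb <- P[, ifelse(is.na(idx), 1L, idx), drop = FALSE]
      amb <- which(is.na(idx))
      cb[, amb] <- P %*% chp[, amb, drop = FALSE]
      cb
    } else {
      P %*% chp
    }
    if (is.null(parts[[par]])) {
      parts[[par]] <- contrib
    } else {
      w <- parts[[par]] * contrib
      ## rescale only when columns drift towards underflow
      cs <- .colSums(w, nrow(w), nsites)
      if (min(cs) < 1e-120) {
        mx <- apply(w, 2, max)
        mx[mx <= 0] <- 1
        logscale <- logscale + log(mx)
        w <- sweep(w, 2, mx, "/")
      }
      parts[[par]] <- w
    }
  }
  root <- edge[nrow(edge), 1]
  lik <- colSums(model$freq * parts[[root]])
  unname(log(lik) + logscale)
}

#' Per-site log-likelihoods by Felsenstein pruning
#'
#' @param tree a `phylo` with branch lengths; its leaves must all be
#'   present in the alignment.
#' @param aln an [msa()] or codon alignment.
#' @param model a [substitution_model()] over the matching state space.
#' @param rate positive scalar multiplying all branch lengths.
#' @return numeric vector of per-site (per-column or per-codon-site)
#'   log-likelihoods; their sum is the total log-likelihood.  Gap and
#'   ambiguity symbols contribute all-ones partial likelihoods, so an
#'   all-gap column has log-likelihood 0.
#' @export
site_log_likelihoods <- function(tree, aln, model, rate = 1) {
  if (rate <= 0) stop("rate must be > 0")
  check_tree_alignment(tree, aln)
  .prune_loglik(tree, .tip_partials(aln), model, rate)
}

#' Maximum-likelihood pairwise distance
#'
#' Maximizes the two-sequence likelihood over the separating branch
#' length.  Columns with a gap or ambiguity symbol in either row are
#' excluded (pairwise deletion).
#'
#' @param row_i,row_j aligned symbol strings (equal lengths).
#' @param model a [substitution_model()].
#' @param d_max upper bracket for the distance (default 10 expected
#'   substitutions/site); saturated pairs are capped here with a warning.
#' @return nonnegative scalar distance; 0 for identical sequences.
#' @export
ml_distance <- function(row_i, row_j, model, d_max = 10) {
  a <- strsplit(toupper(row_i), "")[[1]]
  b <- strsplit(toupper(row_j), "")[[1]]
  if (length(a) != length(b)) stop("unequal sequence lengths")
  ia <- match(a, model$states); ib <- match(b, model$states)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) stop("no comparable (both non-gap) columns")
  tab <- table(factor(ia[keep], seq_along(model$states)),
               factor(ib[keep], seq_along(model$states)))
  tab <- tab + t(tab)   # reversible: symmetrize the count matrix
  if (all(ia[keep] == ib[keep])) return(0)
  nz <- tab > 0
  negll <- function(t) {
    P <- transition_matrix(model, t)
    M <- log(pmax(model$freq * P, 1e-300))
    -sum(tab[nz] * M[nz]) / 2
  }
  opt <- stats::optimize(negll, c(0, d_max), tol = 1e-8)
  d <- opt$minimum
  if (d > d_max * 0.99 && negll(d_max) <= negll(d)) {
    warning("distance saturated; capped at d_max = ", d_max)
    return(d_max)
  }
  max(d, 0)
}

#' ML distance matrix for an alignment
#'
#' @param aln protein or nucleotide [msa()].
#' @inheritParams ml_distance
#' @return symmetric matrix of pairwise [ml_distance()] values.
#' @export
ml_distance_matrix <- function(aln, model, d_max = 10) {
  s <- msa_strings(aln)
  n <- length(s)
  D <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- ml_distance(s[i], s[j], model, d_max)
  }
  D
}

#' BIONJ tree from a distance matrix
#'
#' Variance-weighted neighbour joining.  On an additive (tree-generated)
#' metric the generating topology and branch lengths are recovered
#' exactly.  The three-taxon case uses the closed three-point formulas.
#'
#' @param dist symmetric nonnegative matrix with zero diagonal, with
#'   dimnames, or labelled via `labels`.
#' @param labels optional taxon labels overriding dimnames.
#' @return unrooted `phylo`.
#' @export
bionj <- function(dist, labels = NULL) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 3) stop("need at least 3 taxa")
  if (!is.null(labels)) dimnames(dist) <- list(labels, labels)
  if (is.null(rownames(dist))) stop("distance matrix must be labelled")
  if (max(abs(dist - t(dist))) > 1e-8) stop("non-symmetric distance matrix")
  if (any(dist < 0)) stop("negative distances")
  if (n == 3) {
    l <- rownames(dist)
    b <- c((dist[1, 2] + dist[1, 3] - dist[2, 3]) / 2,
           (dist[1, 2] + dist[2, 3] - dist[1, 3]) / 2,
           (dist[1, 3] + dist[2, 3] - dist[1, 2]) / 2)
    txt <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                   l[1], b[1], l[2], b[2], l[3], b[3])
    return(ape::read.tree(text = txt))
  }
  tr <- ape::bionj(dist)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Optimize branch lengths at fixed topology
#'
#' Coordinate-wise univariate (Brent) optimization of each branch
#' length; the total log-likelihood is non-decreasing at every accepted
#' update and iteration stops when a full sweep improves it by less
#' than `tol`.
#'
#' @inheritParams site_log_likelihoods
#' @param tol convergence tolerance on the total log-likelihood.
#' @param max_rounds maximum number of full sweeps.
#' @param d_max upper bound for any branch length.
#' @return the tree with optimized `edge.length` and attribute
#'   `loglik`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, rate = 1, tol = 1e-6,
                                    max_rounds = 10, d_max = 10) {
  check_tree_alignment(tree, aln)
  tp <- .tip_partials(aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  el <- tr$edge.length
  total <- function(el) sum(.prune_loglik(tr, tp, model, rate,
                                          edge_lengths = el))
  cur <- total(el)
  for (round in seq_len(max_rounds)) {
    prev <- cur
    for (k in seq_along(el)) {
      f <- function(x) {
        el2 <- el; el2[k] <- x
        -total(el2)
      }
      opt <- stats::optimize(f, c(0, d_max), tol = 1e-8)
      if (-opt$objective > cur) {
        el[k] <- opt$minimum
        cur <- -opt$objective
      }
    }
    if (cur - prev < tol) break
  }
  tr$edge.length <- el
  attr(tr, "loglik") <- cur
  tr
}

#' Build a BIONJ tree from an alignment
#'
#' ML pairwise distances under `model`, BIONJ construction and optional
#' ML branch-length refinement at the fixed topology.
#'
#' @inheritParams ml_distance_matrix
#' @param optimize if `TRUE`, refine branch lengths by
#'   [optimize_branch_lengths()].
#' @return unrooted `phylo`.
#' @export
build_bionj_tree <- function(aln, model = jtt_model(), d_max = 10,
                             optimize = FALSE) {
  tr <- bionj(ml_distance_matrix(aln, model, d_max))
  if (optimize) tr <- optimize_branch_lengths(tr, aln, model)
  tr
}

#' Bootstrap support for the splits of a tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `tree_builder`, and reports for each internal node of
#' the reference tree the proportion of replicates containing its
#' bipartition.
#'
#' @param aln an [msa()].
#' @param tree_builder function `aln -> phylo` (e.g. a wrapper around
#'   [build_bionj_tree()]).
#' @param n_replicates number of bootstrap resamplings.
#' @param seed integer seed; results are deterministic given the seed.
#' @param reference optional reference tree (default `tree_builder(aln)`).
#' @return list with `tree` (reference tree with supports as
#'   `node.label`) and `support` (numeric vector in [0,1] per internal
#'   node; `NA` for the root of an unrooted tree).
#' @export
bootstrap_support <- function(aln, tree_builder, n_replicates, seed = 1,
                              reference = NULL) {
  stopifnot(n_replicates >= 1)
  if (is.null(reference)) reference <- tree_builder(aln)
  m <- unclass(aln)
  reps <- local({
    set.seed(seed)
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      sub <- structure(m[, cols, drop = FALSE],
                       alphabet = attr(aln, "alphabet"),
                       offset = 0L, class = "msa")
      tree_builder(sub)
    })
  })
  counts <- ape::prop.clades(reference, reps, rooted = FALSE)
  support <- counts / n_replicates
  reference$node.label <- ifelse(is.na(support), "",
                                 format(support, digits = 3))
  list(tree = reference, support = support)
}
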