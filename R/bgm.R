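## Co-evolution detection: joint ML ancestral codon reconstruction,
## site x branch non-synonymous substitution maps, site filtering, and a
## Bayesian-graphical-model structure MCMC over directed networks with
## at most two parents per node.

#' Joint ML ancestral codon reconstruction
#'
#' Per site, the jointly most probable assignment of codons to all
#' internal nodes under the given codon model (max-product dynamic
#' programming up the tree, backtrace down).  Ties are broken towards
#' the lowest codon index, so the output is deterministic.
#'
#' @param tree `phylo` with branch lengths.
#' @param codon_aln codon alignment covering the tree leaves.
#' @param model a codon [substitution_model()] (e.g. from
#'   [build_codon_model()] or collapsed from a REL fit via
#'   [rel_mean_model()]).
#' @return character matrix (internal nodes x sites) of codons; row
#'   names are internal node numbers as in `tree$edge`.
#' @export
joint_ancestral_codons <- function(tree, codon_aln, model) {
  check_tree_alignment(tree, codon_aln)
  tp <- .tip_partials(codon_aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  nsites <- ncol(tp[[1]])
  ns <- length(model$states)
  logP <- lapply(seq_len(nrow(edge)), function(k)
    log(pmax(transition_matrix(model, tr$edge.length[k]), 1e-300)))
  children <- split(seq_len(nrow(edge)), edge[, 1])

  root <- edge[nrow(edge), 1]
  anc <- matrix("", nnode - ntip, nsites,
                dimnames = list(as.character((ntip + 1):nnode), NULL))
  for (s in seq_len(nsites)) {
    ## upward max-product: C[[k]] = per-parent-state best log score of
    ## the subtree below edge k; B[[k]] = argmax child state
    C <- vector("list", nrow(edge))
    B <- vector("list", nrow(edge))
    node_sum <- matrix(0, ns, nnode)   # sum of child edge C's per node
    for (k in seq_len(nrow(edge))) {
      ch <- edge[k, 2]
      below <- if (ch <= ntip) {
        v <- log(pmax(tp[[tr$tip.label[ch]]][, s], 1e-300))
        v
      } else {
        node_sum[, ch]
      }
      M <- logP[[k]] + rep(below, each = ns)   # parent x child-state
      B[[k]] <- max.col(M, ties.method = "first")
      C[[k]] <- M[cbind(seq_len(ns), B[[k]])]
      node_sum[, edge[k, 1]] <- node_sum[, edge[k, 1]] + C[[k]]
    }
    root_score <- log(model$freq) + node_sum[, root]
    state <- integer(nnode)
    state[root] <- which.max(root_score)
    ## backtrace in preorder (reverse postorder edge order)
    for (k in rev(seq_len(nrow(edge)))) {
      par <- edge[k, 1]; ch <- edge[k, 2]
      if (ch > ntip) state[ch] <- B[[k]][state[par]]
    }
    anc[, s] <- model$states[state[(ntip + 1):nnode]]
  }
  attr(anc, "tree") <- tr
  anc
}

#' Collapse a REL fit to a single averaged codon model
#'
#' Weighted average of the nine class rate matrices using the fitted
#' class weights; used as the reconstruction model for the co-evolution
#' stage.
#'
#' @param fit a [fit_rel()] result.
#' @return a codon `subst_model`.
#' @export
rel_mean_model <- function(fit) {
  dn_bar <- sum(rowSums(fit$grid$weights) * fit$grid$dn)
  ds_bar <- sum(colSums(fit$grid$weights) * fit$grid$ds)
  build_codon_model(fit$nucleotide$exch, fit$codon_freqs, dn_bar, ds_bar)
}

#' Site x branch non-synonymous substitution map
#'
#' Entry (site, branch) is 1 iff the translated amino acids of the
#' parent and child codons differ on that branch.  Branches whose child
#' codon is a gap or ambiguous (at a tip) contribute 0.
#'
#' @param tree `phylo` (must match the reconstruction's tree ordering).
#' @param codon_aln codon alignment.
#' @param reconstruction result of [joint_ancestral_codons()].
#' @param positions optional reference positions per site.
#' @return object of class `subst_map`: list with `matrix` (sites x
#'   branches, 0/1), `branch_count` (row sums), `positions`, `branches`.
#' @export
substitution_map <- function(tree, codon_aln, reconstruction,
                             positions = NULL) {
  tr <- attr(reconstruction, "tree")
  if (is.null(tr)) tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  nsites <- ncol(reconstruction)
  codon_state <- function(node) {
    if (node <= ntip) codon_aln$codons[tr$tip.label[node], ]
    else reconstruction[as.character(node), ]
  }
  aa_of <- function(cd) {
    aa <- translate_codons(cd)
    aa[!(cd %in% SENSE_CODONS)] <- NA
    aa
  }
  M <- matrix(0L, nsites, nrow(edge))
  bnames <- character(nrow(edge))
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    pa <- aa_of(codon_state(par)); ca <- aa_of(codon_state(ch))
    M[, k] <- as.integer(!is.na(pa) & !is.na(ca) & pa != ca)
    bnames[k] <- paste0(par, "->",
                        if (ch <= ntip) tr$tip.label[ch] else ch)
  }
  if (is.null(positions)) {
    positions <- seq_len(nsites) + codon_aln$offset_codons
  }
  structure(list(matrix = M, branch_count = rowSums(M),
                 positions = positions, branches = bnames),
            class = "subst_map")
}

#' @export
print.subst_map <- function(x, ...) {
  cat(sprintf("Substitution map: %d sites x %d branches; %d site(s) with >= 3 events\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$branch_count >= 3)))
  invisible(x)
}

#' Filter map rows by non-synonymous branch count
#'
#' @param map a [substitution_map()].
#' @param min_count retain sites with at least this many branches
#'   showing a non-synonymous substitution (default 3; boundary
#'   inclusive).
#' @return filtered `subst_map` (idempotent).
#' @export
filter_sites <- function(map, min_count = 3) {
  keep <- map$branch_count >= min_count
  structure(list(matrix = map$matrix[keep, , drop = FALSE],
                 branch_count = map$branch_count[keep],
                 positions = map$positions[keep],
                 branches = map$branches),
            class = "subst_map")
}

## K2-style family score: marginal likelihood of node column y given
## parent columns (0-2), Beta(1,1) per parent configuration.
.family_score <- function(y, parents_data) {
  if (is.null(parents_data) || ncol(parents_data) == 0) {
    cfg <- rep(1L, length(y))
  } else {
    cfg <- as.integer(parents_data %*% 2^(seq_len(ncol(parents_data)) - 1)) + 1L
  }
  n1 <- tapply(y, cfg, sum)
  n <- tapply(y, cfg, length)
  sum(lbeta(1 + n1, 1 + (n - n1)) - lbeta(1, 1))
}

## DAG check: does adding edge a->b create a cycle? (is b an ancestor
## of a, i.e. path b ~> a)
.reachable <- function(adj, from, to) {
  n <- nrow(adj)
  seen <- logical(n)
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ] == 1L))
  }
  FALSE
}

#' Bayesian-graphical-model structure MCMC over substitution maps
#'
#' Metropolis-Hastings over directed acyclic networks with in-degree
#' <= `max_parents`, Beta(1,1)-integrated (K2-style) marginal
#' likelihood per node family, and an independent-edge sparsity prior:
#' each directed edge is present a priori with probability
#' `edge_prior`.  (A fully uniform structure prior puts ~0.35 prior
#' mass on every undirected edge once in-degree <= 2 is imposed, which
#' makes a 0.5 posterior threshold meaningless on null data; see the
#' methods vignette.)  Moves are single edge additions, deletions and
#' reversals.  Edge posteriors are direction-marginalized inclusion
#' frequencies over the post-burn-in samples, deterministic given the
#' seed.
#'
#' @param map a (filtered) [substitution_map()] with at least 2 sites.
#' @param max_parents in-degree bound (default 2).
#' @param edge_prior prior inclusion probability of each directed edge
#'   (default 0.05); 0.5 reproduces the uniform structure prior.
#' @param chain_length total MCMC steps (default 1e5).
#' @param burn_in discarded initial steps (default 1e4).
#' @param seed integer seed.
#' @return object of class `bgm_network`: list with `edge_posterior`
#'   (data.frame site1, site2, posterior), `posterior_matrix`, `sites`,
#'   `diagnostics`.
#' @export
bgm_fit <- function(map, max_parents = 2, chain_length = 1e5,
                    burn_in = 1e4, seed = 1, edge_prior = 0.05) {
  stopifnot(edge_prior > 0, edge_prior < 1)
  log_eprior <- log(edge_prior) - log1p(-edge_prior)
  X <- map$matrix
  if (nrow(X) < 2) stop("need at least 2 filtered sites")
  if (!all(X %in% c(0L, 1L))) stop("substitution map must be binary")
  n <- nrow(X)           # nodes = sites; observations = branches
  D <- t(X)              # branches x sites
  stopifnot(burn_in < chain_length)

  ## cache family scores for all parent sets of size <= max_parents
  score_cache <- new.env(parent = emptyenv(), size = 4096L)
  fam_score <- function(node, parents) {
    key <- paste0(node, "|", paste(sort(parents), collapse = ","))
    val <- score_cache[[key]]
    if (is.null(val)) {
      val <- .family_score(D[, node],
                           if (length(parents)) D[, sort(parents), drop = FALSE]
                           else NULL)
      score_cache[[key]] <- val
    }
    val
  }

  adj <- matrix(0L, n, n)
  parents <- lapply(seq_len(n), function(i) integer(0))
  node_score <- vapply(seq_len(n), function(i) fam_score(i, integer(0)),
                       numeric(1))
  incl <- matrix(0, n, n)
  kept <- 0L
  accepted <- 0L

  set.seed(seed)
  pair_i <- sample.int(n, chain_length, replace = TRUE)
  pair_off <- sample.int(n - 1, chain_length, replace = TRUE)
  u_move <- stats::runif(chain_length)
  u_acc <- stats::runif(chain_length)

  for (step in seq_len(chain_length)) {
    i <- pair_i[step]
    j <- pair_i[step] + pair_off[step]
    if (j > n) j <- j - n
    ok <- FALSE
    if (adj[i, j] == 1L) {
      if (u_move[step] < 0.5) {
        ## delete i->j ; reverse-move (add) has q = 1/M vs 0.5/M
        new_pj <- setdiff(parents[[j]], i)
        delta <- fam_score(j, new_pj) - node_score[j] - log_eprior
        log_hastings <- log(2)
        if (log(u_acc[step]) < delta + log_hastings) {
          adj[i, j] <- 0L; parents[[j]] <- new_pj
          node_score[j] <- node_score[j] + delta
          ok <- TRUE
        }
      } else {
        ## reverse i->j to j->i
        if (length(parents[[i]]) < max_parents) {
          adj[i, j] <- 0L
          cyc <- .reachable(adj, i, j)   # path i ~> j still? then cycle
          if (!cyc) {
            new_pj <- setdiff(parents[[j]], i)
            new_pi <- c(parents[[i]], j)
            delta <- (fam_score(j, new_pj) - node_score[j]) +
                     (fam_score(i, new_pi) - node_score[i])
            if (log(u_acc[step]) < delta) {
              adj[j, i] <- 1L
              parents[[j]] <- new_pj; parents[[i]] <- new_pi
              node_score[j] <- fam_score(j, new_pj)
              node_score[i] <- fam_score(i, new_pi)
              ok <- TRUE
            } else adj[i, j] <- 1L
          } else adj[i, j] <- 1L
        }
      }
    } else if (adj[j, i] == 0L) {
      ## add i->j ; reverse-move (delete) has q = 0.5/M vs 1/M
      if (length(parents[[j]]) < max_parents && !.reachable(adj, j, i)) {
        new_pj <- c(parents[[j]], i)
        delta <- fam_score(j, new_pj) - node_score[j] + log_eprior
        log_hastings <- log(0.5)
        if (log(u_acc[step]) < delta + log_hastings) {
          adj[i, j] <- 1L; parents[[j]] <- new_pj
          node_score[j] <- node_score[j] + delta
          ok <- TRUE
        }
      }
    }
    if (ok) accepted <- accepted + 1L
    if (step > burn_in) {
      incl <- incl + (adj | t(adj))
      kept <- kept + 1L
    }
  }
  pm <- incl / kept
  ut <- which(upper.tri(pm), arr.ind = TRUE)
  edges <- data.frame(site1 = map$positions[ut[, 1]],
                      site2 = map$positions[ut[, 2]],
                      posterior = pm[ut])
  edges <- edges[order(-edges$posterior), ]
  rownames(edges) <- NULL
  structure(list(edge_posterior = edges, posterior_matrix = pm,
                 sites = map$positions,
                 diagnostics = list(chain_length = chain_length,
                                    burn_in = burn_in, seed = seed,
                                    edge_prior = edge_prior,
                                    acceptance_rate = accepted / chain_length)),
            class = "bgm_network")
}

#' @export
print.bgm_network <- function(x, ...) {
  cat(sprintf("BGM network over %d sites (chain %d, burn-in %d, accept %.3f)\n",
              length(x$sites), x$diagnostics$chain_length,
              x$diagnostics$burn_in, x$diagnostics$acceptance_rate))
  top <- utils::head(x$edge_posterior, 5)
  for (r in seq_len(nrow(top)))
    cat(sprintf("  %s - %s : %.3f\n", top$site1[r], top$site2[r],
                top$posterior[r]))
  invisible(x)
}

#' Call co-evolving site pairs and groups
#'
#' Pairs with posterior >= `threshold` (boundary inclusive); groups are
#' the connected components of the undirected graph over called pairs.
#'
#' @param network a [bgm_fit()] result, or a data.frame with columns
#'   `site1`, `site2`, `posterior`.
#' @param threshold posterior probability threshold (default 0.5).
#' @return list with `pairs` (data.frame site1, site2, posterior) and
#'   `groups` (list of integer vectors of member sites, sorted).
#' @export
call_coevolving <- function(network, threshold = 0.5) {
  edges <- if (inherits(network, "bgm_network")) network$edge_posterior
           else network
  pairs <- edges[edges$posterior >= threshold, , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0) return(list(pairs = pairs, groups = list()))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs$site1),
               to = as.character(pairs$site2)),
    directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (anyNA(n)) sort(v) else sort(n)
  })
  groups <- groups[order(vapply(groups, function(v) as.character(v[1]),
                                character(1)))]
  names(groups) <- NULL
  list(pairs = pairs, groups = groups)
}

#' Write called co-evolving pairs as TSV
#'
#' @param called a [call_coevolving()] result.
#' @param path output file.
#' @export
write_bgm_tsv <- function(called, path) {
  df <- called$pairs
  df$posterior <- round(df$posterior, 4)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
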