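## Reverse Conservation Analysis: empirical-Bayes per-site rate
## estimation under a discrete-gamma prior, normalized S scores, sliding
## window W mean scores and threshold-based calling of highly variable
## regions.
##
## Sign convention: higher S = more variable (peaks mark regions of high
## amino-acid diversity); some conservation-score literature inverts
## this sign.

#' Mean rates of the K equal-probability discrete gamma categories
#'
#' Category k is the conditional mean of a Gamma(shape = alpha, rate =
#' alpha) variable within its probability-1/K quantile band, so the
#' category means average exactly 1.
#'
#' @param alpha gamma shape.
#' @param K number of categories.
#' @return numeric vector of K category rates.
#' @export
discrete_gamma_rates <- function(alpha, K) {
  stopifnot(alpha > 0, K >= 1)
  if (K == 1) return(1)
  qb <- stats::qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(qb, shape = alpha + 1, rate = alpha)
  r <- K * diff(p)
  r / mean(r)   # guard round-off so the mean is exactly 1
}

## Per-category site log-likelihood matrix (sites x K) for one alpha.
.site_class_loglik <- function(tp, tree, model, rates) {
  vapply(rates, function(r) .prune_loglik(tree, tp, model, rate = r),
         numeric(ncol(tp[[1]])))
}

## log of row means of exp(), stably
.log_mean_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowMeans(exp(m - mx)))
}

#' ML estimate of the gamma shape for among-site rate variation
#'
#' Maximizes the integrated likelihood with per-site rates marginalized
#' over K equal-probability discrete gamma categories.
#'
#' @param aln protein [msa()].
#' @param tree `phylo` with branch lengths.
#' @param model amino-acid [substitution_model()] (default JTT).
#' @param K number of discrete gamma categories.
#' @param alpha_min,alpha_max search bounds.  A fit driven to
#'   `alpha_max` means no detectable rate variation (all rates equal);
#'   a fit driven to `alpha_min` means extreme variation — notably, a
#'   perfectly conserved alignment is best explained by near-zero rates
#'   in most categories, so it pins the shape at the *lower* bound.
#'   Either boundary is returned with a warning.
#' @return list with `alpha`, `loglik`, and `at_bound`.
#' @export
fit_gamma_shape <- function(aln, tree, model = jtt_model(), K = 16,
                            alpha_min = 0.02, alpha_max = 100) {
  stopifnot(K >= 2, alpha_min > 0, alpha_max > alpha_min)
  check_tree_alignment(tree, aln)
  tp <- .tip_partials(aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  ll <- function(log_alpha) {
    rates <- discrete_gamma_rates(exp(log_alpha), K)
    sum(.log_mean_exp(.site_class_loglik(tp, tr, model, rates)))
  }
  opt <- stats::optimize(ll, c(log(alpha_min), log(alpha_max)),
                         maximum = TRUE, tol = 1e-4)
  alpha <- exp(opt$maximum)
  at_bound <- alpha > alpha_max * 0.95 || alpha < alpha_min / 0.95
  if (alpha > alpha_max * 0.95) {
    warning("gamma shape at upper bound (no rate variation detected); ",
            "alpha set to ", alpha_max)
    alpha <- alpha_max
  } else if (at_bound) {
    warning("gamma shape at lower bound (degenerate rate variation, ",
            "e.g. fully conserved data); alpha set to ", alpha_min)
    alpha <- alpha_min
  }
  list(alpha = alpha, loglik = opt$objective, at_bound = at_bound)
}

#' Empirical-Bayes posterior mean rate per alignment column
#'
#' Posterior mean over the K discrete gamma categories with prior weight
#' 1/K each: `rate_c = sum_k r_k L_c(r_k) / sum_k L_c(r_k)`.  Columns
#' with no data (all gaps) fall back to the prior mean 1.
#'
#' @inheritParams fit_gamma_shape
#' @param alpha gamma shape (e.g. from [fit_gamma_shape()]).
#' @return numeric vector of per-column posterior mean rates (> 0).
#' @export
site_posterior_rates <- function(aln, tree, model = jtt_model(), alpha, K = 16) {
  stopifnot(alpha > 0)
  check_tree_alignment(tree, aln)
  rates <- discrete_gamma_rates(alpha, K)
  m <- .site_class_loglik(.tip_partials(aln), ape::reorder.phylo(tree, "postorder"),
                          model, rates)
  mx <- apply(m, 1, max)
  w <- exp(m - mx)
  as.vector(w %*% rates) / rowSums(w)
}

#' Normalize rates to S scores (z-transform)
#'
#' @param rates per-column rate vector.
#' @return vector with mean 0 and population SD 1 across columns; all
#'   zeros if the input is constant.
#' @export
normalize_s <- function(rates) {
  stopifnot(length(rates) >= 2)
  s <- rates - mean(rates)
  sd_pop <- sqrt(mean(s^2))
  if (sd_pop < 1e-12) return(rep(0, length(rates)))
  s / sd_pop
}

#' Sliding-window mean (W mean score)
#'
#' @param s_scores per-column S scores.
#' @param n odd window size (default 7).  Windows are truncated at the
#'   termini rather than dropped.
#' @return vector of window means, same length as the input.
#' @export
window_mean <- function(s_scores, n = 7) {
  stopifnot(n >= 1, n %% 2 == 1)
  L <- length(s_scores)
  h <- (n - 1) / 2
  cs <- cumsum(c(0, s_scores))
  lo <- pmax(seq_len(L) - h, 1)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Call highly variable regions from W mean scores
#'
#' Maximal runs of consecutive columns with `w >= threshold` (ties at
#' the threshold are inside a region).  Regions are reported in
#' reference residue numbering; runs that touch no reference residue
#' (reference-gap-only) are dropped.
#'
#' @param w_scores per-column W mean scores.
#' @param threshold calling threshold (default 0.5 SD units).
#' @param ref_map optional [build_reference_map()] result; if omitted,
#'   columns are numbered directly (plus `offset`).
#' @param offset origin offset used when `ref_map` is absent.
#' @return data.frame with columns `start`, `end` (1-based closed
#'   intervals) plus `start_col`, `end_col` (alignment columns).
#' @export
call_regions <- function(w_scores, threshold = 0.5, ref_map = NULL,
                         offset = 0L) {
  stopifnot(is.finite(threshold))
  above <- w_scores >= threshold
  if (!any(above)) {
    return(data.frame(start = integer(0), end = integer(0),
                      start_col = integer(0), end_col = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  out <- data.frame(start_col = starts[keep], end_col = ends[keep])
  if (is.null(ref_map)) {
    out$start <- out$start_col + as.integer(offset)
    out$end <- out$end_col + as.integer(offset)
  } else {
    c2r <- ref_map$column_to_residue
    map_first <- function(cols) {
      v <- c2r[cols]; v <- v[!is.na(v)]
      if (length(v)) v[1] else NA_integer_
    }
    out$start <- vapply(seq_len(nrow(out)), function(i)
      map_first(out$start_col[i]:out$end_col[i]), integer(1))
    out$end <- vapply(seq_len(nrow(out)), function(i)
      map_first(rev(out$start_col[i]:out$end_col[i])), integer(1))
    out <- out[!is.na(out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  out[, c("start", "end", "start_col", "end_col")]
}

#' Reverse conservation analysis of a protein alignment
#'
#' Fits the gamma shape, computes empirical-Bayes posterior mean rates,
#' normalizes them to S scores, smooths with an n-column sliding window
#' (W mean scores) and calls regions of high amino-acid diversity at a
#' threshold in SD units.
#'
#' @inheritParams fit_gamma_shape
#' @param window odd sliding-window size (default 7).
#' @param threshold region-calling threshold in SD units (default 0.5).
#' @param reference_id optional reference row for residue numbering.
#' @return object of class `conservation_profile`: list with `s_scores`,
#'   `w_scores`, `regions`, `alpha`, `K`, `window`, `threshold`,
#'   `positions` (reference residue per column, `NA` at reference gaps)
#'   and `ref_map`.
#' @export
rca_profile <- function(aln, tree, model = jtt_model(), K = 16, window = 7,
                        threshold = 0.5, reference_id = NULL) {
  fit <- fit_gamma_shape(aln, tree, model, K)
  rates <- site_posterior_rates(aln, tree, model, fit$alpha, K)
  s <- normalize_s(rates)
  w <- window_mean(s, window)
  rm <- if (!is.null(reference_id)) build_reference_map(aln, reference_id)
  regions <- call_regions(w, threshold, ref_map = rm,
                          offset = attr(aln, "offset"))
  positions <- if (is.null(rm)) seq_along(s) + attr(aln, "offset")
               else rm$column_to_residue
  structure(list(s_scores = s, w_scores = w, regions = regions,
                 alpha = fit$alpha, K = K, window = window,
                 threshold = threshold, positions = positions,
                 ref_map = rm),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf(
    "Conservation profile: %d columns, alpha = %.3f (K = %d), %d region(s) at w >= %.2f\n",
    length(x$s_scores), x$alpha, x$K, nrow(x$regions), x$threshold))
  if (nrow(x$regions)) {
    cat(paste(sprintf("  %s: %d-%d", utils::as.roman(seq_len(nrow(x$regions))),
                      x$regions$start, x$regions$end), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a conservation profile as TSV
#'
#' Columns: alignment column, reference residue, S, W, in_region.
#' @param profile a [rca_profile()] result.
#' @param path output file.
#' @export
write_rca_tsv <- function(profile, path) {
  in_region <- rep(FALSE, length(profile$w_scores))
  for (i in seq_len(nrow(profile$regions))) {
    in_region[profile$regions$start_col[i]:profile$regions$end_col[i]] <- TRUE
  }
  df <- data.frame(column = seq_along(profile$s_scores),
                   reference_residue = profile$positions,
                   s = round(profile$s_scores, 6),
                   w = round(profile$w_scores, 6),
                   in_region = in_region)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
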