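## Reversible substitution models over arbitrary finite state spaces.
##
## A model couples a symmetric exchangeability matrix R and a stationary
## frequency vector pi into Q_ij = R_ij * pi_j (i != j), with diagonal
## fixed by zero row sums.  Transition matrices are computed by symmetric
## eigendecomposition of D^{1/2} Q D^{-1/2} (exact for this model class).

#' Construct a reversible substitution model
#'
#' @param states character vector naming the states (4 nucleotides, 20
#'   amino acids, or 61 sense codons).
#' @param exch symmetric nonnegative exchangeability matrix (diagonal
#'   ignored).
#' @param freq stationary frequency vector, summing to 1.
#' @param normalize if `TRUE`, scale `Q` so the expected number of
#'   substitutions per unit time at stationarity is 1.
#' @return object of class `subst_model` with elements `states`, `exch`,
#'   `freq`, `Q` and an eigendecomposition used by [transition_matrix()].
#' @export
substitution_model <- function(states, exch, freq, normalize = TRUE) {
  n <- length(states)
  exch <- as.matrix(exch)
  stopifnot(nrow(exch) == n, ncol(exch) == n)
  if (max(abs(exch - t(exch))) > 1e-9)
    stop("exchangeability matrix must be symmetric")
  if (any(exch[upper.tri(exch)] < 0)) stop("negative exchangeability")
  if (abs(sum(freq) - 1) > 1e-8) stop("frequencies must sum to 1")
  if (any(freq < 0)) stop("negative frequency")
  freq <- freq / sum(freq)

  Q <- exch * rep(freq, each = n)   # Q_ij = R_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  if (normalize) {
    if (mu <= 0) stop("degenerate rate matrix (zero total rate)")
    Q <- Q / mu
  }

  ## symmetrized eigendecomposition; guard zero frequencies (sense-codon
  ## vectors from sparse data may contain zeros after pseudocounting off)
  d <- sqrt(pmax(freq, 1e-12))
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(
    states = states, exch = exch, freq = freq, Q = Q,
    eval = e$values,
    U = e$vectors / d,
    Uinv = t(e$vectors * d)
  ), class = "subst_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [substitution_model()].
#' @param t nonnegative branch length (expected substitutions per site
#'   if the model is normalized).
#' @return row-stochastic matrix of transition probabilities.
#' @export
transition_matrix <- function(model, t) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  P <- model$U %*% (exp(model$eval * t) * model$Uinv)
  ## clip tiny negative round-off
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("Reversible substitution model: %d states (%s...)\n",
              length(x$states), paste(utils::head(x$states, 4), collapse = ",")))
  invisible(x)
}

#' Jones-Taylor-Thornton amino-acid model
#'
#' The JTT empirical exchangeabilities and equilibrium frequencies,
#' normalized to one expected substitution per unit time.
#' @param freq optional replacement frequency vector (defaults to the
#'   JTT equilibrium frequencies).
#' @return a `subst_model` over the 20 amino acids.
#' @export
jtt_model <- function(freq = NULL) {
  key <- if (is.null(freq)) "default" else NULL
  if (!is.null(key) && !is.null(.jtt_env$model)) return(.jtt_env$model)
  R <- matrix(0, 20, 20, dimnames = list(AMINO_ACIDS, AMINO_ACIDS))
  R[lower.tri(R)] <- .jtt_lower
  R <- R + t(R)
  m <- substitution_model(AMINO_ACIDS, R,
                          if (is.null(freq)) .jtt_freq else freq)
  if (!is.null(key)) .jtt_env$model <- m
  m
}

#' General time-reversible nucleotide model
#'
#' @param exch named vector of the six relative exchangeabilities
#'   (`AC`, `AG`, `AT`, `CG`, `CT`, `GT`); `AG` is conventionally the
#'   reference with value 1.
#' @param freq base frequencies in A,C,G,T order.
#' @param normalize passed to [substitution_model()].
#' @return a `subst_model` over A,C,G,T.
#' @export
gtr_model <- function(exch = c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1, GT = 1),
                      freq = rep(0.25, 4), normalize = TRUE) {
  pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
  stopifnot(all(pairs %in% names(exch)))
  R <- matrix(0, 4, 4, dimnames = list(NUCLEOTIDES, NUCLEOTIDES))
  for (p in pairs) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    R[a, b] <- R[b, a] <- exch[[p]]
  }
  substitution_model(NUCLEOTIDES, R, freq, normalize = normalize)
}
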