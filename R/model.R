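## Reversible nucleotide substitution models (HKY / GTR) with discrete-gamma
## rate heterogeneity.  Used both to simulate sequences and to compute
## pruning likelihoods, so the two sides share one parameterisation.

#' Nucleotide substitution model
#'
#' Builds an HKY or GTR rate matrix with stationary frequencies and a
#' 4-category discrete gamma model of among-site rate variation.  The rate
#' matrix is scaled so that the expected number of substitutions per site per
#' unit branch length is 1, and the discretised gamma categories have mean
#' rate 1.
#'
#' @param type `"HKY"` or `"GTR"`.
#' @param base_freq stationary frequencies in A, C, G, T order (sum to 1).
#' @param kappa transition/transversion rate ratio (HKY).
#' @param rates six GTR exchangeabilities in the order AC, AG, AT, CG, CT,
#'   GT (GTR only; the HKY special case sets AG = CT = kappa, others 1).
#' @param alpha gamma shape; smaller values mean stronger heterogeneity.
#' @param ncat number of discrete gamma categories.
#' @return an object of class `subst_model`.
#' @export
subst_model <- function(type = c("HKY", "GTR"),
                        base_freq = c(0.40, 0.10, 0.10, 0.40),
                        kappa = 4, rates = NULL, alpha = 0.4, ncat = 4L) {
  type <- match.arg(type)
  stopifnot(length(base_freq) == 4L, all(base_freq > 0))
  base_freq <- base_freq / sum(base_freq)
  if (type == "HKY") {
    if (!is.null(rates)) stop("'rates' is a GTR parameter; use 'kappa' for HKY")
    if (kappa <= 0) stop("kappa must be positive")
    rates <- c(1, kappa, 1, 1, kappa, 1)
  } else {
    if (is.null(rates)) rates <- rep(1, 6)
    if (length(rates) != 6L || any(rates <= 0))
      stop("GTR needs six positive exchangeabilities (AC, AG, AT, CG, CT, GT)")
  }
  if (alpha <= 0) stop("gamma shape must be positive")
  ncat <- as.integer(ncat)

  ## symmetric exchangeability matrix
  S <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  S["A", "C"] <- rates[1]; S["A", "G"] <- rates[2]; S["A", "T"] <- rates[3]
  S["C", "G"] <- rates[4]; S["C", "T"] <- rates[5]; S["G", "T"] <- rates[6]
  S <- S + t(S)
  Q <- S %*% diag(base_freq)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freq * diag(Q))       # expected rate under stationarity
  Q <- Q / mu
  dimnames(Q) <- list(DNA_BASES, DNA_BASES)

  ## eigendecomposition through the symmetrised matrix (real spectrum)
  sp <- sqrt(base_freq)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  right <- diag(1 / sp) %*% eig$vectors
  left <- t(eig$vectors) %*% diag(sp)

  structure(list(
    type = type, base_freq = setNames(base_freq, DNA_BASES),
    kappa = if (type == "HKY") kappa else NA_real_,
    rates = rates, alpha = alpha, ncat = ncat,
    Q = Q, eigenval = eig$values, right = right, left = left,
    gamma_rates = discrete_gamma_rates(alpha, ncat)),
    class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s+G%d substitution model\n", x$type, x$ncat))
  cat("  base frequencies:",
      paste(sprintf("%s=%.3f", DNA_BASES, x$base_freq), collapse = " "), "\n")
  if (x$type == "HKY") cat(sprintf("  kappa: %.3f\n", x$kappa))
  else cat("  exchangeabilities:", paste(signif(x$rates, 4), collapse = " "), "\n")
  cat(sprintf("  gamma shape: %.3f; category rates: %s\n", x$alpha,
              paste(signif(x$gamma_rates, 4), collapse = " ")))
  invisible(x)
}

#' Mean rates of equal-probability discrete gamma categories
#'
#' Standard mean-per-quantile-bin discretisation of a Gamma(shape = alpha,
#' rate = alpha) distribution; the category means average exactly to 1.
#'
#' @param alpha gamma shape.
#' @param ncat number of categories.
#' @return numeric vector of `ncat` category rates.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L) {
  if (ncat == 1L) return(1)
  q <- qgamma(seq_len(ncat - 1L) / ncat, shape = alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  ## E[X; a < X < b] for Gamma(alpha, alpha) uses shape alpha + 1
  r <- ncat * diff(pgamma(bounds, shape = alpha + 1, rate = alpha))
  r / mean(r)
}

## transition probability matrix P(t) for one rate category
prob_matrix <- function(model, t) {
  if (t < 0) stop("negative branch length")
  P <- model$right %*% (exp(model$eigenval * t) * model$left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}

## evolve integer-coded states (1..4) along one branch; `cats` gives the
## gamma category of each site.  Vectorised over (category, parent state).
evolve_states <- function(states, cats, t, model) {
  out <- states
  for (k in seq_len(model$ncat)) {
    in_k <- which(cats == k)
    if (!length(in_k)) next
    P <- prob_matrix(model, t * model$gamma_rates[k])
    for (b in 1:4) {
      idx <- in_k[states[in_k] == b]
      if (length(idx))
        out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  out
}

int_to_dna <- function(states) paste(DNA_BASES[states], collapse = "")
dna_to_int <- function(x) {
  m <- match(seq_chars(toupper(x)), DNA_BASES)
  if (anyNA(m)) stop("non-ACGT base in sequence to encode")
  m
}

## draw stationary bases as integers
draw_bases <- function(n, base_freq) {
  sample.int(4L, n, replace = TRUE, prob = base_freq)
}
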