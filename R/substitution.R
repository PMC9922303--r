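#' GTR substitution model parameters
#'
#' Container for the general time-reversible model: six symmetric
#' exchangeabilities (order AC, AG, AT, CG, CT, GT; GT is conventionally
#' fixed to 1 for identifiability) and four stationary base frequencies
#' in the order A, C, G, T.
#'
#' @param rates numeric vector of 6 positive exchangeabilities
#'   (AC, AG, AT, CG, CT, GT).
#' @param freq numeric vector of 4 positive stationary frequencies
#'   (A, C, G, T); normalized to sum to 1.
#' @return an object of class `gtr_params`.
#' @examples
#' gtr_params()  # Jukes-Cantor limit
#' @export
gtr_params <- function(rates = rep(1, 6), freq = rep(0.25, 4)) {
  rates <- as.numeric(rates)
  freq <- as.numeric(freq)
  if (length(rates) != 6 || any(!is.finite(rates)) || any(rates <= 0))
    stop("'rates' must be 6 positive exchangeabilities (AC,AG,AT,CG,CT,GT)")
  if (length(freq) != 4 || any(!is.finite(freq)) || any(freq <= 0))
    stop("'freq' must be 4 positive base frequencies (A,C,G,T)")
  freq <- freq / sum(freq)
  structure(list(rates = setNames(rates, c("AC","AG","AT","CG","CT","GT")),
                 freq = setNames(freq, c("A","C","G","T"))),
            class = "gtr_params")
}

#' GTR instantaneous rate matrix
#'
#' Builds the 4x4 rate matrix Q with off-diagonals q_ij = s_ij * pi_j,
#' diagonals set so rows sum to zero, normalized so the expected
#' substitution rate at stationarity, -sum(pi_i q_ii), equals 1. Branch
#' lengths are therefore in expected substitutions per site.
#'
#' @param params a [gtr_params()] object.
#' @return 4x4 numeric matrix with dimnames A,C,G,T.
#' @export
gtr_rate_matrix <- function(params) {
  if (!inherits(params, "gtr_params")) params <- do.call(gtr_params, params)
  s <- params$rates
  pi <- params$freq
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  pair <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
  for (k in 1:6) {
    i <- pair[k, 1]; j <- pair[k, 2]
    Q[i, j] <- s[k] * pi[j]
    Q[j, i] <- s[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Eigen-decomposition of a reversible Q via the symmetrizing similarity
# transform; P(t) = U exp(diag(eigval) t) Uinv. Reused by the C++ core.
gtr_eigen <- function(params) {
  Q <- gtr_rate_matrix(params)
  pi <- params$freq
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = diag(1 / d) %*% e$vectors,
       Uinv = t(e$vectors) %*% diag(d),
       eigval = e$values,
       Q = Q)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q a 4x4 rate matrix (from [gtr_rate_matrix()]) or a
#'   [gtr_params()] object.
#' @param t branch length (expected substitutions per site), `t >= 0`.
#' @param params optional [gtr_params()] supplying the stationary
#'   frequencies when `Q` is a plain matrix; if missing they are solved
#'   from `Q`.
#' @return 4x4 stochastic matrix.
#' @export
transition_matrix <- function(Q, t, params = NULL) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("branch length 't' must be a single finite value >= 0")
  if (inherits(Q, "gtr_params")) {
    e <- gtr_eigen(Q)
  } else {
    pi <- if (!is.null(params)) params$freq else stationary_from_Q(Q)
    d <- sqrt(pi)
    S <- diag(d) %*% Q %*% diag(1 / d)
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE)
    e <- list(U = diag(1 / d) %*% ev$vectors,
              Uinv = t(ev$vectors) %*% diag(d), eigval = ev$values)
  }
  P <- e$U %*% diag(exp(e$eigval * t)) %*% e$Uinv
  P[P < 0] <- 0
  dimnames(P) <- list(c("A","C","G","T"), c("A","C","G","T"))
  P
}

# stationary distribution as the null-space left eigenvector of Q
stationary_from_Q <- function(Q) {
  e <- eigen(t(Q))
  v <- Re(e$vectors[, which.min(abs(e$values))])
  v / sum(v)
}

#' Discrete-Gamma model of among-site rate variation
#'
#' K equal-probability categories of a Gamma(alpha, alpha) distribution;
#' each category rate is the mean of the distribution over its quantile
#' bin (not the median), so the probability-weighted mean rate is exactly
#' one.
#'
#' @param alpha positive gamma shape parameter; small values mean strong
#'   rate heterogeneity, large values approach rate homogeneity.
#' @param K number of categories (default 4).
#' @return an object of class `site_rate_model` with fields `alpha`, `K`,
#'   `rates` (increasing) and `probs` (each 1/K).
#' @export
discretize_gamma <- function(alpha, K = 4) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0)
    stop("'alpha' must be a single positive number")
  K <- as.integer(K)
  if (is.na(K) || K < 1) stop("'K' must be a positive integer")
  if (K == 1) {
    rates <- 1
  } else {
    breaks <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha,
                     rate = alpha)
    # mean of Gamma(a, a) over (lo, hi] = K * (F_{a+1}(hi) - F_{a+1}(lo))
    cum <- pgamma(breaks, shape = alpha + 1, rate = alpha)
    rates <- K * diff(cum)
    rates <- rates / mean(rates)  # enforce exact unit mean
  }
  structure(list(alpha = alpha, K = K, rates = rates,
                 probs = rep(1 / K, K)),
            class = "site_rate_model")
}
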