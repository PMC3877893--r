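## The K2P+G+I substitution model: Kimura's two-parameter model (separate
## transition and transversion rates, equal base frequencies) with
## discrete-gamma rate variation across sites and a proportion of invariant
## sites.

#' Construct a K2P+G+I substitution model
#'
#' @param kappa transition/transversion rate ratio (> 0; default 4).
#' @param alpha gamma shape for among-site rate variation (> 0; default 0.5).
#' @param p_inv proportion of invariant sites in [0, 1) (default 0.1).
#' @param n_categories number of discrete gamma rate categories (default 5).
#' @return list of class "substitution_model" with fields kappa, alpha,
#'   p_inv, n_categories and `category_rates` (the means of equal-probability
#'   gamma slices, renormalized to mean exactly 1).
#' @export
substitution_model <- function(kappa = 4, alpha = 0.5, p_inv = 0.1,
                               n_categories = 5L) {
  stopifnot(kappa > 0, alpha > 0, p_inv >= 0, p_inv < 1, n_categories >= 1)
  structure(
    list(kappa = kappa, alpha = alpha, p_inv = p_inv,
         n_categories = as.integer(n_categories),
         category_rates = gamma_category_rates(alpha, n_categories)),
    class = "substitution_model"
  )
}

#' Discrete-gamma category rates (mean-of-slice discretization)
#'
#' Splits the gamma(alpha, alpha) distribution (mean 1) into `k` equal
#' probability slices and returns each slice's conditional mean, renormalized
#' so the categories average exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories.
#' @return numeric vector of k positive rates with mean 1.
#' @export
gamma_category_rates <- function(alpha, k) {
  k <- as.integer(k)
  if (k == 1L) return(1)
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha,
                          rate = alpha)
  # E[X ; a < X < b] under gamma(a, a) equals F_{a+1,a}(b) - F_{a+1,a}(a)
  upper <- stats::pgamma(breaks[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(breaks[-(k + 1L)], shape = alpha + 1, rate = alpha)
  r <- (upper - lower) * k
  r / mean(r)
}

#' K2P transition probability matrix
#'
#' Closed-form K80 probabilities at effective branch length `r * t`, with
#' the rate matrix scaled to one expected substitution per site per unit
#' branch length: with e1 = exp(-4rt/(kappa+2)) and
#' e2 = exp(-2rt(kappa+1)/(kappa+2)), the probability of observing the same
#' base is 1/4 + e1/4 + e2/2, a transition 1/4 + e1/4 - e2/2, and each
#' transversion 1/4 - e1/4.
#'
#' @param model a "substitution_model" (only `kappa` is used).
#' @param t branch length in substitutions/site (>= 0).
#' @param r rate multiplier (> 0; default 1).
#' @return 4x4 row-stochastic matrix over bases A, C, G, T.
#' @export
transition_probability <- function(model, t, r = 1) {
  stopifnot(t >= 0, r > 0)
  kappa <- model$kappa
  rt <- r * t
  e1 <- exp(-4 * rt / (kappa + 2))
  e2 <- exp(-2 * rt * (kappa + 1) / (kappa + 2))
  ps <- 0.25 + 0.25 * e1 + 0.5 * e2
  pt <- 0.25 + 0.25 * e1 - 0.5 * e2
  pv <- 0.25 - 0.25 * e1
  bases <- c("A", "C", "G", "T")
  partner <- c(A = "G", C = "T", G = "A", T = "C")
  P <- matrix(pv, 4, 4, dimnames = list(bases, bases))
  diag(P) <- ps
  for (b in bases) P[b, partner[[b]]] <- pt
  P
}
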