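## Felsenstein pruning likelihood under K2P+G+I.
##
## Alignments are compressed to unique site patterns; gaps and ambiguity
## codes enter the pruning as partial vectors with a 1 for every compatible
## base. The invariant-site term contributes p_inv * m/4 for a column whose
## per-leaf compatible base sets intersect in m bases (m = 1 for a plain
## constant column, 0 for a variable one).

## Compress an alignment into (mask matrix: patterns x taxa, weights).
.site_patterns <- function(alignment) {
  mat <- alignment_matrix(alignment)
  n_tax <- nrow(mat); n_site <- ncol(mat)
  masks <- matrix(15L, n_tax, n_site)
  nongap <- mat != "-"
  masks[nongap] <- .iupac_mask_table[mat[nongap]]
  key <- apply(masks, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  list(mask = t(masks[, first, drop = FALSE]), weight = weights)
}

## Precompute everything the C++ pruning needs for one (tree, alignment).
## Returns a function f(edge_length, kappa, rates, p_inv) -> logL plus the
## postorder tree used (edge order defines the edge_length layout).
.make_loglik <- function(tree, alignment, pat = NULL) {
  if (!setequal(tree$tip.label, alignment$id)) {
    stop("tree leaves and alignment ids differ", call. = FALSE)
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(pat)) pat <- .site_patterns(alignment)
  ord <- match(tree$tip.label, alignment$id)
  mask <- pat$mask[, ord, drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  acc <- rep(15L, nrow(mask))
  for (j in seq_len(ncol(mask))) acc <- bitwAnd(acc, mask[, j])
  nconst <- ifelse(acc == 0L, 0L, .popcount4[pmax(acc, 1L)])
  force(mask)
  list(
    tree = tree, mask = mask, weight = pat$weight,
    n_tip = n_tip, n_node = n_node, nconst = nconst,
    fn = function(edge_length, kappa, rates, p_inv) {
      k2p_loglik_cpp(tree$edge[, 1L], tree$edge[, 2L], edge_length,
                     n_tip, n_node, mask, pat$weight, kappa, rates, p_inv)
    }
  )
}

## K80 transition matrix at effective length d (plain numeric helper).
.k2p_pmat <- function(kappa, d) {
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  ps <- 0.25 + 0.25 * e1 + 0.5 * e2
  pt <- 0.25 + 0.25 * e1 - 0.5 * e2
  pv <- 0.25 - 0.25 * e1
  matrix(c(ps, pv, pt, pv,
           pv, ps, pv, pt,
           pt, pv, ps, pv,
           pv, pt, pv, ps), 4, 4, byrow = TRUE)
}

## Cheap single-branch log-likelihood function built from the edge's
## inside/outside vectors; mathematically identical to a full pruning pass
## with only edge `e`'s length varying.
.branch_loglik_fun <- function(ctx, bl, kappa, rates, p_inv, e) {
  vec <- k2p_edge_vectors_cpp(ctx$tree$edge[, 1L], ctx$tree$edge[, 2L],
                              bl, ctx$n_tip, ctx$n_node, ctx$mask,
                              kappa, rates, as.integer(e - 1L))
  eS <- exp(vec$S)
  K <- length(rates)
  const_part <- p_inv * ctx$nconst / 4
  function(t) {
    var_part <- 0
    for (k in seq_len(K)) {
      idx <- ((k - 1L) * 4L + 1L):((k - 1L) * 4L + 4L)
      A <- vec$G[, idx, drop = FALSE] %*% .k2p_pmat(kappa, t * rates[k])
      var_part <- var_part +
        rowSums(A * vec$I[, idx, drop = FALSE]) * eS[, k]
    }
    site <- const_part + (1 - p_inv) * var_part / K
    sum(ctx$weight * log(site))
  }
}

#' Log-likelihood of an alignment on a tree under K2P+G+I
#'
#' Per-site likelihood is p_inv * (m/4) + (1 - p_inv) * (1/K) *
#' sum_k L(site | rate_k), where m counts bases compatible with every leaf at
#' that site, and L is the pruning likelihood with uniform 1/4 root
#' frequencies. Identical site patterns are computed once.
#'
#' @param tree a "phylo" tree whose tip labels equal the alignment ids.
#' @param alignment a "seq_alignment".
#' @param model a "substitution_model".
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(tree, alignment, model) {
  ctx <- .make_loglik(tree, alignment)
  ctx$fn(ctx$tree$edge.length, model$kappa, model$category_rates, model$p_inv)
}
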