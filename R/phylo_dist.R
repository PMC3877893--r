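## Kimura 2-parameter distances and the neighbor-joining starting tree.

#' K2P distance between two (possibly gapped) alignment rows
#'
#' Sites where either row carries a gap or an ambiguity code are excluded
#' (pairwise deletion). With P the proportion of transitions (A<->G, C<->T)
#' and Q the proportion of transversions among compared sites, the distance
#' is d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q).
#'
#' @param row_a,row_b equal-length residue strings.
#' @return list of class "k2p_distance": `p_transitions`, `q_transversions`,
#'   `sites_compared`, `distance`.
#' @export
k2p_distance <- function(row_a, row_b) {
  a <- strsplit(toupper(row_a), "")[[1]]
  b <- strsplit(toupper(row_b), "")[[1]]
  if (length(a) != length(b)) stop("rows differ in length", call. = FALSE)
  plain <- c("A", "C", "G", "T")
  use <- a %in% plain & b %in% plain
  n <- sum(use)
  if (n == 0L) stop("no comparable sites (all gapped or ambiguous)", call. = FALSE)
  a <- a[use]; b <- b[use]
  purine <- c("A", "G")
  diff <- a != b
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance saturated (1-2P-Q = ", signif(w1, 4), ", 1-2Q = ",
         signif(w2, 4), ")", call. = FALSE)
  }
  structure(
    list(p_transitions = P, q_transversions = Q, sites_compared = n,
         distance = -0.5 * log(w1) - 0.25 * log(w2)),
    class = "k2p_distance"
  )
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param alignment a "seq_alignment".
#' @param on_saturation "error" propagates saturation errors;
#'   "cap" substitutes `cap` for saturated or incomparable pairs (used by the
#'   bootstrap, where resampled replicates can saturate by chance).
#' @param cap distance substituted under `on_saturation = "cap"` (default 5).
#' @return symmetric numeric matrix with dimnames = record ids.
#' @export
k2p_distance_matrix <- function(alignment, on_saturation = c("error", "cap"),
                                cap = 5) {
  on_saturation <- match.arg(on_saturation)
  n <- nrow(alignment)
  ids <- alignment$id
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- if (on_saturation == "error") {
        k2p_distance(alignment$residues[i], alignment$residues[j])$distance
      } else {
        tryCatch(
          k2p_distance(alignment$residues[i], alignment$residues[j])$distance,
          error = function(e) cap
        )
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (the starting tree for the likelihood search);
#' negative branch length estimates are clamped to zero.
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal,
#'   finite entries and at least 3 taxa; dimnames give the leaf labels.
#' @return an unrooted "phylo" tree.
#' @export
nj_tree <- function(distance_matrix) {
  if (!all(is.finite(distance_matrix))) {
    stop("distance matrix contains non-finite entries", call. = FALSE)
  }
  if (nrow(distance_matrix) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (max(abs(distance_matrix - t(distance_matrix))) > 1e-12) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tr <- ape::nj(stats::as.dist(distance_matrix))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
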