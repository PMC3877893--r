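## Nonparametric bootstrap support mapped onto the best ML tree.

#' Bootstrap configuration
#'
#' @param n_replicates number of column-resampling replicates (>= 1).
#' @param seed integer seed; replicate r draws its resampling stream from
#'   seed + r, so replicates are reproducible and independent.
#' @return list of class "bootstrap_config".
#' @export
bootstrap_config <- function(n_replicates = 1000L, seed = 1L) {
  stopifnot(n_replicates >= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

## Column-resample an alignment (indices drawn with replacement).
.resample_alignment <- function(alignment, idx) {
  mat <- alignment_matrix(alignment)[, idx, drop = FALSE]
  out <- seq_set(alignment$id, apply(mat, 1L, paste, collapse = ""),
                 alignment$description)
  as_alignment(out)
}

## One tree estimate: K2P distances (saturation capped) -> NJ -> branch
## lengths -> NNI. Model parameters are held fixed.
.estimate_tree <- function(alignment, model) {
  D <- k2p_distance_matrix(alignment, on_saturation = "cap")
  start <- nj_tree(D)
  nni_search(start, alignment, model, tol = 1e-2)$tree
}

#' Nonparametric bootstrap clade support for a maximum-likelihood tree
#'
#' Each replicate resamples alignment columns with replacement (replicate r
#' is seeded with `config$seed + r`), re-estimates a tree (NJ start,
#' branch-length optimization, NNI search; model parameters fixed at their
#' values fitted on the original alignment), and each internal edge of
#' `best_tree` receives the percentage of replicate trees containing the
#' same bipartition.
#'
#' @param alignment a "seq_alignment".
#' @param model the "substitution_model" fitted on the original alignment.
#' @param config a "bootstrap_config".
#' @param best_tree the ML tree to annotate (tips == alignment ids).
#' @param refit_per_replicate refit model parameters on every replicate
#'   instead of reusing the original fit (default FALSE; much slower).
#' @return `best_tree` with `node.label` holding support percentages in
#'   [0, 100] (root label empty), plus attribute "support_table": a
#'   data.frame of split keys and supports.
#' @export
bootstrap_support <- function(alignment, model, config, best_tree,
                              refit_per_replicate = FALSE) {
  if (!setequal(best_tree$tip.label, alignment$id)) {
    stop("best_tree leaves must match the alignment ids", call. = FALSE)
  }
  n_col <- attr(alignment, "columns")
  target <- tree_splits(best_tree)
  counts <- stats::setNames(numeric(length(target)), target)
  for (r in seq_len(config$n_replicates)) {
    set.seed(config$seed + r)
    idx <- sample.int(n_col, n_col, replace = TRUE)
    rep_aln <- .resample_alignment(alignment, idx)
    rep_model <- if (refit_per_replicate) {
      D <- k2p_distance_matrix(rep_aln, on_saturation = "cap")
      st <- nj_tree(D)
      suppressWarnings(optimize_phylo(st, rep_aln, model)$model)
    } else {
      model
    }
    rep_tree <- .estimate_tree(rep_aln, rep_model)
    hits <- tree_splits(rep_tree)
    inboth <- target %in% hits
    counts[inboth] <- counts[inboth] + 1
  }
  support <- 100 * counts / config$n_replicates
  annotate_supports(best_tree, support)
}

#' Attach split supports to a tree as node labels
#'
#' @param tree a "phylo" tree.
#' @param support named numeric vector: split key (as from [tree_splits()])
#'   to support percentage.
#' @return the tree with `node.label` set (empty where no support applies)
#'   and attribute "support_table".
#' @export
annotate_supports <- function(tree, support) {
  n_tip <- length(tree$tip.label)
  sets <- .node_leafsets(tree)
  labels <- character(tree$Nnode)
  for (nd in (n_tip + 1L):(n_tip + tree$Nnode)) {
    key <- .split_key(sets[[nd]], tree$tip.label)
    if (key %in% names(support)) {
      labels[nd - n_tip] <- format(round(support[[key]], 1))
    }
  }
  tree$node.label <- labels
  attr(tree, "support_table") <- data.frame(
    split = names(support), support = unname(support),
    stringsAsFactors = FALSE
  )
  tree
}

#' Per-edge supports of an annotated tree
#'
#' @param tree a "phylo" with numeric `node.label` supports.
#' @return data.frame: `split` (canonical key), `support` (numeric; NA for
#'   unlabeled edges).
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) {
    stop("tree has no support labels; run bootstrap_support first",
         call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  sets <- .node_leafsets(tree)
  splits <- tree_splits(tree)
  rows <- lapply((n_tip + 1L):(n_tip + tree$Nnode), function(nd) {
    key <- .split_key(sets[[nd]], tree$tip.label)
    if (!key %in% splits) return(NULL)
    lab <- tree$node.label[nd - n_tip]
    data.frame(split = key,
               support = suppressWarnings(as.numeric(lab)),
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
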