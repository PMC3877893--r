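## Branch-length / model optimization by coordinate ascent and the
## nearest-neighbor-interchange topology search.

.BL_RANGE <- c(1e-8, 10)
.KAPPA_RANGE <- c(0.1, 100)
.ALPHA_RANGE <- c(0.05, 50)
.PINV_RANGE <- c(0, 0.99)

## One-dimensional maximization that never returns a point worse than the
## incumbent (stats::optimize is golden-section based and can land a hair
## below the current value near a boundary).
.maximize1 <- function(f, range, current_x, current_y) {
  opt <- stats::optimize(f, interval = range, maximum = TRUE,
                         tol = .Machine$double.eps^0.3)
  if (opt$objective > current_y) {
    list(x = opt$maximum, y = opt$objective)
  } else {
    list(x = current_x, y = current_y)
  }
}

#' Optimize branch lengths (and optionally model parameters) on a fixed topology
#'
#' Coordinate ascent: each branch length is maximized by golden-section
#' search on [1e-8, 10]; then, when `fit_model` is TRUE, kappa on [0.1, 100],
#' alpha on [0.05, 50] and p_inv on [0, 0.99]. Sweeps repeat until the
#' log-likelihood gain drops below `tol`. The log-likelihood never decreases
#' across sweeps.
#'
#' @param tree starting "phylo" tree (tips must match the alignment ids).
#' @param alignment a "seq_alignment".
#' @param model starting "substitution_model".
#' @param fit_model also fit the model parameters (default TRUE).
#' @param fit_params which model parameters to fit when `fit_model` is TRUE
#'   (default all of kappa, alpha, p_inv).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_sweeps maximum coordinate-ascent sweeps (default 50); hitting
#'   it raises a warning and returns the best configuration so far.
#' @param edge_subset optional indices (into the postorder edge rows) of the
#'   only branches to optimize; used by the NNI search to rescore candidate
#'   rearrangements on the affected quartet.
#' @param warn emit the non-convergence warning (default TRUE).
#' @param site_patterns precompressed site patterns (internal reuse across
#'   repeated calls on one alignment).
#' @return list: `tree` (optimized branch lengths), `model` (fitted),
#'   `logL`, `sweeps`.
#' @export
optimize_phylo <- function(tree, alignment, model, fit_model = TRUE,
                           tol = 1e-6, max_sweeps = 50L, edge_subset = NULL,
                           warn = TRUE, site_patterns = NULL,
                           fit_params = c("kappa", "alpha", "p_inv")) {
  ctx <- .make_loglik(tree, alignment, pat = site_patterns)
  tree <- ctx$tree
  bl <- pmax(tree$edge.length, .BL_RANGE[1])
  kappa <- model$kappa; alpha <- model$alpha; p_inv <- model$p_inv
  rates <- gamma_category_rates(alpha, model$n_categories)
  cur <- ctx$fn(bl, kappa, rates, p_inv)
  sweeps <- 0L
  which_edges <- if (is.null(edge_subset)) seq_along(bl) else edge_subset
  repeat {
    sweeps <- sweeps + 1L
    before <- cur
    for (e in which_edges) {
      f <- .branch_loglik_fun(ctx, bl, kappa, rates, p_inv, e)
      res <- .maximize1(f, .BL_RANGE, bl[e], cur)
      bl[e] <- res$x; cur <- res$y
    }
    if (fit_model) {
      if ("kappa" %in% fit_params) {
        res <- .maximize1(function(x) ctx$fn(bl, x, rates, p_inv),
                          .KAPPA_RANGE, kappa, cur)
        kappa <- res$x; cur <- res$y
      }
      if ("alpha" %in% fit_params && model$n_categories > 1L) {
        res <- .maximize1(function(x) {
          ctx$fn(bl, kappa, gamma_category_rates(x, model$n_categories),
                 p_inv)
        }, .ALPHA_RANGE, alpha, cur)
        alpha <- res$x
        rates <- gamma_category_rates(alpha, model$n_categories)
        cur <- res$y
      }
      if ("p_inv" %in% fit_params) {
        res <- .maximize1(function(x) ctx$fn(bl, kappa, rates, x),
                          .PINV_RANGE, p_inv, cur)
        p_inv <- res$x; cur <- res$y
      }
    }
    if (cur - before < tol) break
    if (sweeps >= max_sweeps) {
      if (warn) {
        warning("optimize_phylo did not converge in ", max_sweeps,
                " sweeps; returning best so far")
      }
      break
    }
  }
  tree$edge.length <- bl
  out_model <- substitution_model(kappa, alpha, p_inv, model$n_categories)
  list(tree = tree, model = out_model, logL = cur, sweeps = sweeps)
}

## Deterministic split key of an internal edge: child-side leaf labels,
## canonicalized to the side not containing the alphabetically first leaf.
.split_key <- function(side, all_labels) {
  first <- min(all_labels)
  if (first %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

## Leaf label sets below every node (1-based node ids, ape convention).
.node_leafsets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

#' Non-trivial splits (bipartitions) of an unrooted tree
#'
#' @param tree a "phylo" tree.
#' @return character vector of canonical split keys, one per internal edge
#'   (the leaf set not containing the alphabetically first label, sorted and
#'   joined by "|").
#' @export
tree_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- .node_leafsets(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  internal <- which(tree$edge[, 2L] > n_tip)
  keys <- vapply(internal, function(e) {
    .split_key(sets[[tree$edge[e, 2L]]], tree$tip.label)
  }, character(1))
  # the root-adjacent "split" can duplicate another or be trivial
  sizes <- vapply(strsplit(keys, "|", fixed = TRUE), length, integer(1))
  unique(keys[sizes >= 2L & sizes <= n_tip - 2L])
}

## The two NNI rearrangements across internal edge row `e` of tree$edge.
## Returns a list of edge matrices (parent reassignments applied).
.nni_neighbors <- function(tree, e) {
  edge <- tree$edge
  u <- edge[e, 1L]; v <- edge[e, 2L]
  children_v <- which(edge[, 1L] == v)          # rows of v's child edges
  # the swap partner on u's side: another child edge of u (not v)
  sib_rows <- setdiff(which(edge[, 1L] == u), e)
  if (!length(children_v) || !length(sib_rows)) return(list())
  s_row <- sib_rows[1L]
  lapply(children_v[seq_len(min(2L, length(children_v)))], function(c_row) {
    ed <- edge
    ed[c_row, 1L] <- u   # child of v moves under u
    ed[s_row, 1L] <- v   # u's other subtree moves under v
    ed
  })
}

.rebuild_tree <- function(tree, new_edge) {
  out <- tree
  out$edge <- new_edge
  attr(out, "order") <- NULL  # force a true reorder after surgery
  ape::reorder.phylo(out, "postorder")
}

#' Nearest-neighbor-interchange search for the maximum-likelihood topology
#'
#' Evaluates both NNI rearrangements across every internal edge (edges
#' visited in the deterministic order of their label-sorted bipartitions),
#' re-optimizing branch lengths on each candidate, and accepts the best
#' strict improvement; repeats until no rearrangement improves the
#' log-likelihood.
#'
#' @param tree optimized starting "phylo" tree (typically NJ + branch-length
#'   optimization).
#' @param alignment a "seq_alignment".
#' @param model a "substitution_model" (held fixed during the search).
#' @param tol acceptance tolerance: a candidate must improve the
#'   log-likelihood by more than this (default 1e-6).
#' @param max_rounds safety cap on accepted rearrangements (default 100).
#' @return list: `tree` (branch lengths re-optimized), `logL`, `n_accepted`.
#' @export
nni_search <- function(tree, alignment, model, tol = 1e-6, max_rounds = 100L) {
  pat <- .site_patterns(alignment)
  opt <- optimize_phylo(tree, alignment, model, fit_model = FALSE,
                        tol = max(tol, 1e-6), warn = FALSE,
                        site_patterns = pat)
  tree <- opt$tree; cur <- opt$logL
  n_accepted <- 0L
  repeat {
    n_tip <- length(tree$tip.label)
    sets <- .node_leafsets(tree)
    tree <- ape::reorder.phylo(tree, "postorder")
    internal <- which(tree$edge[, 2L] > n_tip)
    keys <- vapply(internal, function(e) {
      .split_key(sets[[tree$edge[e, 2L]]], tree$tip.label)
    }, character(1))
    internal <- internal[order(keys)]
    best <- NULL; best_logL <- cur
    for (e in internal) {
      u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
      for (ed in .nni_neighbors(tree, e)) {
        cand <- .rebuild_tree(tree, ed)
        quartet <- which(cand$edge[, 1L] %in% c(u, v) |
                           cand$edge[, 2L] %in% c(u, v))
        cand_opt <- optimize_phylo(cand, alignment, model, fit_model = FALSE,
                                   tol = max(tol, 1e-6), max_sweeps = 1L,
                                   edge_subset = quartet, warn = FALSE,
                                   site_patterns = pat)
        if (cand_opt$logL > best_logL + tol) {
          best <- cand_opt$tree; best_logL <- cand_opt$logL
        }
      }
    }
    if (is.null(best)) break
    tree <- best; cur <- best_logL
    n_accepted <- n_accepted + 1L
    if (n_accepted >= max_rounds) break
  }
  final <- optimize_phylo(tree, alignment, model, fit_model = FALSE,
                          tol = max(tol, 1e-6), warn = FALSE,
                          site_patterns = pat)
  list(tree = final$tree, logL = final$logL, n_accepted = n_accepted)
}
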