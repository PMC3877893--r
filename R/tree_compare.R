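## Gene-tree versus species-tree analysis: supported-clade extraction at the
## display thresholds, Robinson-Foulds incongruence, greedy identification of
## displaced taxa (lateral-transfer candidates), and novel-clade flagging.

#' Extract supported clades from a bootstrapped tree
#'
#' Returns every internal-edge bipartition whose support meets the
#' threshold; each clade is reported as the smaller-side leaf set of its
#' edge. The conventional display thresholds are 70 for gene trees and 50
#' for 16S reference trees.
#'
#' @param tree a "phylo" with support `node.label`s (run
#'   [bootstrap_support()] first).
#' @param threshold minimum support percentage (default 70).
#' @return list of class "clade_set": `clades` (list of entries with
#'   `members`, `support`), `threshold`.
#' @export
extract_clades <- function(tree, threshold = 70) {
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label))) {
    stop("tree carries no bootstrap supports; run bootstrap_support first",
         call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  sets <- .node_leafsets(tree)
  splits <- tree_splits(tree)
  seen <- character(0)
  clades <- list()
  for (nd in (n_tip + 1L):(n_tip + tree$Nnode)) {
    key <- .split_key(sets[[nd]], tree$tip.label)
    if (!key %in% splits || key %in% seen) next
    lab <- tree$node.label[nd - n_tip]
    if (!nzchar(lab)) next
    support <- as.numeric(lab)
    if (is.na(support) || support < threshold) next
    seen <- c(seen, key)
    side <- sets[[nd]]
    other <- setdiff(tree$tip.label, side)
    members <- if (length(side) <= length(other)) side else other
    clades[[length(clades) + 1L]] <- list(members = sort(members),
                                          support = support)
  }
  structure(list(clades = clades, threshold = threshold),
            class = "clade_set")
}

#' Restrict two trees to their shared leaves
#'
#' Drops unshared leaves from both trees; degree-2 nodes created by the
#' pruning are suppressed with their branch lengths summed.
#'
#' @param t1,t2 "phylo" trees with >= 4 shared leaf labels.
#' @return list `t1`, `t2` of pruned trees.
#' @export
prune_shared <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) {
    stop("trees share only ", length(shared),
         " leaves; need >= 4 to compare", call. = FALSE)
  }
  list(t1 = ape::keep.tip(t1, shared), t2 = ape::keep.tip(t2, shared))
}

#' Robinson-Foulds incongruence between two trees
#'
#' Trees are first pruned to their shared leaves; the RF distance counts the
#' non-trivial bipartitions present in exactly one tree. The maximum is
#' 2(n - 3) for n shared leaves (fully resolved trees).
#'
#' @param t1,t2 "phylo" trees with >= 4 shared leaves.
#' @return list of class "incongruence_report": `shared_taxa`,
#'   `rf_distance`, `max_rf`, `normalized_rf`.
#' @export
robinson_foulds <- function(t1, t2) {
  pr <- prune_shared(t1, t2)
  s1 <- tree_splits(pr$t1)
  s2 <- tree_splits(pr$t2)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  n <- length(pr$t1$tip.label)
  max_rf <- 2L * (n - 3L)
  structure(
    list(shared_taxa = n, rf_distance = rf, max_rf = max_rf,
         normalized_rf = if (max_rf > 0) rf / max_rf else 0),
    class = "incongruence_report"
  )
}

#' Greedy identification of displaced taxa (lateral-transfer candidates)
#'
#' Repeatedly removes the single leaf whose removal most reduces the
#' Robinson-Foulds distance between the two trees (ties broken
#' alphabetically), until the trees agree (RF = 0), no removal helps, or the
#' budget is exhausted. Taxa removed early are the strongest candidates for
#' having moved by horizontal gene transfer.
#'
#' @param t1,t2 comparable "phylo" trees (>= 4 shared leaves).
#' @param budget maximum number of removals (default 5).
#' @return data.frame: `taxon` (removal order), `rf_after_removal`; zero
#'   rows when the trees are already congruent.
#' @export
displaced_taxa <- function(t1, t2, budget = 5L) {
  pr <- prune_shared(t1, t2)
  t1 <- pr$t1; t2 <- pr$t2
  out <- data.frame(taxon = character(0), rf_after_removal = integer(0),
                    stringsAsFactors = FALSE)
  cur_rf <- robinson_foulds(t1, t2)$rf_distance
  while (cur_rf > 0L && nrow(out) < budget &&
         length(t1$tip.label) > 4L) {
    cands <- sort(t1$tip.label)
    best_taxon <- NULL; best_rf <- cur_rf
    for (tax in cands) {
      r1 <- ape::drop.tip(t1, tax)
      r2 <- ape::drop.tip(t2, tax)
      rf <- robinson_foulds(r1, r2)$rf_distance
      if (rf < best_rf) { best_rf <- rf; best_taxon <- tax }
    }
    if (is.null(best_taxon)) break  # no strict improvement available
    t1 <- ape::drop.tip(t1, best_taxon)
    t2 <- ape::drop.tip(t2, best_taxon)
    cur_rf <- best_rf
    out <- rbind(out, data.frame(taxon = best_taxon,
                                 rf_after_removal = cur_rf,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Flag novel clades among supported gene-tree clades
#'
#' A supported clade is novel when it contains at least two query taxa and
#' no taxon with a known chemotype annotation, and is maximal with that
#' property. Query taxa in no novel clade are reported separately as loner
#' candidates.
#'
#' @param gene_clades a "clade_set" from [extract_clades()].
#' @param annotations named character vector: taxon -> known chemotype label
#'   or "query"; every clade member must be annotated.
#' @return list: `novel` (list of clades with `members`, `support`),
#'   `loners` (query taxa outside every novel clade).
#' @export
flag_novel_clades <- function(gene_clades, annotations) {
  all_members <- unique(unlist(lapply(gene_clades$clades, `[[`, "members")))
  missing <- setdiff(all_members, names(annotations))
  if (length(missing)) {
    stop("unannotated taxa: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  qualifies <- vapply(gene_clades$clades, function(cl) {
    ann <- annotations[cl$members]
    sum(ann == "query") >= 2L && all(ann == "query")
  }, logical(1))
  qual <- gene_clades$clades[qualifies]
  # maximality: drop qualifying clades strictly contained in another
  keep <- rep(TRUE, length(qual))
  for (i in seq_along(qual)) {
    for (j in seq_along(qual)) {
      if (i == j) next
      if (all(qual[[i]]$members %in% qual[[j]]$members) &&
          length(qual[[i]]$members) < length(qual[[j]]$members)) {
        keep[i] <- FALSE
      }
    }
  }
  novel <- qual[keep]
  queries <- names(annotations)[annotations == "query"]
  in_novel <- unique(unlist(lapply(novel, `[[`, "members")))
  list(novel = novel, loners = sort(setdiff(queries, in_novel)))
}
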