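## Progressive multiple alignment: k-mer guide tree plus profile-profile
## global alignment with affine gaps. A deliberate, deterministic stand-in
## for a production aligner — externally computed alignments can always be
## imported as gapped FASTA and fed to as_alignment().

#' Alignment scoring scheme
#'
#' Integer scores: match +1, mismatch -1, gap open -4 (cost of the first gap
#' position), gap extend -1 (each further position).
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores with
#'   gap_open <= gap_extend <= 0 < match.
#' @return list of class "scoring_scheme".
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -4,
                           gap_extend = -1) {
  if (!(gap_open <= gap_extend && gap_extend <= 0 && 0 < match)) {
    stop("scheme must satisfy gap_open <= gap_extend <= 0 < match",
         call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

## 4 x L residue-frequency profile of a set of aligned rows; ambiguity codes
## contribute fractional counts over their base sets, gaps contribute 0.
.profile_of <- function(rows) {
  L <- nchar(rows[1])
  prof <- matrix(0, 4, L)
  for (s in rows) {
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(L)) {
      if (ch[i] == "-") next
      m <- .iupac_mask_table[[ch[i]]]
      bits <- which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
      prof[bits, i] <- prof[bits, i] + 1 / length(bits)
    }
  }
  prof / length(rows)
}

## Apply a traceback op vector to two row sets, producing merged gapped rows.
.apply_ops <- function(rows_a, rows_b, ops) {
  idx_a <- integer(0); idx_b <- integer(0)  # source column or NA (gap)
  ia <- 0L; ib <- 0L
  for (op in ops) {
    if (op == 0L) { ia <- ia + 1L; ib <- ib + 1L; idx_a <- c(idx_a, ia); idx_b <- c(idx_b, ib) }
    else if (op == 1L) { ia <- ia + 1L; idx_a <- c(idx_a, ia); idx_b <- c(idx_b, NA) }
    else { ib <- ib + 1L; idx_a <- c(idx_a, NA); idx_b <- c(idx_b, ib) }
  }
  expand <- function(rows, idx) {
    vapply(rows, function(s) {
      ch <- strsplit(s, "")[[1]]
      out <- rep("-", length(idx))
      out[!is.na(idx)] <- ch[idx[!is.na(idx)]]
      paste(out, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  list(a = expand(rows_a, idx_a), b = expand(rows_b, idx_b))
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment; traceback ties prefer the diagonal,
#' then consuming from `a` ("up"), then from `b` ("left"), so output is
#' deterministic.
#'
#' @param a,b single-row "seq_set"s or ungapped sequence strings.
#' @param scheme a "scoring_scheme".
#' @return list: `aligned_a`, `aligned_b` (gapped strings), `score`.
#' @export
pairwise_global <- function(a, b, scheme = scoring_scheme()) {
  sa <- if (is.data.frame(a)) a$residues[1] else toupper(a)
  sb <- if (is.data.frame(b)) b$residues[1] else toupper(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  res <- nw_affine_profile_cpp(.profile_of(sa), .profile_of(sb),
                               scheme$match, scheme$mismatch,
                               scheme$gap_open, scheme$gap_extend)
  out <- .apply_ops(sa, sb, res$ops)
  list(aligned_a = out$a, aligned_b = out$b, score = res$score)
}

## Average-linkage (UPGMA) clustering with lexicographic tie-breaks on
## cluster labels; returns the merge order as nested index lists.
.average_linkage <- function(D, labels) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))             # member row indices
  names(clusters) <- labels
  active <- rep(TRUE, n_total <- n)
  Dm <- D
  merges <- list()
  cl_label <- labels
  while (sum(active) > 1L) {
    act <- which(active)
    best <- NULL
    for (ii in seq_along(act)) {
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        i <- act[ii]; j <- act[jj]
        d <- Dm[i, j]
        key <- sort(c(cl_label[i], cl_label[j]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    # average-linkage update of distances to the merged cluster (stored at i)
    for (k in which(active)) {
      if (k == i || k == j) next
      Dm[i, k] <- Dm[k, i] <- (ni * Dm[i, k] + nj * Dm[j, k]) / (ni + nj)
    }
    merges[[length(merges) + 1L]] <- list(left = clusters[[i]],
                                          right = clusters[[j]])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    cl_label[i] <- min(cl_label[i], cl_label[j])
    active[j] <- FALSE
  }
  merges
}

#' k-mer guide tree for progressive alignment
#'
#' Pairwise distances are 1 - Jaccard similarity of canonical k-mer sets,
#' clustered by average linkage with lexicographic tie-breaks, so the guide
#' tree is deterministic.
#'
#' @param records a "seq_set" with >= 2 records.
#' @param k k-mer size (default 8).
#' @return list: `merges` (ordered merge list of record-index groups),
#'   `distances` (matrix).
#' @export
guide_tree <- function(records, k = 8L) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records", call. = FALSE)
  sets <- lapply(records$residues, function(s) canonical_kmers(degap(s), k))
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      u <- length(union(sets[[i]], sets[[j]]))
      jac <- if (u == 0L) 0 else length(intersect(sets[[i]], sets[[j]])) / u
      D[i, j] <- D[j, i] <- 1 - jac
    }
  }
  list(merges = .average_linkage(D, records$id), distances = D)
}

#' Progressive multiple alignment
#'
#' Aligns profiles up the guide tree with affine-gap profile-profile global
#' alignment (column score = mean pair score over residue frequencies).
#' Every input sequence is recoverable by deleting gaps from its row.
#'
#' @param records a "seq_set" of >= 2 ungapped sequences.
#' @param scheme a "scoring_scheme".
#' @param k guide-tree k-mer size (default 8).
#' @return a "seq_alignment" in the input record order.
#' @export
progressive_align <- function(records, scheme = scoring_scheme(), k = 8L) {
  if (nrow(records) < 2L) stop("need at least 2 records", call. = FALSE)
  gt <- guide_tree(records, k)
  rows <- as.list(toupper(records$residues))      # per-record gapped rows
  groups <- lapply(seq_len(nrow(records)), identity)
  for (m in gt$merges) {
    left <- m$left; right <- m$right
    rows_a <- unlist(rows[left]); rows_b <- unlist(rows[right])
    res <- nw_affine_profile_cpp(.profile_of(rows_a), .profile_of(rows_b),
                                 scheme$match, scheme$mismatch,
                                 scheme$gap_open, scheme$gap_extend)
    merged <- .apply_ops(rows_a, rows_b, res$ops)
    rows[left] <- as.list(merged$a)
    rows[right] <- as.list(merged$b)
  }
  out <- seq_set(records$id, unlist(rows), records$description)
  # drop any all-gap columns produced by profile bookkeeping
  mat <- alignment_matrix(out)
  keep <- colSums(mat != "-") > 0L
  if (!all(keep)) {
    out <- seq_set(records$id,
                   apply(mat[, keep, drop = FALSE], 1L, paste, collapse = ""),
                   records$description)
  }
  as_alignment(out)
}
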