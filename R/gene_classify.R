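## A-versus-G homolog triage by canonical k-mer containment.
##
## The cyanobactin N-terminal (A) and C-terminal (G) protease genes are
## homologous over part of their length, so a recovered amplicon must be
## assigned to one family before phylogenetics. This replaces a BLASTn
## confirmation with a transparent classifier: each class keeps the union of
## canonical k-mers over its references, and a query is scored by the
## fraction of its own k-mers contained in each class profile.

## Canonical k-mer set of one ungapped sequence: each k-mer is represented by
## the lexicographic minimum of itself and its reverse complement, so
## profiles are strand-merged. K-mers containing ambiguity codes are skipped.
canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) return(character(0))
  rc <- vapply(kmers, revcomp_iupac, character(1), USE.NAMES = FALSE)
  unique(pmin(kmers, rc))
}

#' Build an A/G reference panel of canonical k-mer profiles
#'
#' @param a_refs,g_refs non-empty "seq_set"s of reference A-gene and G-gene
#'   sequences (each reference at least 200 bases).
#' @param k k-mer size (default 11).
#' @return list of class "reference_panel" with per-class canonical k-mer
#'   sets.
#' @export
build_panel <- function(a_refs, g_refs, k = 11L) {
  if (!is.data.frame(a_refs) || !nrow(a_refs) ||
      !is.data.frame(g_refs) || !nrow(g_refs)) {
    stop("both reference classes must be non-empty", call. = FALSE)
  }
  k <- as.integer(k)
  lens <- nchar(c(a_refs$residues, g_refs$residues))
  if (any(lens < 200L)) {
    stop("every reference must be at least 200 bases", call. = FALSE)
  }
  if (k > min(lens)) {
    stop("k (", k, ") exceeds the shortest reference length (", min(lens), ")",
         call. = FALSE)
  }
  profile <- function(refs) {
    unique(unlist(lapply(refs$residues, canonical_kmers, k = k)))
  }
  structure(
    list(k = k, a_kmers = profile(a_refs), g_kmers = profile(g_refs),
         n_a = nrow(a_refs), n_g = nrow(g_refs)),
    class = "reference_panel"
  )
}

#' Classify a query sequence as A-gene, G-gene, or ambiguous
#'
#' Scores are the containment of the query's canonical k-mer set in each
#' class profile, |Q intersect Ref| / |Q|, which is robust to the length
#' imbalance between a short amplicon and full-length references. The winner
#' takes the label unless the winning margin falls below `threshold`, in
#' which case the call is "ambiguous" (borderline hits are surfaced rather
#' than silently dropped).
#'
#' @param query single-row "seq_set" or ungapped sequence string.
#' @param panel a "reference_panel".
#' @param threshold ambiguity margin in [0, 1] (default 0.05).
#' @return data.frame: `query_id`, `label` ("A", "G" or "ambiguous"),
#'   `score_a`, `score_g`, `margin`.
#' @export
classify_seq <- function(query, panel, threshold = 0.05) {
  qid <- if (is.data.frame(query)) query$id[1] else "query"
  qseq <- if (is.data.frame(query)) query$residues[1] else toupper(query)
  if (grepl("-", qseq, fixed = TRUE)) stop("query must be ungapped", call. = FALSE)
  if (nchar(qseq) < panel$k) stop("query shorter than k", call. = FALSE)
  q <- canonical_kmers(qseq, panel$k)
  if (!length(q)) {
    score_a <- score_g <- 0
  } else {
    score_a <- mean(q %in% panel$a_kmers)
    score_g <- mean(q %in% panel$g_kmers)
  }
  margin <- abs(score_a - score_g)
  label <- if (margin < threshold) "ambiguous" else if (score_a > score_g) "A" else "G"
  data.frame(query_id = qid, label = label, score_a = score_a,
             score_g = score_g, margin = margin, stringsAsFactors = FALSE)
}

#' Classify every record of a sequence set
#'
#' @param queries a "seq_set".
#' @inheritParams classify_seq
#' @return data.frame with one [classify_seq()] row per query.
#' @export
classify_all <- function(queries, panel, threshold = 0.05) {
  out <- do.call(rbind, lapply(seq_len(nrow(queries)), function(i) {
    classify_seq(queries[i, , drop = FALSE], panel, threshold)
  }))
  rownames(out) <- NULL
  out
}

#' Scan genome-scale contigs for A/G-gene candidate regions
#'
#' Slides a window along each contig, classifies each window against the
#' panel, and merges overlapping same-label windows into maximal intervals.
#' Ambiguous windows are not reported. This is a desk-scale stand-in for a
#' biosynthetic-gene-cluster search service.
#'
#' @param contigs a "seq_set" of contigs.
#' @param panel a "reference_panel".
#' @param window window size in bases (default 900; must be >= 2k).
#' @param step step size in bases (default 300).
#' @param threshold ambiguity margin passed to [classify_seq()].
#' @param min_score windows whose winning score falls below this are treated
#'   as background and skipped (default 0.1).
#' @return data.frame of merged intervals: `contig`, `start`, `end` (0-based
#'   half-open), `label`, `score` (maximum window score in the interval),
#'   sorted by contig then start.
#' @export
scan_genome <- function(contigs, panel, window = 900L, step = 300L,
                        threshold = 0.05, min_score = 0.1) {
  window <- as.integer(window); step <- as.integer(step)
  if (window < 2L * panel$k) stop("window must be at least 2k", call. = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(contigs))) {
    cseq <- contigs$residues[ci]
    n <- nchar(cseq)
    starts <- unique(c(seq(0L, max(0L, n - window), by = step),
                       max(0L, n - window)))
    current <- NULL
    for (s in starts) {
      e <- min(s + window, n)
      res <- classify_seq(substr(cseq, s + 1L, e), panel, threshold)
      win_score <- max(res$score_a, res$score_g)
      lab <- res$label
      if (lab == "ambiguous" || win_score < min_score) lab <- NA_character_
      if (!is.na(lab) && !is.null(current) && current$label == lab &&
          s <= current$end) {
        current$end <- e
        current$score <- max(current$score, win_score)
      } else {
        if (!is.null(current)) rows[[length(rows) + 1L]] <- current
        current <- if (is.na(lab)) NULL else
          list(contig = contigs$id[ci], start = s, end = e, label = lab,
               score = win_score)
      }
    }
    if (!is.null(current)) rows[[length(rows) + 1L]] <- current
  }
  if (!length(rows)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
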