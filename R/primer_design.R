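## Degenerate primer design from a nucleotide multiple alignment.
##
## The design logic mirrors how "universal" screening primers for the
## cyanobactin N-terminal protease gene are derived: find alignment windows
## whose per-column consensus (the minimal IUPAC code covering every observed
## base) stays lowly degenerate, then pair upstream forward windows with
## reverse-complemented downstream windows at the desired product length.

#' Per-column conservation profile of an alignment
#'
#' For every alignment column, computes the minimal IUPAC code covering all
#' non-gap observed bases (ambiguity codes in the input expand to their base
#' sets first), the column degeneracy (base-set size, 1-4) and the gap
#' fraction.
#'
#' @param alignment a "seq_alignment".
#' @return data.frame with columns `column`, `consensus`, `degeneracy`,
#'   `gap_fraction`.
#' @export
conservation_profile <- function(alignment) {
  mat <- alignment_matrix(alignment)
  n <- nrow(mat)
  masks <- matrix(0L, n, ncol(mat))
  nongap <- mat != "-"
  masks[nongap] <- .iupac_mask_table[mat[nongap]]
  colmask <- as.integer(apply(masks, 2L, function(m) Reduce(bitwOr, m, 0L)))
  gap_fraction <- colMeans(!nongap)
  # all-gap columns are excluded by the alignment invariant, so colmask > 0
  data.frame(
    column = seq_len(ncol(mat)),
    consensus = mask_to_iupac(colmask),
    degeneracy = .popcount4[colmask],
    gap_fraction = gap_fraction,
    stringsAsFactors = FALSE
  )
}

#' Wallace-rule melting temperature range of a degenerate primer
#'
#' Tm = 2(A+T) + 4(G+C) degrees C per plain expansion; the range is taken over
#' the degenerate family. Families larger than `enumerate_limit` use exact
#' per-position minimum/maximum contributions instead of enumeration (the two
#' routes agree because positions contribute independently).
#'
#' @param primer_sequence ungapped IUPAC string or a "degenerate_primer".
#' @param enumerate_limit switch to per-position bounds above this degeneracy.
#' @return numeric `c(min, max)` in degrees Celsius.
#' @export
melting_temp <- function(primer_sequence, enumerate_limit = 1e4) {
  if (inherits(primer_sequence, "degenerate_primer")) {
    primer_sequence <- primer_sequence$sequence
  }
  m <- iupac_mask(primer_sequence)
  if (primer_degeneracy(primer_sequence) <= enumerate_limit) {
    tms <- vapply(iupac_expand(primer_sequence, enumerate_limit), function(s) {
      ch <- strsplit(s, "")[[1]]
      2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
    }, numeric(1))
    return(c(min(tms), max(tms)))
  }
  # per-position contribution: A/T weigh 2, G/C weigh 4
  lo <- hi <- 0
  for (mask in m) {
    has_at <- bitwAnd(mask, 9L) > 0L   # A=1, T=8
    has_gc <- bitwAnd(mask, 6L) > 0L   # C=2, G=4
    lo <- lo + if (has_at) 2 else 4
    hi <- hi + if (has_gc) 4 else 2
  }
  c(lo, hi)
}

#' Construct a degenerate primer record
#'
#' @param name token naming the primer.
#' @param sequence ungapped IUPAC string, length >= 10.
#' @param orientation "forward" or "reverse".
#' @return list of class "degenerate_primer" with fields name, sequence,
#'   orientation, degeneracy.
#' @export
degenerate_primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (grepl("-", sequence, fixed = TRUE)) stop("primer may not contain gaps", call. = FALSE)
  if (nchar(sequence) < 10L) stop("primer length must be >= 10", call. = FALSE)
  structure(
    list(name = name, sequence = sequence, orientation = orientation,
         degeneracy = primer_degeneracy(sequence)),
    class = "degenerate_primer"
  )
}

#' Construct a primer pair
#'
#' @param forward,reverse "degenerate_primer" objects with matching
#'   orientations.
#' @param nominal_product_length expected product size in bases, including
#'   both primer footprints; must be at least the summed primer lengths.
#' @param design_window optional list of two `c(start, end)` 0-based half-open
#'   alignment column ranges.
#' @return list of class "primer_pair".
#' @export
primer_pair <- function(forward, reverse, nominal_product_length,
                        design_window = NULL) {
  stopifnot(inherits(forward, "degenerate_primer"),
            inherits(reverse, "degenerate_primer"))
  if (forward$orientation != "forward" || reverse$orientation != "reverse") {
    stop("primer orientations must be forward/reverse", call. = FALSE)
  }
  if (nominal_product_length < nchar(forward$sequence) + nchar(reverse$sequence)) {
    stop("nominal product length shorter than the primer footprints", call. = FALSE)
  }
  structure(
    list(forward = forward, reverse = reverse,
         nominal_product_length = as.integer(nominal_product_length),
         design_window = design_window),
    class = "primer_pair"
  )
}

#' The published cyanobactin A-gene screening primer pair
#'
#' CBT_AF (TTVGGYTAYGAYTTYGG, degeneracy 48) and CBT_AR
#' (AGACCARGAACGRACTTC, degeneracy 4), which amplify a nominal 804 bp region
#' of the A-gene.
#'
#' @return a "primer_pair".
#' @export
cbt_primer_pair <- function() {
  primer_pair(
    degenerate_primer("CBT_AF", "TTVGGYTAYGAYTTYGG", "forward"),
    degenerate_primer("CBT_AR", "AGACCARGAACGRACTTC", "reverse"),
    nominal_product_length = 804L
  )
}

#' Design ranked degenerate primer pairs from an alignment
#'
#' Scans all alignment windows in the allowed length range, keeps windows
#' whose consensus degeneracy, gap exposure and Wallace Tm satisfy the
#' constraints, and pairs upstream forward windows with reverse-complemented
#' downstream windows whose span falls in the product length range. Pairs are
#' ranked by (total degeneracy, mean gap fraction, 3'-end degeneracy)
#' ascending, ties broken by leftmost forward start.
#'
#' The nominal product length is measured on the consensus: alignment columns
#' whose gap fraction exceeds 0.5 are dropped before the span is counted, so
#' one nominal figure is reported even though real amplicons vary.
#'
#' @param alignment a "seq_alignment" (designs on fewer than 4 sequences are
#'   flagged with a warning, not refused).
#' @param primer_length `c(min, max)` window lengths (default c(17, 22)).
#' @param max_degeneracy maximum degeneracy per primer (default 96).
#' @param max_gap_fraction columns gappier than this are disqualified
#'   (default 0.10).
#' @param product_length `c(min, max)` nominal product lengths.
#' @param tm_window `c(min, max)` acceptable Wallace Tm bounds (applied to the
#'   primer's Tm range; default c(40, 70)).
#' @param max_end_degeneracy maximum degeneracy allowed at each of the 3
#'   3'-terminal positions (default 2).
#' @param max_pairs return at most this many top-ranked pairs (default 20).
#' @return data.frame of ranked pairs: sequences, degeneracies, Tm ranges,
#'   0-based half-open window coordinates and nominal product length; zero
#'   rows when no window qualifies.
#' @export
design_primer_pairs <- function(alignment,
                                primer_length = c(17L, 22L),
                                max_degeneracy = 96,
                                max_gap_fraction = 0.10,
                                product_length = c(700L, 900L),
                                tm_window = c(40, 70),
                                max_end_degeneracy = 2L,
                                max_pairs = 20L) {
  if (nrow(alignment) < 4L) {
    warning("designing on fewer than 4 sequences; consensus may over-fit")
  }
  prof <- conservation_profile(alignment)
  ncol_aln <- nrow(prof)
  # consensus coordinate map: columns retained for nominal length measurement
  kept <- prof$gap_fraction <= 0.5
  cum_kept <- cumsum(kept)

  windows <- list()
  for (len in seq(primer_length[1], primer_length[2])) {
    if (len > ncol_aln) next
    for (start in seq_len(ncol_aln - len + 1L)) {
      cols <- start:(start + len - 1L)
      if (any(prof$gap_fraction[cols] > max_gap_fraction)) next
      deg <- prod(prof$degeneracy[cols])
      if (deg > max_degeneracy) next
      windows[[length(windows) + 1L]] <- list(
        start = start - 1L, end = start + len - 1L,  # 0-based half-open
        cols = cols, degeneracy = deg,
        gap_mean = mean(prof$gap_fraction[cols]),
        consensus = paste(prof$consensus[cols], collapse = "")
      )
    }
  }
  empty <- data.frame(
    forward_name = character(0), forward_seq = character(0),
    forward_degeneracy = numeric(0), forward_tm_min = numeric(0),
    forward_tm_max = numeric(0), forward_start = integer(0),
    forward_end = integer(0), reverse_name = character(0),
    reverse_seq = character(0), reverse_degeneracy = numeric(0),
    reverse_tm_min = numeric(0), reverse_tm_max = numeric(0),
    reverse_start = integer(0), reverse_end = integer(0),
    total_degeneracy = numeric(0), mean_gap_fraction = numeric(0),
    end_degeneracy = numeric(0), nominal_product_length = integer(0),
    stringsAsFactors = FALSE
  )
  if (!length(windows)) return(empty)

  tm_ok <- function(seqs) {
    tm <- melting_temp(seqs)
    tm[1] >= tm_window[1] && tm[2] <= tm_window[2]
  }
  end_deg <- function(seqs) {
    # degeneracy across the three 3'-terminal positions
    m <- iupac_mask(seqs)
    tail_deg <- .popcount4[utils::tail(m, 3L)]
    if (any(tail_deg > max_end_degeneracy)) Inf else prod(tail_deg)
  }

  fwd <- list(); rev_ <- list()
  for (w in windows) {
    fseq <- w$consensus
    if (tm_ok(fseq) && is.finite(end_deg(fseq))) {
      fwd[[length(fwd) + 1L]] <- c(w, list(seq = fseq, e3 = end_deg(fseq)))
    }
    rseq <- revcomp_iupac(w$consensus)
    if (tm_ok(rseq) && is.finite(end_deg(rseq))) {
      rev_[[length(rev_) + 1L]] <- c(w, list(seq = rseq, e3 = end_deg(rseq)))
    }
  }
  if (!length(fwd) || !length(rev_)) return(empty)

  rows <- list()
  for (f in fwd) {
    for (r in rev_) {
      if (r$start < f$end) next  # reverse window strictly downstream
      # nominal length on the consensus: majority-gap columns dropped
      span_cols <- (f$start + 1L):r$end
      nominal <- cum_kept[r$end] - (if (f$start > 0L) cum_kept[f$start] else 0L)
      if (nominal < product_length[1] || nominal > product_length[2]) next
      ftm <- melting_temp(f$seq); rtm <- melting_temp(r$seq)
      rows[[length(rows) + 1L]] <- data.frame(
        forward_name = sprintf("F_%d_%d", f$start, f$end),
        forward_seq = f$seq, forward_degeneracy = f$degeneracy,
        forward_tm_min = ftm[1], forward_tm_max = ftm[2],
        forward_start = f$start, forward_end = f$end,
        reverse_name = sprintf("R_%d_%d", r$start, r$end),
        reverse_seq = r$seq, reverse_degeneracy = r$degeneracy,
        reverse_tm_min = rtm[1], reverse_tm_max = rtm[2],
        reverse_start = r$start, reverse_end = r$end,
        total_degeneracy = f$degeneracy * r$degeneracy,
        mean_gap_fraction = (f$gap_mean + r$gap_mean) / 2,
        end_degeneracy = f$e3 * r$e3,
        nominal_product_length = nominal,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  ord <- order(out$total_degeneracy, out$mean_gap_fraction,
               out$end_degeneracy, out$forward_start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_pairs)
}

#' Convert one row of a design table to a primer_pair object
#' @param row single-row data.frame from [design_primer_pairs()].
#' @return a "primer_pair".
#' @export
pair_from_design <- function(row) {
  primer_pair(
    degenerate_primer(row$forward_name, row$forward_seq, "forward"),
    degenerate_primer(row$reverse_name, row$reverse_seq, "reverse"),
    nominal_product_length = row$nominal_product_length,
    design_window = list(c(row$forward_start, row$forward_end),
                         c(row$reverse_start, row$reverse_end))
  )
}
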