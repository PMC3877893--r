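## In-silico PCR: locate degenerate primer binding sites under IUPAC
## semantics and excise predicted products. The dry-lab analogue of the
## screening reaction: a template with no compatible site pair is simply
## "PCR-negative" and yields an empty hit list.

## Vectorized site scan of one primer (as bitmasks) against one strand.
## Returns 0-based starts and mismatch counts for all windows with
## mismatches <= max_mismatch.
.scan_strand <- function(template_mask, primer_mask, max_mismatch) {
  n <- length(template_mask); m <- length(primer_mask)
  if (n < m) return(data.frame(start = integer(0), mismatches = integer(0)))
  n_win <- n - m + 1L
  mism <- integer(n_win)
  for (j in seq_len(m)) {
    ok <- bitwAnd(template_mask[j:(j + n_win - 1L)], primer_mask[j]) > 0L
    mism <- mism + !ok
  }
  keep <- which(mism <= max_mismatch)
  data.frame(start = keep - 1L, mismatches = mism[keep])
}

#' Find degenerate primer binding sites on both strands of a template
#'
#' A position mismatches when the primer code's base set and the template
#' code's base set do not intersect ([iupac_match()]); degenerate positions
#' therefore already tolerate their encoded variants at zero mismatches.
#' Reverse-strand hits are reported in forward-strand coordinates (0-based,
#' half-open over the primer footprint).
#'
#' @param primer a "degenerate_primer" or an IUPAC string.
#' @param template a single-row "seq_set" or an ungapped IUPAC string.
#' @param max_mismatch maximum tolerated mismatches (default 0).
#' @return data.frame with columns `start`, `strand` ("+"/"-") and
#'   `mismatches`, sorted by start; zero rows when the template is shorter
#'   than the primer or no site qualifies.
#' @export
find_sites <- function(primer, template, max_mismatch = 0L) {
  pseq <- if (inherits(primer, "degenerate_primer")) primer$sequence else toupper(primer)
  tseq <- if (is.data.frame(template)) template$residues[1] else toupper(template)
  if (grepl("-", tseq, fixed = TRUE)) stop("template must be ungapped", call. = FALSE)
  tm <- iupac_mask(tseq)
  pm <- iupac_mask(pseq)
  pm_rc <- iupac_mask(revcomp_iupac(pseq))
  fwd <- .scan_strand(tm, pm, max_mismatch)
  rev_ <- .scan_strand(tm, pm_rc, max_mismatch)
  out <- rbind(
    if (nrow(fwd)) data.frame(start = fwd$start, strand = "+",
                              mismatches = fwd$mismatches) else NULL,
    if (nrow(rev_)) data.frame(start = rev_$start, strand = "-",
                               mismatches = rev_$mismatches) else NULL
  )
  if (is.null(out)) {
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict PCR products of a primer pair on one template
#'
#' Emulates PCR on double-stranded DNA: a product forms between any
#' plus-strand primer site (a primer extending rightwards) and any
#' downstream minus-strand site (a primer annealed to the plus strand,
#' extending leftwards). With the usual geometry this pairs the forward
#' primer's plus-strand site with the reverse primer's minus-strand site, but
#' self-pairings (a primer with its own downstream reverse-complement site)
#' are reported like any other pair and can be filtered downstream. Products
#' are kept inside the length range and excised verbatim from the template.
#'
#' @param pair a "primer_pair".
#' @param template single-row "seq_set" or ungapped IUPAC string.
#' @param max_mismatch maximum mismatches per primer site (default 0).
#' @param product_length_range `c(min, max)` product footprint in bases
#'   (default `c(50, 5000)`).
#' @return data.frame of amplicon hits: `template_id`, `start`, `end`
#'   (0-based half-open footprint including both primer sites),
#'   `product_length`, `primer_left`, `primer_right`, `mismatches_fwd`,
#'   `mismatches_rev` (left and right site mismatches), `product` (sequence
#'   string). Empty (zero rows) means PCR-negative.
#' @export
pcr_products <- function(pair, template, max_mismatch = 0L,
                         product_length_range = c(50L, 5000L)) {
  tid <- if (is.data.frame(template)) template$id[1] else "template"
  tseq <- if (is.data.frame(template)) template$residues[1] else toupper(template)
  primers <- list(pair$forward, pair$reverse)
  plus <- list(); minus <- list()
  for (p in primers) {
    s <- find_sites(p, tseq, max_mismatch)
    s$name <- rep(p$name, nrow(s))
    s$len <- rep(nchar(p$sequence), nrow(s))
    plus[[length(plus) + 1L]] <- s[s$strand == "+", , drop = FALSE]
    minus[[length(minus) + 1L]] <- s[s$strand == "-", , drop = FALSE]
  }
  plus <- do.call(rbind, plus); minus <- do.call(rbind, minus)
  hits <- list()
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      start <- plus$start[i]
      if (minus$start[j] < start + plus$len[i]) next  # right site downstream
      end <- minus$start[j] + minus$len[j]  # half-open footprint end
      len <- end - start
      if (len < product_length_range[1] || len > product_length_range[2]) next
      hits[[length(hits) + 1L]] <- data.frame(
        template_id = tid, start = start, end = end, product_length = len,
        primer_left = plus$name[i], primer_right = minus$name[j],
        mismatches_fwd = plus$mismatches[i],
        mismatches_rev = minus$mismatches[j],
        product = substr(tseq, start + 1L, end),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), product_length = integer(0),
                      primer_left = character(0), primer_right = character(0),
                      mismatches_fwd = integer(0), mismatches_rev = integer(0),
                      product = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$end, out$primer_left, out$primer_right), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the in-silico PCR screen over a set of templates
#'
#' The dry-lab analogue of a screening table: each template is scored
#' positive (>= 1 product) or negative.
#'
#' @param pair a "primer_pair".
#' @param templates a "seq_set" of templates.
#' @inheritParams pcr_products
#' @return list with `hits` (rbind of all [pcr_products()] rows) and `screen`
#'   (data.frame: template_id, n_products, product_lengths, positive).
#' @export
pcr_screen <- function(pair, templates, max_mismatch = 0L,
                       product_length_range = c(50L, 5000L)) {
  all_hits <- list(); screen <- list()
  for (i in seq_len(nrow(templates))) {
    h <- pcr_products(pair, templates[i, , drop = FALSE], max_mismatch,
                      product_length_range)
    all_hits[[i]] <- h
    screen[[i]] <- data.frame(
      template_id = templates$id[i],
      n_products = nrow(h),
      product_lengths = paste(h$product_length, collapse = ","),
      positive = nrow(h) > 0L,
      stringsAsFactors = FALSE
    )
  }
  list(hits = do.call(rbind, all_hits), screen = do.call(rbind, screen))
}
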