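## FASTA input/output and the sequence containers used across the package.
##
## A sequence set is a plain data.frame with columns id, description and
## residues (class "seq_set"); an alignment additionally carries class
## "seq_alignment" and an attribute "columns". Residues are upper-case IUPAC
## nucleotide codes; '-' is the only gap character and may appear only in
## alignments read from gapped FASTA or produced by the aligner.

.valid_residue_chars <- c(names(IUPAC_BASES), "-")

#' Construct a sequence set
#'
#' @param id character vector of unique, whitespace-free identifiers.
#' @param residues character vector of IUPAC nucleotide strings (upper-cased
#'   and U-to-T normalized here).
#' @param description optional free-text descriptions (default "").
#' @return a data.frame of class "seq_set" with columns id, description,
#'   residues.
#' @export
seq_set <- function(id, residues, description = "") {
  if (length(id) != length(residues)) {
    stop("id and residues must have equal length", call. = FALSE)
  }
  description <- rep_len(as.character(description), length(id))
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  residues <- gsub("U", "T", residues, fixed = TRUE)
  if (any(!nzchar(id)) || any(grepl("[[:space:]]", id))) {
    stop("sequence ids must be non-empty and contain no whitespace",
         call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(residues))) {
    stop("empty residue string for id(s): ",
         paste(id[!nzchar(residues)], collapse = ", "), call. = FALSE)
  }
  bad <- vapply(strsplit(residues, ""), function(ch) {
    w <- which(!ch %in% .valid_residue_chars)
    if (length(w)) ch[w[1]] else NA_character_
  }, character(1))
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    stop("illegal residue character '", bad[i], "' in sequence '", id[i], "'",
         call. = FALSE)
  }
  out <- data.frame(id = id, description = description, residues = residues,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Read a nucleotide FASTA file
#'
#' Parses a multi-record FASTA file with strict validation: lower-case
#' residues are upper-cased, U is mapped to T, and any malformed header,
#' empty sequence, illegal character or duplicate identifier raises an error
#' naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return a "seq_set" data.frame in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1],
         ": expected '>' header", call. = FALSE)
  }
  ids <- character(0); descs <- character(0); seqs <- character(0)
  buf <- character(0)
  flush_record <- function(line_no) {
    if (!length(ids)) return(invisible())
    if (!length(buf) || !nzchar(paste(buf, collapse = ""))) {
      stop("FASTA parse error near line ", line_no, ": record '",
           ids[length(ids)], "' has no sequence", call. = FALSE)
    }
    seqs[length(ids)] <<- paste(buf, collapse = "")
    buf <<- character(0)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush_record(i)
      header <- sub("^>", "", line)
      id <- sub("[[:space:]].*$", "", header)
      if (!nzchar(id)) {
        stop("FASTA parse error at line ", i, ": empty header", call. = FALSE)
      }
      desc <- trimws(sub("^[^[:space:]]*[[:space:]]*", "", header))
      if (id %in% ids) {
        stop("FASTA parse error at line ", i, ": duplicate id '", id, "'",
             call. = FALSE)
      }
      ids <- c(ids, id); descs <- c(descs, desc); seqs <- c(seqs, NA_character_)
    } else {
      chars <- strsplit(toupper(line), "")[[1]]
      chars[chars == "U"] <- "T"
      bad <- which(!chars %in% .valid_residue_chars)
      if (length(bad)) {
        stop("FASTA parse error at line ", i, ": illegal character '",
             chars[bad[1]], "'", call. = FALSE)
      }
      buf <- c(buf, paste(chars, collapse = ""))
    }
  }
  flush_record(length(lines) + 1L)
  seq_set(ids, seqs, descs)
}

#' Write a sequence set to FASTA
#'
#' Output is deterministic for a fixed input and wrap width.
#'
#' @param records a "seq_set" (or data.frame with id/description/residues).
#' @param path output path.
#' @param wrap positive line width for the sequence body (default 70).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, wrap = 70L) {
  if (!nrow(records)) stop("refusing to write an empty record set", call. = FALSE)
  if (!is.numeric(wrap) || wrap < 1) stop("wrap must be positive", call. = FALSE)
  wrap <- as.integer(wrap)
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(records$description[i])) {
      paste0(">", records$id[i], " ", records$description[i])
    } else {
      paste0(">", records$id[i])
    }
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = wrap)
    body <- substring(s, starts, pmin(starts + wrap - 1L, nchar(s)))
    writeLines(c(header, body), con, sep = "\n")
  }
  invisible(path)
}

#' Interpret a sequence set as a multiple alignment
#'
#' Verifies that all records share one length and that no column is entirely
#' gaps, then attaches the alignment class and column count.
#'
#' @param records a "seq_set" with at least 2 records.
#' @return the records with class "seq_alignment" and attribute "columns".
#' @export
as_alignment <- function(records) {
  if (nrow(records) < 2L) stop("an alignment needs at least 2 records", call. = FALSE)
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1L) {
    off <- records$id[lens != lens[1]]
    stop("ragged alignment; offending id(s): ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  mat <- alignment_matrix(records)
  allgap <- which(colSums(mat != "-") == 0L)
  if (length(allgap)) {
    stop("all-gap alignment column(s): ", paste(allgap, collapse = ", "),
         call. = FALSE)
  }
  attr(records, "columns") <- lens[1]
  class(records) <- unique(c("seq_alignment", class(records)))
  records
}

#' Alignment as a character matrix (rows = records, columns = positions)
#' @param records a seq_set / seq_alignment.
#' @return character matrix with rownames = ids.
#' @keywords internal
alignment_matrix <- function(records) {
  mat <- do.call(rbind, strsplit(records$residues, ""))
  rownames(mat) <- records$id
  mat
}

#' Strip gaps from a sequence string
#' @keywords internal
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Write a data.frame as a TSV report with header row
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv_report <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
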