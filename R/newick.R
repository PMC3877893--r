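## Newick serialization. Internal-node labels carry bootstrap supports;
## branch lengths survive a round trip to 6 decimal places.

#' Parse a Newick string into a tree
#'
#' @param text a single Newick string (terminating ';' required).
#' @return a "phylo" tree; internal-node labels (supports) are preserved.
#' @export
read_newick <- function(text) {
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error at offset ", i,
             ": unbalanced ')'", call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error at offset ", length(chars),
         ": ", depth, " unclosed '('", call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop("Newick parse error at offset ", nchar(text),
         ": missing terminating ';'", call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL)
  if (is.null(tr)) stop("Newick parse error: unreadable tree", call. = FALSE)
  tr
}

#' Serialize a tree to a Newick string
#'
#' @param tree a "phylo" tree; `node.label` (supports) are written as
#'   internal-node labels, branch lengths with up to 6 decimals.
#' @return Newick string ending in ';'.
#' @export
write_newick <- function(tree) {
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, digits = 6)
}

#' Read a Newick file (first tree)
#' @param path file containing one Newick tree.
#' @return a "phylo".
#' @export
read_newick_file <- function(path) {
  read_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a tree to a Newick file
#' @param tree a "phylo".
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_newick_file <- function(tree, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(write_newick(tree), con, sep = "\n")
  invisible(path)
}
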