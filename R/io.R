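#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] accepting wrapped or
#' unwrapped records. Record descriptions are truncated at the first
#' whitespace to form the names.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (empty vector for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first)) return(stats::setNames(character(0), character(0)))
  if (!startsWith(lines[first], ">")) {
    stop("Malformed FASTA at line ", first, ": expected '>' header in ", path)
  }
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#'
#' Emits unwrapped records (one sequence line per record) so output files are
#' byte-stable across platforms.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) && is.null(names(seqs))) {
    stop("sequences must be named")
  }
  con <- file(path, "wb")  # binary mode: fixed "\n" line endings
  on.exit(close(con))
  if (length(seqs)) {
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)),
               con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Write a data frame as TSV
#'
#' Header row, tab separators, no quoting, no row names; numeric columns are
#' rendered with full precision for reproducible byte-identical reruns.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_tsv_file()]
#' @param path Path to the file.
#' @return Data frame.
#' @export
read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a phylogenetic tree in Newick format
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a square labelled matrix as TSV (first column = row labels)
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param label Name for the label column.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, label = "sample") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(label, colnames(m))
  write_tsv_file(df, path)
}
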