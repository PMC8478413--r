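#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings that return/accept plain named character
#' vectors. `read_fasta()` accepts gapped (aligned) FASTA; gaps are kept.
#' `write_fasta()` wraps lines at 60 columns.
#'
#' @param file Path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::BStringSet(vapply(seqs, as.character, ""))
  names(x) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, file, width = 60L)
  invisible(file)
}

#' Read spacers from FASTA or plain text
#'
#' Plain-text input holds one sequence per line (optionally `name<TAB>seq`).
#'
#' @param file Path to a FASTA (`>`-headed) or plain-text spacer file.
#' @return List of [spacer()] objects.
#' @export
read_spacers <- function(file) {
  first <- readLines(file, n = 1L, warn = FALSE)
  if (length(first) == 0L) abort_input(sprintf("'%s' is empty", file))
  if (startsWith(first, ">")) {
    seqs <- read_fasta(file)
  } else {
    lines <- trimws(readLines(file, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) abort_input(sprintf("'%s' is empty", file))
    parts <- strsplit(lines, "[\t,]")
    named <- lengths(parts) >= 2L
    seqs <- ifelse(named, vapply(parts, function(p) p[[2L]], ""), lines)
    names(seqs) <- ifelse(named, vapply(parts, function(p) p[[1L]], ""),
                          paste0("spacer", seq_along(lines)))
  }
  if (anyDuplicated(names(seqs))) abort_input("duplicate spacer names in input")
  unname(mapply(spacer, names(seqs), seqs, SIMPLIFY = FALSE))
}

#' Read a name/response table
#'
#' Two-column CSV (`name`, `response`), e.g. percent GFP-positive cells per
#' array.
#'
#' @param file CSV path.
#' @return data.frame with columns `name`, `response`.
#' @export
read_responses <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("name", "response") %in% names(tab))) {
    abort_input("responses CSV must have columns 'name' and 'response'")
  }
  tab[, c("name", "response")]
}

#' Read a pre-computed alignment as an aligned set
#'
#' The alignment must be produced externally (e.g. with T-Coffee or MAFFT);
#' this package consumes, never produces, multiple-sequence alignments.
#'
#' @param file Aligned (gapped) FASTA path.
#' @param anchor `"5prime"` or `"3prime"`; recorded on the object.
#' @return An `aligned_set` (see [aligned_set()]).
#' @export
read_aligned_fasta <- function(file, anchor = "5prime") {
  aligned_set(read_fasta(file), anchor = anchor)
}
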