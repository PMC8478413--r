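#' Nucleotide sequence primitives
#'
#' All sequences in the package are stored 5'-to-3' as uppercase character
#' strings carrying an alphabet flag (`"DNA"` or `"RNA"`). DNA is the
#' canonical storage alphabet; RNA views are produced on demand for folding.
#' Coordinates throughout the package are 0-based, half-open, top strand.
#'
#' @param raw Character scalar with the raw sequence (case and whitespace
#'   are ignored).
#' @param kind `"DNA"` or `"RNA"`.
#' @return `nuc_seq()` returns a `nuc_seq` object: a character scalar with
#'   attribute `kind`.
#' @examples
#' nuc_seq("aatt")
#' nuc_seq("AAUU", "DNA")  # U is converted to T under the DNA alphabet
#' @export
nuc_seq <- function(raw, kind = c("DNA", "RNA")) {
  kind <- match.arg(kind)
  if (length(raw) != 1L || is.na(raw)) {
    abort_input("`raw` must be a single, non-NA character string")
  }
  s <- toupper(gsub("[[:space:]]+", "", raw))
  if (!nzchar(s)) abort_input("sequence must be non-empty")
  # cross-alphabet letters are converted, not rejected: T<->U per `kind`
  s <- if (kind == "DNA") chartr("U", "T", s) else chartr("T", "U", s)
  alpha <- if (kind == "DNA") IUPAC_DNA else IUPAC_RNA
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% alpha)
  if (length(bad)) {
    abort_input(sprintf("invalid %s character '%s' at position %d",
                        kind, ch[bad[1L]], bad[1L]))
  }
  structure(s, kind = kind, class = "nuc_seq")
}

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")
IUPAC_RNA <- chartr("T", "U", IUPAC_DNA)

#' @rdname nuc_seq
#' @export
normalize_sequence <- function(raw, kind = c("DNA", "RNA")) {
  nuc_seq(raw, kind)
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq %s, %d nt> %s\n", attr(x, "kind"), nchar(x),
              if (nchar(x) > 60) paste0(substr(x, 1, 57), "...") else x))
  invisible(x)
}

seq_kind <- function(x) attr(x, "kind") %||% "DNA"

as_nuc <- function(x, kind = "DNA") {
  if (inherits(x, "nuc_seq")) x else nuc_seq(as.character(x), kind)
}

#' Convert between DNA and RNA views
#'
#' @param seq A `nuc_seq` (or plain character) sequence.
#' @return A `nuc_seq` in the requested alphabet.
#' @export
as_rna <- function(seq) nuc_seq(chartr("T", "U", as.character(as_nuc(seq))), "RNA")

#' @rdname as_rna
#' @export
as_dna <- function(seq) nuc_seq(chartr("U", "T", as.character(seq)), "DNA")

#' GC fraction of a sequence
#'
#' Fraction of residues that are G or C. The two-state ambiguity codes are
#' resolved where unambiguous with respect to GC: `S` (G/C) counts as 1 and
#' `W` (A/T) as 0. Other ambiguity codes are rejected unless
#' `permissive = TRUE`, in which case they count as 0.5.
#'
#' @param seq Sequence (`nuc_seq` or character scalar).
#' @param permissive Allow ambiguity codes beyond S/W, counted as 0.5.
#' @return Fraction in \[0, 1\].
#' @examples
#' gc_fraction("ATGC")  # 0.5
#' @export
gc_fraction <- function(seq, permissive = FALSE) {
  s <- as.character(as_nuc(seq))
  if (!nzchar(s)) abort_input("sequence must be non-empty")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  other <- !ch %in% c("A", "C", "G", "T", "U", "S", "W")
  if (any(other) && !permissive) {
    abort_input(sprintf(
      "ambiguity code '%s' at position %d; set permissive = TRUE to count it as 0.5",
      ch[which(other)[1L]], which(other)[1L]))
  }
  sum((ch %in% c("G", "C", "S")) + 0.5 * other) / length(ch)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq DNA sequence (`nuc_seq` or character).
#' @return The Watson-Crick reverse complement as a `nuc_seq`.
#' @export
reverse_complement <- function(seq) {
  x <- as_nuc(seq)
  if (seq_kind(x) != "DNA") abort_input("reverse_complement() requires DNA input")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(as.character(x))))
  nuc_seq(rc, "DNA")
}

#' GC fraction of the 3'-terminal k residues
#'
#' GC content of the last few bases of a spacer, next to the Cas12a cleavage
#' site, is the single most predictive spacer feature for downstream gRNA
#' performance; `k = 3` is the default window.
#'
#' @param seq Sequence.
#' @param k Number of 3'-terminal residues.
#' @return Fraction in \[0, 1\].
#' @export
terminal_gc <- function(seq, k = 3L) {
  s <- as.character(as_nuc(seq))
  n <- nchar(s)
  if (k < 1L || k > n) abort_input("`k` must be in 1..length(seq)")
  gc_fraction(substr(s, n - k + 1L, n))
}
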