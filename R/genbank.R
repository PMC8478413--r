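#' Write an array design as a GenBank flat file
#'
#' Emits a minimal GenBank record (LOCUS / FEATURES / ORIGIN) with one
#' `misc_feature` per annotated feature, labelled `type:name`. Intervals
#' are converted to GenBank's 1-based inclusive convention. The companion
#' [read_genbank()] parses files in this subset of the format, so designs
#' round-trip exactly.
#'
#' @param design An `array_design`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_genbank <- function(design, file) {
  s <- as.character(design$sequence)
  L <- nchar(s)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN %s",
                     gsub("\\s", "_", design$name), L,
                     toupper(format(Sys.Date(), "%d-%b-%Y"))), con)
  writeLines(sprintf("DEFINITION  %s.", design$name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  f <- design$features
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("     misc_feature    %d..%d", f$start[i] + 1L, f$end[i]), con)
    writeLines(sprintf("                     /label=\"%s:%s\"", f$type[i], f$name[i]), con)
  }
  writeLines("ORIGIN", con)
  low <- tolower(s)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substr(low, off, min(off + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(file)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' @param file Path.
#' @return List with `sequence` (`nuc_seq`) and `features` (data.frame
#'   with 0-based half-open `start`/`end`, `type`, `name`).
#' @export
read_genbank <- function(file) {
  lines <- readLines(file, warn = FALSE)
  ostart <- which(lines == "ORIGIN")
  if (length(ostart) != 1L) abort_input("no ORIGIN section found")
  seqlines <- lines[(ostart + 1L):length(lines)]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  feats <- list()
  i <- 1L
  while (i <= ostart) {
    m <- regmatches(lines[i],
                    regexec("^     misc_feature    (\\d+)\\.\\.(\\d+)", lines[i]))[[1L]]
    if (length(m)) {
      lab <- regmatches(lines[i + 1L],
                        regexec("/label=\"([^:]+):(.*)\"", lines[i + 1L]))[[1L]]
      feats[[length(feats) + 1L]] <- data.frame(
        type = lab[2L], start = as.integer(m[2L]) - 1L,
        end = as.integer(m[3L]), name = lab[3L], stringsAsFactors = FALSE)
      i <- i + 2L
    } else i <- i + 1L
  }
  list(sequence = nuc_seq(seq),
       features = if (length(feats)) do.call(rbind, feats) else NULL)
}
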