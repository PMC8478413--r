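#!/usr/bin/env Rscript
# Optional validation against curated natural CRISPR sequence collections
# (distributed as supplementary species records, not bundled with the
# package). Given FASTA files of natural Cas12a spacers and/or separator
# sequences, recomputes the summary statistics the package's profiling
# operations are designed for.
#
#   Rscript scripts/validate_natural_sets.R --spacers <spacers.fa> \
#       [--separators <separators.fa>] [--aligned-separators <aln.fa>]

suppressPackageStartupMessages(library(cas12array))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag) {
  i <- which(args == flag)
  if (length(i) && i[1] < length(args)) args[i[1] + 1] else NULL
}

sp_fa <- get_arg("--spacers")
sep_fa <- get_arg("--separators")
aln_fa <- get_arg("--aligned-separators")
if (is.null(sp_fa) && is.null(sep_fa) && is.null(aln_fa)) {
  stop("supply --spacers and/or --separators / --aligned-separators FASTA files",
       call. = FALSE)
}

if (!is.null(sp_fa)) {
  seqs <- read_fasta(sp_fa)
  s <- spacer_set_summary(seqs)
  cat(sprintf("natural spacers: n = %d, mean GC = %.0f%%, range %.0f-%.0f%%\n",
              s$count, 100 * s$mean_gc, 100 * s$min_gc, 100 * s$max_gc))
  aln <- anchor_3prime(seqs, target_length = 25)
  prof <- column_gc_profile(aln)
  cat("3'-anchored column GC profile (start,width,gc):\n")
  print(prof, row.names = FALSE)
}

if (!is.null(sep_fa)) {
  seps <- read_fasta(sep_fa)
  cat(sprintf("separator sequences: n = %d, mean GC = %.0f%%\n",
              length(seps), 100 * mean(vapply(seps, gc_fraction, 0))))
}

if (!is.null(aln_fa)) {
  aln <- read_aligned_fasta(aln_fa)
  cat(sprintf("aligned separators: n = %d rows\n", length(aln$rows)))
  cat("consensus:", iupac_consensus(aln), "\n")
}
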