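#' Spacer objects
#'
#' A spacer is a candidate guide sequence annotated with the two GC metrics
#' that drive array performance: whole-spacer GC fraction and the GC
#' fraction of the 3'-terminal three residues (next to the Cas12a cleavage
#' site).
#'
#' @param name Unique spacer name.
#' @param seq DNA sequence (`nuc_seq` or character).
#' @return A `spacer` object (list with `name`, `seq`, `gc_fraction`,
#'   `terminal_gc_k3`).
#' @export
spacer <- function(name, seq) {
  s <- as_nuc(seq)
  if (seq_kind(s) != "DNA") abort_input("spacers are stored as DNA")
  structure(
    list(name = as.character(name), seq = s,
         gc_fraction = gc_fraction(s),
         terminal_gc_k3 = terminal_gc(s, min(3L, nchar(s)))),
    class = "spacer")
}

#' @export
print.spacer <- function(x, ...) {
  cat(sprintf("<spacer %s> %s  GC=%.2f  GC(last3)=%.2f\n",
              x$name, as.character(x$seq), x$gc_fraction, x$terminal_gc_k3))
  invisible(x)
}

#' Generate a random spacer with an exact GC count
#'
#' The spacer carries exactly `round(gc_target * length)` G/C residues
#' (round half up), with positions and base identities drawn uniformly from
#' a seeded generator, so the realized GC fraction is exactly the nearest
#' achievable value and libraries built from these spacers have exactly
#' reproducible GC histograms.
#'
#' @param length Spacer length in nt (default 20, the benchmark length).
#' @param gc_target Target GC fraction; clamped to \[0, 1\].
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param name Optional name (default derived from parameters).
#' @return A [spacer()].
#' @export
generate_spacer <- function(length = 20L, gc_target = 0.5, seed = 1L,
                            name = NULL) {
  length <- as.integer(length)
  if (length < 1L) abort_input("`length` must be >= 1")
  gc_target <- min(1, max(0, gc_target))
  n_gc <- as.integer(round_half_up(gc_target * length))
  res <- with_seed(seed, {
    pos <- sample.int(length, n_gc)
    ch <- rep(NA_character_, length)
    ch[pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
    ch[is.na(ch)] <- sample(c("A", "T"), length - n_gc, replace = TRUE)
    paste(ch, collapse = "")
  })
  spacer(name %||% sprintf("sp_L%d_gc%02d_s%d", length,
                           round_half_up(100 * gc_target), seed),
         res)
}

#' Generate the 51-spacer GC benchmark library
#'
#' Reproduces the recipe of the benchmark dummy-spacer library used to
#' probe the GC sensitivity of two-gRNA Cas12a arrays: five random 20-nt
#' spacers for each 10%-GC decile from 10% to 90% (45 spacers), plus six
#' pilot spacers spanning 30--80% GC, one per decile. Sequences are random
#' but the per-decile GC histogram is exact by construction.
#'
#' @param seed Integer seed; two different seeds give different sequences
#'   with the identical GC histogram.
#' @return A `spacer_library`: list with `entries` (list of [spacer()]),
#'   `recipe`, and `seed`.
#' @export
generate_benchmark_library <- function(seed = 1L) {
  deciles <- seq(0.1, 0.9, by = 0.1)
  entries <- list()
  k <- 0L
  for (g in deciles) {
    for (r in seq_len(5L)) {
      k <- k + 1L
      entries[[k]] <- generate_spacer(
        20L, g, seed = seed * 1000L + k,
        name = sprintf("lib%02d_gc%02d_r%d", k, round_half_up(100 * g), r))
    }
  }
  # pilot spacers: the recipe states only the 30--80% GC range; one per
  # decile in that range is generated
  for (g in seq(0.3, 0.8, by = 0.1)) {
    k <- k + 1L
    entries[[k]] <- generate_spacer(
      20L, g, seed = seed * 1000L + k,
      name = sprintf("pilot%02d_gc%02d", k - 45L, round_half_up(100 * g)))
  }
  structure(
    list(entries = entries,
         recipe = paste(
           "5 x 20-nt spacers per GC decile 10-90% (45) +",
           "6 pilot spacers, one per decile 30-80% GC;",
           "exact GC counts via round-half-up"),
         seed = as.integer(seed)),
    class = "spacer_library")
}

#' @export
print.spacer_library <- function(x, ...) {
  cat(sprintf("<spacer_library, %d spacers, seed %d>\n  %s\n",
              length(x$entries), x$seed, x$recipe))
  invisible(x)
}

#' Tabulate a spacer library
#'
#' @param lib A `spacer_library`.
#' @return data.frame with name, sequence, gc_fraction, decile (percent),
#'   terminal_gc_k3.
#' @export
library_table <- function(lib) {
  data.frame(
    name = vapply(lib$entries, function(s) s$name, ""),
    sequence = vapply(lib$entries, function(s) as.character(s$seq), ""),
    gc_fraction = vapply(lib$entries, function(s) s$gc_fraction, 0),
    decile = vapply(lib$entries, function(s) round_half_up(10 * s$gc_fraction) * 10, 0),
    terminal_gc_k3 = vapply(lib$entries, function(s) s$terminal_gc_k3, 0),
    stringsAsFactors = FALSE)
}

#' Export a spacer library as CSV
#'
#' Columns: name, sequence, gc_fraction, decile, recipe, seed.
#'
#' @param lib A `spacer_library`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_library_csv <- function(lib, file) {
  tab <- library_table(lib)
  tab$recipe <- lib$recipe
  tab$seed <- lib$seed
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
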