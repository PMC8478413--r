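#' Sliding-window GC profile with 3'-end shrinkage
#'
#' Computes GC content in a sliding window of `base_width` nt (positions
#' 1..w, then 2..w+1, ...). As the window reaches the 3' end, its width is
#' reduced one nucleotide at a time down to `min_width`, each shrunk window
#' anchored at the 3' terminus, to increase resolution at the very 3' end
#' -- the region next to the Cas12a cleavage site. For a 20-nt spacer with
#' the defaults (5 down to 2) this yields 19 windows.
#'
#' @param seq Sequence (`nuc_seq` or character).
#' @param base_width Full window width (default 5).
#' @param min_width Smallest shrunk width at the 3' end (default 2).
#' @return A `gc_profile`: data.frame with columns `start` (0-based),
#'   `width`, `gc`, plus attribute `source_length`.
#' @export
sliding_gc <- function(seq, base_width = 5L, min_width = 2L) {
  s <- as.character(as_nuc(seq))
  L <- nchar(s)
  if (L < base_width) abort_input("sequence shorter than base_width")
  starts <- 0:(L - base_width)
  widths <- rep.int(base_width, length(starts))
  if (min_width < base_width) {
    shrunk <- (base_width - 1L):min_width
    starts <- c(starts, L - shrunk)
    widths <- c(widths, shrunk)
  }
  gc <- mapply(function(st, w) gc_fraction(substr(s, st + 1L, st + w)),
               starts, widths)
  structure(data.frame(start = starts, width = widths, gc = gc),
            source_length = L, class = c("gc_profile", "data.frame"))
}

#' Group spacers by response and average their GC profiles
#'
#' Reproduces the grouped sliding-window analysis: spacers are split into
#' `n_groups` response tiers (tertiles by default: high / medium / low
#' activation, assigned by response rank with ties broken by input order),
#' and per window the mean GC and its standard error across group members
#' are reported.
#'
#' @param spacers List of [spacer()] objects, all the same length.
#' @param responses Numeric response per spacer (e.g. percent GFP+ cells).
#' @param n_groups Number of response tiers (default 3).
#' @inheritParams sliding_gc
#' @return data.frame with columns `group` (1 = highest response),
#'   `start`, `width`, `gc_mean`, `gc_se`, `n`.
#' @export
group_profiles <- function(spacers, responses, n_groups = 3L,
                           base_width = 5L, min_width = 2L) {
  n <- length(spacers)
  if (n != length(responses)) abort_input("one response per spacer required")
  if (n < n_groups) abort_input("fewer spacers than groups")
  lens <- vapply(spacers, function(s) nchar(s$seq), 0L)
  if (length(unique(lens)) != 1L) abort_input("all spacers must be the same length")
  # rank by decreasing response; stable w.r.t. input order on ties
  ord <- order(-responses, seq_len(n))
  sizes <- diff(round(seq(0, n, length.out = n_groups + 1L)))
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), times = sizes)
  profs <- lapply(spacers, function(s) sliding_gc(s$seq, base_width, min_width))
  out <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    mat <- vapply(profs[grp == g], function(p) p$gc, numeric(nrow(profs[[1L]])))
    mat <- matrix(mat, nrow = nrow(profs[[1L]]))
    m <- rowMeans(mat)
    se <- if (ncol(mat) > 1L) apply(mat, 1L, stats::sd) / sqrt(ncol(mat)) else rep(0, nrow(mat))
    data.frame(group = g, start = profs[[1L]]$start, width = profs[[1L]]$width,
               gc_mean = m, gc_se = se, n = ncol(mat))
  }))
  rownames(out) <- NULL
  out
}

# Squared Pearson correlation; 0 by convention when either side has zero
# variance (degenerate regression).
r_squared <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Predictive power of window GC content
#'
#' Divides each spacer into all contiguous `window_width`-nt windows (a
#' 20-nt spacer gives eighteen 3-nt windows), computes the window GC
#' content across the library, and for each window reports the R-squared of
#' a simple linear regression of the response on window GC. The R-squared
#' of whole-spacer GC is reported alongside for comparison. Degenerate fits
#' (zero-variance response or predictor) give R-squared 0 by convention.
#'
#' @param spacers List of [spacer()] objects, equal length.
#' @param responses Numeric response per spacer.
#' @param window_width Window width in nt (default 3).
#' @return A `window_scan`: data.frame (`start`, `width`, `r2`) with
#'   attribute `whole_sequence_r2`.
#' @export
window_predictive_power <- function(spacers, responses, window_width = 3L) {
  n <- length(spacers)
  if (n != length(responses)) abort_input("one response per spacer required")
  if (n < 3L) abort_input("need at least 3 spacers for a regression")
  seqs <- vapply(spacers, function(s) as.character(s$seq), "")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort_input("all spacers must be the same length")
  if (L < window_width) abort_input("spacers shorter than window_width")
  starts <- 0:(L - window_width)
  r2 <- vapply(starts, function(st) {
    wgc <- vapply(seqs, function(s)
      gc_fraction(substr(s, st + 1L, st + window_width)), 0)
    r_squared(wgc, responses)
  }, 0)
  whole <- r_squared(vapply(seqs, gc_fraction, 0), responses)
  structure(data.frame(start = starts, width = window_width, r2 = r2),
            whole_sequence_r2 = whole,
            class = c("window_scan", "data.frame"))
}

#' Aligned sequence sets
#'
#' A gapped, equal-length stack of sequences, either from an external
#' multiple-sequence alignment (`anchor = "5prime"`) or from 3'-anchored
#' stacking via [anchor_3prime()].
#'
#' @param rows Character vector of equal-length gapped sequences
#'   (gap character `-`).
#' @param anchor `"5prime"` or `"3prime"`.
#' @return An `aligned_set`.
#' @export
aligned_set <- function(rows, anchor = c("5prime", "3prime")) {
  anchor <- match.arg(anchor)
  rows <- unname(toupper(vapply(rows, as.character, "")))
  if (length(rows) < 1L) abort_input("alignment needs at least one row")
  if (length(unique(nchar(rows))) != 1L) {
    abort_input("all alignment rows must have equal length")
  }
  structure(list(rows = rows, anchor = anchor), class = "aligned_set")
}

#' Stack sequences anchored at their 3' ends
#'
#' Natural Cas12a spacers vary in length (typically 25--36 nt). To compare
#' the region next to the cleavage site across spacers, sequences longer
#' than `target_length` are truncated at the 5' end (keeping their 3'-most
#' `target_length` residues) and shorter sequences are left-padded with
#' gaps, so every row ends at the 3' terminus.
#'
#' @param seqs Character vector (or list of `nuc_seq`) of sequences.
#' @param target_length Row length after stacking (default 25).
#' @return An [aligned_set()] with `anchor = "3prime"`.
#' @export
anchor_3prime <- function(seqs, target_length = 25L) {
  seqs <- vapply(seqs, function(s) as.character(as_nuc(s)), "")
  rows <- vapply(seqs, function(s) {
    L <- nchar(s)
    if (L >= target_length) {
      substr(s, L - target_length + 1L, L)
    } else {
      paste0(strrep("-", target_length - L), s)
    }
  }, "")
  aligned_set(rows, anchor = "3prime")
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

#' Per-column GC with sliding-window averaging
#'
#' Computes GC content per alignment column over non-gap residues (a column
#' of all gaps is missing), then applies the same sliding/shrinking window
#' averaging as [sliding_gc()] to the column GC vector; missing columns are
#' excluded from window means.
#'
#' @param aln An [aligned_set()].
#' @inheritParams sliding_gc
#' @return A `gc_profile` data.frame (`start`, `width`, `gc`).
#' @export
column_gc_profile <- function(aln, base_width = 5L, min_width = 2L) {
  mat <- aln_matrix(aln)
  colgc <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return(NA_real_)
    mean(col %in% c("G", "C", "S"))
  })
  L <- length(colgc)
  if (L < base_width) abort_input("alignment shorter than base_width")
  starts <- 0:(L - base_width)
  widths <- rep.int(base_width, length(starts))
  if (min_width < base_width) {
    shrunk <- (base_width - 1L):min_width
    starts <- c(starts, L - shrunk)
    widths <- c(widths, shrunk)
  }
  gc <- mapply(function(st, w) mean(colgc[(st + 1L):(st + w)], na.rm = TRUE),
               starts, widths)
  gc[is.nan(gc)] <- NA_real_
  structure(data.frame(start = starts, width = widths, gc = gc),
            source_length = L, class = c("gc_profile", "data.frame"))
}

# base set -> minimal IUPAC code
IUPAC_CODE <- c(A = "A", C = "C", G = "G", T = "T",
                AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
                CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")

#' IUPAC consensus of an alignment
#'
#' For each column, the minimal IUPAC degeneracy code covering every base
#' whose frequency among non-gap residues is at least `min_freq`. The
#' default threshold 0.25 makes a 50/50 two-state column a two-fold code
#' (e.g. C/T -> Y). If no base reaches the threshold, all observed bases
#' are covered. All-gap columns give `-`. U is treated as T.
#'
#' @param aln An [aligned_set()].
#' @param min_freq Minimum base frequency for inclusion (default 0.25).
#' @return Consensus string over IUPAC codes.
#' @export
iupac_consensus <- function(aln, min_freq = 0.25) {
  mat <- aln_matrix(aln)
  codes <- apply(mat, 2L, function(col) {
    col <- chartr("U", "T", col[col != "-"])
    if (length(col) == 0L) return("-")
    fr <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    keep <- names(fr)[fr >= min_freq]
    if (length(keep) == 0L) keep <- names(fr)[fr > 0]
    IUPAC_CODE[[paste(sort(keep), collapse = "")]]
  })
  paste(codes, collapse = "")
}

#' Summary statistics of a spacer set
#'
#' Count, unweighted mean GC, GC range, and a per-decile histogram
#' (deciles by nearest 10%).
#'
#' @param seqs Character vector (or list) of sequences.
#' @return List with `count`, `mean_gc`, `min_gc`, `max_gc`,
#'   `decile_histogram` (named integer vector, "0%".."100%").
#' @export
spacer_set_summary <- function(seqs) {
  gc <- vapply(seqs, function(s) gc_fraction(as_nuc(as.character(s))), 0)
  if (length(gc) < 1L) abort_input("need at least one sequence")
  dec <- factor(round_half_up(gc * 10) * 10, levels = seq(0, 100, 10))
  hist <- table(dec)
  names(hist) <- paste0(levels(dec), "%")
  list(count = length(gc), mean_gc = mean(gc),
       min_gc = min(gc), max_gc = max(gc),
       decile_histogram = hist)
}

#' Export a GC profile or window scan as CSV
#'
#' @param x A `gc_profile`, grouped profile, or `window_scan` data.frame.
#' @param file Output path.
#' @export
write_profile_csv <- function(x, file) {
  tab <- as.data.frame(x)
  if (inherits(x, "window_scan")) {
    tab$whole_sequence_r2 <- attr(x, "whole_sequence_r2")
  }
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
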