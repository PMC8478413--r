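#' Secondary-structure scoring of spacers in array context
#'
#' High-GC spacers can fold with the downstream gRNA (repeat + spacer) into
#' structures that block Cas12a access to its cleavage site. This module
#' scores that interference via the ensemble free energy of the folded
#' transcript: the more negative the ensemble free energy, the more stable
#' the predicted structure, and `score = max(0, -dG)` so a larger score
#' means stronger predicted structure.
#'
#' Two backends are available: `"vienna"` delegates to the RNAfold program
#' (ViennaRNA) for a thermodynamic partition-function fold; `"oracle"` is
#' an internal exact base-pair-maximization (weighted nested-pairing
#' dynamic program) rescaled to pseudo-kcal/mol. The backend is never
#' substituted silently: if RNAfold is not on the PATH, `"vienna"` errors
#' and instructs you to select `backend = "oracle"`.
#'
#' @name structure-backends
NULL

#' Is the thermodynamic backend available?
#'
#' @return TRUE if the RNAfold executable is on the PATH.
#' @export
has_vienna_backend <- function() nzchar(Sys.which("RNAfold"))

#' Fold RNA sequences and return ensemble free energies
#'
#' @param seqs Character vector (or list of `nuc_seq`) of sequences; DNA is
#'   converted to its RNA view.
#' @param temperature Folding temperature in Celsius (default 37).
#' @param backend `"vienna"` (RNAfold, thermodynamic) or `"oracle"`
#'   (internal weighted pairing DP, pseudo-energies).
#' @return data.frame with columns `sequence` (RNA), `ensemble_free_energy`
#'   (kcal/mol), `backend_name`.
#' @export
fold <- function(seqs, temperature = 37, backend = c("vienna", "oracle")) {
  backend <- match.arg(backend)
  rna <- vapply(seqs, function(s) as.character(as_rna(as_nuc(as.character(s)))), "")
  if (any(nchar(rna) < 1L)) abort_input("sequences must be non-empty")
  dg <- switch(backend,
    vienna = fold_vienna(rna, temperature),
    oracle = vapply(rna, function(s) -0.8 * pairing_oracle(s), 0))
  data.frame(sequence = rna, ensemble_free_energy = unname(dg),
             backend_name = if (backend == "vienna") "RNAfold" else "pairing_oracle",
             stringsAsFactors = FALSE)
}

fold_vienna <- function(rna, temperature) {
  if (!has_vienna_backend()) {
    abort_input(paste(
      "RNAfold was not found on the PATH; install ViennaRNA or select",
      "backend = 'oracle' (internal pairing fallback)"))
  }
  fin <- tempfile(fileext = ".fa")
  on.exit(unlink(fin), add = TRUE)
  writeLines(paste0(">s", seq_along(rna), "\n", rna), fin)
  out <- system2("RNAfold",
                 c("--noPS", "-p0", sprintf("--temp=%s", temperature)),
                 stdin = fin, stdout = TRUE, stderr = FALSE)
  efe <- regmatches(out, regexpr("free energy of ensemble\\s*=\\s*(-?[0-9.]+)", out))
  if (length(efe) != length(rna)) {
    abort_input("RNAfold output could not be parsed (expected one ensemble energy per record)")
  }
  as.numeric(sub(".*=\\s*", "", efe))
}

PAIR_WEIGHT <- matrix(0, 4, 4, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
PAIR_WEIGHT["G","C"] <- PAIR_WEIGHT["C","G"] <- 3
PAIR_WEIGHT["A","U"] <- PAIR_WEIGHT["U","A"] <- 2
PAIR_WEIGHT["G","U"] <- PAIR_WEIGHT["U","G"] <- 1

#' Maximum weighted nested base pairing (exact DP)
#'
#' Nussinov-style dynamic program maximizing the total pair weight
#' (GC = 3, AU = 2, GU = 1) over pseudoknot-free structures with hairpin
#' loops of at least `min_loop` unpaired bases. Serves as the internal
#' fallback folding backend and as an independent oracle in tests.
#'
#' @param seq Sequence (DNA or RNA; folded as RNA).
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return Maximum total pair weight (non-negative number).
#' @export
pairing_oracle <- function(seq, min_loop = 3L) {
  s <- strsplit(as.character(as_rna(as_nuc(as.character(seq)))), "", fixed = TRUE)[[1L]]
  n <- length(s)
  if (n < min_loop + 2L) return(0)
  idx <- match(s, c("A", "C", "G", "U"))
  W <- matrix(0, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- W[i, j - 1L]  # j unpaired
      ks <- i:(j - min_loop - 1L)
      w <- PAIR_WEIGHT[cbind(idx[ks], idx[j])]
      w[is.na(w)] <- 0
      hit <- which(w > 0)
      if (length(hit)) {
        kh <- ks[hit]
        left <- ifelse(kh > i, W[i, pmax(kh - 1L, 1L)], 0)
        inner <- W[cbind(kh + 1L, j - 1L)]
        best <- max(best, left + w[hit] + inner)
      }
      W[i, j] <- best
    }
  }
  W[1L, n]
}

#' Structure-interference score of a spacer with its downstream gRNA
#'
#' Folds the direct concatenation (no linker) of the upstream spacer and
#' the downstream gRNA (repeat + spacer) and returns
#' `score = max(0, -ensemble_free_energy)`; larger scores predict stronger
#' structure and worse processing of the downstream gRNA.
#'
#' @param upstream_spacer A [spacer()] (or sequence).
#' @param downstream_grna Downstream gRNA sequence (repeat + spacer), or
#'   NULL to score the spacer alone.
#' @inheritParams fold
#' @return List with `score`, `ensemble_free_energy`, `context_kind`
#'   (`"spacer-plus-downstream-gRNA"` or `"spacer-only"`), `backend_name`.
#' @export
context_score <- function(upstream_spacer, downstream_grna = NULL,
                          temperature = 37, backend = c("vienna", "oracle")) {
  backend <- match.arg(backend)
  up <- if (inherits(upstream_spacer, "spacer")) upstream_spacer$seq else
    as_nuc(as.character(upstream_spacer))
  kind <- "spacer-only"
  full <- as.character(up)
  if (!is.null(downstream_grna)) {
    full <- paste0(full, as.character(as_nuc(as.character(downstream_grna))))
    kind <- "spacer-plus-downstream-gRNA"
  }
  fr <- fold(full, temperature = temperature, backend = backend)
  list(score = max(0, -fr$ensemble_free_energy),
       ensemble_free_energy = fr$ensemble_free_energy,
       context_kind = kind, backend_name = fr$backend_name)
}

#' Per-spacer structure/GC risk report
#'
#' Combines the two predictive spacer features (3'-terminal GC and context
#' structure score) into a categorical risk flag: `HIGH` if the GC fraction
#' of the last three nucleotides is at least `terminal_gc_cutoff`
#' (default 2/3), otherwise `ELEVATED` if the context score exceeds the
#' collection's 75th percentile, otherwise `LOW`.
#'
#' @param spacers List of [spacer()] objects.
#' @param downstream_contexts Character vector of downstream gRNA sequences,
#'   one per spacer (recycled if length 1).
#' @param terminal_gc_cutoff Threshold on last-3-nt GC for `HIGH`.
#' @inheritParams fold
#' @return data.frame: `name`, `gc_fraction`, `terminal_gc_k3`, `score`,
#'   `flag`.
#' @export
risk_report <- function(spacers, downstream_contexts,
                        terminal_gc_cutoff = 2 / 3,
                        temperature = 37, backend = c("vienna", "oracle")) {
  backend <- match.arg(backend)
  n <- length(spacers)
  ctx <- rep_len(vapply(downstream_contexts, as.character, ""), n)
  full <- vapply(seq_len(n), function(i)
    paste0(as.character(spacers[[i]]$seq), ctx[[i]]), "")
  fr <- fold(full, temperature = temperature, backend = backend)
  score <- pmax(0, -fr$ensemble_free_energy)
  q75 <- stats::quantile(score, 0.75, names = FALSE, type = 7)
  tgc <- vapply(spacers, function(s) s$terminal_gc_k3, 0)
  flag <- ifelse(tgc >= terminal_gc_cutoff, "HIGH",
                 ifelse(score > q75, "ELEVATED", "LOW"))
  data.frame(name = vapply(spacers, function(s) s$name, ""),
             gc_fraction = vapply(spacers, function(s) s$gc_fraction, 0),
             terminal_gc_k3 = tgc, score = score, flag = flag,
             stringsAsFactors = FALSE)
}
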