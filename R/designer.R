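#' Per-site separator policies
#'
#' An array with n spacers and a trailing repeat has n + 1 repeats and
#' therefore n + 1 cleavage sites (one at the 5' end of every repeat). A
#' separator policy assigns one entry per site, each of:
#' `"none"` (no separator), `"full"` (the species' full natural separator),
#' `"syn"` (the species' default synSeparator), or a literal DNA sequence
#' such as `"AAAT"`, `"AT"`, `"G"`.
#'
#' @param sites Character vector, one entry per cleavage site, or a single
#'   entry to apply at every site (see `n`).
#' @param n Number of cleavage sites when recycling a single entry.
#' @return Character vector of per-site entries (class `separator_policy`).
#' @examples
#' separator_policy("AAAT", n = 3)         # synSeparator everywhere
#' separator_policy(c("none", "none", "AAAT"))  # only at the trailing site
#' @export
separator_policy <- function(sites, n = length(sites)) {
  sites <- rep_len(as.character(sites), n)
  structure(sites, class = "separator_policy")
}

resolve_separator <- function(entry, profile) {
  if (is.na(entry) || entry %in% c("none", "")) return(NULL)
  if (entry == "full") return(profile$full_separator)
  if (entry == "syn") return(profile$default_synseparator)
  as_nuc(entry)
}

#' Build an annotated CRISPR array
#'
#' Assembles leader + \[separator + repeat + spacer\] per unit + optional
#' (separator + trailing repeat) + 3' flank, annotating every feature with
#' 0-based half-open intervals. The features tile the sequence exactly.
#' Cas12a cleaves at the 5' end of every repeat; any separator upstream of
#' a cleavage site stays attached to the upstream fragment.
#'
#' @param spacers List of [spacer()] objects (in array order).
#' @param profile A [species_profile()].
#' @param policy A [separator_policy()] with one entry per repeat
#'   (spacer count + 1 if `include_trailing_repeat`).
#' @param include_trailing_repeat Append a trailing repeat (default TRUE;
#'   a two-gRNA assay array then has three cleavage sites).
#' @param leader Optional leader sequence (5' of the first unit).
#' @param three_prime_flank Optional 3' flank after the trailing repeat.
#' @param name Construct name.
#' @return An `array_design`: list with `sequence` (`nuc_seq`), `features`
#'   (data.frame: `type`, `start`, `end`, `name`), `profile`, `policy`,
#'   `name`.
#' @export
build_array <- function(spacers, profile,
                        policy = separator_policy("syn", n_sites),
                        include_trailing_repeat = TRUE,
                        leader = NULL, three_prime_flank = NULL,
                        name = "crispr_array") {
  if (length(spacers) < 1L) abort_input("need at least one spacer")
  if (inherits(spacers, "spacer")) spacers <- list(spacers)
  n_sites <- length(spacers) + as.integer(include_trailing_repeat)
  if (length(policy) != n_sites) {
    abort_input(sprintf("policy has %d entries but the design has %d repeats",
                        length(policy), n_sites))
  }
  feats <- list(); seqparts <- character(); pos <- 0L
  add <- function(type, s, nm) {
    s <- as.character(s)
    if (!nzchar(s)) return(invisible())
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, start = pos, end = pos + nchar(s), name = nm,
      stringsAsFactors = FALSE)
    seqparts[length(seqparts) + 1L] <<- s
    pos <<- pos + nchar(s)
  }
  if (!is.null(leader)) add("leader", as_nuc(as.character(leader)), "leader")
  for (i in seq_along(spacers)) {
    sep <- resolve_separator(policy[[i]], profile)
    if (!is.null(sep)) add("separator", sep, sprintf("separator_%d", i))
    add("repeat", profile$mature_repeat, sprintf("repeat_%d", i))
    add("spacer", spacers[[i]]$seq, spacers[[i]]$name)
  }
  if (include_trailing_repeat) {
    sep <- resolve_separator(policy[[n_sites]], profile)
    if (!is.null(sep)) add("separator", sep, sprintf("separator_%d", n_sites))
    add("repeat", profile$mature_repeat, sprintf("repeat_%d", n_sites))
  }
  if (!is.null(three_prime_flank)) {
    add("flank", as_nuc(as.character(three_prime_flank)), "three_prime_flank")
  }
  features <- do.call(rbind, feats)
  design <- structure(
    list(sequence = nuc_seq(paste(seqparts, collapse = "")),
         features = features, profile = profile,
         policy = policy, spacers = spacers, name = name),
    class = "array_design")
  stopifnot(identical(features$start,
                      c(0L, utils::head(features$end, -1L))))
  design
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf("<array_design %s, %d nt, %d spacers, %d repeats>\n",
              x$name, nchar(x$sequence), length(x$spacers),
              sum(x$features$type == "repeat")))
  print(x$features)
  invisible(x)
}

#' Fragment models of processed arrays
#'
#' `fragment_model()` describes the RNA species released by complete Cas12a
#' processing: the ordered fragment lengths and which fragments are single
#' gRNAs (repeat + spacer, plus a retained downstream separator if
#' present). `predicted_fragments()` derives the model from an
#' [build_array()] design by cutting at the 5' boundary of every repeat;
#' separators upstream of a cut stay on the upstream fragment, so a
#' synSeparator slightly lengthens the gRNA it follows.
#'
#' @param fragment_lengths Ordered integer fragment lengths (nt).
#' @param single_grna_indices Positions (1-based) of single-gRNA fragments.
#' @return A `fragment_model`.
#' @export
fragment_model <- function(fragment_lengths, single_grna_indices) {
  fragment_lengths <- as.integer(fragment_lengths)
  single_grna_indices <- as.integer(single_grna_indices)
  if (any(fragment_lengths <= 0L)) abort_input("fragment lengths must be positive")
  if (length(single_grna_indices) &&
      (min(single_grna_indices) < 1L ||
       max(single_grna_indices) > length(fragment_lengths))) {
    abort_input("single_grna_indices out of range")
  }
  structure(list(fragment_lengths = fragment_lengths,
                 single_grna_indices = single_grna_indices),
            class = "fragment_model")
}

#' @rdname fragment_model
#' @param design An `array_design`.
#' @export
predicted_fragments <- function(design) {
  f <- design$features
  L <- nchar(design$sequence)
  cuts <- sort(unique(f$start[f$type == "repeat"]))
  cuts <- cuts[cuts > 0L & cuts < L]
  bounds <- c(0L, cuts, L)
  lens <- diff(bounds)
  singles <- vapply(seq_along(lens), function(i) {
    inside <- f[f$start >= bounds[i] & f$end <= bounds[i + 1L], ]
    all(inside$type %in% c("repeat", "spacer", "separator")) &&
      sum(inside$type == "repeat") == 1L &&
      sum(inside$type == "spacer") == 1L
  }, TRUE)
  fragment_model(lens, which(singles))
}

#' @export
print.fragment_model <- function(x, ...) {
  cat(sprintf("<fragment_model> lengths: %s; single gRNAs at: %s\n",
              paste(x$fragment_lengths, collapse = ", "),
              paste(x$single_grna_indices, collapse = ", ")))
  invisible(x)
}

#' Polyadenylation-signal hexamers
#'
#' The twelve common variants of the human polyadenylation signal. AT-rich
#' insertions such as synSeparators could in principle create one of these
#' motifs, prematurely terminating the array transcript, so designs are
#' screened for them.
#' @export
POLYA_HEXAMERS <- c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA",
                    "AATATA", "AATACA", "CATAAA", "GATAAA", "AATGAA",
                    "TTTAAA", "ACTAAA")

#' Scan a sequence for polyadenylation-signal motifs
#'
#' Reports every (possibly overlapping) occurrence of any motif on the
#' sense strand.
#'
#' @param seq DNA sequence.
#' @param motifs Hexamer motif set (default [POLYA_HEXAMERS]).
#' @return data.frame with 0-based `position` and `motif`, sorted by
#'   position.
#' @export
polya_scan <- function(seq, motifs = POLYA_HEXAMERS) {
  s <- as.character(as_nuc(as.character(seq)))
  L <- nchar(s); w <- nchar(motifs[1L])
  if (L < w) return(data.frame(position = integer(), motif = character()))
  subs <- substring(s, 1:(L - w + 1L), w:L)
  hit <- which(subs %in% motifs)
  out <- data.frame(position = hit - 1L, motif = subs[hit],
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Combined design report
#'
#' Per-spacer structure/GC risk (downstream context = the next repeat +
#' spacer in the array), polyadenylation-signal hits annotated with the
#' feature they fall in, the predicted processing fragments, and the total
#' length.
#'
#' @param design An `array_design`.
#' @inheritParams fold
#' @return List with `risk` (data.frame), `polya_hits` (data.frame with
#'   feature context), `fragments` ([fragment_model()]), `total_length`.
#' @export
design_report <- function(design, backend = c("vienna", "oracle"),
                          temperature = 37) {
  backend <- match.arg(backend)
  rep_seq <- as.character(design$profile$mature_repeat)
  n <- length(design$spacers)
  ctx <- vapply(seq_len(n), function(i) {
    if (i < n) paste0(rep_seq, as.character(design$spacers[[i + 1L]]$seq))
    else rep_seq  # last spacer: trailing repeat (or repeat alone)
  }, "")
  risk <- risk_report(design$spacers, ctx, backend = backend,
                      temperature = temperature)
  hits <- polya_scan(design$sequence)
  if (nrow(hits)) {
    f <- design$features
    hits$feature <- vapply(hits$position, function(p) {
      inside <- f$type[f$start <= p & f$end > p]
      if (length(inside)) inside[1L] else "junction"
    }, "")
    hits$feature_name <- vapply(hits$position, function(p) {
      inside <- f$name[f$start <= p & f$end > p]
      if (length(inside)) inside[1L] else ""
    }, "")
  }
  list(risk = risk, polya_hits = hits,
       fragments = predicted_fragments(design),
       total_length = nchar(design$sequence))
}
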