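#' Electropherogram peak tables
#'
#' A peak table holds the Bioanalyzer-style output for one sample: one row
#' per RNA peak with its sized fragment length (nt) and peak area
#' (arbitrary units, proportional to RNA mass). A declared marker length
#' (the 25-nt RNA marker by default) is excluded from all quantification.
#'
#' @param length_nt Numeric vector of peak lengths (nt).
#' @param area Numeric vector of peak areas (>= 0).
#' @param sample_id Sample label.
#' @param timepoint Incubation time in minutes (optional).
#' @param marker_length Marker length in nt (default 25).
#' @param marker_tolerance Relative tolerance for marker recognition
#'   (default 0.05).
#' @return A `peak_table` data.frame with attributes `sample_id`,
#'   `timepoint`, `marker_length`; marker peaks flagged in column `marker`.
#' @export
peak_table <- function(length_nt, area, sample_id = "sample",
                       timepoint = NA_real_, marker_length = 25,
                       marker_tolerance = 0.05) {
  if (length(length_nt) != length(area)) {
    abort_input("length_nt and area must have equal length")
  }
  if (any(area < 0)) abort_input("peak areas must be non-negative")
  if (any(length_nt <= 0)) abort_input("peak lengths must be positive")
  marker <- abs(length_nt - marker_length) <= marker_tolerance * marker_length
  structure(
    data.frame(length_nt = length_nt, area = area, marker = marker),
    sample_id = sample_id, timepoint = timepoint,
    marker_length = marker_length,
    class = c("peak_table", "data.frame"))
}

#' Read peak tables from CSV
#'
#' Expected columns: `length_nt`, `area`, optionally `sample_id` and
#' `timepoint`; one [peak_table()] is returned per distinct
#' (sample_id, timepoint).
#'
#' @param file CSV path.
#' @inheritParams peak_table
#' @return List of `peak_table` objects.
#' @export
read_peak_csv <- function(file, marker_length = 25) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("length_nt", "area")
  if (!all(need %in% names(tab))) {
    abort_input("peak CSV must have columns 'length_nt' and 'area'")
  }
  if (is.null(tab$sample_id)) tab$sample_id <- "sample"
  if (is.null(tab$timepoint)) tab$timepoint <- NA_real_
  key <- paste(tab$sample_id, tab$timepoint, sep = "@")
  lapply(split(tab, factor(key, levels = unique(key))), function(g) {
    peak_table(g$length_nt, g$area, sample_id = g$sample_id[1L],
               timepoint = g$timepoint[1L], marker_length = marker_length)
  })
}

#' Theoretical maximum single-gRNA mass fraction
#'
#' If processing of an array proceeds to completion, the fraction of total
#' RNA mass contained in single gRNAs equals the length-weighted fraction
#' of the single-gRNA fragments (RNA mass is proportional to length):
#' for fragments 57, 41, 42 and 158 nt with the 41/42-nt single gRNAs,
#' (41 + 42) / (57 + 41 + 42 + 158) = 0.28.
#'
#' @param model A [fragment_model()].
#' @return Fraction in (0, 1\].
#' @export
theoretical_max_fraction <- function(model) {
  if (length(model$single_grna_indices) < 1L) {
    abort_input("fragment model has no single-gRNA fragments")
  }
  sum(model$fragment_lengths[model$single_grna_indices]) /
    sum(model$fragment_lengths)
}

#' Match peaks to expected fragments
#'
#' Greedy one-to-one assignment of peaks to expected fragment lengths in
#' order of increasing relative distance; a peak matches a fragment only
#' within `rel_tolerance` of the expected length. Marker peaks are always
#' excluded. Unresolvable doublets (an expected fragment left unmatched
#' although a peak within its tolerance was claimed by another fragment)
#' raise an ambiguous-assignment error listing the candidates, unless the
#' two fragments belong to the same declared co-migration `group` (e.g.
#' 41/42-nt gRNAs sized as one peak), in which case the peak covers the
#' whole group.
#'
#' @param table A [peak_table()].
#' @param model A [fragment_model()].
#' @param rel_tolerance Relative sizing tolerance (default 0.10).
#' @param groups Optional list of integer vectors of fragment indices that
#'   co-migrate as one peak.
#' @return data.frame, one row per peak: `length_nt`, `area`, `class`
#'   (`"marker"`, `"fragment"`, `"unassigned"`), `fragment` (index or NA),
#'   `is_single` (peak assigned to a single-gRNA fragment/group).
#' @export
match_peaks <- function(table, model, rel_tolerance = 0.10, groups = NULL) {
  if (nrow(table) < 1L) abort_input("peak table is empty")
  exp_len <- model$fragment_lengths
  nfrag <- length(exp_len)
  group_of <- seq_len(nfrag)
  if (!is.null(groups)) {
    for (g in groups) group_of[g] <- min(g)
  }
  peaks <- which(!table$marker)
  cand <- expand.grid(peak = peaks, frag = seq_len(nfrag))
  cand$dist <- abs(table$length_nt[cand$peak] - exp_len[cand$frag])
  cand <- cand[cand$dist <= rel_tolerance * exp_len[cand$frag], , drop = FALSE]
  cand <- cand[order(cand$dist, cand$frag), , drop = FALSE]
  assign_frag <- rep(NA_integer_, nrow(table))
  used_frag <- logical(nfrag)
  for (r in seq_len(nrow(cand))) {
    p <- cand$peak[r]; fr <- cand$frag[r]
    if (!is.na(assign_frag[p]) || used_frag[fr]) next
    assign_frag[p] <- fr
    used_frag[fr] <- TRUE
  }
  # ambiguity: a still-unmatched fragment within tolerance of a claimed
  # peak, outside the claimed fragment's co-migration group
  if (nrow(cand)) {
    for (r in seq_len(nrow(cand))) {
      p <- cand$peak[r]; fr <- cand$frag[r]
      if (!used_frag[fr] && !is.na(assign_frag[p]) &&
          group_of[assign_frag[p]] != group_of[fr]) {
        abort_input(sprintf(
          "ambiguous assignment: peak at %.1f nt is within tolerance of expected fragments %d nt and %d nt; declare a fragment group or tighten rel_tolerance",
          table$length_nt[p], exp_len[assign_frag[p]], exp_len[fr]))
      }
    }
  }
  singles <- model$single_grna_indices
  single_groups <- unique(group_of[singles])
  data.frame(
    length_nt = table$length_nt, area = table$area,
    class = ifelse(table$marker, "marker",
                   ifelse(is.na(assign_frag), "unassigned", "fragment")),
    fragment = assign_frag,
    is_single = !table$marker & !is.na(assign_frag) &
      group_of[ifelse(is.na(assign_frag), 1L, assign_frag)] %in% single_groups &
      !is.na(assign_frag),
    stringsAsFactors = FALSE)
}

#' Normalize replicate peak tables to equal total RNA
#'
#' Scales every table's areas by (minimum total non-marker area across
#' tables) / (its own total), emulating normalization to the sample with
#' the lowest RNA concentration; afterwards all non-marker totals are
#' equal.
#'
#' @param tables List of [peak_table()] objects.
#' @return List of normalized `peak_table` objects.
#' @export
normalize_replicates <- function(tables) {
  if (length(tables) < 1L) abort_input("need at least one table")
  totals <- vapply(tables, function(t) sum(t$area[!t$marker]), 0)
  if (any(totals <= 0)) abort_input("a table has zero total (non-marker) area")
  lo <- min(totals)
  mapply(function(t, tot) {
    t$area <- t$area * lo / tot
    t
  }, tables, totals, SIMPLIFY = FALSE)
}

#' Percent of maximum processing
#'
#' Observed single-gRNA mass fraction (area of peaks matched to
#' single-gRNA fragments over total non-marker area) divided by the
#' theoretical maximum fraction of the fragment model, times 100. A fully
#' processed array scores 100%.
#'
#' @inheritParams match_peaks
#' @return List with `observed_single_fraction`, `theoretical_max_fraction`,
#'   `percent_of_max`, `sample_id`, `timepoint`.
#' @export
percent_of_max <- function(table, model, rel_tolerance = 0.10, groups = NULL) {
  m <- match_peaks(table, model, rel_tolerance, groups)
  total <- sum(m$area[m$class != "marker"])
  if (total <= 0) abort_input("no non-marker peak area to quantify")
  obs <- sum(m$area[m$is_single]) / total
  theo <- theoretical_max_fraction(model)
  list(observed_single_fraction = obs,
       theoretical_max_fraction = theo,
       percent_of_max = 100 * obs / theo,
       sample_id = attr(table, "sample_id"),
       timepoint = attr(table, "timepoint"))
}

#' Simulate an electropherogram at a given processing completeness
#'
#' Generates a synthetic peak table for a cleavage reaction in which a
#' fraction `completeness` of the RNA mass has been fully processed into
#' the model's fragments while the remainder stays as the intact
#' transcript. Peak lengths are jittered by Gaussian sizing noise and
#' areas by multiplicative noise; a marker peak is added. Used to validate
#' that [percent_of_max()] recovers the simulated completeness.
#'
#' @param model A [fragment_model()].
#' @param completeness Fraction of RNA mass fully processed, in \[0, 1\].
#' @param seed Integer seed.
#' @param sizing_cv Relative SD of peak-length jitter (default 0.01).
#' @param area_cv Relative SD of area noise (default 0.01).
#' @param marker_length Marker peak length (default 25).
#' @inheritParams peak_table
#' @return A [peak_table()].
#' @export
simulate_electropherogram <- function(model, completeness, seed = 1L,
                                      sizing_cv = 0.01, area_cv = 0.01,
                                      marker_length = 25,
                                      sample_id = "sim",
                                      timepoint = NA_real_) {
  if (completeness < 0 || completeness > 1) {
    abort_input("completeness must be in [0, 1]")
  }
  lens <- model$fragment_lengths
  total <- sum(lens)
  with_seed(seed, {
    pk_len <- c(lens, total)
    pk_area <- c(completeness * lens, (1 - completeness) * total)
    keep <- pk_area > 0
    pk_len <- pk_len[keep]; pk_area <- pk_area[keep]
    pk_len <- pk_len * (1 + stats::rnorm(length(pk_len), 0, sizing_cv))
    pk_area <- pk_area * (1 + stats::rnorm(length(pk_area), 0, area_cv))
    pk_area <- pmax(pk_area, 0)
    peak_table(c(pk_len, marker_length), c(pk_area, 0.2 * total),
               sample_id = sample_id, timepoint = timepoint,
               marker_length = marker_length)
  })
}

#' Summarize processing results across samples
#'
#' @param results List of [percent_of_max()] results.
#' @return data.frame: sample_id, timepoint, observed_fraction,
#'   theoretical_max, percent_of_max.
#' @export
processing_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id %||% "sample",
               timepoint = r$timepoint %||% NA_real_,
               observed_fraction = r$observed_single_fraction,
               theoretical_max = r$theoretical_max_fraction,
               percent_of_max = r$percent_of_max,
               stringsAsFactors = FALSE)
  }))
}
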