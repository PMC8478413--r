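#' Oligonucleotide duplexing-and-ligation assembly planning
#'
#' A designed array is converted into an orderable set of single-stranded
#' oligos: the double-stranded sequence is divided into duplexes of at most
#' `max_oligo` nt per strand, adjacent duplexes joined by unique 4-nt 5'
#' overhangs, and duplexes partitioned into ligation pots of at most
#' `pot_capacity`; pot products are ligated together in a second round, so
#' overhang uniqueness is enforced globally across the whole plan.
#'
#' Stagger convention: at an internal junction at top-strand position j,
#' the top strand is cut at j and the bottom strand at j + 4 (top
#' coordinates). The 4-nt region in between is single-stranded on both
#' flanking duplexes -- a 5' extension of the downstream duplex's top oligo
#' and of the upstream duplex's bottom oligo -- and is reported as the
#' junction overhang (top-strand sequence). Plan ends are blunt by default
#' (the array joins the vector by In-Fusion, not ligation).
#'
#' @name assembly-planning
NULL

#' Add In-Fusion vector flanks
#'
#' Prepends the 3'-terminal 20 nt of the left vector arm and appends the
#' 5'-terminal 20 nt of the right arm, the homology required for In-Fusion
#' cloning into the opened backbone.
#'
#' @param array_seq Array sequence.
#' @param left_arm,right_arm Vector arm sequences (>= 20 nt).
#' @param overlap Homology length (default 20 bp).
#' @return Flanked `nuc_seq`.
#' @export
add_infusion_flanks <- function(array_seq, left_arm, right_arm, overlap = 20L) {
  la <- as.character(as_nuc(as.character(left_arm)))
  ra <- as.character(as_nuc(as.character(right_arm)))
  if (nchar(la) < overlap || nchar(ra) < overlap) {
    abort_input(sprintf("vector arms must be at least %d nt", overlap))
  }
  s <- as.character(as_nuc(as.character(array_seq)))
  nuc_seq(paste0(substr(la, nchar(la) - overlap + 1L, nchar(la)), s,
                 substr(ra, 1L, overlap)))
}

#' Balanced partition of duplexes into ligation pots
#'
#' `ceiling(n / pot_capacity)` pots with sizes as equal as possible
#' (differing by at most one, larger pots first): 12 duplexes give two pots
#' of six.
#'
#' @param n_duplexes Number of duplexes.
#' @param pot_capacity Maximum duplexes per pot (default 8).
#' @return Integer vector of pot sizes.
#' @export
partition_pots <- function(n_duplexes, pot_capacity = 8L) {
  if (n_duplexes < 1L) abort_input("need at least one duplex")
  np <- ceiling(n_duplexes / pot_capacity)
  base <- n_duplexes %/% np
  extra <- n_duplexes %% np
  c(rep.int(base + 1L, extra), rep.int(base, np - extra))
}

# fast plain-character reverse complement (hot path: called once per
# candidate overhang during the junction search)
rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x),
                     "", fixed = TRUE)[[1L]]), collapse = "")
}

overhang_ok <- function(o, accepted, forbid_palindrome = TRUE,
                        forbid_revcomp = TRUE) {
  if (o %in% accepted) return(FALSE)
  if (forbid_palindrome && rc_chr(o) == o) return(FALSE)
  if (forbid_revcomp && rc_chr(o) %in% accepted) return(FALSE)
  TRUE
}

#' Plan the oligo duplexes for a double-stranded sequence
#'
#' Deterministic backtracking over staggered cut positions: junctions are
#' placed as close as possible to equal fragment lengths (offsets explored
#' outward from the ideal position, positive before negative), subject to
#' every single-stranded oligo being at most `max_oligo` nt and every
#' internal overhang being `overhang_len` nt, pairwise distinct,
#' non-palindromic, and not the reverse complement of any other (both
#' exclusions prevent misligation and are toggleable). If no junction
#' placement satisfies the constraints the planner raises an infeasibility
#' error naming the first violated constraint rather than emitting an
#' invalid plan.
#'
#' @param ds_seq Double-stranded (top-strand) DNA sequence.
#' @param max_oligo Maximum single-stranded oligo length (default 60).
#' @param overhang_len Overhang length (default 4).
#' @param pot_capacity Maximum duplexes per ligation pot (default 8).
#' @param forbid_palindrome,forbid_revcomp Overhang exclusions beyond
#'   uniqueness (default TRUE).
#' @return A `ligation_plan`: list with `duplexes` (list of records:
#'   `top_oligo`, `bottom_oligo`, `left_overhang`, `right_overhang`,
#'   `pot`), `pots` (list of duplex indices), `junction_overhangs`,
#'   `source_sequence`, `params`.
#' @export
plan_oligos <- function(ds_seq, max_oligo = 60L, overhang_len = 4L,
                        pot_capacity = 8L, forbid_palindrome = TRUE,
                        forbid_revcomp = TRUE) {
  s <- as.character(as_nuc(as.character(ds_seq)))
  L <- nchar(s)
  ov <- as.integer(overhang_len)
  if (L < 2L * ov) {
    abort_input(sprintf("sequence (%d nt) shorter than 2 x overhang length", L))
  }
  if (L <= max_oligo) {
    return(finish_plan(s, integer(), ov, max_oligo, pot_capacity))
  }
  min_frag <- 2L * ov
  # start from fragment sizes ~ max_oligo - 2*overhang so each junction has
  # placement slack; densely packed fragments make overhang conflicts hard
  # to resolve locally
  k_min <- max(2L, ceiling(L / (max_oligo - 2L * ov)))
  err <- NULL
  for (k in k_min:(k_min + 8L)) {
    if (k * max_oligo < L) next
    if (k * min_frag > L) break
    sol <- search_junctions(s, L, k, ov, max_oligo, min_frag,
                            forbid_palindrome, forbid_revcomp)
    if (is.character(sol)) { err <- err %||% sol; next }
    if (!is.null(sol)) return(finish_plan(s, sol, ov, max_oligo, pot_capacity))
  }
  abort_input("infeasible assembly plan: ",
              err %||% "no junction placement satisfies the oligo-length constraints")
}

# Depth-first search over junction positions; returns integer junction
# vector, NULL if exhausted, or a character message describing the first
# violated overhang constraint (for error reporting).
search_junctions <- function(s, L, k, ov, max_oligo, min_frag,
                             forbid_palindrome, forbid_revcomp,
                             node_budget = 20000L) {
  ideal <- round(seq_len(k - 1L) * L / k)
  first_fail <- NULL
  nodes <- 0L
  # per-junction upper bound from oligo-length caps (first bottom oligo is
  # fragment1 + ov; last bottom is fragment_k - ov and must keep >= 1 nt)
  solve <- function(i, prev, accepted) {
    nodes <<- nodes + 1L
    if (nodes > node_budget) return(NULL)  # give up on this k, try k + 1
    if (i == k) {
      last_top <- L - prev
      if (last_top <= max_oligo && last_top - ov >= 1L) return(integer())
      return(NULL)
    }
    cap <- if (i == 1L) max_oligo - ov else max_oligo
    lo <- max(prev + min_frag, L - (k - i) * max_oligo)
    hi <- min(prev + cap, L - (k - i) * min_frag, L - ov - 1L)
    if (lo > hi) return(NULL)
    cand <- lo:hi
    cand <- cand[order(abs(cand - ideal[i]), -(cand))]
    for (j in cand) {
      o <- substr(s, j + 1L, j + ov)
      if (!overhang_ok(o, accepted, forbid_palindrome, forbid_revcomp)) {
        if (is.null(first_fail)) {
          first_fail <<- sprintf(
            "overhang '%s' at position %d violates uniqueness/complementarity constraints", o, j)
        }
        next
      }
      rest <- solve(i + 1L, j, c(accepted, o))
      if (!is.null(rest)) return(c(j, rest))
    }
    NULL
  }
  res <- solve(1L, 0L, character())
  if (is.null(res)) return(first_fail)  # may be NULL (pure length infeasibility)
  res
}

finish_plan <- function(s, junctions, ov, max_oligo, pot_capacity) {
  L <- nchar(s)
  k <- length(junctions) + 1L
  top_b <- c(0L, junctions, L)
  bot_b <- c(0L, junctions + ov, L)
  duplexes <- lapply(seq_len(k), function(i) {
    list(top_oligo = substr(s, top_b[i] + 1L, top_b[i + 1L]),
         bottom_oligo = rc_chr(substr(s, bot_b[i] + 1L, bot_b[i + 1L])),
         left_overhang = if (i > 1L) substr(s, junctions[i - 1L] + 1L,
                                            junctions[i - 1L] + ov) else "",
         right_overhang = if (i < k) substr(s, junctions[i] + 1L,
                                            junctions[i] + ov) else "")
  })
  sizes <- partition_pots(k, pot_capacity)
  pots <- split(seq_len(k), rep(seq_along(sizes), sizes))
  for (p in seq_along(pots)) {
    for (d in pots[[p]]) duplexes[[d]]$pot <- p
  }
  plan <- structure(
    list(duplexes = duplexes, pots = unname(pots),
         junction_overhangs = if (k > 1L)
           vapply(duplexes[-k], function(d) d$right_overhang, "") else character(),
         source_sequence = nuc_seq(s),
         params = list(max_oligo = max_oligo, overhang_len = ov,
                       pot_capacity = pot_capacity)),
    class = "ligation_plan")
  v <- verify_plan(plan)
  if (!v$ok) {
    abort_input("internal error: planner produced an invalid plan: ",
                v$violations[1L])
  }
  plan
}

#' @export
print.ligation_plan <- function(x, ...) {
  cat(sprintf("<ligation_plan: %d duplexes in %d pot(s), source %d bp>\n",
              length(x$duplexes), length(x$pots), nchar(x$source_sequence)))
  invisible(x)
}

#' Independently verify a ligation plan
#'
#' Re-checks every plan constraint from the oligos themselves: top and
#' bottom strands each reassemble the source sequence exactly, every
#' single-stranded oligo is within the length cap, every pot is within
#' capacity, and all internal overhangs pass a brute-force pairwise
#' uniqueness / palindrome / reverse-complement check.
#'
#' @param plan A `ligation_plan` (or the result of [read_plan()]).
#' @return List with `ok` (logical) and `violations` (character vector).
#' @export
verify_plan <- function(plan) {
  v <- character()
  d <- plan$duplexes
  src <- as.character(plan$source_sequence)
  p <- plan$params
  top <- paste(vapply(d, function(x) x$top_oligo, ""), collapse = "")
  if (top != src) v <- c(v, "top-strand oligos do not reassemble the source sequence")
  bottom <- paste(rev(vapply(d, function(x) x$bottom_oligo, "")), collapse = "")
  if (bottom != rc_chr(src)) {
    v <- c(v, "bottom-strand oligos do not reassemble the source sequence")
  }
  lens <- unlist(lapply(d, function(x) nchar(c(x$top_oligo, x$bottom_oligo))))
  if (any(lens > p$max_oligo)) {
    v <- c(v, sprintf("oligo length %d exceeds the %d-nt cap",
                      max(lens), p$max_oligo))
  }
  if (any(lengths(plan$pots) > p$pot_capacity)) {
    v <- c(v, sprintf("a pot exceeds the %d-duplex capacity", p$pot_capacity))
  }
  oh <- plan$junction_overhangs
  if (length(oh)) {
    if (any(nchar(oh) != p$overhang_len)) {
      v <- c(v, "an internal overhang has the wrong length")
    }
    for (a in seq_along(oh)) {
      if (rc_chr(oh[a]) == oh[a]) {
        v <- c(v, sprintf("overhang '%s' is palindromic", oh[a]))
      }
      if (a < length(oh)) for (b in (a + 1L):length(oh)) {
        if (oh[a] == oh[b]) {
          v <- c(v, sprintf("duplicated overhang '%s' (junctions %d and %d)",
                            oh[a], a, b))
        }
        if (oh[a] == rc_chr(oh[b])) {
          v <- c(v, sprintf("overhangs '%s' and '%s' are reverse complements (junctions %d and %d)",
                            oh[a], oh[b], a, b))
        }
      }
    }
    # stagger consistency: each junction overhang is the 5' extension of
    # both flanking oligos
    for (i in seq_along(oh)) {
      if (substr(d[[i + 1L]]$top_oligo, 1L, p$overhang_len) != oh[i]) {
        v <- c(v, sprintf("junction %d overhang does not match the downstream top oligo", i))
      }
      if (substr(d[[i]]$bottom_oligo, 1L, p$overhang_len) != rc_chr(oh[i])) {
        v <- c(v, sprintf("junction %d overhang does not match the upstream bottom oligo", i))
      }
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Vendor-ready order sheet
#'
#' One row per single-stranded oligo: name, pot, duplex, strand, 5'-to-3'
#' sequence, length, and overhang annotations (top-strand sequence of the
#' junction region).
#'
#' @param plan A `ligation_plan`.
#' @return data.frame.
#' @export
order_sheet <- function(plan) {
  rows <- lapply(seq_along(plan$duplexes), function(i) {
    dd <- plan$duplexes[[i]]
    data.frame(
      name = sprintf("duplex%02d_%s", i, c("top", "bottom")),
      pot = dd$pot, duplex = i, strand = c("top", "bottom"),
      sequence = c(dd$top_oligo, dd$bottom_oligo),
      length = nchar(c(dd$top_oligo, dd$bottom_oligo)),
      left_overhang = dd$left_overhang, right_overhang = dd$right_overhang,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize / restore a ligation plan
#'
#' The plan is stored as its order sheet (CSV) with the planning parameters
#' in `#`-prefixed header comments; [read_plan()] reconstructs the plan
#' (deriving the source sequence from the top-strand oligos) so that
#' [verify_plan()] can re-check all constraints of a stored plan.
#'
#' @param plan A `ligation_plan`.
#' @param file Path.
#' @return `read_plan()` returns a `ligation_plan`.
#' @export
write_plan <- function(plan, file) {
  con <- file(file, "w")
  on.exit(close(con))
  p <- plan$params
  writeLines(sprintf("# cas12array ligation plan: max_oligo=%d overhang_len=%d pot_capacity=%d",
                     p$max_oligo, p$overhang_len, p$pot_capacity), con)
  utils::write.csv(order_sheet(plan), con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_plan
#' @export
read_plan <- function(file) {
  hdr <- readLines(file, n = 1L)
  m <- regmatches(hdr, regexec(
    "max_oligo=(\\d+) overhang_len=(\\d+) pot_capacity=(\\d+)", hdr))[[1L]]
  if (length(m) != 4L) abort_input("not a cas12array plan file")
  sheet <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  ids <- sort(unique(sheet$duplex))
  duplexes <- lapply(ids, function(i) {
    rows <- sheet[sheet$duplex == i, ]
    list(top_oligo = rows$sequence[rows$strand == "top"],
         bottom_oligo = rows$sequence[rows$strand == "bottom"],
         left_overhang = rows$left_overhang[1L] %|NA|% "",
         right_overhang = rows$right_overhang[1L] %|NA|% "",
         pot = rows$pot[1L])
  })
  pots <- lapply(sort(unique(sheet$pot)), function(p)
    sort(unique(sheet$duplex[sheet$pot == p])))
  oh <- vapply(duplexes[-length(duplexes)], function(d) d$right_overhang, "")
  structure(
    list(duplexes = duplexes, pots = pots,
         junction_overhangs = if (length(duplexes) > 1L) oh else character(),
         source_sequence = nuc_seq(paste(
           vapply(duplexes, function(d) d$top_oligo, ""), collapse = "")),
         params = list(max_oligo = as.integer(m[2L]),
                       overhang_len = as.integer(m[3L]),
                       pot_capacity = as.integer(m[4L]))),
    class = "ligation_plan")
}

`%|NA|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a
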