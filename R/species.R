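#' Species profiles and the editable registry
#'
#' A species profile bundles the sequences needed to build an array for one
#' Cas12a (or Cas13d) variant: the mature (post-processing) direct repeat,
#' the full natural separator (the ~16-18 nt AT-rich fragment of the
#' pre-processing repeat that is excised during maturation), and the default
#' synSeparator (the short AT-rich 3'-terminal fragment of that separator,
#' e.g. AAAT for *Lachnospiraceae bacterium*, TTTT for *Acidaminococcus*
#' sp.). Profiles ship in an editable plain-text registry; every separator
#' default carries provenance text and can be overridden.
#'
#' @param species_name Species/variant label.
#' @param mature_repeat Mature repeat sequence (DNA).
#' @param full_separator Full natural separator, 6--25 nt.
#' @param default_synseparator Default synSeparator, 1--8 nt.
#' @param leader Optional leader sequence.
#' @param provenance Free-text provenance of the separator sequences.
#' @return A `species_profile` object.
#' @export
species_profile <- function(species_name, mature_repeat, full_separator,
                            default_synseparator, leader = NULL,
                            provenance = "") {
  fs <- as_nuc(full_separator); ss <- as_nuc(default_synseparator)
  if (nchar(fs) < 6L || nchar(fs) > 25L) {
    abort_input("full_separator length must be in [6, 25] nt")
  }
  if (nchar(ss) < 1L || nchar(ss) > 8L) {
    abort_input("default_synseparator length must be in [1, 8] nt")
  }
  structure(
    list(species_name = species_name,
         mature_repeat = as_nuc(mature_repeat),
         full_separator = fs,
         default_synseparator = ss,
         leader = if (!is.null(leader)) as_nuc(leader) else NULL,
         provenance = provenance),
    class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile %s>\n  repeat:        %s\n  separator:     %s\n  synSeparator:  %s\n",
              x$species_name, as.character(x$mature_repeat),
              as.character(x$full_separator),
              as.character(x$default_synseparator)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read / write the species registry
#'
#' The registry is a plain-text key-value config with one `[section]` per
#' species. Recognized keys: `mature_repeat`, `full_separator`,
#' `default_synseparator`, `leader`, `provenance`. The packaged default
#' registry is at `system.file("extdata", "species_registry.cfg",
#' package = "cas12array")`.
#'
#' @param file Registry path; default the packaged registry.
#' @return Named list of [species_profile()] objects.
#' @export
read_species_registry <- function(file = default_registry_path()) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  profiles <- list()
  cur <- NULL; fields <- list()
  flush <- function() {
    if (is.null(cur)) return()
    profiles[[cur]] <<- species_profile(
      species_name = cur,
      mature_repeat = fields$mature_repeat,
      full_separator = fields$full_separator,
      default_synseparator = fields$default_synseparator,
      leader = fields$leader,
      provenance = fields$provenance %||% "")
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush()
      cur <- sub("^\\[(.+)\\]$", "\\1", ln)
      fields <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1L]]
      fields[[trimws(kv[1L])]] <- trimws(kv[2L])
    }
  }
  flush()
  profiles
}

default_registry_path <- function() {
  system.file("extdata", "species_registry.cfg", package = "cas12array",
              mustWork = TRUE)
}

#' Look up one species profile
#'
#' @param species Section name in the registry (e.g. `"LbCas12a"`).
#' @inheritParams read_species_registry
#' @export
get_species_profile <- function(species = "LbCas12a",
                                file = default_registry_path()) {
  reg <- read_species_registry(file)
  if (!species %in% names(reg)) {
    abort_input(sprintf("species '%s' not in registry (%s); available: %s",
                        species, file, paste(names(reg), collapse = ", ")))
  }
  reg[[species]]
}
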