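# Shared fixtures: all test inputs are generated in code under fixed seeds.

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_profile <- function() {
  species_profile("TestCas12a",
                  mature_repeat = "AATTTCTACTAAGTGTAGAT",
                  full_separator = "GTCTAAGAACTTAAAT",
                  default_synseparator = "AAAT")
}

# Two-gRNA assay geometry: 57-nt leader, 20-nt repeat, 21/22-nt spacers,
# 138-nt 3' flank -> fragments 57/41/42/158 without separators.
assay_design <- function(policy_entry = "none") {
  build_array(
    list(generate_spacer(21, 0.70, seed = 11, name = "dummy70"),
         generate_spacer(22, 0.45, seed = 12, name = "gfp")),
    test_profile(),
    separator_policy(policy_entry, n = 3),
    include_trailing_repeat = TRUE,
    leader = random_dna(57, 13),
    three_prime_flank = random_dna(138, 14))
}

# Independent brute-force enumeration of nested pairings (oracle for the
# weighted pairing DP); exponential, use only for short sequences.
enum_pairing <- function(seq, min_loop = 3L) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1L]]
  w <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1, 0)
  }
  best <- function(i, j) {
    if (i >= j) return(0)
    out <- best(i + 1L, j)  # i unpaired
    if (i + min_loop + 1L <= j) {
      for (k in (i + min_loop + 1L):j) {
        wk <- w(s[i], s[k])
        if (wk > 0) {
          out <- max(out, wk + best(i + 1L, k - 1L) + best(k + 1L, j))
        }
      }
    }
    out
  }
  best(1L, length(s))
}
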