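test_that("sequence normalization uppercases, converts T/U, rejects bad symbols", {
  expect_equal(as.character(normalize_sequence("aatt", "DNA")), "AATT")
  expect_equal(as.character(normalize_sequence("AAUU", "DNA")), "AATT")
  expect_equal(as.character(normalize_sequence("aatt", "RNA")), "AAUU")
  expect_error(normalize_sequence("AAXT", "DNA"), "position 3")
  expect_error(normalize_sequence("", "DNA"), "non-empty")
  # idempotent
  for (seed in 1:5) {
    s <- random_dna(30, seed)
    once <- normalize_sequence(s, "DNA")
    expect_identical(normalize_sequence(as.character(once), "DNA"), once)
  }
})

test_that("gc_fraction counts G/C with S/W resolution and rejects other codes", {
  expect_equal(gc_fraction("AAAT"), 0)
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("SSWW"), 0.5)
  expect_error(gc_fraction("ANAT"), "ambiguity")
  expect_equal(gc_fraction("ANAT", permissive = TRUE), 0.125)
})

test_that("reverse_complement matches a brute-force oracle and is an involution", {
  expect_equal(as.character(reverse_complement("AAAT")), "ATTT")
  expect_equal(as.character(reverse_complement("GATC")), "GATC")
  # independent oracle: complement each base, then reverse
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  brute_rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  expect_equal(as.character(reverse_complement("GGGAAACCC")), brute_rc("GGGAAACCC"))
  for (seed in 1:20) {
    s <- random_dna(25, seed)
    expect_equal(as.character(reverse_complement(s)), brute_rc(s))
    expect_equal(as.character(reverse_complement(reverse_complement(s))), s)
  }
  expect_error(reverse_complement(nuc_seq("AAUU", "RNA")), "DNA")
})

test_that("generate_spacer realizes the exact GC count, deterministically per seed", {
  for (L in c(1L, 7L, 20L, 50L)) {
    for (g in seq(0, 1, by = 0.1)) {
      sp <- generate_spacer(L, g, seed = 1000L + L)
      expect_equal(sp$gc_fraction, floor(g * L + 0.5) / L)
      expect_equal(nchar(sp$seq), L)
    }
  }
  a <- generate_spacer(20, 0.7, seed = 42)
  b <- generate_spacer(20, 0.7, seed = 42)
  expect_identical(as.character(a$seq), as.character(b$seq))
  expect_false(identical(as.character(generate_spacer(20, 0.7, seed = 43)$seq),
                         as.character(a$seq)))
  # gc_target clamped, never errors
  expect_equal(generate_spacer(20, 1.7, seed = 1)$gc_fraction, 1)
})

test_that("benchmark library has 51 spacers with the exact decile recipe", {
  lib <- generate_benchmark_library(seed = 7)
  tab <- library_table(lib)
  expect_equal(nrow(tab), 51L)
  expect_true(all(nchar(tab$sequence) == 20L))
  expect_true(all(!duplicated(tab$name)))
  expect_equal(sum(abs(tab$gc_fraction - 0.10) < 1e-9), 5L)
  # 45 decile spacers (5 each, 10-90%) + 6 pilots (one each, 30-80%)
  counts <- table(factor(round(tab$gc_fraction * 10) * 10, levels = seq(10, 90, 10)))
  expect_equal(as.integer(counts), c(5L, 5L, 6L, 6L, 6L, 6L, 6L, 6L, 5L))
  # different seed: same GC histogram, different sequences
  tab2 <- library_table(generate_benchmark_library(seed = 8))
  expect_equal(sort(tab2$gc_fraction), sort(tab$gc_fraction))
  expect_false(any(tab2$sequence == tab$sequence))
})

test_that("species registry loads editable profiles with provenance", {
  reg <- read_species_registry()
  expect_true(all(c("LbCas12a", "AsCas12a") %in% names(reg)))
  lb <- get_species_profile("LbCas12a")
  expect_equal(as.character(lb$default_synseparator), "AAAT")
  expect_equal(as.character(get_species_profile("AsCas12a")$default_synseparator),
               "TTTT")
  expect_true(nchar(lb$full_separator) >= 6 && nchar(lb$full_separator) <= 25)
  expect_match(lb$provenance, "synthetic placeholder")
  expect_error(get_species_profile("NoSuchCas"), "not in registry")
  # custom registry files override the packaged defaults
  f <- tempfile(fileext = ".cfg")
  writeLines(c("[MyCas]", "mature_repeat = AATTTCTACT",
               "full_separator = TTTTAAAATT", "default_synseparator = TA"), f)
  expect_equal(as.character(get_species_profile("MyCas", f)$default_synseparator), "TA")
})

test_that("FASTA and spacer input round-trips preserve sequences", {
  f <- tempfile(fileext = ".fa")
  seqs <- c(s1 = random_dna(40, 1), s2 = random_dna(61, 2))
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
  sp <- read_spacers(f)
  expect_equal(vapply(sp, function(x) x$name, ""), c("s1", "s2"))
  # plain text with names
  g <- tempfile(fileext = ".txt")
  writeLines(c("a\tACGTACGT", "b\tTTTTAAAA"), g)
  sp2 <- read_spacers(g)
  expect_equal(as.character(sp2[[2]]$seq), "TTTTAAAA")
})
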