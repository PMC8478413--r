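test_that("sliding_gc emits base windows plus 3'-anchored shrunk windows", {
  p <- sliding_gc(strrep("A", 20))
  expect_equal(nrow(p), 19L)
  expect_true(all(p$gc == 0))
  # window-count formula across lengths and widths
  for (L in c(5, 8, 20, 33)) {
    s <- random_dna(L, L)
    for (bw in c(3, 5)) {
      p <- sliding_gc(s, base_width = bw, min_width = 2)
      expect_equal(nrow(p), (L - bw + 1) + (bw - 2))
    }
  }
  # brute-force per-window oracle
  s <- "ATGCGCATATATATATATAT"
  p <- sliding_gc(s)
  ch <- strsplit(s, "")[[1]]
  for (r in seq_len(nrow(p))) {
    win <- ch[(p$start[r] + 1):(p$start[r] + p$width[r])]
    expect_equal(p$gc[r], mean(win %in% c("G", "C")))
  }
  # shrunk windows all end at the 3' terminus
  expect_true(all(p$start[p$width < 5] + p$width[p$width < 5] == nchar(s)))
  expect_error(sliding_gc("ATG"), "shorter")
})

test_that("group_profiles forms response tertiles and per-window means/SEs", {
  sp <- lapply(1:6, function(i) spacer(paste0("s", i), "ATGCATGCAT"))
  g <- group_profiles(sp, responses = 6:1, n_groups = 3, base_width = 5)
  single <- sliding_gc("ATGCATGCAT")
  for (grp in 1:3) {
    expect_equal(g$gc_mean[g$group == grp], single$gc)
    expect_true(all(g$gc_se[g$group == grp] == 0))
  }
  # groups of size one: SE = 0
  sp3 <- lapply(1:3, function(i) spacer(paste0("t", i), random_dna(10, i)))
  g3 <- group_profiles(sp3, c(3, 1, 2), n_groups = 3)
  expect_true(all(g3$n == 1) && all(g3$gc_se == 0))
  # 51-spacer library with responses = 1 - gc: the low-GC spacers occupy
  # the high-response group
  lib <- generate_benchmark_library(seed = 3)
  resp <- 1 - vapply(lib$entries, function(s) s$gc_fraction, 0)
  gl <- group_profiles(lib$entries, resp)
  m <- tapply(gl$gc_mean, gl$group, mean)
  expect_lt(m[["1"]], m[["3"]])  # group 1 = highest response = lowest GC
  expect_error(group_profiles(sp3[1:2], c(1, 2), n_groups = 3), "fewer")
})

test_that("window predictive power matches an independent regression oracle", {
  lib <- generate_benchmark_library(seed = 5)
  seqs <- vapply(lib$entries, function(s) as.character(s$seq), "")
  set.seed(99)
  resp <- runif(51)
  scan <- window_predictive_power(lib$entries, resp)
  expect_equal(nrow(scan), 18L)
  for (r in seq_len(nrow(scan))) {
    wgc <- vapply(seqs, function(s)
      gc_fraction(substr(s, scan$start[r] + 1, scan$start[r] + 3)), 0)
    expected <- if (sd(wgc) == 0) 0 else summary(lm(resp ~ wgc))$r.squared
    expect_equal(scan$r2[r], expected, tolerance = 1e-10)
  }
  # whole-sequence R2 against lm
  whole_gc <- vapply(seqs, gc_fraction, 0)
  expect_equal(attr(scan, "whole_sequence_r2"),
               summary(lm(resp ~ whole_gc))$r.squared, tolerance = 1e-10)
})

test_that("window scan handles exact fits, degenerate responses, and is affine-invariant", {
  lib <- generate_benchmark_library(seed = 6)
  seqs <- vapply(lib$entries, function(s) as.character(s$seq), "")
  gc_w8 <- vapply(seqs, function(s) gc_fraction(substr(s, 8, 10)), 0)
  scan <- window_predictive_power(lib$entries, 3 - 2 * gc_w8)
  expect_equal(scan$r2[scan$start == 7], 1.0, tolerance = 1e-12)
  expect_true(all(window_predictive_power(lib$entries, rep(2, 51))$r2 == 0))
  set.seed(4); resp <- rnorm(51)
  s1 <- window_predictive_power(lib$entries, resp)
  s2 <- window_predictive_power(lib$entries, 10 - 3.5 * resp)
  expect_equal(s1$r2, s2$r2, tolerance = 1e-10)
})

test_that("anchor_3prime truncates 5' ends and pads short rows with gaps", {
  s36 <- random_dna(36, 1)
  a <- anchor_3prime(c(s36, random_dna(25, 2), random_dna(20, 3)))
  expect_equal(a$rows[[1]], substr(s36, 12, 36))
  expect_equal(nchar(a$rows), rep(25L, 3))
  expect_equal(substr(a$rows[[3]], 1, 5), "-----")
  # 3'-terminal residue is always preserved
  for (seed in 1:10) {
    s <- random_dna(sample(15:40, 1), seed)
    row <- anchor_3prime(list(s))$rows[[1]]
    expect_equal(substr(row, 25, 25), substr(s, nchar(s), nchar(s)))
  }
})

test_that("column GC profiles ignore gaps and match per-column counting", {
  allg <- aligned_set(c("GGGGGG", "GGGGGG"))
  expect_true(all(column_gc_profile(allg, 5, 2)$gc == 1))
  two <- aligned_set(c("ATATAT", "GCGCGC"))
  expect_true(all(column_gc_profile(two, 5, 2)$gc == 0.5))
  # gapped oracle
  aln <- aligned_set(c("AT-GCATG", "A--GCCTG", "GTAGC-TG"))
  prof <- column_gc_profile(aln, base_width = 5, min_width = 2)
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  colgc <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) NA_real_ else mean(col %in% c("G", "C"))
  })
  for (r in seq_len(nrow(prof))) {
    expect_equal(prof$gc[r],
                 mean(colgc[(prof$start[r] + 1):(prof$start[r] + prof$width[r])],
                      na.rm = TRUE))
  }
})

test_that("IUPAC consensus reproduces degeneracy codes and is duplication-invariant", {
  expect_equal(iupac_consensus(aligned_set(c("GTCTA", "GTTTA"))), "GTYTA")
  expect_equal(iupac_consensus(aligned_set(c("ACGT", "ACGT"))), "ACGT")
  expect_equal(iupac_consensus(aligned_set(c("A", "C", "G", "T"))), "N")
  expect_equal(iupac_consensus(aligned_set(c("A-", "C-"))), "M-")
  rows <- c("GTCTAAT", "GTTTA-T", "GTCTATT")
  expect_equal(iupac_consensus(aligned_set(rep(rows, 3))),
               iupac_consensus(aligned_set(rows)))
})

test_that("spacer set summaries report count, mean, range and decile histogram", {
  s <- spacer_set_summary(c("AAAA", "GGGG"))
  expect_equal(s$count, 2L)
  expect_equal(s$mean_gc, 0.5)
  expect_equal(c(s$min_gc, s$max_gc), c(0, 1))
  one <- spacer_set_summary("ATGC")
  expect_equal(one$mean_gc, 0.5)
  expect_equal(one$min_gc, one$max_gc)
  # 1000 spacers generated at 39% GC: mean within construction rounding
  seqs <- vapply(1:1000, function(i)
    as.character(generate_spacer(20, 0.39, seed = i)$seq), "")
  expect_equal(spacer_set_summary(seqs)$mean_gc, 0.4, tolerance = 1e-9)
})
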