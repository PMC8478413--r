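test_that("build_array places separators per site and tiles features exactly", {
  prof <- test_profile()
  sp <- list(generate_spacer(20, 0.3, 1, "a"), generate_spacer(20, 0.5, 2, "b"))
  # synSeparator upstream of every repeat: 3 repeats, 3 separators
  d <- build_array(sp, prof, separator_policy("AAAT", n = 3))
  expect_equal(sum(d$features$type == "repeat"), 3L)
  seps <- d$features[d$features$type == "separator", ]
  expect_equal(nrow(seps), 3L)
  expect_true(all(vapply(seq_len(nrow(seps)), function(i)
    substr(d$sequence, seps$start[i] + 1, seps$end[i]) == "AAAT", TRUE)))
  # no separators: exact concatenation
  d0 <- build_array(sp, prof, separator_policy("none", n = 3))
  rep_ <- as.character(prof$mature_repeat)
  expect_equal(as.character(d0$sequence),
               paste0(rep_, as.character(sp[[1]]$seq),
                      rep_, as.character(sp[[2]]$seq), rep_))
  # trailing-site-only policy: one separator, 3' of the last spacer
  d1 <- build_array(sp, prof, separator_policy(c("none", "none", "AAAT")))
  s1 <- d1$features[d1$features$type == "separator", ]
  expect_equal(nrow(s1), 1L)
  last_spacer_end <- max(d1$features$end[d1$features$type == "spacer"])
  expect_equal(s1$start, last_spacer_end)
  # features tile the sequence with no gaps or overlaps
  for (dd in list(d, d0, d1)) {
    f <- dd$features
    expect_equal(f$start, c(0L, head(f$end, -1)))
    expect_equal(tail(f$end, 1), nchar(dd$sequence))
    expect_equal(paste(vapply(seq_len(nrow(f)), function(i)
      substr(dd$sequence, f$start[i] + 1, f$end[i]), ""), collapse = ""),
      as.character(dd$sequence))
  }
  expect_error(build_array(sp, prof, separator_policy("AAAT", n = 2)),
               "policy")
})

test_that("predicted fragments reproduce the two-gRNA assay worked lengths", {
  f0 <- predicted_fragments(assay_design("none"))
  expect_equal(f0$fragment_lengths, c(57L, 41L, 42L, 158L))
  expect_equal(f0$single_grna_indices, c(2L, 3L))
  f1 <- predicted_fragments(assay_design("AAAT"))
  expect_equal(f1$fragment_lengths, c(61L, 45L, 46L, 158L))
  expect_equal(f1$single_grna_indices, c(2L, 3L))
  # AAAT everywhere vs none: every single-gRNA fragment and the leader
  # gain exactly the 4-nt separator
  expect_equal(f1$fragment_lengths[1:3] - f0$fragment_lengths[1:3],
               rep(4L, 3))
  expect_equal(f1$fragment_lengths[4], f0$fragment_lengths[4])
})

test_that("fragment lengths always sum to the transcript length", {
  prof <- test_profile()
  sp <- lapply(1:4, function(i) generate_spacer(20, 0.4, i, paste0("s", i)))
  for (pol in list("none", "AAAT", "full", c("G", "none", "AAAT", "AT", "AAT"))) {
    d <- build_array(sp, prof, separator_policy(pol, n = 5),
                     leader = random_dna(30, 1), three_prime_flank = random_dna(50, 2))
    fm <- predicted_fragments(d)
    expect_equal(sum(fm$fragment_lengths), nchar(d$sequence))
  }
  # single spacer, no trailing repeat: one cleavage site, two fragments
  d1 <- build_array(list(sp[[1]]), prof, separator_policy("none", 1),
                    include_trailing_repeat = FALSE, leader = random_dna(25, 3))
  expect_equal(length(predicted_fragments(d1)$fragment_lengths), 2L)
})

test_that("polyadenylation scan finds all overlapping sense-strand motifs", {
  h <- polya_scan("GGGAATAAAGGG")
  expect_equal(h$position, 3L)
  expect_equal(h$motif, "AATAAA")
  expect_equal(nrow(polya_scan(strrep("GC", 20))), 0L)
  expect_equal(polya_scan("AATAATAAA")$position, 3L)
  # naive substring oracle on random sequences
  for (seed in 1:10) {
    s <- random_dna(200, seed + 40)
    hits <- polya_scan(s)
    naive <- integer()
    for (p in 0:(nchar(s) - 6)) {
      if (substr(s, p + 1, p + 6) %in% POLYA_HEXAMERS) naive <- c(naive, p)
    }
    expect_equal(hits$position, naive)
  }
})

test_that("design reports combine risk, poly-A context and fragments", {
  prof <- test_profile()
  clean <- lapply(1:3, function(i)
    spacer(paste0("c", i), paste(rep(c("T", "G", "T", "T"), 5), collapse = "")))
  d <- build_array(clean, prof, separator_policy("none", 4))
  rep0 <- design_report(d, backend = "oracle")
  expect_false(any(rep0$risk$flag == "HIGH"))
  expect_equal(nrow(rep0$polya_hits), 0L)
  expect_equal(rep0$total_length, nchar(d$sequence))
  # a poly-A signal inside a spacer is reported with its feature context
  bad <- list(spacer("bad", paste0("GGGGCC", "AATAAA", "CCGGGGCC")),
              generate_spacer(20, 0.5, 5, "ok"))
  db <- build_array(bad, prof, separator_policy("none", 3))
  repb <- design_report(db, backend = "oracle")
  expect_true(any(repb$polya_hits$feature == "spacer" &
                  repb$polya_hits$feature_name == "bad"))
  # 7-spacer multiplex design under the AAAT policy: 8 repeats, 8 separators
  sp7 <- lapply(1:7, function(i) generate_spacer(20, 0.35, 60 + i, paste0("g", i)))
  d7 <- build_array(sp7, prof, separator_policy("AAAT", 8))
  expect_equal(sum(d7$features$type == "repeat"), 8L)
  expect_equal(sum(d7$features$type == "separator"), 8L)
})

test_that("GenBank round trip preserves sequence and features", {
  d <- assay_design("AAAT")
  f <- tempfile(fileext = ".gb")
  write_genbank(d, f)
  back <- read_genbank(f)
  expect_equal(as.character(back$sequence), as.character(d$sequence))
  expect_equal(back$features$start, d$features$start)
  expect_equal(back$features$end, d$features$end)
  expect_equal(back$features$type, d$features$type)
  expect_equal(back$features$name, d$features$name)
})
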