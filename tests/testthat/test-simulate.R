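# Synthetic-data generators: determinism, construction guarantees, and
# round-trip consistency with the caller.

test_that("make_locus is deterministic and verified by scan", {
  a <- make_locus(seed = 12)
  b <- make_locus(seed = 12)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$planted, b$planted)

  # every 10-mer unique (exhaustive scan)
  L <- nchar(a$sequence)
  kmers <- substring(a$sequence, 1:(L - 9), 10:L)
  expect_equal(anyDuplicated(kmers), 0L)

  # planted repeats present at the stated offsets with exact microhomology
  pairs <- default_mh_pairs()
  cut <- a$cut_site
  for (p in seq_len(nrow(pairs))) {
    left <- substr(
      a$sequence,
      cut - pairs$left_gap[p] - pairs$mh_len[p] + 1, cut - pairs$left_gap[p]
    )
    right <- substr(
      a$sequence,
      cut + pairs$right_gap[p] + 1, cut + pairs$right_gap[p] + pairs$mh_len[p]
    )
    expect_identical(left, right)
    expect_identical(a$planted$mh_len[p], pairs$mh_len[p])
    expect_identical(a$planted$mh_seq[p], left)
  }
})

test_that("simulate_reads is byte-identical under a fixed seed", {
  loc <- make_locus(seed = 1)
  a <- simulate_reads(loc, n_reads = 150, seed = 33)
  b <- simulate_reads(loc, n_reads = 150, seed = 33)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  f1 <- withr::local_tempfile(fileext = ".fastq.gz")
  f2 <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(a$reads, f1)
  write_fastq(b$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_fastq(f1), a$reads)
})

test_that("a pure-intact mixture reproduces the reference amplicon", {
  loc <- make_locus(seed = 1)
  mix <- c(intact = 1, mhd = 0, tins = 0, nhej_ins1 = 0, nhej_del = 0, long_del = 0)
  sim <- simulate_reads(loc, n_reads = 40, mixture = mix, seed = 3,
                        substitution_rate = 0, ambiguity_rate = 0)
  trimmed <- trim_reads(sim$reads, loc$primer_fwd)
  after_primer <- substr(loc$sequence, nchar(loc$primer_fwd) + 1, nchar(loc$sequence))
  expect_true(all(startsWith(after_primer, trimmed$sequence)))
  calls <- call_junctions(trimmed, loc)
  expect_true(all(calls$status == "INTACT"))
})

test_that("a pure-MHD mixture yields only planted microhomology deletions", {
  loc <- make_locus(seed = 2)
  mix <- c(intact = 0, mhd = 1, tins = 0, nhej_ins1 = 0, nhej_del = 0, long_del = 0)
  sim <- simulate_reads(loc, n_reads = 120, mixture = mix, seed = 5,
                        substitution_rate = 0, ambiguity_rate = 0)
  calls <- call_junctions(trim_reads(sim$reads, loc$primer_fwd), loc)
  expect_true(all(calls$status == "PASS"))
  expect_true(all(calls$junction_key %in% loc$planted$junction_key))
  m <- match(calls$junction_key, loc$planted$junction_key)
  expect_equal(calls$mh_len, loc$planted$mh_len[m])
})

test_that("templated insertions come from the flanking window, direct or inverted", {
  loc <- make_locus(seed = 3)
  mix <- c(intact = 0, mhd = 0, tins = 1, nhej_ins1 = 0, nhej_del = 0, long_del = 0)
  sim <- simulate_reads(loc, n_reads = 60, mixture = mix, seed = 7,
                        substitution_rate = 0, ambiguity_rate = 0)
  expect_true(all(nchar(sim$truth$insertion) >= 5 & nchar(sim$truth$insertion) <= 30))
  window <- substr(loc$sequence, loc$cut_site - 50, loc$cut_site + 50)
  found <- vapply(sim$truth$insertion, function(ins) {
    grepl(ins, window, fixed = TRUE) ||
      grepl(ins, as.character(Biostrings::reverseComplement(Biostrings::DNAString(window))),
            fixed = TRUE)
  }, logical(1))
  expect_true(all(found))
})

test_that("two-condition simulation depletes TMEJ classes and re-channels to NHEJ", {
  mix <- default_event_mixture()
  scaled <- scale_tmej_mixture(mix, 0.25)
  expect_equal(sum(scaled), 1)
  expect_equal(unname(scaled["mhd"] / mix["mhd"]), 0.25, ignore_attr = TRUE)
  expect_equal(unname(scaled["tins"] / mix["tins"]), 0.25, ignore_attr = TRUE)
  expect_gt(scaled[["nhej_ins1"]], mix[["nhej_ins1"]])
  expect_equal(scaled[["intact"]], mix[["intact"]])

  # factor 0: no TMEJ-class reads at all in the null condition
  loc <- make_locus(seed = 1)
  sim0 <- simulate_two_conditions(loc, n_reads = 300, depletion = 0, seed = 9,
                                  substitution_rate = 0, ambiguity_rate = 0)
  expect_false(any(sim0$polq_null$truth$class %in% c("mhd", "tins")))
  expect_true(any(sim0$wt$truth$class %in% c("mhd", "tins")))
})

test_that("injected isolated substitutions near the break are filtered at >=99%", {
  loc <- make_locus(seed = 4)
  ref <- loc$sequence
  cut <- loc$cut_site
  # an error model emitting only artifact-type events: one substitution at
  # distance 3-10 from the cut, neighbors untouched
  reads <- character(0)
  for (d in 3:10) {
    for (side in c(-1, 1)) {
      pos <- if (side < 0) cut - d + 1 else cut + d
      for (b in setdiff(c("A", "C", "G", "T"), substr(ref, pos, pos))) {
        reads <- c(reads, paste0(substr(ref, 1, pos - 1), b,
                                 substr(ref, pos + 1, nchar(ref))))
      }
    }
  }
  calls <- call_junctions(reads, loc)
  expect_gte(mean(calls$status == "SUBSTITUTION_ARTIFACT"), 0.99)
})

test_that("ddPCR and qPCR table generators are deterministic", {
  w1 <- simulate_ddpcr(seed = 19)
  w2 <- simulate_ddpcr(seed = 19)
  expect_identical(w1, w2)
  q1 <- simulate_qpcr(c(wt = 1, olaparib = 0.61), seed = 23)
  q2 <- simulate_qpcr(c(wt = 1, olaparib = 0.61), seed = 23)
  expect_identical(q1, q2)
  # delta-delta Ct recovers the programmed truth
  rel <- quantify_qpcr(q1, calibrator = "wt")
  expect_equal(rel$relative[rel$sample_id == "olaparib"], 0.61, tolerance = 0.05)
})
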