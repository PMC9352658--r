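# TMEJ / NHEJ / other classification and contribution arithmetic.

toy_row <- function(key, del, ins_len, mh) {
  data.frame(
    junction_key = key, deletion_length = del, ins_len = ins_len, mh_len = mh,
    stringsAsFactors = FALSE
  )
}

test_that("classification follows signature membership then the size/MH rule", {
  sig_keys <- c("6:6:")
  # +1 insertion, no MH, not in signature -> NHEJ
  expect_equal(as.character(classify_junctions(toy_row("0:0:A", 0L, 1L, 0L), sig_keys)), "NHEJ")
  # 7 nt deletion with 3 nt MH, in signature -> TMEJ
  expect_equal(as.character(classify_junctions(toy_row("6:6:", 12L, 0L, 4L), sig_keys)), "TMEJ")
  # 12 nt templated insertion: not a deletion, cannot be signature -> OTHER
  expect_equal(
    as.character(classify_junctions(toy_row("0:0:GGATCCAAGCTT", 0L, 12L, 0L), sig_keys)),
    "OTHER"
  )
  # long-MH deletion not in the signature -> OTHER
  expect_equal(as.character(classify_junctions(toy_row("9:0:", 9L, 0L, 3L), sig_keys)), "OTHER")
  # signature membership overrides the NHEJ size rule
  expect_equal(
    as.character(classify_junctions(toy_row("2:1:", 3L, 0L, 0L), c("2:1:"))),
    "TMEJ"
  )
  # 4 nt deletion with 1 nt MH -> NHEJ ("indels < 5 bp and MH < 2 bp")
  expect_equal(as.character(classify_junctions(toy_row("2:2:", 4L, 0L, 1L), sig_keys)), "NHEJ")
  # boundary: total indel exactly 5 is not NHEJ
  expect_equal(as.character(classify_junctions(toy_row("3:2:", 5L, 0L, 0L), sig_keys)), "OTHER")
  # boundary: MH exactly 2 is not NHEJ
  expect_equal(as.character(classify_junctions(toy_row("2:2:", 4L, 0L, 2L), sig_keys)), "OTHER")
})

test_that("intact reads are rejected by the classifier", {
  loc <- make_locus(seed = 1)
  calls <- call_junctions(loc$sequence, loc)
  expect_error(classify_junctions(calls, character(0)), "repair product")
})

test_that("pathway fractions sum to one and deltas to zero", {
  panel <- junction_key_panel(12)
  keys <- panel
  keys$prob <- NULL
  keys$mh_len <- c(0L, 3L, 0L, 0L, 2L, 0L, 0L, 0L, 4L, 0L, 0L, 0L)
  keys$count <- c(40L, 30L, 25L, 20L, 15L, 10L, 8L, 6L, 4L, 3L, 2L, 1L)
  t1 <- junction_table(keys, sample_id = "wt")
  keys$count <- rev(keys$count)
  t2 <- junction_table(keys, sample_id = "treated")
  fr <- pathway_fractions(list(wt = t1, treated = t2), c("1:1:", "2:1:"))
  expect_equal(fr$frac_tmej + fr$frac_nhej + fr$frac_other, c(1, 1))
  d <- tmej_contribution(fr, "wt")
  expect_equal(d$delta_tmej + d$delta_nhej + d$delta_other, c(0, 0))
  expect_equal(unlist(d[d$sample_id == "wt", -1]), c(0, 0, 0), ignore_attr = TRUE)
  expect_error(tmej_contribution(fr, "missing"), "not found")
})

test_that("a table of only NHEJ-class reads gives fractions (0, 1, 0)", {
  keys <- data.frame(
    junction_key = c("0:0:A", "1:0:"), del_left = c(0L, 1L), del_right = 0L,
    deletion_length = c(0L, 1L), insertion = c("A", ""), ins_len = c(1L, 0L),
    mh_len = 0L, mh_seq = "", count = c(60L, 40L), stringsAsFactors = FALSE
  )
  tbl <- junction_table(keys, sample_id = "s")
  fr <- pathway_fractions(tbl, character(0))
  expect_equal(c(fr$frac_tmej, fr$frac_nhej, fr$frac_other), c(0, 1, 0))
})

test_that("empty signature means no TMEJ-class reads; empty table errors", {
  loc <- make_locus(seed = 2)
  sim <- simulate_reads(loc, n_reads = 300, seed = 3,
                        substitution_rate = 0, ambiguity_rate = 0)
  tbl <- tabulate_junctions(call_junctions(trim_reads(sim$reads, loc$primer_fwd), loc))
  fr <- pathway_fractions(tbl, character(0))
  expect_equal(fr$frac_tmej, 0)
  empty <- tabulate_junctions(call_junctions(character(0), loc))
  expect_error(pathway_fractions(empty, character(0)), "repair_total")
})

test_that("recovered fractions match a known mixture within binomial bounds", {
  loc <- make_locus(seed = 1)
  mix <- c(intact = 0.1, mhd = 0.18, tins = 0.09, nhej_ins1 = 0.36,
           nhej_del = 0.18, long_del = 0.09)
  sim <- simulate_reads(loc, n_reads = 4000, mixture = mix, seed = 41,
                        substitution_rate = 0, ambiguity_rate = 0)
  tbl <- tabulate_junctions(call_junctions(trim_reads(sim$reads, loc$primer_fwd), loc))
  fr <- pathway_fractions(tbl, loc$planted$junction_key)
  n <- fr$n_repair
  expected <- c(tmej = 0.2, nhej = 0.6, other = 0.2) # conditional on repair
  got <- c(fr$frac_tmej, fr$frac_nhej, fr$frac_other)
  half <- 1.96 * sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(got - expected) <= half))
})
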