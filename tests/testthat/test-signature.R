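# Depletion testing and the Benjamini-Hochberg signature set.

panel_tables <- function(counts_wt, counts_null) {
  panel <- junction_key_panel(length(counts_wt))
  keys <- panel
  keys$prob <- NULL
  keys$count <- counts_wt
  wt <- junction_table(keys[keys$count > 0, ], sample_id = "wt")
  keys$count <- counts_null
  nl <- junction_table(keys[keys$count > 0, ], sample_id = "null")
  list(wt = wt, null = nl)
}

test_that("depletion p-values match the exact hypergeometric/Fisher oracle", {
  # 50/1000 in both conditions: no depletion, p ~ 0.54
  tabs <- panel_tables(c(50, 950, rep(0, 58)), c(50, 950, rep(0, 58)))
  res <- test_depletion(tabs$wt, tabs$null)
  p_even <- res$p_value[res$junction_key == "1:1:"]
  fisher_even <- stats::fisher.test(
    matrix(c(50, 950, 50, 950), 2, byrow = TRUE),
    alternative = "less"
  )$p.value
  expect_equal(p_even, fisher_even, tolerance = 1e-12)
  expect_gt(p_even, 0.5)
  expect_lt(p_even, 0.6)

  # 50/1000 vs 0/1000: strong depletion
  tabs2 <- panel_tables(c(50, 950, rep(0, 58)), c(0, 1000, rep(0, 58)))
  res2 <- test_depletion(tabs2$wt, tabs2$null)
  p_dep <- res2$p_value[res2$junction_key == "1:1:"]
  fisher_dep <- stats::fisher.test(
    matrix(c(0, 1000, 50, 950), 2, byrow = TRUE),
    alternative = "less"
  )$p.value
  expect_equal(p_dep, fisher_dep, tolerance = 1e-12)
  expect_lt(p_dep, 1e-10)

  # identical tables: symmetry forces p >= 0.5 everywhere
  counts <- c(200, 150, 100, 80, 60, 40, 30, 20, 10, 10, rep(5, 50))
  tabs3 <- panel_tables(counts, counts)
  res3 <- test_depletion(tabs3$wt, tabs3$null)
  expect_true(all(res3$p_value >= 0.5))
})

test_that("only deletion-only junctions are tested", {
  panel <- junction_key_panel(4)
  keys <- panel
  keys$prob <- NULL
  keys$count <- c(100L, 100L, 100L, 100L)
  # make one junction an insertion product
  keys$junction_key[2] <- "0:0:GATTACA"
  keys$ins_len[2] <- 7L
  keys$deletion_length[2] <- 0L
  wt <- junction_table(keys, sample_id = "wt")
  nl <- junction_table(keys, sample_id = "null")
  res <- test_depletion(wt, nl)
  expect_equal(nrow(res), 3L)
  expect_false("0:0:GATTACA" %in% res$junction_key)
})

test_that("BH step-up matches its definition and the brute-force oracle", {
  expect_equal(bh_reject(c(0.001, 0.02, 0.04, 0.5), fdr = 0.10),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_reject(rep(1, 10), 0.10), rep(FALSE, 10))
  expect_equal(bh_reject(0.05, 0.10), TRUE)
  expect_equal(bh_reject(numeric(0), 0.10), logical(0))

  set.seed(31)
  for (k in 1:1000) {
    m <- sample(1:40, 1)
    p <- switch(sample(3, 1),
      runif(m),
      rbeta(m, 0.3, 4), # enriched small p-values
      round(runif(m), 2) # ties
    )
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(bh_reject(p, q), oracle_bh(p, q))
  }
})

test_that("replicate tables are pooled before testing", {
  tabs <- panel_tables(c(30, 970, rep(0, 58)), c(10, 990, rep(0, 58)))
  half <- function(t) {
    k <- as.data.frame(t)
    k$count <- k$count %/% 2L
    junction_table(k, sample_id = attr(t, "sample_id"))
  }
  res_pooled <- test_depletion(tabs$wt, tabs$null)
  res_reps <- test_depletion(list(half(tabs$wt), half(tabs$wt)),
                             list(half(tabs$null), half(tabs$null)))
  expect_equal(res_pooled$p_value, res_reps$p_value, tolerance = 1e-12)
})

test_that("false-discovery proportion is controlled under the null", {
  # WT and null drawn from the same junction distribution; every rejection is
  # a false discovery
  panel <- junction_key_panel(40)
  fdp <- vapply(1:40, function(k) {
    wt <- simulate_junction_table(panel, 4000, seed = 1000 + k)
    nl <- simulate_junction_table(panel, 4000, seed = 5000 + k)
    sig <- tmej_signature(wt, nl, fdr = 0.10)
    # all null: any rejection is false, so FDP = V / max(R, 1) is 1{R > 0}
    as.numeric(length(sig$members) > 0)
  }, numeric(1))
  expect_lte(mean(fdp), 0.10 + 2 * stats::sd(fdp) / sqrt(length(fdp)))
})

test_that("planted depleted junctions are recovered into the signature", {
  loc <- make_locus(seed = 1)
  sim <- simulate_two_conditions(loc,
    n_reads = 4000, depletion = 0.25, seed = 77,
    substitution_rate = 0, ambiguity_rate = 0
  )
  wt <- tabulate_junctions(call_junctions(trim_reads(sim$wt$reads, loc$primer_fwd), loc))
  nl <- tabulate_junctions(call_junctions(trim_reads(sim$polq_null$reads, loc$primer_fwd), loc))
  sig <- tmej_signature(wt, nl, fdr = 0.10)
  expect_true(all(loc$planted$junction_key %in% sig$members))
  expect_output(print(sig), "tmej_signature")
})
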