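# qPCR, ddPCR, gene-targeting, clonogenic quantification arithmetic.

test_that("delta-delta Ct closed forms and scale invariance", {
  expect_equal(relative_signature(26, 21, 26, 21), 1.0)
  expect_equal(relative_signature(26, 21, 24, 21), 0.25)
  # random Ct table vs an independently coded oracle
  set.seed(5)
  for (k in 1:50) {
    ct <- runif(4, 15, 35)
    eff <- runif(1, 1.8, 2.0)
    oracle <- eff^(-((ct[1] - ct[2]) - (ct[3] - ct[4])))
    expect_equal(relative_signature(ct[1], ct[2], ct[3], ct[4], eff), oracle,
                 tolerance = 1e-12)
    # shifting every Ct by a constant changes nothing
    expect_equal(relative_signature(ct[1] + 3, ct[2] + 3, ct[3] + 3, ct[4] + 3, eff),
                 oracle, tolerance = 1e-12)
  }
})

test_that("spike-in normalization cancels transfection efficiency", {
  expect_equal(spike_in_normalized_tmej(4, 2, 4, 2), 1.0)
  expect_equal(spike_in_normalized_tmej(2, 2, 4, 2), 0.5)
  set.seed(9)
  for (k in 1:20) {
    jitter <- runif(1, 0.5, 2) # both channels scale with transfection
    expect_equal(
      spike_in_normalized_tmej(3 * jitter, 2 * jitter, 6, 4),
      spike_in_normalized_tmej(3, 2, 6, 4),
      tolerance = 1e-12
    )
  }
  expect_error(spike_in_normalized_tmej(1, 0, 4, 2), "spike-in")
})

test_that("Poisson droplet estimator: closed forms and vanishing bias", {
  expect_equal(poisson_concentration(0, 20000), 0)
  f <- 1 - exp(-1)
  expect_equal(poisson_concentration(round(20000 * f), 20000), 1, tolerance = 1e-3)
  expect_error(poisson_concentration(100, 100), "saturated")

  # bias shrinks with droplet number
  set.seed(13)
  bias <- vapply(c(2000L, 20000L), function(n) {
    lam <- vapply(1:200, function(k) {
      poisson_concentration(rbinom(1, n, 1 - exp(-0.5)), n)
    }, numeric(1))
    abs(mean(lam) - 0.5)
  }, numeric(1))
  expect_lt(bias[2], 0.01 * 0.5)
  expect_lt(bias[2], bias[1] + 0.002)
})

test_that("ssDNA fraction recovers simulated truth and is scale invariant", {
  wells <- simulate_ddpcr(
    ssdna = c(flank_d8 = 0.091), broken = 0.3, n_droplets = 1000000L, seed = 7
  )
  got <- ssdna_fraction(wells, "flank_d8")
  expect_lt(abs(got - 0.091), 0.01)

  # identical mock and ExoI wells: no ssDNA
  w0 <- simulate_ddpcr(ssdna = c(flank_d8 = 0), broken = 0, n_droplets = 50000L, seed = 8)
  w0$positives[w0$amplicon == "flank_d8" & w0$treatment == "exoI"] <-
    w0$positives[w0$amplicon == "flank_d8" & w0$treatment == "mock"]
  w0$positives[w0$amplicon == "ref1" & w0$treatment == "exoI"] <-
    w0$positives[w0$amplicon == "ref1" & w0$treatment == "mock"]
  expect_equal(ssdna_fraction(w0, "flank_d8"), 0)

  # ratio estimator: rescaling all droplet totals leaves the result unchanged
  scaled <- wells
  scaled$positives <- scaled$positives * 3L
  scaled$total <- scaled$total * 3L
  expect_equal(ssdna_fraction(scaled, "flank_d8"), got, tolerance = 1e-12)
})

test_that("PstI-resistance variant reproduces the same resected truth", {
  wells <- simulate_ddpcr(
    ssdna = c(flank_d8 = 0.091), ssdna_psti = 0.091,
    broken = 0.3, n_droplets = 1000000L, seed = 11
  )
  expect_lt(abs(psti_resistant_fraction(wells) - 0.091), 0.01)
})

test_that("broken and deleted fractions recover simulated truth", {
  # uncut sample
  w0 <- simulate_ddpcr(ssdna = c(flank_d8 = 0), broken = 0, n_droplets = 1000000L, seed = 21)
  bd0 <- broken_deleted_fractions(w0)
  expect_lt(abs(bd0[["broken_fraction"]]), 0.01)
  expect_lt(abs(bd0[["deletion_fraction"]]), 0.01)

  # 30% cut, no deletions past the flank
  w1 <- simulate_ddpcr(ssdna = c(flank_d8 = 0), broken = 0.3, n_droplets = 1000000L, seed = 22)
  expect_lt(abs(broken_deleted_fractions(w1)[["broken_fraction"]] - 0.30), 0.01)

  # 10% two-strand deletions past the flank
  w2 <- simulate_ddpcr(
    ssdna = c(flank_d8 = 0.02), deleted = c(flank_d8 = 0.10),
    broken = 0.3, n_droplets = 1000000L, seed = 23
  )
  expect_lt(abs(broken_deleted_fractions(w2)[["deletion_fraction"]] - 0.10), 0.01)
})

test_that("resection profile is non-increasing with distance on noise-free input", {
  truth <- c(flank_d8 = 0.091, flank_d284 = 0.038, flank_d527 = 0.017)
  # expected (noise-free) positives computed directly from the model
  lam0 <- 0.5
  rows <- list()
  add <- function(a, tr, lam) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = "s", amplicon = a, treatment = tr,
      positives = round(1e6 * (1 - exp(-lam))), total = 1e6
    )
  }
  add("ref1", "mock", lam0); add("ref1", "exoI", lam0)
  for (f in names(truth)) {
    add(f, "mock", lam0)
    add(f, "exoI", lam0 * (1 - truth[[f]]))
  }
  prof <- resection_profile(do.call(rbind, rows), intact_amplicon = NULL)
  expect_equal(unname(prof$ssdna), unname(truth), tolerance = 5e-3)
  expect_true(all(diff(prof$ssdna) <= 0))
})

test_that("gene targeting and clonogenic survival closed forms", {
  expect_equal(gene_targeting_fraction(0, 5), 0)
  expect_equal(gene_targeting_fraction(2, 2), 0.5)
  expect_equal(gene_targeting_fraction(3, 1), 0.75)
  expect_error(gene_targeting_fraction(0, 0), "zero")

  expect_equal(clonogenic_survival(100, 1000, 100, 1000), 1.0)
  expect_equal(clonogenic_survival(50, 1000, 100, 1000), 0.5)
  expect_error(clonogenic_survival(50, 1000, 0, 1000), "plating")
})
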