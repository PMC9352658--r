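# Quantification arithmetic for the signature qPCR, ddPCR resection,
# gene-targeting, and clonogenic survival assays.

#' Relative signature abundance by delta-delta Ct
#'
#' Signature-amplicon qPCR normalized to a reference amplicon (genome count)
#' and expressed as a fraction of a calibrator sample:
#' `efficiency^-((ct_sig - ct_ref) - (cal_sig - cal_ref))`.
#' With perfect doubling (efficiency 2) this is the classic delta-delta Ct.
#' The result is scale-free: adding a constant to every Ct leaves it
#' unchanged.
#'
#' @param ct_sig,ct_ref Ct values of the signature and reference amplicons.
#' @param cal_ct_sig,cal_ct_ref Calibrator-sample Ct values.
#' @param efficiency Amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @return Numeric: abundance as a fraction of the calibrator.
#' @examples
#' relative_signature(26, 21, 24, 21) # 2 cycles later than calibrator -> 0.25
#' @export
relative_signature <- function(ct_sig, ct_ref, cal_ct_sig, cal_ct_ref, efficiency = 2) {
  stopifnot(
    all(is.finite(ct_sig)), all(is.finite(ct_ref)),
    all(is.finite(cal_ct_sig)), all(is.finite(cal_ct_ref)), efficiency > 1
  )
  efficiency^-((ct_sig - ct_ref) - (cal_ct_sig - cal_ct_ref))
}

#' Spike-in normalized extrachromosomal TMEJ efficiency
#'
#' TMEJ substrate joining efficiency adjusted by the NHEJ spike-in control
#' (which corrects for transfection efficiency) and expressed as a fraction of
#' the calibrator pair: `(tmej/nhej) / (cal_tmej/cal_nhej)`.
#'
#' @param tmej,nhej Joining efficiencies of the TMEJ substrate and the NHEJ
#'   spike-in for the sample.
#' @param cal_tmej,cal_nhej The same pair for the calibrator.
#' @return Numeric fraction of calibrator.
#' @export
spike_in_normalized_tmej <- function(tmej, nhej, cal_tmej, cal_nhej) {
  if (any(nhej <= 0) || any(cal_nhej <= 0)) {
    stop("NHEJ spike-in efficiency must be > 0 (spike-in failure)", call. = FALSE)
  }
  stopifnot(all(tmej >= 0), all(cal_tmej > 0))
  (tmej / nhej) / (cal_tmej / cal_nhej)
}

#' Poisson concentration estimate from droplet counts
#'
#' Mean template copies per droplet from the fraction of positive droplets:
#' `lambda = -ln(1 - positives/total)`.
#'
#' @param positives Number of positive droplets.
#' @param total Total droplets (must exceed `positives`; a fully positive
#'   well is saturated and carries no concentration information).
#' @return Estimated mean copies per droplet.
#' @examples
#' poisson_concentration(0, 20000)                      # 0
#' poisson_concentration(round(20000 * (1 - exp(-1))), 20000) # ~1
#' @export
poisson_concentration <- function(positives, total) {
  stopifnot(all(positives >= 0), all(total > 0), length(positives) == length(total))
  if (any(positives >= total)) {
    stop("saturated well: positives must be < total", call. = FALSE)
  }
  -log1p(-positives / total)
}

# merged-well estimator: sum positives and totals over wells matching
# amplicon/treatment, then apply the Poisson transform
ddpcr_lambda <- function(wells, amplicon, treatment) {
  sel <- wells$amplicon == amplicon & wells$treatment == treatment
  if (!any(sel)) {
    stop(sprintf("no wells for amplicon '%s', treatment '%s'", amplicon, treatment),
      call. = FALSE
    )
  }
  poisson_concentration(sum(wells$positives[sel]), sum(wells$total[sel]))
}

clamp01 <- function(x, label = "fraction") {
  if (x < 0 || x > 1) {
    message(sprintf("%s = %.4f clamped to [0, 1]", label, x))
  }
  min(max(x, 0), 1)
}

#' ssDNA (resected) fraction from ExoI-sensitivity ddPCR
#'
#' Thermolabile exonuclease I degrades the 3' ssDNA tails produced by 5'-to-3'
#' end resection, so templates resected past a flank amplicon lose
#' amplification after ExoI treatment. The resected fraction at that flank
#' distance is the drop in the reference-normalized flank concentration:
#' `(lambda_flank/lambda_ref)_mock - (lambda_flank/lambda_ref)_exoI`,
#' clamped to `[0, 1]`. Wells for one quantity are merged by summing droplet
#' counts before the Poisson transform.
#'
#' @param wells Data.frame of droplet counts with columns `amplicon`,
#'   `treatment` (`"mock"` / `"exoI"`), `positives`, `total`.
#' @param flank_amplicon Name of the break-proximal flank amplicon (e.g.
#'   `"flank_d8"`).
#' @param ref_amplicon Name of the reference amplicon (default `"ref1"`).
#' @return Fraction of genomes with ssDNA extending past the flank distance.
#' @export
ssdna_fraction <- function(wells, flank_amplicon, ref_amplicon = "ref1") {
  r_mock <- ddpcr_lambda(wells, flank_amplicon, "mock") /
    ddpcr_lambda(wells, ref_amplicon, "mock")
  r_exo <- ddpcr_lambda(wells, flank_amplicon, "exoI") /
    ddpcr_lambda(wells, ref_amplicon, "exoI")
  clamp01(r_mock - r_exo, sprintf("ssDNA fraction (%s)", flank_amplicon))
}

#' ssDNA fraction from PstI-resistance ddPCR
#'
#' Restriction-resistance variant of the resection assay: PstI cuts only
#' double-stranded DNA, so templates whose PstI site has been resected to
#' ssDNA survive digestion. The resistant (resected) fraction is
#' `(lambda_flankPstI / lambda_ref)` measured on PstI-digested DNA.
#'
#' @param wells Data.frame as in [ssdna_fraction()], with treatment `"psti"`.
#' @param flank_psti_amplicon Amplicon spanning the PstI site (default
#'   `"flank_psti"`).
#' @param ref_amplicon Reference amplicon (default `"ref1"`).
#' @return Resistant (resected) fraction in `[0, 1]`.
#' @export
psti_resistant_fraction <- function(wells, flank_psti_amplicon = "flank_psti",
                                    ref_amplicon = "ref1") {
  clamp01(
    ddpcr_lambda(wells, flank_psti_amplicon, "psti") /
      ddpcr_lambda(wells, ref_amplicon, "psti"),
    "PstI-resistant fraction"
  )
}

#' Broken-end and two-strand deletion fractions
#'
#' The "intact" amplicon spans the cut site and only amplifies unbroken (or
#' precisely rejoined) templates; the flank amplicon fails when both strands
#' are deleted past the flank distance. Fractions relative to the reference
#' amplicon: `broken = 1 - lambda_intact/lambda_ref` and
#' `deleted = 1 - lambda_flank_mock/lambda_ref`, both clamped to `[0, 1]`.
#'
#' @param wells Data.frame as in [ssdna_fraction()].
#' @param intact_amplicon Cut-spanning amplicon (default `"intact"`).
#' @param flank_amplicon Flank amplicon (default `"flank_d8"`).
#' @param ref_amplicon Reference amplicon (default `"ref1"`).
#' @return Named numeric vector `c(broken_fraction=, deletion_fraction=)`.
#' @export
broken_deleted_fractions <- function(wells, intact_amplicon = "intact",
                                     flank_amplicon = "flank_d8",
                                     ref_amplicon = "ref1") {
  lam_ref <- ddpcr_lambda(wells, ref_amplicon, "mock")
  broken <- clamp01(
    1 - ddpcr_lambda(wells, intact_amplicon, "mock") / lam_ref,
    "broken fraction"
  )
  deleted <- clamp01(
    1 - ddpcr_lambda(wells, flank_amplicon, "mock") / lam_ref,
    "deletion fraction"
  )
  c(broken_fraction = broken, deletion_fraction = deleted)
}

#' End-resection profile across flank distances
#'
#' Convenience wrapper computing the ssDNA fraction at each flank amplicon
#' plus broken-end and deletion fractions from one well table.
#'
#' @param wells Data.frame as in [ssdna_fraction()].
#' @param flank_amplicons Named character vector mapping distance labels to
#'   flank amplicon names.
#' @param ref_amplicon Reference amplicon (default `"ref1"`).
#' @param intact_amplicon Optional cut-spanning amplicon name; set `NULL` to
#'   skip broken/deletion fractions.
#' @return A list with `ssdna` (named fractions per distance) and, when
#'   available, `broken_fraction` and `deletion_fraction`.
#' @export
resection_profile <- function(wells,
                              flank_amplicons = c(
                                d8 = "flank_d8", d284 = "flank_d284", d527 = "flank_d527"
                              ),
                              ref_amplicon = "ref1",
                              intact_amplicon = "intact") {
  present <- flank_amplicons[flank_amplicons %in% wells$amplicon]
  ss <- vapply(present, ssdna_fraction, numeric(1),
    wells = wells, ref_amplicon = ref_amplicon
  )
  out <- list(ssdna = ss)
  if (!is.null(intact_amplicon) && intact_amplicon %in% wells$amplicon) {
    bd <- broken_deleted_fractions(wells,
      intact_amplicon = intact_amplicon,
      flank_amplicon = present[[1]], ref_amplicon = ref_amplicon
    )
    out$broken_fraction <- bd[["broken_fraction"]]
    out$deletion_fraction <- bd[["deletion_fraction"]]
  }
  out
}

#' Gene-targeting fraction from band intensities
#'
#' Fraction of repair events that used the homology donor, from the
#' restriction-digest band intensities:
#' `sensitive / (sensitive + resistant)`.
#'
#' @param sensitive,resistant Non-negative band intensities (digest-sensitive
#'   = donor-derived; resistant = unmodified).
#' @return Fraction in `[0, 1]`.
#' @examples
#' gene_targeting_fraction(3, 1) # 0.75
#' @export
gene_targeting_fraction <- function(sensitive, resistant) {
  stopifnot(all(sensitive >= 0), all(resistant >= 0))
  if (any(sensitive + resistant == 0)) {
    stop("both band intensities are zero", call. = FALSE)
  }
  sensitive / (sensitive + resistant)
}

#' Clonogenic surviving fraction
#'
#' Ratio of plating efficiencies of treated vs untreated cells:
#' `(colonies_treated/plated_treated) / (colonies_untreated/plated_untreated)`.
#'
#' @param colonies_treated,plated_treated Colonies and cells plated, treated.
#' @param colonies_untreated,plated_untreated Same for the untreated control.
#' @return Surviving fraction.
#' @examples
#' clonogenic_survival(50, 1000, 100, 1000) # 0.5
#' @export
clonogenic_survival <- function(colonies_treated, plated_treated,
                                colonies_untreated, plated_untreated) {
  stopifnot(all(plated_treated > 0), all(plated_untreated > 0))
  if (any(colonies_untreated <= 0)) {
    stop("untreated plating efficiency is zero", call. = FALSE)
  }
  (colonies_treated / plated_treated) / (colonies_untreated / plated_untreated)
}
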