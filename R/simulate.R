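# Synthetic-data generators with known ground truth: a toy locus with planted
# microhomology pairs, repair-event reads in full library layout, paired
# two-condition experiments, and qPCR/ddPCR measurement tables. Everything is
# deterministic under a fixed seed.

#' Default repair-event class mixture
#'
#' Probabilities over read classes, calibrated so that the repair-read
#' composition matches a wild-type vehicle-treated experiment: 35% of reads
#' intact, and among repair reads 19% microhomology-mediated deletions at the
#' planted TMEJ junctions, 63% NHEJ products (42% +1 insertions, 21% small
#' deletions without microhomology), and 18% other products (5% templated
#' insertions, 13% long deletions without microhomology).
#'
#' @return Named numeric vector over classes `intact`, `mhd`, `tins`,
#'   `nhej_ins1`, `nhej_del`, `long_del`; sums to 1.
#' @export
default_event_mixture <- function() {
  repair <- c(mhd = 0.19, nhej_ins1 = 0.42, nhej_del = 0.21, tins = 0.05, long_del = 0.13)
  c(intact = 0.35, repair * 0.65)
}

#' Scale TMEJ-class event probabilities (Polq deficiency / re-channeling)
#'
#' Multiplies the probabilities of the Polq-dependent classes (`mhd`, `tins`)
#' by `factor` and re-channels the lost probability mass to the NHEJ classes
#' proportionally, emulating the depletion of TMEJ products and compensatory
#' NHEJ increase seen in Polq-deficient or PARP-inhibited cells.
#'
#' @param mixture Named mixture as from [default_event_mixture()].
#' @param factor Multiplicative factor in `[0, 1]` applied to TMEJ classes.
#' @param classes Which event classes to scale (default both Polq-dependent
#'   classes; pass `"mhd"` to deplete only the signature deletions, e.g. when
#'   emulating a condition in which the "other" fraction is unchanged).
#' @return Rescaled mixture (sums to 1).
#' @export
scale_tmej_mixture <- function(mixture, factor, classes = c("mhd", "tins")) {
  stopifnot(factor >= 0, factor <= 1)
  tmej_cls <- intersect(classes, names(mixture))
  nhej_cls <- intersect(c("nhej_ins1", "nhej_del"), names(mixture))
  lost <- sum(mixture[tmej_cls]) * (1 - factor)
  mixture[tmej_cls] <- mixture[tmej_cls] * factor
  mixture[nhej_cls] <- mixture[nhej_cls] + lost * mixture[nhej_cls] / sum(mixture[nhej_cls])
  mixture
}

default_mh_pairs <- function() {
  data.frame(
    mh_len = c(4L, 3L, 5L, 2L, 6L),
    left_gap = c(2L, 8L, 15L, 12L, 22L),
    right_gap = c(6L, 12L, 17L, 25L, 30L)
  )
}

# boundary-extension microhomology + left-aligned canonical register for a
# clean deletion with kept-left end s = cut-dl and deleted-through e = cut+dr
canonical_deletion <- function(ref, cut, dl, dr) {
  L <- nchar(ref)
  s <- cut - dl
  e <- cut + dr
  kl <- 0L
  while (s - kl >= 1L && base_at(ref, s - kl) == base_at(ref, e - kl)) kl <- kl + 1L
  kr <- 0L
  while (e + kr + 1L <= L && base_at(ref, s + kr + 1L) == base_at(ref, e + kr + 1L)) {
    kr <- kr + 1L
  }
  mh <- min(kl + kr, dl + dr)
  shift <- min(kl, dr)
  dl <- dl + shift
  dr <- dr - shift
  s <- s - shift
  list(
    del_left = dl, del_right = dr, mh_len = mh,
    mh_seq = if (mh > 0L) substr(ref, s + 1L, s + mh) else "",
    junction_key = sprintf("%d:%d:", dl, dr)
  )
}

#' Generate a toy amplicon locus with planted microhomology pairs
#'
#' Builds a random amplicon whose cut site is flanked by planted repeated
#' sequences (2-6 bp microhomology pairs) at specified offsets; deleting from
#' one copy to the other produces a microhomology-mediated deletion with known
#' canonical junction. The construction is verified by scan: every 10-mer in
#' the sequence is unique (so exact anchors are unambiguous) and each planted
#' repeat is maximal (the microhomology length is exactly as planted). The
#' first and last `primer_len` bases serve as the forward and reverse primers.
#'
#' @param seed Integer seed; a fixed seed reproduces the identical locus.
#' @param length Amplicon length (default 240; must be >= 120).
#' @param cut_site Position of the blunt cut (bases to the left of the cut);
#'   defaults to one third of the amplicon so that a 150 nt read from the
#'   forward primer retains a downstream anchor even for the longest
#'   templated insertions.
#' @param mh_pairs Data.frame with columns `mh_len` (2-6), `left_gap`,
#'   `right_gap`: the left repeat copy ends `left_gap` bases left of the cut,
#'   the right copy starts `right_gap + 1` bases right of it.
#' @param primer_len Primer length (default 20).
#' @param max_tries Resampling attempts before giving up.
#' @return A [locus_reference()] with an extra `planted` data.frame giving the
#'   canonical truth of each planted deletion (`del_left`, `del_right`,
#'   `deletion_length`, `mh_len`, `mh_seq`, `junction_key`).
#' @examples
#' loc <- make_locus(seed = 1)
#' loc$planted
#' @export
make_locus <- function(seed = 1L, length = 240L, cut_site = NULL,
                       mh_pairs = default_mh_pairs(), primer_len = 20L,
                       max_tries = 200L) {
  stopifnot(length >= 120L)
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  cut <- as.integer(cut_site %||% (length %/% 3L))
  stopifnot(all(mh_pairs$mh_len >= 2L), all(mh_pairs$mh_len <= 6L))

  left_start <- cut - mh_pairs$left_gap - mh_pairs$mh_len + 1L
  left_end <- cut - mh_pairs$left_gap
  right_start <- cut + mh_pairs$right_gap + 1L
  right_end <- cut + mh_pairs$right_gap + mh_pairs$mh_len
  if (any(left_start <= primer_len + 1L) || any(right_end >= length - primer_len)) {
    stop("planted microhomology pairs must lie between the primers", call. = FALSE)
  }
  ivs <- cbind(c(left_start, right_start), c(left_end, right_end))
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  if (any(ivs[-1, 1] <= ivs[-nrow(ivs), 2])) {
    stop("planted microhomology copies overlap", call. = FALSE)
  }

  for (try in seq_len(max_tries)) {
    seqv <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    for (p in seq_len(nrow(mh_pairs))) {
      seqv[right_start[p]:right_end[p]] <- seqv[left_start[p]:left_end[p]]
    }
    ref <- paste(seqv, collapse = "")

    kmers <- substring(ref, 1:(length - 9L), 10:length)
    if (anyDuplicated(kmers)) next

    ok <- TRUE
    for (p in seq_len(nrow(mh_pairs))) {
      s <- left_start[p] - 1L # kept-left end of the leftmost register
      e <- right_start[p] - 1L # deleted-through position
      m <- mh_pairs$mh_len[p]
      if (base_at(ref, s) == base_at(ref, e) ||
          base_at(ref, s + m + 1L) == base_at(ref, e + m + 1L)) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next

    loc <- locus_reference(
      name = sprintf("synthetic_locus_seed%d", seed),
      sequence = ref, cut_site = cut,
      primer_fwd = substr(ref, 1L, primer_len),
      primer_rev = revcomp(substr(ref, length - primer_len + 1L, length))
    )
    planted <- do.call(rbind, lapply(seq_len(nrow(mh_pairs)), function(p) {
      dl <- mh_pairs$left_gap[p] + mh_pairs$mh_len[p]
      dr <- mh_pairs$right_gap[p]
      cd <- canonical_deletion(ref, cut, dl, dr)
      data.frame(
        del_left = cd$del_left, del_right = cd$del_right,
        deletion_length = dl + dr, mh_len = cd$mh_len, mh_seq = cd$mh_seq,
        junction_key = cd$junction_key, stringsAsFactors = FALSE
      )
    }))
    # planted truth must be self-consistent with the pair definition
    stopifnot(identical(planted$mh_len, mh_pairs$mh_len))
    # and each planted junction must be its own minimal-deletion
    # reconstruction (no accidental smaller-deletion reinterpretation)
    canonical_ok <- all(vapply(seq_len(nrow(planted)), function(p) {
      variant <- paste0(
        substr(ref, 1L, cut - planted$del_left[p]),
        substr(ref, cut + planted$del_right[p] + 1L, length)
      )
      got <- .call_core(variant, ref, cut, loc$anchor_length)
      identical(got$junction_key, planted$junction_key[p]) &&
        identical(got$mh_len, planted$mh_len[p])
    }, logical(1)))
    if (!canonical_ok) next
    loc$planted <- planted
    return(loc)
  }
  stop(sprintf("could not build a valid locus in %d tries", max_tries), call. = FALSE)
}

ambiguity_codes <- c("N", "W", "S", "R", "K")

mutate_read <- function(read, n_sub, add_ambiguity) {
  v <- chars(read)
  n <- length(v)
  if (n_sub > 0L) {
    pos <- sample.int(n, min(n_sub, n))
    for (q in pos) {
      v[q] <- sample(setdiff(c("A", "C", "G", "T"), v[q]), 1L)
    }
  }
  if (add_ambiguity) {
    v[sample.int(n, 1L)] <- sample(ambiguity_codes, 1L)
  }
  paste(v, collapse = "")
}

#' Simulate amplicon reads with known repair-event truth
#'
#' Draws read classes from `mixture`, constructs the repaired amplicon for
#' each read (microhomology-mediated deletions at the planted repeats,
#' templated insertions copied directly or inverted from sequence flanking the
#' cut, +1 NHEJ insertions, small and long deletions without microhomology),
#' assembles the library layout (6 bp barcode + 1-8 bp spacer + forward primer
#' + 150 nt of template), and injects substitution errors and ambiguity bases
#' at the configured rates. Truth records store the canonical junction of
#' every read.
#'
#' @param locus A locus from [make_locus()] (needs `$planted` for `mhd`
#'   events).
#' @param n_reads Number of reads.
#' @param mixture Event-class mixture; see [default_event_mixture()].
#' @param seed Integer seed (all randomness local to this call).
#' @param substitution_rate Per-base substitution error probability
#'   (default 1e-3, typical post-filter short-read accuracy).
#' @param ambiguity_rate Per-read probability of one ambiguity base
#'   (default 2e-3).
#' @param read_length Template bases retained from the forward-primer start
#'   (default 150).
#' @param barcode 6 bp sample barcode.
#' @param sample_id Sample identifier used in read names and truth records.
#' @param tins_window Half-width of the template window around the cut for
#'   templated insertions (default 50 nt).
#' @param tins_len Length range of templated insertions (default 5-30 nt).
#' @return A list with `reads` (named character vector, raw library reads),
#'   `truth` (data.frame: `read_id`, `class`, `del_left`, `del_right`,
#'   `deletion_length`, `insertion`, `mh_len`, `junction_key`, `n_sub`,
#'   `has_ambiguity`), and `sample_id`.
#' @export
simulate_reads <- function(locus, n_reads, mixture = default_event_mixture(),
                           seed = NULL, substitution_rate = 1e-3,
                           ambiguity_rate = 2e-3, read_length = 150L,
                           barcode = "ACGTAC", sample_id = "sample1",
                           tins_window = 50L, tins_len = c(5L, 30L)) {
  stopifnot(inherits(locus, "locus_reference"))
  stopifnot(abs(sum(mixture) - 1) < 1e-8, all(mixture >= 0))
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  ref <- locus$sequence
  cut <- locus$cut_site
  L <- nchar(ref)
  planted <- locus$planted
  if (is.null(planted) && mixture[["mhd"]] > 0) {
    stop("locus has no planted microhomology pairs; use make_locus()", call. = FALSE)
  }
  primer <- locus$primer_fwd
  plen <- nchar(primer)

  classes <- sample(names(mixture), n_reads, replace = TRUE, prob = mixture)
  spacers <- sample.int(8L, n_reads, replace = TRUE) # spacer length 1-8
  n_sub <- stats::rbinom(n_reads, read_length + nchar(barcode) + 8L, substitution_rate)
  amb <- stats::runif(n_reads) < ambiguity_rate

  # precomputed variants for deterministic classes
  intact_variant <- ref
  mhd_variants <- if (!is.null(planted)) {
    vapply(seq_len(nrow(planted)), function(p) {
      paste0(
        substr(ref, 1L, cut - planted$del_left[p]),
        substr(ref, cut + planted$del_right[p] + 1L, L)
      )
    }, character(1))
  }
  canon_cache <- new.env(parent = emptyenv())
  canon <- function(dl, dr) {
    key <- paste(dl, dr)
    v <- canon_cache[[key]]
    if (is.null(v)) {
      v <- canonical_deletion(ref, cut, dl, dr)
      canon_cache[[key]] <- v
    }
    v
  }
  planted_keys <- if (!is.null(planted)) planted$junction_key else character(0)

  # a candidate deletion is kept only if its junction is not reinterpretable:
  # accidental homology between the joined flanks can make the junction
  # explainable by a smaller deletion, in which case the minimal-deletion
  # reconstruction (the ground truth of the read) differs from the planted
  # event. Verified once per candidate and cached.
  verify_cache <- new.env(parent = emptyenv())
  deletion_is_canonical <- function(cd) {
    v <- verify_cache[[cd$junction_key]]
    if (is.null(v)) {
      variant <- paste0(
        substr(ref, 1L, cut - cd$del_left),
        substr(ref, cut + cd$del_right + 1L, L)
      )
      got <- .call_core(variant, ref, cut, locus$anchor_length)
      v <- identical(got$junction_key, cd$junction_key)
      verify_cache[[cd$junction_key]] <- v
    }
    v
  }
  draw_deletion <- function(t_range) {
    repeat {
      t <- sample(t_range, 1L)
      dl <- sample(0:t, 1L)
      dr <- t - dl
      if (cut - dl < locus$anchor_length) next
      if (cut + dr > L - locus$anchor_length) next
      cd <- canon(dl, dr)
      if (cd$mh_len <= 1L && !(cd$junction_key %in% planted_keys) &&
          deletion_is_canonical(cd)) {
        return(list(cd = cd, t = t))
      }
    }
  }

  reads <- character(n_reads)
  truth <- vector("list", n_reads)
  bases <- c("A", "C", "G", "T")
  for (r in seq_len(n_reads)) {
    cl <- classes[r]
    if (cl == "intact") {
      variant <- intact_variant
      tr <- list(dl = 0L, dr = 0L, ins = "", mh = 0L, key = "0:0:")
    } else if (cl == "mhd") {
      p <- sample.int(nrow(planted), 1L)
      variant <- mhd_variants[p]
      tr <- list(
        dl = planted$del_left[p], dr = planted$del_right[p], ins = "",
        mh = planted$mh_len[p], key = planted$junction_key[p]
      )
    } else if (cl == "tins") {
      ilen <- sample(tins_len[1]:tins_len[2], 1L)
      a_min <- max(1L, cut - tins_window)
      a_max <- min(L - ilen + 1L, cut + tins_window - ilen + 1L)
      a <- sample(a_min:a_max, 1L)
      tpl <- substr(ref, a, a + ilen - 1L)
      ins <- if (stats::runif(1) < 0.5) tpl else revcomp(tpl)
      variant <- paste0(substr(ref, 1L, cut), ins, substr(ref, cut + 1L, L))
      tr <- list(dl = 0L, dr = 0L, ins = ins, mh = 0L, key = sprintf("0:0:%s", ins))
    } else if (cl == "nhej_ins1") {
      b <- sample(bases, 1L)
      variant <- paste0(substr(ref, 1L, cut), b, substr(ref, cut + 1L, L))
      tr <- list(dl = 0L, dr = 0L, ins = b, mh = 0L, key = sprintf("0:0:%s", b))
    } else if (cl == "nhej_del") {
      d <- draw_deletion(1:4)
      variant <- paste0(
        substr(ref, 1L, cut - (d$cd$del_left)),
        substr(ref, cut + d$cd$del_right + 1L, L)
      )
      tr <- list(
        dl = d$cd$del_left, dr = d$cd$del_right, ins = "",
        mh = d$cd$mh_len, key = d$cd$junction_key
      )
    } else if (cl == "long_del") {
      d <- draw_deletion(5:40)
      variant <- paste0(
        substr(ref, 1L, cut - (d$cd$del_left)),
        substr(ref, cut + d$cd$del_right + 1L, L)
      )
      tr <- list(
        dl = d$cd$del_left, dr = d$cd$del_right, ins = "",
        mh = d$cd$mh_len, key = d$cd$junction_key
      )
    } else {
      stop(sprintf("unknown event class '%s'", cl), call. = FALSE)
    }
    spacer <- paste(sample(bases, spacers[r], replace = TRUE), collapse = "")
    read <- paste0(barcode, spacer, substr(variant, 1L, read_length))
    if (n_sub[r] > 0L || amb[r]) read <- mutate_read(read, n_sub[r], amb[r])
    reads[r] <- read
    truth[[r]] <- data.frame(
      read_id = sprintf("%s_r%06d", sample_id, r),
      class = cl, del_left = tr$dl, del_right = tr$dr,
      deletion_length = tr$dl + tr$dr, insertion = tr$ins,
      mh_len = tr$mh, junction_key = tr$key,
      n_sub = n_sub[r], has_ambiguity = amb[r],
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  names(reads) <- truth$read_id
  list(reads = reads, truth = truth, sample_id = sample_id, mixture = mixture)
}

#' Simulate paired wild-type / Polq-null conditions
#'
#' Generates two read sets from the same locus: the wild-type condition uses
#' `mixture` unchanged; in the Polq-null condition the TMEJ-class event
#' probabilities are multiplied by `depletion` and the lost mass re-channeled
#' to NHEJ (see [scale_tmej_mixture()]). Expected repair-class fractions for
#' both conditions are returned alongside.
#'
#' @inheritParams simulate_reads
#' @param depletion Multiplicative factor applied to TMEJ-class probabilities
#'   in the null condition. Default 12.7/19 (the residual signature fraction
#'   observed in Polq-deficient cells).
#' @param ... Passed to [simulate_reads()] (error rates, read length, ...).
#' @return List with `wt` and `polq_null` (each as [simulate_reads()]),
#'   `expected` (data.frame of expected TMEJ/NHEJ/other fractions of repair
#'   reads per condition), and `depletion`.
#' @export
simulate_two_conditions <- function(locus, n_reads = 10000L,
                                    mixture = default_event_mixture(),
                                    depletion = 12.7 / 19, seed = NULL, ...) {
  seed <- seed %||% 1L
  null_mixture <- scale_tmej_mixture(mixture, depletion)
  wt <- simulate_reads(locus, n_reads,
    mixture = mixture, seed = seed,
    sample_id = "wt", ...
  )
  nl <- simulate_reads(locus, n_reads,
    mixture = null_mixture, seed = seed + 1L,
    sample_id = "polq_null", ...
  )
  class_frac <- function(m) {
    repair <- m[names(m) != "intact"]
    repair <- repair / sum(repair)
    c(
      tmej = unname(repair["mhd"]),
      nhej = unname(repair["nhej_ins1"] + repair["nhej_del"]),
      other = unname(repair["tins"] + repair["long_del"])
    )
  }
  expected <- rbind(
    data.frame(condition = "wt", t(class_frac(mixture))),
    data.frame(condition = "polq_null", t(class_frac(null_mixture)))
  )
  list(wt = wt, polq_null = nl, expected = expected, depletion = depletion)
}

#' Deterministic panel of deletion junction keys
#'
#' A fixed set of deletion-only junction keys with power-law abundance,
#' used for count-level simulations (e.g. null calibration of the
#' depletion test). No randomness involved.
#'
#' @param n_keys Number of junction keys (default 60).
#' @param alpha Power-law exponent of the abundance profile (default 1).
#' @return Data.frame with junction features and a `prob` column summing to 1.
#' @export
junction_key_panel <- function(n_keys = 60L, alpha = 1) {
  dl <- ((seq_len(n_keys) - 1L) %% 12L) + 1L
  dr <- ((seq_len(n_keys) - 1L) %/% 12L) + 1L
  p <- (1 / seq_len(n_keys))^alpha
  data.frame(
    junction_key = sprintf("%d:%d:", dl, dr),
    del_left = dl, del_right = dr, deletion_length = dl + dr,
    insertion = "", ins_len = 0L, mh_len = 0L, mh_seq = "",
    prob = p / sum(p),
    stringsAsFactors = FALSE
  )
}

#' Simulate a junction table by multinomial sampling of key counts
#'
#' Count-level twin of the read simulator: draws `n_reads` repair reads from
#' the per-key probabilities and returns a ready [junction_table()]. Used for
#' calibration studies (e.g. false-discovery control under the null) where
#' read-level detail is irrelevant.
#'
#' @param panel Data.frame from [junction_key_panel()] (or any data.frame with
#'   the junction-table feature columns plus `prob`).
#' @param n_reads Total repair reads.
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return A `junction_table`.
#' @export
simulate_junction_table <- function(panel, n_reads, seed = NULL,
                                    sample_id = NA_character_) {
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  counts <- as.integer(stats::rmultinom(1L, n_reads, panel$prob))
  keys <- panel
  keys$prob <- NULL
  keys$count <- counts
  junction_table(keys[keys$count > 0L, , drop = FALSE], sample_id = sample_id)
}

#' Simulate ddPCR droplet-count tables
#'
#' Generative twin of the resection ddPCR assay: droplet positives are drawn
#' as `Binomial(n_droplets, 1 - exp(-lambda))` per amplicon/treatment well.
#' Mock-treated flank wells see all templates not deleted past the flank;
#' ExoI-treated wells additionally lose the resected (ssDNA) fraction; the
#' cut-spanning "intact" amplicon sees unbroken templates; the PstI wells
#' retain only the resected fraction at the PstI-site flank.
#'
#' @param ssdna Named fractions of genomes with ssDNA past each flank
#'   amplicon, e.g. `c(flank_d8 = 0.091, flank_d284 = 0.038, flank_d527 =
#'   0.017)`.
#' @param deleted Named fractions with two-strand deletions past each flank
#'   (same names as `ssdna`; default 0).
#' @param broken Fraction of broken (not precisely rejoined) genomes.
#' @param ssdna_psti Resected fraction at the PstI flank site; `NULL` skips
#'   the PstI wells.
#' @param lambda_ref Reference-amplicon mean copies per droplet.
#' @param n_droplets Droplets per well.
#' @param n_wells Wells per amplicon/treatment (merged downstream).
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return Data.frame with columns `sample_id`, `amplicon`, `treatment`,
#'   `positives`, `total`.
#' @export
simulate_ddpcr <- function(ssdna = c(flank_d8 = 0.091, flank_d284 = 0.038, flank_d527 = 0.017),
                           deleted = NULL, broken = 0.2, ssdna_psti = NULL,
                           lambda_ref = 0.5, n_droplets = 20000L, n_wells = 1L,
                           seed = NULL, sample_id = "sample1") {
  stopifnot(all(ssdna >= 0 & ssdna <= 1), broken >= 0, broken <= 1)
  if (is.null(deleted)) deleted <- stats::setNames(rep(0, length(ssdna)), names(ssdna))
  stopifnot(all(names(ssdna) %in% names(deleted) | names(deleted) %in% names(ssdna)))
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)

  rows <- list()
  add <- function(amplicon, treatment, lambda) {
    pos <- stats::rbinom(n_wells, n_droplets, 1 - exp(-lambda))
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, amplicon = amplicon, treatment = treatment,
      positives = pos, total = rep(n_droplets, n_wells),
      stringsAsFactors = FALSE
    )
  }
  add("ref1", "mock", lambda_ref)
  add("ref1", "exoI", lambda_ref)
  for (f in names(ssdna)) {
    dd <- if (f %in% names(deleted)) deleted[[f]] else 0
    add(f, "mock", lambda_ref * (1 - dd))
    add(f, "exoI", lambda_ref * max(0, 1 - dd - ssdna[[f]]))
  }
  add("intact", "mock", lambda_ref * (1 - broken))
  if (!is.null(ssdna_psti)) {
    add("ref1", "psti", lambda_ref)
    add("flank_psti", "psti", lambda_ref * ssdna_psti)
  }
  do.call(rbind, rows)
}

#' Simulate a signature/reference qPCR Ct table
#'
#' Generates replicate Ct pairs whose delta-delta Ct recovers the specified
#' true relative abundances. The calibrator sample must be present in
#' `true_rel` with value 1.
#'
#' @param true_rel Named numeric vector of true signature abundances as
#'   fractions of the calibrator.
#' @param calibrator Name of the calibrator sample (default first element).
#' @param n_reps Technical replicates per sample (default 3).
#' @param ct_ref_mean Mean reference-amplicon Ct (default 24).
#' @param delta_cal Signature-minus-reference Ct offset of the calibrator
#'   (default 6 cycles).
#' @param noise_sd SD of Ct noise per well (default 0.05 cycles).
#' @param efficiency Amplification efficiency (default 2).
#' @param seed Integer seed.
#' @return Data.frame with `sample_id`, `replicate`, `amplicon`
#'   (`"signature"`/`"reference"`), `ct`.
#' @export
simulate_qpcr <- function(true_rel, calibrator = names(true_rel)[1], n_reps = 3L,
                          ct_ref_mean = 24, delta_cal = 6, noise_sd = 0.05,
                          efficiency = 2, seed = NULL) {
  stopifnot(!is.null(names(true_rel)), calibrator %in% names(true_rel))
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  rows <- list()
  for (s in names(true_rel)) {
    for (r in seq_len(n_reps)) {
      ct_ref <- stats::rnorm(1, ct_ref_mean, noise_sd)
      ct_sig <- ct_ref + delta_cal - log(true_rel[[s]], base = efficiency) +
        stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, replicate = r,
        amplicon = c("signature", "reference"), ct = c(ct_sig, ct_ref),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
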