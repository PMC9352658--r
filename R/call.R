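# Junction reconstruction by exact anchor matching.
#
# The caller scans outward from the cut site for an upstream and a downstream
# exact anchor match (default 10 nt) whose reference placements minimize the
# total deletion. Reference k-mers are searched in the read with overlapping
# occurrences allowed; the upstream anchor takes its leftmost occurrence (the
# read's own left flank precedes any templated copy of flanking sequence), the
# downstream anchor its rightmost. Among decompositions with minimal total
# deletion the caller prefers the shortest insertion and then the largest
# del_left; clean deletions are afterwards canonicalized by left-aligning the
# deletion so that every microhomology register of the same event collapses to
# a single junction key.

UNALIGNED_FIELDS <- list(
  status = "UNALIGNABLE", del_left = NA_integer_, del_right = NA_integer_,
  deletion_length = NA_integer_, insertion = NA_character_, ins_len = NA_integer_,
  mh_len = NA_integer_, mh_seq = NA_character_, junction_key = NA_character_,
  read_left_end = NA_integer_, read_right_start = NA_integer_,
  ambiguous = FALSE, sub_artifact = FALSE
)

# Core per-read characterization. `seq` is a trimmed read, `ref` the amplicon,
# `cut` the 1-based index of the last base left of the cut, `A` anchor length.
.call_core <- function(seq, ref, cut, A) {
  if (is.na(seq)) return(UNALIGNED_FIELDS)
  L <- nchar(ref)
  n <- nchar(seq)
  if (n < 2L * A) return(UNALIGNED_FIELDS)
  dl_max <- cut - A
  dr_max <- L - cut - A

  iv <- rep(NA_integer_, dl_max + 1L) # leftmost end pos of upstream anchor, 0 = absent
  jv <- rep(NA_integer_, dr_max + 1L) # rightmost start pos of downstream anchor, 0 = absent
  get_i <- function(dl) {
    v <- iv[dl + 1L]
    if (is.na(v)) {
      occ <- find_all(seq, substr(ref, cut - dl - A + 1L, cut - dl))
      v <- if (length(occ)) occ[1L] + A - 1L else 0L
      iv[dl + 1L] <<- v
    }
    v
  }
  get_j <- function(dr) {
    v <- jv[dr + 1L]
    if (is.na(v)) {
      occ <- find_all(seq, substr(ref, cut + 1L + dr, cut + dr + A))
      v <- if (length(occ)) occ[length(occ)] else 0L
      jv[dr + 1L] <<- v
    }
    v
  }

  best <- NULL
  for (t in 0:(dl_max + dr_max)) {
    for (dl in min(t, dl_max):max(0L, t - dr_max)) { # descending: prefer larger del_left
      dr <- t - dl
      i <- get_i(dl)
      if (i == 0L) next
      j <- get_j(dr)
      if (j == 0L) next
      if (j < i + 1L) next # anchors must not overlap in the read
      il <- j - i - 1L
      if (is.null(best) || il < best$ins_len) {
        best <- list(dl = dl, dr = dr, i = i, j = j, ins_len = il)
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) return(UNALIGNED_FIELDS)

  dl <- best$dl; dr <- best$dr; i <- best$i; j <- best$j
  t <- dl + dr
  ins <- if (best$ins_len > 0L) substr(seq, i + 1L, j - 1L) else ""
  junction_seq <- substr(seq, i - A + 1L, j + A - 1L)
  ambiguous <- grepl("[^ACGT]", junction_seq)

  # Amplification-artifact signature: the read is colinear with the reference
  # across the junction (called insertion length equals the called deletion),
  # and carries an isolated substitution 3-10 nt from the break whose
  # neighbours match the reference.
  sub_artifact <- FALSE
  if (t > 0L && best$ins_len == t) {
    off <- i - (cut - dl)
    win <- c((cut - 9L):(cut - 2L), (cut + 3L):(cut + 10L))
    for (p in win) {
      rp <- p + off
      if (p - 1L < 1L || p + 1L > L || rp - 1L < 1L || rp + 1L > n) next
      if (base_at(seq, rp) != base_at(ref, p) &&
          base_at(seq, rp - 1L) == base_at(ref, p - 1L) &&
          base_at(seq, rp + 1L) == base_at(ref, p + 1L)) {
        sub_artifact <- TRUE
        break
      }
    }
  }

  mh <- 0L
  mh_seq <- ""
  if (best$ins_len == 0L && t > 0L) {
    s <- cut - dl
    e <- cut + dr
    kl <- 0L
    while (s - kl >= 1L && base_at(ref, s - kl) == base_at(ref, e - kl)) kl <- kl + 1L
    kr <- 0L
    while (e + kr + 1L <= L && base_at(ref, s + kr + 1L) == base_at(ref, e + kr + 1L)) {
      kr <- kr + 1L
    }
    mh <- min(kl + kr, t) # microhomology cannot exceed the deletion
    # canonicalize: left-align the deletion (del_right slack absorbed into MH)
    shift <- min(kl, dr)
    dl <- dl + shift
    dr <- dr - shift
    s <- s - shift
    mh_seq <- if (mh > 0L) substr(ref, s + 1L, s + mh) else ""
  }

  status <- if (t == 0L && best$ins_len == 0L) "INTACT" else "PASS"
  list(
    status = status, del_left = dl, del_right = dr, deletion_length = t,
    insertion = ins, ins_len = best$ins_len, mh_len = mh, mh_seq = mh_seq,
    junction_key = sprintf("%d:%d:%s", dl, dr, ins),
    read_left_end = i, read_right_start = j,
    ambiguous = ambiguous, sub_artifact = sub_artifact
  )
}

#' Locate the minimal-deletion anchor pair for one read
#'
#' Finds the upstream and downstream exact anchor matches (length
#' `locus$anchor_length`) whose reference placements minimize the total
#' deletion `del_left + del_right`, scanning outward from the cut site.
#'
#' @param read A single trimmed read sequence.
#' @param locus A [locus_reference()].
#' @return A list with `del_left`, `del_right`, `read_left_end` (read position
#'   of the last upstream-anchor base), `read_right_start` (read position of
#'   the first downstream-anchor base), or `NULL` if no anchor pair exists
#'   (the read is unalignable). Deletion lengths are the canonical
#'   (left-aligned) values; the read positions are those of the anchors found
#'   by the outward scan.
#' @export
find_anchors <- function(read, locus) {
  stopifnot(inherits(locus, "locus_reference"), length(read) == 1L)
  res <- .call_core(read, locus$sequence, locus$cut_site, locus$anchor_length)
  if (res$status == "UNALIGNABLE") return(NULL)
  list(
    del_left = res$del_left,
    del_right = res$del_right,
    read_left_end = res$read_left_end,
    read_right_start = res$read_right_start
  )
}

#' Call the repair junction of a single read
#'
#' Reconstructs the junction of one trimmed read against the reference locus:
#' deletion lengths left and right of the cut, inserted sequence,
#' microhomology, and a canonical junction key. See [call_junctions()] for the
#' vectorized interface and a description of the status codes.
#'
#' @inheritParams find_anchors
#' @param apply_filters Apply the ambiguity and substitution-artifact filters
#'   (default `TRUE`).
#' @return A list of class `junction_call`.
#' @examples
#' loc <- make_locus(seed = 1)
#' call_junction(loc$sequence, loc) # the intact amplicon
#' @export
call_junction <- function(read, locus, apply_filters = TRUE) {
  stopifnot(inherits(locus, "locus_reference"), length(read) == 1L)
  res <- .call_core(read, locus$sequence, locus$cut_site, locus$anchor_length)
  if (apply_filters) {
    if (res$status %in% c("PASS", "INTACT") && res$ambiguous) res$status <- "AMBIGUOUS_BASE"
    if (res$status == "PASS" && res$sub_artifact) res$status <- "SUBSTITUTION_ARTIFACT"
  }
  structure(res, class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  if (x$status %in% c("PASS", "INTACT", "AMBIGUOUS_BASE", "SUBSTITUTION_ARTIFACT")) {
    cat(sprintf(
      "<junction_call> %s  del %d+%d=%d nt, ins '%s' (%d nt), MH '%s' (%d nt), key %s\n",
      x$status, x$del_left, x$del_right, x$deletion_length,
      x$insertion, x$ins_len, x$mh_seq, x$mh_len, x$junction_key
    ))
  } else {
    cat("<junction_call> UNALIGNABLE\n")
  }
  invisible(x)
}

#' Call repair junctions for a set of reads
#'
#' Vectorized junction reconstruction. Each read is characterized relative to
#' the reference locus and cut site by exact anchor matching (see Details of
#' the package vignette), then passed through the exclusion filters. Identical
#' read sequences are characterized once.
#'
#' Status codes: `PASS` (a repair product), `INTACT` (no deletion, no
#' insertion), `UNALIGNABLE` (no exact anchor pair on both sides),
#' `AMBIGUOUS_BASE` (IUPAC ambiguity code, e.g. N/W/S/R/K, inside the
#' reconstructed junction region), `SUBSTITUTION_ARTIFACT` (colinear read with
#' an isolated substitution 3-10 nt from the break whose neighbours match the
#' reference; consistent with polymerase error during amplification).
#' Reads failing any filter are excluded from both numerator and denominator
#' of all downstream fractions.
#'
#' @param reads Either a character vector of trimmed read sequences (names are
#'   used as read ids) or the data.frame returned by [trim_reads()].
#' @param locus A [locus_reference()].
#' @param apply_filters Apply the ambiguity and substitution-artifact filters
#'   (default `TRUE`). When `FALSE` the filter flags are still computed and
#'   stored in the `ambiguous` / `sub_artifact` columns.
#' @return A data.frame of class `junction_calls`, one row per read, with
#'   columns `read_id`, `sample_id`, `status`, `del_left`, `del_right`,
#'   `deletion_length`, `insertion`, `ins_len`, `mh_len`, `mh_seq`,
#'   `junction_key`, `read_left_end`, `read_right_start`, `ambiguous`,
#'   `sub_artifact`.
#' @examples
#' loc <- make_locus(seed = 1)
#' sim <- simulate_reads(loc, n_reads = 50, seed = 2,
#'                       substitution_rate = 0, ambiguity_rate = 0)
#' trimmed <- trim_reads(sim$reads, loc$primer_fwd)
#' calls <- call_junctions(trimmed, loc)
#' table(calls$status)
#' @export
call_junctions <- function(reads, locus, apply_filters = TRUE) {
  stopifnot(inherits(locus, "locus_reference"))
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    sample_id <- if ("sample_id" %in% names(reads)) reads$sample_id else NA_character_
    seqs <- ifelse(reads$status == "PASS", reads$sequence, NA_character_)
  } else {
    seqs <- as.character(reads)
    ids <- names(reads) %||% sprintf("read%d", seq_along(seqs))
    sample_id <- rep(NA_character_, length(seqs))
  }
  uq <- unique(seqs[!is.na(seqs)])
  cores <- lapply(uq, .call_core,
    ref = locus$sequence, cut = locus$cut_site, A = locus$anchor_length
  )
  cores <- c(cores, list(UNALIGNED_FIELDS))
  idx <- match(seqs, uq)
  idx[is.na(idx)] <- length(cores)

  pull_chr <- function(f) vapply(cores, function(r) r[[f]], character(1))[idx]
  pull_int <- function(f) vapply(cores, function(r) as.integer(r[[f]]), integer(1))[idx]
  pull_lgl <- function(f) vapply(cores, function(r) r[[f]], logical(1))[idx]

  out <- data.frame(
    read_id = ids,
    sample_id = sample_id,
    status = pull_chr("status"),
    del_left = pull_int("del_left"),
    del_right = pull_int("del_right"),
    deletion_length = pull_int("deletion_length"),
    insertion = pull_chr("insertion"),
    ins_len = pull_int("ins_len"),
    mh_len = pull_int("mh_len"),
    mh_seq = pull_chr("mh_seq"),
    junction_key = pull_chr("junction_key"),
    read_left_end = pull_int("read_left_end"),
    read_right_start = pull_int("read_right_start"),
    ambiguous = pull_lgl("ambiguous"),
    sub_artifact = pull_lgl("sub_artifact"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("junction_calls", "data.frame")
  if (apply_filters) {
    out <- filter_ambiguous(out)
    out <- filter_substitution_artifacts(out)
  }
  out
}

#' Exclude junctions containing ambiguity bases
#'
#' Marks calls whose reconstructed junction region contains an IUPAC ambiguity
#' code (any non-A/C/G/T base, e.g. N, W, S, R, K) with status
#' `AMBIGUOUS_BASE`. Ambiguity takes precedence over the substitution-artifact
#' status, so the two filters commute.
#'
#' @param calls A `junction_calls` data.frame from [call_junctions()].
#' @return The calls with updated `status`.
#' @export
filter_ambiguous <- function(calls) {
  hit <- calls$status %in% c("PASS", "INTACT", "SUBSTITUTION_ARTIFACT") & calls$ambiguous
  calls$status[hit] <- "AMBIGUOUS_BASE"
  calls
}

#' Exclude amplification substitution artifacts
#'
#' Marks calls consistent with polymerase error during sample amplification:
#' the read is colinear with the reference across the junction and carries a
#' base substitution 3-10 nt from the break site whose adjacent nucleotides
#' match the reference. Such reads would otherwise be misattributed as
#' deletion+insertion repair products. Genuine clean deletions are never
#' flagged (they are not colinear).
#'
#' @param calls A `junction_calls` data.frame from [call_junctions()].
#' @return The calls with updated `status`.
#' @export
filter_substitution_artifacts <- function(calls) {
  hit <- calls$status == "PASS" & calls$sub_artifact & !calls$ambiguous
  calls$status[hit] <- "SUBSTITUTION_ARTIFACT"
  calls
}

#' @export
print.junction_calls <- function(x, ...) {
  cat(sprintf("<junction_calls> %d reads\n", nrow(x)))
  print(table(status = x$status))
  invisible(x)
}

#' Reconstruct the full amplicon sequence implied by a junction call
#'
#' Inverse of the caller for PASS/INTACT calls: rebuilds the repaired amplicon
#' `ref[1..s] + insertion + ref[e+1..L]` from the canonical junction
#' boundaries. Calling the reconstructed sequence returns the identical
#' junction call.
#'
#' @param call A `junction_call` (or a one-row slice of `junction_calls`).
#' @param locus A [locus_reference()].
#' @return A DNA string.
#' @export
reconstruct_read <- function(call, locus) {
  stopifnot(inherits(locus, "locus_reference"))
  ref <- locus$sequence
  cut <- locus$cut_site
  dl <- as.integer(call$del_left)
  dr <- as.integer(call$del_right)
  ins <- as.character(call$insertion)
  if (is.na(dl) || is.na(dr)) stop("cannot reconstruct an unalignable call", call. = FALSE)
  paste0(substr(ref, 1L, cut - dl), ins, substr(ref, cut + dr + 1L, nchar(ref)))
}
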