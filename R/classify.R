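# Pathway classification and subtraction-based contribution estimates.

#' Classify repair junctions as TMEJ, NHEJ, or other
#'
#' A junction is classified `TMEJ` if its key belongs to the depletion-derived
#' signature set (membership takes precedence over the size rule); otherwise
#' `NHEJ` if the total indel length (deletion plus insertion) is below
#' `max_indel` and the microhomology is shorter than `min_mh`; everything else
#' is `OTHER` (large indels, templated insertions, long-microhomology
#' deletions without significant Polq dependence).
#'
#' @param x A `junction_table`, a `junction_calls` data.frame, or any
#'   data.frame carrying `junction_key`, `deletion_length`, `ins_len`,
#'   `mh_len`. Intact rows are not allowed (an intact read is not a repair
#'   product).
#' @param signature A `tmej_signature`, or a character vector of signature
#'   junction keys.
#' @param max_indel NHEJ indel-size bound: NHEJ requires
#'   `deletion_length + ins_len < max_indel` (default 5 bp).
#' @param min_mh NHEJ microhomology bound: NHEJ requires `mh_len < min_mh`
#'   (default 2 bp).
#' @return Factor with levels `TMEJ`, `NHEJ`, `OTHER`, one per row of `x`.
#' @export
classify_junctions <- function(x, signature, max_indel = 5L, min_mh = 2L) {
  members <- if (inherits(signature, "tmej_signature")) signature$members else as.character(signature)
  stopifnot(is.data.frame(x))
  if ("status" %in% names(x)) {
    if (any(x$status == "INTACT")) {
      stop("intact reads are not repair products; remove them before classifying", call. = FALSE)
    }
    if (any(x$status != "PASS")) {
      stop("only PASS calls can be classified", call. = FALSE)
    }
  }
  indel <- x$deletion_length + x$ins_len
  cls <- ifelse(
    x$junction_key %in% members, "TMEJ",
    ifelse(indel < max_indel & x$mh_len < min_mh, "NHEJ", "OTHER")
  )
  factor(cls, levels = c("TMEJ", "NHEJ", "OTHER"))
}

#' Per-sample pathway fractions of all repair
#'
#' Fractions of PASS repair reads classified TMEJ / NHEJ / other for one or
#' several junction tables. Fractions sum to 1 per sample.
#'
#' @param tables A `junction_table` or a (possibly named) list of them.
#' @param signature A `tmej_signature` or vector of signature keys.
#' @param ... Passed to [classify_junctions()].
#' @return Data.frame with columns `sample_id`, `frac_tmej`, `frac_nhej`,
#'   `frac_other`, `n_repair`.
#' @export
pathway_fractions <- function(tables, signature, ...) {
  if (inherits(tables, "junction_table")) tables <- list(tables)
  rows <- lapply(seq_along(tables), function(k) {
    tbl <- tables[[k]]
    stopifnot(inherits(tbl, "junction_table"))
    total <- attr(tbl, "repair_total")
    if (is.null(total) || total <= 0L) {
      stop("pathway fractions undefined: repair_total is 0", call. = FALSE)
    }
    cls <- classify_junctions(tbl, signature, ...)
    w <- tapply(tbl$count, cls, sum, default = 0L)
    sid <- names(tables)[k] %||% NA_character_
    if (is.null(names(tables)) || !nzchar(sid) || is.na(sid)) {
      sid <- attr(tbl, "sample_id") %||% NA_character_
    }
    data.frame(
      sample_id = sid,
      frac_tmej = w[["TMEJ"]] / total,
      frac_nhej = w[["NHEJ"]] / total,
      frac_other = w[["OTHER"]] / total,
      n_repair = total,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pathway contributions relative to a calibrator condition
#'
#' Subtraction-based contribution estimates: for each condition, the signed
#' difference (in percentage points) between its class fractions and those of
#' the designated calibrator (canonically vehicle-treated wild type). Because
#' each sample's fractions sum to 1, the three deltas of any condition sum
#' to 0.
#'
#' @param fractions Data.frame from [pathway_fractions()].
#' @param calibrator `sample_id` of the calibrator condition.
#' @return Data.frame with `sample_id`, `delta_tmej`, `delta_nhej`,
#'   `delta_other` in percentage points.
#' @export
tmej_contribution <- function(fractions, calibrator) {
  i <- match(calibrator, fractions$sample_id)
  if (is.na(i)) stop(sprintf("calibrator sample '%s' not found", calibrator), call. = FALSE)
  data.frame(
    sample_id = fractions$sample_id,
    delta_tmej = 100 * (fractions$frac_tmej - fractions$frac_tmej[i]),
    delta_nhej = 100 * (fractions$frac_nhej - fractions$frac_nhej[i]),
    delta_other = 100 * (fractions$frac_other - fractions$frac_other[i]),
    stringsAsFactors = FALSE
  )
}
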