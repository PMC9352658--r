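#' Tabulate junction calls into a per-sample junction table
#'
#' Counts reads per canonical junction key, restricted to status `PASS`
#' (repair products). Intact reads are counted separately, and the full filter
#' attrition table is kept as an attribute. The sum of PASS counts is the
#' "all repair" denominator used for every downstream fraction.
#'
#' @param calls A `junction_calls` data.frame from [call_junctions()].
#' @param sample_id Sample identifier recorded on the table. Defaults to the
#'   (single) non-missing `sample_id` in `calls`, if any.
#' @return A data.frame of class `junction_table` with one row per junction
#'   key (`junction_key`, `del_left`, `del_right`, `deletion_length`,
#'   `insertion`, `ins_len`, `mh_len`, `mh_seq`, `count`), sorted by
#'   decreasing count. Attributes: `sample_id`, `intact`, `repair_total`,
#'   `attrition` (reads per status).
#' @export
tabulate_junctions <- function(calls, sample_id = NULL) {
  stopifnot(is.data.frame(calls))
  if (is.null(sample_id)) {
    sid <- unique(calls$sample_id[!is.na(calls$sample_id)])
    sample_id <- if (length(sid) == 1L) sid else NA_character_
  }
  pass <- calls[calls$status == "PASS", , drop = FALSE]
  if (nrow(pass)) {
    counts <- table(pass$junction_key)
    first <- pass[!duplicated(pass$junction_key), , drop = FALSE]
    first <- first[match(names(counts), first$junction_key), , drop = FALSE]
    tbl <- data.frame(
      junction_key = names(counts),
      del_left = first$del_left,
      del_right = first$del_right,
      deletion_length = first$deletion_length,
      insertion = first$insertion,
      ins_len = first$ins_len,
      mh_len = first$mh_len,
      mh_seq = first$mh_seq,
      count = as.integer(counts),
      stringsAsFactors = FALSE
    )
    tbl <- tbl[order(-tbl$count, tbl$junction_key), , drop = FALSE]
    rownames(tbl) <- NULL
  } else {
    tbl <- data.frame(
      junction_key = character(0), del_left = integer(0), del_right = integer(0),
      deletion_length = integer(0), insertion = character(0), ins_len = integer(0),
      mh_len = integer(0), mh_seq = character(0), count = integer(0),
      stringsAsFactors = FALSE
    )
  }
  attr(tbl, "sample_id") <- sample_id
  attr(tbl, "intact") <- sum(calls$status == "INTACT")
  attr(tbl, "repair_total") <- sum(tbl$count)
  attr(tbl, "attrition") <- table(calls$status)
  class(tbl) <- c("junction_table", "data.frame")
  tbl
}

#' Assemble a junction table directly from key-level counts
#'
#' Used by the count-level simulator and by I/O; bypasses read-level calling.
#'
#' @param keys Data.frame with columns `junction_key`, `del_left`, `del_right`,
#'   `deletion_length`, `insertion`, `ins_len`, `mh_len`, `mh_seq`, `count`.
#' @param sample_id Sample identifier.
#' @param intact Number of intact reads (default 0).
#' @return A `junction_table`.
#' @export
junction_table <- function(keys, sample_id = NA_character_, intact = 0L) {
  need <- c(
    "junction_key", "del_left", "del_right", "deletion_length",
    "insertion", "ins_len", "mh_len", "mh_seq", "count"
  )
  miss <- setdiff(need, names(keys))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  tbl <- as.data.frame(keys[, need], stringsAsFactors = FALSE)
  rownames(tbl) <- NULL
  attr(tbl, "sample_id") <- sample_id
  attr(tbl, "intact") <- as.integer(intact)
  attr(tbl, "repair_total") <- sum(tbl$count)
  attr(tbl, "attrition") <- NULL
  class(tbl) <- c("junction_table", "data.frame")
  tbl
}

#' @export
print.junction_table <- function(x, n = 10L, ...) {
  cat(sprintf(
    "<junction_table> sample %s: %d junctions, %d repair reads, %d intact\n",
    attr(x, "sample_id") %||% NA, nrow(x), attr(x, "repair_total"), attr(x, "intact")
  ))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("  ... %d more junctions\n", nrow(x) - n))
  invisible(x)
}

#' Write / read a junction table as annotated TSV
#'
#' The file starts with `#`-prefixed header lines recording `sample_id`,
#' `intact`, and `repair_total`, followed by a tab-separated table with the
#' column schema of [tabulate_junctions()].
#'
#' @param tbl A `junction_table`.
#' @param path Output path.
#' @return `path` (write) or a `junction_table` (read).
#' @export
write_junction_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "junction_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_id=%s", attr(tbl, "sample_id") %||% NA),
    sprintf("# intact=%d", attr(tbl, "intact")),
    sprintf("# repair_total=%d", attr(tbl, "repair_total")),
    "# columns: junction_key del_left del_right deletion_length insertion ins_len mh_len mh_seq count"
  ), con)
  utils::write.table(as.data.frame(tbl), con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, na = ""
  )
  invisible(path)
}

#' @rdname write_junction_table
#' @export
read_junction_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(sprintf("^# %s=", key), "", ln[1])
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(
    text = body, sep = "\t", header = TRUE,
    colClasses = c(
      junction_key = "character", insertion = "character", mh_seq = "character"
    ),
    stringsAsFactors = FALSE
  )
  df$insertion[is.na(df$insertion)] <- ""
  df$mh_seq[is.na(df$mh_seq)] <- ""
  junction_table(df,
    sample_id = get_meta("sample_id"),
    intact = as.integer(get_meta("intact"))
  )
}
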