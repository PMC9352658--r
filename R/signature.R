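# TMEJ deletion-signature identification by differential depletion.
#
# Deletion junctions significantly depleted in Polq-deficient samples carry a
# significant TMEJ contribution. Each deletion-only junction is tested with a
# one-sided exact conditional test on the pooled 2x2 table (junction count vs
# all other repair, wild type vs Polq-null), and the Benjamini-Hochberg
# step-up rule at the stated FDR defines the signature set.

pool_tables <- function(x) {
  if (inherits(x, "junction_table")) x <- list(x)
  stopifnot(length(x) >= 1L, all(vapply(x, inherits, logical(1), "junction_table")))
  df <- do.call(rbind, lapply(x, as.data.frame))
  counts <- tapply(df$count, df$junction_key, sum)
  first <- df[!duplicated(df$junction_key), , drop = FALSE]
  first <- first[match(names(counts), first$junction_key), , drop = FALSE]
  first$count <- as.integer(counts)
  rownames(first) <- NULL
  list(table = first, repair_total = sum(first$count))
}

#' Test deletion junctions for depletion in Polq-deficient samples
#'
#' For every deletion-only junction (positive deletion length, empty
#' insertion) observed in either condition, computes a one-sided p-value for
#' depletion in the Polq-null condition from the pooled 2x2 contingency table
#' (this junction vs all other repair reads, wild type vs null) using the
#' exact conditional (hypergeometric tail) test. Replicate tables are pooled
#' by summing counts before testing.
#'
#' @param wt A `junction_table` or list of replicate tables for the wild-type
#'   (Polq-proficient) condition.
#' @param polq_null A `junction_table` or list of replicate tables for the
#'   Polq-deficient condition.
#' @return A data.frame with columns `junction_key`, `del_left`, `del_right`,
#'   `deletion_length`, `ins_len`, `mh_len`, `count_wt`, `count_null`,
#'   `p_value`, sorted by p-value.
#' @examples
#' # a junction present at 50/1000 in both conditions shows no depletion:
#' # the exact tail gives p ~ 0.54
#' @export
test_depletion <- function(wt, polq_null) {
  pw <- pool_tables(wt)
  pn <- pool_tables(polq_null)
  if (pw$repair_total <= 0L || pn$repair_total <= 0L) {
    stop("both conditions need repair_total > 0", call. = FALSE)
  }
  feats <- rbind(
    pw$table[, c("junction_key", "del_left", "del_right", "deletion_length", "ins_len", "mh_len")],
    pn$table[, c("junction_key", "del_left", "del_right", "deletion_length", "ins_len", "mh_len")]
  )
  feats <- feats[!duplicated(feats$junction_key), , drop = FALSE]
  del_only <- feats$deletion_length > 0L & feats$ins_len == 0L
  feats <- feats[del_only, , drop = FALSE]
  if (!nrow(feats)) {
    return(cbind(feats,
      count_wt = integer(0), count_null = integer(0),
      p_value = numeric(0)
    ))
  }
  cw <- pw$table$count[match(feats$junction_key, pw$table$junction_key)]
  cn <- pn$table$count[match(feats$junction_key, pn$table$junction_key)]
  cw[is.na(cw)] <- 0L
  cn[is.na(cn)] <- 0L
  Tw <- pw$repair_total
  Tn <- pn$repair_total
  # one-sided exact conditional test: P(X <= count_null) with
  # X ~ Hypergeometric(m = count_wt + count_null, n = rest, k = Tn)
  p <- stats::phyper(cn, cw + cn, (Tw - cw) + (Tn - cn), Tn)
  out <- feats
  out$count_wt <- as.integer(cw)
  out$count_null <- as.integer(cn)
  out$p_value <- p
  out <- out[order(out$p_value, out$junction_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up rejection
#'
#' Applies the standard BH step-up rule: with ordered p-values p(1) <= ... <=
#' p(m), reject all hypotheses with rank `i <= max{k : p(k) <= k*fdr/m}`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param fdr Target false discovery rate (default 0.10).
#' @return Logical vector aligned with `p`: `TRUE` where rejected.
#' @examples
#' bh_reject(c(0.001, 0.02, 0.04, 0.5), fdr = 0.10) # first three rejected
#' @export
bh_reject <- function(p, fdr = 0.10) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE), fdr > 0, fdr < 1)
  if (!length(p)) return(logical(0))
  stats::p.adjust(p, method = "BH") <= fdr
}

#' Identify the TMEJ deletion-signature set
#'
#' Runs [test_depletion()] on wild-type vs Polq-null junction tables and
#' applies the Benjamini-Hochberg procedure at the given FDR. Deletion
#' junctions rejected by the step-up rule constitute the TMEJ signature: the
#' set of repair products with a significant TMEJ contribution, used to
#' classify reads in every condition.
#'
#' @inheritParams test_depletion
#' @param fdr False discovery rate for the BH procedure (default 0.10).
#' @return An object of class `tmej_signature`: a list with `table` (the
#'   per-junction test results plus a `rejected` column and BH rank),
#'   `members` (character vector of signature junction keys), `fdr`, and the
#'   pooled `repair_totals`.
#' @examples
#' loc <- make_locus(seed = 1)
#' sim <- simulate_two_conditions(loc, n_reads = 2000, seed = 7,
#'                                substitution_rate = 0, ambiguity_rate = 0)
#' wt <- tabulate_junctions(call_junctions(trim_reads(sim$wt$reads, loc$primer_fwd), loc))
#' nl <- tabulate_junctions(call_junctions(trim_reads(sim$polq_null$reads, loc$primer_fwd), loc))
#' sig <- tmej_signature(wt, nl, fdr = 0.10)
#' sig
#' @export
tmej_signature <- function(wt, polq_null, fdr = 0.10) {
  res <- test_depletion(wt, polq_null)
  res$rejected <- bh_reject(res$p_value, fdr)
  res$bh_rank <- rank(res$p_value, ties.method = "first")
  structure(
    list(
      table = res,
      members = res$junction_key[res$rejected],
      fdr = fdr,
      repair_totals = c(
        wt = pool_tables(wt)$repair_total,
        polq_null = pool_tables(polq_null)$repair_total
      )
    ),
    class = "tmej_signature"
  )
}

#' @export
print.tmej_signature <- function(x, ...) {
  cat(sprintf(
    "<tmej_signature> %d deletion junctions tested, %d in signature (FDR %.0f%%)\n",
    nrow(x$table), length(x$members), 100 * x$fdr
  ))
  cat(sprintf(
    "  repair totals: wt = %d, polq_null = %d\n",
    x$repair_totals[["wt"]], x$repair_totals[["polq_null"]]
  ))
  invisible(x)
}

#' @method summary tmej_signature
#' @export
summary.tmej_signature <- function(object, ...) {
  tab <- object$table
  sig <- tab[tab$rejected, , drop = FALSE]
  cat(sprintf(
    "TMEJ deletion signature: %d of %d deletion junctions (FDR %.0f%%)\n",
    nrow(sig), nrow(tab), 100 * object$fdr
  ))
  if (nrow(sig)) {
    cat(sprintf(
      "  signature reads: %d/%d (%.1f%%) of wild-type repair, %d/%d (%.1f%%) of null repair\n",
      sum(sig$count_wt), object$repair_totals[["wt"]],
      100 * sum(sig$count_wt) / object$repair_totals[["wt"]],
      sum(sig$count_null), object$repair_totals[["polq_null"]],
      100 * sum(sig$count_null) / object$repair_totals[["polq_null"]]
    ))
    print.data.frame(utils::head(
      sig[, c("junction_key", "deletion_length", "mh_len", "count_wt", "count_null", "p_value")],
      10L
    ))
  }
  invisible(object)
}

#' Write a signature set as annotated TSV
#'
#' @param signature A `tmej_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "tmej_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fdr=%g", signature$fdr),
    sprintf(
      "# repair_total_wt=%d repair_total_null=%d",
      signature$repair_totals[["wt"]], signature$repair_totals[["polq_null"]]
    ),
    "# columns: junction_key del_left del_right deletion_length ins_len mh_len count_wt count_null p_value rejected bh_rank"
  ), con)
  utils::write.table(signature$table, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
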