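#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]:
#' locus generation parameters, simulation settings (read counts, event
#' mixture, error rates, Polq-null depletion factor), analysis thresholds
#' (anchor length via the locus, NHEJ indel/microhomology bounds, FDR),
#' the calibrator sample, and optional assay-simulation blocks. Any element
#' can be overridden via a YAML config file or the `config` argument.
#'
#' @return Named list of configuration defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    locus = list(seed = 1L, length = 240L),
    simulate = list(
      n_reads = 5000L,
      depletion = 12.7 / 19,
      substitution_rate = 1e-3,
      ambiguity_rate = 2e-3
    ),
    fdr = 0.10,
    nhej = list(max_indel = 5L, min_mh = 2L),
    calibrator = "wt",
    ddpcr = list(
      ssdna = c(flank_d8 = 0.091, flank_d284 = 0.038, flank_d527 = 0.017),
      broken = 0.2, lambda_ref = 0.5, n_droplets = 20000L
    ),
    qpcr = list(true_rel = c(wt = 1.0, olaparib = 0.61, polq_null = 0.02))
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> trim -> call -> tabulate -> signature -> classify ->
#' quantify and writes every intermediate table plus a run manifest to
#' `out_dir`. Re-running with the same configuration and seed reproduces
#' byte-identical outputs.
#'
#' Outputs written: `locus.yaml`, `reads_<condition>.fastq.gz`,
#' `truth_<condition>.tsv`, `junctions_<condition>.tsv` (junction tables),
#' `signature.tsv`, `fractions.tsv`, `deltas.tsv`, `ddpcr_wells.csv`,
#' `resection.csv`, `qpcr_ct.csv`, `qpcr_relative.csv`, `manifest.json`.
#'
#' @param config `NULL` (defaults), a configuration list, or a path to a YAML
#'   file; entries override [default_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with the locus, junction tables, signature,
#'   fractions, deltas, resection profile, and qPCR results.
#' @export
run_pipeline <- function(config = NULL, out_dir = "tmejscan_run", seed = NULL) {
  cfg <- default_pipeline_config()
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  locus <- make_locus(
    seed = cfg$locus$seed %||% cfg$seed,
    length = cfg$locus$length %||% 240L
  )
  write_locus_config(locus, file.path(out_dir, "locus.yaml"))

  sim <- simulate_two_conditions(
    locus,
    n_reads = cfg$simulate$n_reads,
    depletion = cfg$simulate$depletion,
    seed = cfg$seed,
    substitution_rate = cfg$simulate$substitution_rate,
    ambiguity_rate = cfg$simulate$ambiguity_rate
  )

  tables <- list()
  for (cond in c("wt", "polq_null")) {
    s <- sim[[cond]]
    write_fastq(s$reads, file.path(out_dir, sprintf("reads_%s.fastq.gz", cond)))
    write_tsv(s$truth, file.path(out_dir, sprintf("truth_%s.tsv", cond)),
      comments = "simulator ground truth, one row per read"
    )
    trimmed <- trim_reads(s$reads, locus$primer_fwd)
    calls <- call_junctions(trimmed, locus)
    tbl <- tabulate_junctions(calls, sample_id = cond)
    write_junction_table(tbl, file.path(out_dir, sprintf("junctions_%s.tsv", cond)))
    tables[[cond]] <- tbl
  }

  sig <- tmej_signature(tables$wt, tables$polq_null, fdr = cfg$fdr)
  write_signature(sig, file.path(out_dir, "signature.tsv"))

  fr <- pathway_fractions(tables, sig,
    max_indel = cfg$nhej$max_indel, min_mh = cfg$nhej$min_mh
  )
  write_tsv(fr, file.path(out_dir, "fractions.tsv"),
    comments = "class fractions of all PASS repair reads per sample"
  )
  deltas <- tmej_contribution(fr, cfg$calibrator)
  write_tsv(deltas, file.path(out_dir, "deltas.tsv"),
    comments = "percentage-point differences relative to the calibrator"
  )

  wells <- simulate_ddpcr(
    ssdna = unlist(cfg$ddpcr$ssdna), broken = cfg$ddpcr$broken,
    lambda_ref = cfg$ddpcr$lambda_ref, n_droplets = cfg$ddpcr$n_droplets,
    seed = cfg$seed + 2L
  )
  utils::write.csv(wells, file.path(out_dir, "ddpcr_wells.csv"), row.names = FALSE)
  prof <- resection_profile(wells)
  resection <- data.frame(
    quantity = c(paste0("ssdna_", names(prof$ssdna)), "broken_fraction", "deletion_fraction"),
    value = c(unname(prof$ssdna), prof$broken_fraction, prof$deletion_fraction)
  )
  utils::write.csv(resection, file.path(out_dir, "resection.csv"), row.names = FALSE)

  qp <- simulate_qpcr(unlist(cfg$qpcr$true_rel), seed = cfg$seed + 3L)
  utils::write.csv(qp, file.path(out_dir, "qpcr_ct.csv"), row.names = FALSE)
  qrel <- quantify_qpcr(qp, calibrator = names(cfg$qpcr$true_rel)[1])
  utils::write.csv(qrel, file.path(out_dir, "qpcr_relative.csv"), row.names = FALSE)

  manifest <- list(
    package = "tmejscan",
    version = as.character(utils::packageVersion("tmejscan")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    n_reads = cfg$simulate$n_reads,
    depletion = cfg$simulate$depletion,
    fdr = cfg$fdr,
    attrition = lapply(tables, function(t) as.list(attr(t, "attrition"))),
    signature_size = length(sig$members)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    locus = locus, tables = tables, signature = sig, fractions = fr,
    deltas = deltas, resection = prof, qpcr = qrel, out_dir = out_dir
  ))
}

#' Relative signature abundance from a long-format Ct table
#'
#' Averages replicate Ct values per sample/amplicon and applies
#' [relative_signature()] against the calibrator sample.
#'
#' @param ct_table Data.frame with columns `sample_id`, `amplicon`
#'   (`"signature"`/`"reference"`), `ct` (as produced by [simulate_qpcr()] or
#'   read from CSV).
#' @param calibrator Calibrator `sample_id`.
#' @param efficiency Amplification efficiency (default 2).
#' @return Data.frame with `sample_id` and `relative` (fraction of
#'   calibrator).
#' @export
quantify_qpcr <- function(ct_table, calibrator, efficiency = 2) {
  need <- c("sample_id", "amplicon", "ct")
  stopifnot(all(need %in% names(ct_table)))
  mean_ct <- stats::aggregate(ct ~ sample_id + amplicon, ct_table, mean)
  wide <- stats::reshape(mean_ct,
    idvar = "sample_id", timevar = "amplicon", direction = "wide"
  )
  names(wide) <- sub("^ct\\.", "", names(wide))
  i <- match(calibrator, wide$sample_id)
  if (is.na(i)) stop(sprintf("calibrator sample '%s' not found", calibrator), call. = FALSE)
  data.frame(
    sample_id = wide$sample_id,
    relative = relative_signature(
      wide$signature, wide$reference,
      wide$signature[i], wide$reference[i],
      efficiency = efficiency
    ),
    stringsAsFactors = FALSE
  )
}
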