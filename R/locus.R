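#' Reference locus for a Cas9 amplicon
#'
#' Describes the amplified locus around a Cas9 cut site: the amplicon sequence,
#' the cut-site coordinate, and the two PCR primers delimiting the amplicon.
#' All junction calls are expressed in coordinates of this sequence.
#'
#' @param name Identifier for the locus.
#' @param sequence Uppercase DNA string (A/C/G/T only), the full amplicon.
#' @param cut_site Integer: number of bases to the left of the blunt Cas9 cut,
#'   i.e. the 1-based index of the last base on the left of the cut. Cas9 cuts
#'   3 bp 5' of the PAM; store the resolved coordinate here, not the PAM.
#' @param primer_fwd Forward primer sequence; must occur exactly once at the
#'   amplicon in forward orientation.
#' @param primer_rev Reverse primer sequence (its own 5'->3' orientation); its
#'   reverse complement must occur exactly once in the amplicon.
#' @param anchor_length Exact-match anchor length used by the junction caller
#'   (default 10 nt).
#'
#' @return An object of class `locus_reference`.
#' @examples
#' loc <- locus_reference("toy",
#'   sequence = paste0(strrep("ACGT", 10), "TTGACGGAAC", strrep("TGCA", 10)),
#'   cut_site = 45)
#' loc
#' @export
locus_reference <- function(name, sequence, cut_site,
                            primer_fwd = NULL, primer_rev = NULL,
                            anchor_length = 10L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("locus sequence may contain only A/C/G/T", call. = FALSE)
  }
  L <- nchar(sequence)
  cut_site <- as.integer(cut_site)
  anchor_length <- as.integer(anchor_length)
  if (anchor_length < 2L) stop("anchor_length must be >= 2", call. = FALSE)
  if (cut_site < anchor_length || L - cut_site < anchor_length) {
    stop(sprintf(
      "cut_site must leave at least anchor_length (%d) bases on each side",
      anchor_length
    ), call. = FALSE)
  }
  if (!is.null(primer_fwd)) {
    primer_fwd <- toupper(primer_fwd)
    if (length(find_all(sequence, primer_fwd)) != 1L) {
      stop("primer_fwd must occur exactly once in the amplicon", call. = FALSE)
    }
  }
  if (!is.null(primer_rev)) {
    primer_rev <- toupper(primer_rev)
    if (length(find_all(sequence, revcomp(primer_rev))) != 1L) {
      stop("reverse complement of primer_rev must occur exactly once in the amplicon",
           call. = FALSE)
    }
  }
  structure(
    list(
      name = as.character(name),
      sequence = sequence,
      cut_site = cut_site,
      primer_fwd = primer_fwd,
      primer_rev = primer_rev,
      anchor_length = anchor_length
    ),
    class = "locus_reference"
  )
}

#' @export
print.locus_reference <- function(x, ...) {
  cat(sprintf(
    "<locus_reference> %s: %d bp amplicon, cut after base %d (anchor %d nt)\n",
    x$name, nchar(x$sequence), x$cut_site, x$anchor_length
  ))
  left <- substr(x$sequence, max(1L, x$cut_site - 19L), x$cut_site)
  right <- substr(x$sequence, x$cut_site + 1L, min(nchar(x$sequence), x$cut_site + 20L))
  cat(sprintf("  ...%s / %s...\n", left, right))
  invisible(x)
}

#' Read a locus description from a YAML config file
#'
#' The file must contain keys `name`, `sequence`, `cut_site`, and optionally
#' `primer_fwd`, `primer_rev`, `anchor_length`.
#'
#' @param path Path to a YAML file.
#' @return A [locus_reference()] object.
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (k in c("name", "sequence", "cut_site")) {
    if (is.null(cfg[[k]])) stop(sprintf("locus config missing key '%s'", k), call. = FALSE)
  }
  locus_reference(
    name = cfg$name, sequence = cfg$sequence, cut_site = cfg$cut_site,
    primer_fwd = cfg$primer_fwd, primer_rev = cfg$primer_rev,
    anchor_length = cfg$anchor_length %||% 10L
  )
}

#' Write a locus description to a YAML config file
#'
#' @param locus A [locus_reference()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_config <- function(locus, path) {
  stopifnot(inherits(locus, "locus_reference"))
  yaml::write_yaml(
    list(
      name = locus$name, sequence = locus$sequence, cut_site = locus$cut_site,
      primer_fwd = locus$primer_fwd, primer_rev = locus$primer_rev,
      anchor_length = locus$anchor_length
    ),
    path
  )
  invisible(path)
}
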