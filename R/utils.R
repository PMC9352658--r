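# Internal string / RNG helpers shared across the package.

# All occurrences (overlapping allowed) of fixed pattern `pat` in `x`.
# Returns integer start positions, possibly empty.
find_all <- function(x, pat) {
  out <- integer(0)
  from <- 1L
  n <- nchar(x)
  w <- nchar(pat)
  if (w == 0L || w > n) return(out)
  repeat {
    m <- regexpr(pat, substr(x, from, n), fixed = TRUE)
    if (m == -1L) break
    pos <- from + as.integer(m) - 1L
    out <- c(out, pos)
    from <- pos + 1L
    if (from + w - 1L > n) break
  }
  out
}

# character -> vector of single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

base_at <- function(x, i) substr(x, i, i)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Set the RNG seed locally; returns a function restoring the previous state.
# Call as: restore <- push_seed(seed); on.exit(restore(), add = TRUE)
push_seed <- function(seed) {
  if (is.null(seed)) return(function() invisible(NULL))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
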