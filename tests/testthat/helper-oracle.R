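# Independent brute-force oracle for junction reconstruction: enumerates ALL
# anchor placements, keeps those minimizing total deletion, then applies the
# same canonicalization rules as the spec of the caller (shortest insertion,
# largest del_left, left-aligned deletion registers). Naive loops throughout;
# shares no code with the package implementation.

oracle_find_all <- function(x, pat) {
  n <- nchar(x)
  w <- nchar(pat)
  out <- integer(0)
  if (w < 1L || w > n) return(out)
  for (s in 1:(n - w + 1L)) {
    if (substr(x, s, s + w - 1L) == pat) out <- c(out, s)
  }
  out
}

oracle_call <- function(read, ref, cut, A = 10L) {
  L <- nchar(ref)
  n <- nchar(read)
  unal <- list(
    status = "UNALIGNABLE", del_left = NA_integer_, del_right = NA_integer_,
    deletion_length = NA_integer_, insertion = NA_character_, mh_len = NA_integer_
  )
  if (n < 2L * A) return(unal)
  cand <- list()
  for (dl in 0:(cut - A)) {
    occ <- oracle_find_all(read, substr(ref, cut - dl - A + 1L, cut - dl))
    if (!length(occ)) next
    i <- occ[1] + A - 1L # leftmost upstream occurrence (end position)
    for (dr in 0:(L - cut - A)) {
      occ2 <- oracle_find_all(read, substr(ref, cut + 1L + dr, cut + dr + A))
      if (!length(occ2)) next
      j <- occ2[length(occ2)] # rightmost downstream occurrence (start position)
      if (j < i + 1L) next
      cand[[length(cand) + 1L]] <- c(t = dl + dr, inslen = j - i - 1L, dl = dl, dr = dr, i = i, j = j)
    }
  }
  if (!length(cand)) return(unal)
  cand <- do.call(rbind, cand)
  cand <- cand[cand[, "t"] == min(cand[, "t"]), , drop = FALSE]
  cand <- cand[cand[, "inslen"] == min(cand[, "inslen"]), , drop = FALSE]
  best <- cand[which.max(cand[, "dl"]), ]
  dl <- best[["dl"]]; dr <- best[["dr"]]
  t <- dl + dr
  ins <- if (best[["inslen"]] > 0L) substr(read, best[["i"]] + 1L, best[["j"]] - 1L) else ""
  mh <- 0L
  if (ins == "" && t > 0L) {
    s <- cut - dl
    e <- cut + dr
    kl <- 0L
    while (s - kl >= 1L && substr(ref, s - kl, s - kl) == substr(ref, e - kl, e - kl)) kl <- kl + 1L
    kr <- 0L
    while (e + kr + 1L <= L &&
           substr(ref, s + kr + 1L, s + kr + 1L) == substr(ref, e + kr + 1L, e + kr + 1L)) {
      kr <- kr + 1L
    }
    mh <- min(kl + kr, t)
    shift <- min(kl, dr)
    dl <- dl + shift
    dr <- dr - shift
  }
  list(
    status = if (t == 0L && ins == "") "INTACT" else "PASS",
    del_left = dl, del_right = dr, deletion_length = t,
    insertion = ins, mh_len = mh
  )
}

# brute-force BH step-up: reject everything up to the largest k with
# p(k) <= k*q/m
oracle_bh <- function(p, q) {
  m <- length(p)
  if (!m) return(logical(0))
  o <- order(p)
  ps <- p[o]
  kmax <- 0L
  for (k in 1:m) if (ps[k] <= k * q / m) kmax <- k
  rej_sorted <- seq_len(m) <= kmax
  rej <- logical(m)
  rej[o] <- rej_sorted
  rej
}

# random toy locus + read pairs exercising every event shape; returns a list
# of cases, each with ref/cut/read
oracle_cases <- function(n_cases, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  cases <- vector("list", n_cases)
  for (k in seq_len(n_cases)) {
    L <- sample(48:70, 1)
    ref <- paste(sample(bases, L, replace = TRUE), collapse = "")
    cut <- sample((10 + 4):(L - 10 - 4), 1)
    kind <- sample(c("intact", "del", "ins", "delins", "junk", "subst"), 1)
    read <- switch(kind,
      intact = ref,
      del = {
        dl <- sample(0:min(8, cut - 10), 1)
        dr <- sample(0:min(8, L - cut - 10), 1)
        paste0(substr(ref, 1, cut - dl), substr(ref, cut + dr + 1, L))
      },
      ins = {
        w <- sample(1:12, 1)
        ins <- if (runif(1) < 0.5) {
          paste(sample(bases, w, replace = TRUE), collapse = "")
        } else {
          a <- sample(max(1, cut - 20):(min(L, cut + 20) - w + 1), 1)
          substr(ref, a, a + w - 1)
        }
        paste0(substr(ref, 1, cut), ins, substr(ref, cut + 1, L))
      },
      delins = {
        dl <- sample(0:min(6, cut - 10), 1)
        dr <- sample(0:min(6, L - cut - 10), 1)
        w <- sample(1:6, 1)
        ins <- paste(sample(bases, w, replace = TRUE), collapse = "")
        paste0(substr(ref, 1, cut - dl), ins, substr(ref, cut + dr + 1, L))
      },
      junk = paste(sample(bases, L, replace = TRUE), collapse = ""),
      subst = {
        v <- strsplit(ref, "")[[1]]
        for (q in sample(L, sample(1:3, 1))) v[q] <- sample(setdiff(bases, v[q]), 1)
        paste(v, collapse = "")
      }
    )
    cases[[k]] <- list(ref = ref, cut = cut, read = read, kind = kind)
  }
  cases
}

# compare package call vs oracle on a list of cases; returns fraction agreeing
oracle_agreement <- function(cases) {
  ok <- vapply(cases, function(cs) {
    loc <- locus_reference("toy", cs$ref, cs$cut)
    got <- call_junction(cs$read, loc, apply_filters = FALSE)
    exp <- oracle_call(cs$read, cs$ref, cs$cut)
    if (exp$status == "UNALIGNABLE") {
      return(got$status == "UNALIGNABLE")
    }
    identical(got$status, exp$status) &&
      identical(as.integer(got$del_left), as.integer(exp$del_left)) &&
      identical(as.integer(got$del_right), as.integer(exp$del_right)) &&
      identical(as.integer(got$deletion_length), as.integer(exp$deletion_length)) &&
      identical(as.character(got$insertion), exp$insertion) &&
      identical(as.integer(got$mh_len), as.integer(exp$mh_len))
  }, logical(1))
  mean(ok)
}
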