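# Exhaustive-partition oracle for junction decomposition.
#
# Independent of the package implementation: enumerates every legal
# assignment (V prefix length, J suffix length, all single D matches and all
# disjoint ordered pairs of D sub-matches found by direct substring search)
# and scores it with the same objective the decomposition contract states:
# maximal templated + P coverage, then maximal templated, then larger V,
# larger J, leftmost/longest first then second D match. P is the maximal
# reverse-complement palindromic run at an untrimmed V/J end, capped by gap
# space (V side first).

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

oracle_lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b)); k <- 0L
  while (k < n && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L))
    k <- k + 1L
  k
}

# all (start, len) with len >= min_d such that the window substring matches
# some D sequence; start is 1-based within the window string
oracle_d_matches <- function(win, d_seqs, min_d) {
  out <- list()
  W <- nchar(win)
  if (W < min_d) return(out)
  for (s in seq_len(W - min_d + 1L)) {
    for (l in min_d:(W - s + 1L)) {
      sub <- substr(win, s, s + l - 1L)
      if (any(vapply(d_seqs, function(d) grepl(sub, d, fixed = TRUE),
                     logical(1))))
        out[[length(out) + 1L]] <- c(s, l)
    }
  }
  out
}

oracle_pal_v <- function(jx, vt, v, max_p) {
  k <- 0L
  L <- nchar(jx); vl <- nchar(vt)
  while (k < max_p && v + k + 1L <= L && k < vl &&
         substr(jx, v + k + 1L, v + k + 1L) ==
         chartr("ACGT", "TGCA", substr(vt, vl - k, vl - k)))
    k <- k + 1L
  k
}

oracle_pal_j <- function(jx, jt, jstart, max_p) {
  # jstart: 1-based position of the first J nucleotide in the junction
  k <- 0L
  while (k < max_p && jstart - 1L - k >= 1L && k < nchar(jt) &&
         substr(jx, jstart - 1L - k, jstart - 1L - k) ==
         chartr("ACGT", "TGCA", substr(jt, k + 1L, k + 1L)))
    k <- k + 1L
  k
}

oracle_decompose <- function(junction, vt, jt, d_seqs,
                             min_d = 3L, max_p = 3L, max_d = 2L) {
  L <- nchar(junction)
  maxv <- oracle_lcp(junction, vt)
  rj <- paste(rev(strsplit(junction, "")[[1]]), collapse = "")
  rt <- paste(rev(strsplit(jt, "")[[1]]), collapse = "")
  maxj <- oracle_lcp(rj, rt)
  best <- NULL
  score_of <- function(v, j, ivs) {
    # ivs: list of c(start, len) in junction coordinates (1-based), ordered
    dtot <- sum(vapply(ivs, `[`, 0, 2))
    T <- v + j + dtot
    # P at V end
    pv <- 0L
    if (v == nchar(vt) && v > 0L) {
      space <- (if (length(ivs)) ivs[[1]][1] - 1L else L - j) - v
      pv <- min(oracle_pal_v(junction, vt, v, max_p), max(0L, space))
    }
    pj <- 0L
    if (j == nchar(jt) && j > 0L) {
      gap_lo <- if (length(ivs)) ivs[[length(ivs)]][1] +
        ivs[[length(ivs)]][2] else v + pv
      space <- (L - j + 1L) - gap_lo
      # V-side claim has priority when both share the same gap
      if (length(ivs) == 0L) space <- L - j - v - pv
      pj <- min(oracle_pal_j(junction, jt, L - j + 1L, max_p),
                max(0L, space))
    }
    i1s <- if (length(ivs) >= 1L) ivs[[1]][1] else Inf
    i1l <- if (length(ivs) >= 1L) ivs[[1]][2] else 0L
    i2s <- if (length(ivs) >= 2L) ivs[[2]][1] else Inf
    i2l <- if (length(ivs) >= 2L) ivs[[2]][2] else 0L
    list(key = c(T + pv + pj, T, v, j, -i1s, i1l, -i2s, i2l),
         T = T, P = pv + pj, v = v, j = j, n = L - T - pv - pj)
  }
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    for (i in seq_along(a$key)) {
      if (a$key[i] > b$key[i]) return(TRUE)
      if (a$key[i] < b$key[i]) return(FALSE)
    }
    FALSE
  }
  for (v in 0:maxv) {
    for (j in 0:maxj) {
      if (v + j > L) next
      win <- substr(junction, v + 1L, L - j)
      cand <- score_of(v, j, list())
      if (better(cand, best)) best <- cand
      if (max_d >= 1L && length(d_seqs)) {
        ms <- oracle_d_matches(win, d_seqs, min_d)
        for (m in ms) {
          iv1 <- c(m[1] + v, m[2])
          cand <- score_of(v, j, list(iv1))
          if (better(cand, best)) best <- cand
        }
        if (max_d >= 2L) {
          for (a in ms) for (b in ms) {
            if (a[1] + a[2] <= b[1]) {      # disjoint, a before b
              cand <- score_of(v, j, list(c(a[1] + v, a[2]),
                                          c(b[1] + v, b[2])))
              if (better(cand, best)) best <- cand
            }
          }
        }
      }
    }
  }
  list(templated_total = best$T, n_additions_total = best$n,
       p_total = best$P, v_match_len = best$v, j_match_len = best$j)
}

# recombination-style random junction against a germline subset: pieces of
# V suffix, optional D substring(s), random N, J prefix
random_junction <- function(gdb, vname, jname, dnames, max_len = 33L) {
  vt <- gdb$junction_template_nt[gdb$name == vname]
  jt <- gdb$junction_template_nt[gdb$name == jname]
  repeat {
    vlen <- sample.int(min(nchar(vt), 12L), 1L)
    jlen <- sample.int(min(nchar(jt), 12L), 1L)
    mid <- ""
    if (length(dnames) && stats::runif(1) < 0.7) {
      dn <- sample(dnames, 1L)
      dt <- gdb$junction_template_nt[gdb$name == dn]
      s <- sample.int(nchar(dt), 1L)
      l <- sample.int(nchar(dt) - s + 1L, 1L)
      mid <- substr(dt, s, s + l - 1L)
    }
    n1 <- paste0(sample(c("A", "C", "G", "T"),
                        stats::rpois(1, 2), replace = TRUE), collapse = "")
    n2 <- paste0(sample(c("A", "C", "G", "T"),
                        stats::rpois(1, 2), replace = TRUE), collapse = "")
    jx <- paste0(substr(vt, 1L, vlen), n1, mid, n2,
                 substr(jt, nchar(jt) - jlen + 1L, nchar(jt)))
    if (nchar(jx) >= 6L && nchar(jx) <= max_len) return(jx)
  }
}
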