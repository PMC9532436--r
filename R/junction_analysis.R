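#' Decomposition parameters
#'
#' @param min_d_match Minimum length (nt) of an exact D-segment match
#'   assignable inside a junction. Default 3.
#' @param max_p Maximum length (nt) of a palindromic (P) extension recognised
#'   at an untrimmed germline end. Default 3.
#' @param max_d Maximum number of D-segment matches per junction (tandem D
#'   usage). Default 2.
#' @return A list of parameters for [decompose()].
#' @export
junction_params <- function(min_d_match = 3L, max_p = 3L, max_d = 2L) {
  stopifnot(min_d_match >= 1L, max_p >= 0L, max_d >= 0L)
  list(min_d_match = as.integer(min_d_match), max_p = as.integer(max_p),
       max_d = as.integer(max_d))
}

#' Decompose a junction into templated, P and N parts
#'
#' Partitions a junction nucleotide sequence into a V-templated prefix (an
#' exact prefix match against the V junction template), a J-templated suffix,
#' up to `max_d` exact interior D-segment matches of length at least
#' `min_d_match`, palindromic (P) nucleotides adjacent to untrimmed germline
#' ends, and non-templated (N) additions. The decomposition minimises the N
#' count (equivalently, maximises templated + P nucleotides), preferring more
#' templated nucleotides, then a longer V match, then a longer J match, then
#' the leftmost and longest D matches, so the result is deterministic.
#'
#' @param junction_nt Junction nucleotide string (ACGT).
#' @param v_seg,j_seg One-row germline database entries (or `NULL` for no
#'   template) whose `junction_template_nt` is matched.
#' @param d_segs Germline database rows of D segments (may have zero rows).
#' @param params See [junction_params()].
#' @return A list with elements `v_match_len`, `j_match_len`, `d_matches`
#'   (data.frame `d_name`, `start` (0-based), `length`), `p_nt_5v`,
#'   `p_nt_3j`, `p_nt_5d`, `p_nt_3d`, `n_regions`, `n_additions_total`,
#'   `templated_total`, `junction_nt_length`. Components always satisfy
#'   `v + j + sum(d) + sum(P) + N == junction_nt_length`.
#' @export
decompose <- function(junction_nt, v_seg, j_seg, d_segs = NULL,
                      params = junction_params()) {
  junction_nt <- toupper(junction_nt)
  if (!.valid_nt(junction_nt))
    stop("junction contains non-ACGT characters")
  if (nchar(junction_nt) < 6L)
    stop("junction shorter than 6 nt")
  vt <- if (is.null(v_seg)) "" else v_seg$junction_template_nt[1]
  jt <- if (is.null(j_seg)) "" else j_seg$junction_template_nt[1]
  dseq <- character(0)
  dnames <- character(0)
  if (!is.null(d_segs) && nrow(d_segs) > 0L) {
    dseq <- d_segs$junction_template_nt
    dnames <- d_segs$name
  }
  res <- .decompose_cpp(junction_nt, vt, jt, dseq,
                        params$min_d_match, params$max_p, params$max_d)
  dm <- data.frame(
    d_name = if (length(res$d_index)) dnames[res$d_index] else character(0),
    start = res$d_start, length = res$d_length,
    stringsAsFactors = FALSE)
  out <- list(v_match_len = res$v_match_len, j_match_len = res$j_match_len,
              d_matches = dm,
              p_nt_5v = res$p_nt_5v, p_nt_3j = res$p_nt_3j,
              p_nt_5d = res$p_nt_5d, p_nt_3d = res$p_nt_3d,
              n_regions = res$n_regions,
              n_additions_total = res$n_additions_total,
              templated_total = res$templated_total,
              junction_nt_length = res$junction_nt_length)
  class(out) <- "junction_decomposition"
  out
}

#' @export
print.junction_decomposition <- function(x, ...) {
  cat("junction decomposition (", x$junction_nt_length, " nt)\n", sep = "")
  cat("  V match:", x$v_match_len, "nt  J match:", x$j_match_len, "nt\n")
  if (nrow(x$d_matches))
    cat("  D:", paste0(x$d_matches$d_name, "[", x$d_matches$length, " nt]",
                       collapse = " + "), "\n")
  cat("  P:", x$p_nt_5v + x$p_nt_3j + x$p_nt_5d + x$p_nt_3d,
      "nt  N additions:", x$n_additions_total, "nt\n")
  invisible(x)
}

.codon_table <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

#' Translate a junction nucleotide sequence
#'
#' Standard-code translation. An internal stop codon flags the junction as
#' unproductive rather than raising an error.
#'
#' @param junction_nt Nucleotide string, length divisible by 3.
#' @return A list with `junction_aa` and logical `productive` (FALSE when an
#'   internal stop codon is present).
#' @export
translate_junction <- function(junction_nt) {
  junction_nt <- toupper(junction_nt)
  n <- nchar(junction_nt)
  if (n %% 3L != 0L) stop("junction not codon-aligned (length ", n, ")")
  if (!.valid_nt(junction_nt)) stop("junction contains non-ACGT characters")
  codons <- substring(junction_nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(.codon_table[codons])
  list(junction_aa = paste0(aa, collapse = ""),
       productive = !any(aa == "*"))
}

#' Attach junction decomposition features to chain records
#'
#' Resolves each chain's `v_call`/`j_call` against the germline database
#' (allele suffixes such as `*01` are stripped), decomposes the junction, and
#' fills `n_additions_total`, `templated_total`, `junction_nt_length`,
#' `np1_length` and `np2_length`. TRG chains are decomposed without D
#' segments. Chains whose V or J cannot be resolved are flagged
#' `no_germline = TRUE` and excluded from N-addition statistics.
#'
#' @param chains A chain table as returned by [read_airr()].
#' @param germline_db A germline database (see [read_germline_fasta()]).
#' @param params See [junction_params()].
#' @return `chains` with feature columns appended.
#' @export
junction_features <- function(chains, germline_db, params = junction_params()) {
  stopifnot(is.data.frame(chains))
  n <- nrow(chains)
  chains$n_additions_total <- NA_integer_
  chains$templated_total <- NA_integer_
  chains$junction_nt_length <- nchar(chains$junction_nt)
  chains$np1_length <- NA_integer_
  chains$np2_length <- NA_integer_
  chains$no_germline <- FALSE
  if (n == 0L) return(chains)
  d_trd <- germline_db[germline_db$segment_type == "D", , drop = FALSE]
  # memoise: identical (junction, v, j, locus) triples are frequent
  key <- paste(chains$junction_nt, chains$v_call, chains$j_call, chains$locus)
  uidx <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  n_unresolved <- 0L
  for (i in which(uidx)) {
    v <- germline_lookup(germline_db, chains$v_call[i], "V")
    j <- germline_lookup(germline_db, chains$j_call[i], "J")
    if (is.null(v) || is.null(j)) {
      assign(key[i], NULL, envir = cache)
      n_unresolved <- n_unresolved + 1L
      next
    }
    dset <- if (identical(chains$locus[i], "TRG")) d_trd[0, ] else d_trd
    dec <- decompose(chains$junction_nt[i], v, j, dset, params)
    nr <- dec$n_regions
    assign(key[i], list(
      n = dec$n_additions_total, t = dec$templated_total,
      np1 = if (length(nr) >= 1L) nchar(nr[1]) else 0L,
      np2 = if (length(nr) >= 2L) nchar(nr[2]) else 0L), envir = cache)
  }
  for (i in seq_len(n)) {
    val <- get0(key[i], envir = cache, inherits = FALSE)
    if (is.null(val)) {
      chains$no_germline[i] <- TRUE
    } else {
      chains$n_additions_total[i] <- val$n
      chains$templated_total[i] <- val$t
      chains$np1_length[i] <- val$np1
      chains$np2_length[i] <- val$np2
    }
  }
  if (n_unresolved > 0L)
    message(n_unresolved, " chain(s) flagged no_germline (unresolvable V or J call)")
  chains
}
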