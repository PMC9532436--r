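#' Build a repertoire collection for publicity analysis
#'
#' A repertoire collection is the set of named single-cell and bulk datasets
#' over which CDR3 publicity is computed. Each dataset is reduced to its set
#' of distinct (locus, junction amino-acid sequence) keys. Bulk files that
#' belong to the same dataset id (e.g. the sorted Vg9Vd2 and nonVg9Vd2 files
#' of one subject) must be merged into one dataset before insertion; passing
#' them under the same name in `bulk` does this.
#'
#' @param sc Named list of single-cell chain tables (need columns `locus`,
#'   `junction_aa`).
#' @param bulk Named list of bulk clonotype tables (same columns). Repeated
#'   names are merged into one dataset.
#' @return A `repertoire_collection` object.
#' @export
repertoire_collection <- function(sc = list(), bulk = list()) {
  keyset <- function(df) {
    ok <- !is.na(df$junction_aa) & nzchar(df$junction_aa)
    unique(paste(df$locus[ok], df$junction_aa[ok], sep = "|"))
  }
  merge_named <- function(lst) {
    if (length(lst) == 0L) return(list())
    if (is.null(names(lst)) || any(!nzchar(names(lst))))
      stop("all datasets must be named")
    out <- list()
    for (nm in names(lst))
      out[[nm]] <- unique(c(out[[nm]], keyset(lst[[nm]])))
    out
  }
  sc_sets <- merge_named(sc)
  bulk_sets <- merge_named(bulk)
  if (any(names(sc_sets) %in% names(bulk_sets)))
    stop("dataset ids must be unique across sc and bulk datasets")
  structure(list(sc = sc_sets, bulk = bulk_sets),
            class = "repertoire_collection")
}

#' @export
print.repertoire_collection <- function(x, ...) {
  cat("repertoire collection: ", length(x$sc), " sc + ", length(x$bulk),
      " bulk dataset(s)\n", sep = "")
  invisible(x)
}

#' Compute CDR3 publicity levels across a repertoire collection
#'
#' For each distinct (locus, junction amino-acid sequence) key, counts the
#' number of datasets (single-cell plus bulk) containing it. The publicity
#' level is that count when the sequence occurs in two or more datasets, and
#' 0 when it is private to a single dataset; with the full study design of 9
#' single-cell and 10 bulk repertoires, levels therefore range from 0 to 19,
#' the self-inclusive convention that reconciles both printed extremes.
#' Publicity is keyed on the amino-acid sequence (V-gene-agnostic).
#'
#' @param collection A [repertoire_collection()].
#' @return A `publicity_table` data.frame with columns `locus`,
#'   `junction_aa`, `publicity_level`.
#' @export
compute_publicity <- function(collection) {
  stopifnot(inherits(collection, "repertoire_collection"))
  sets <- c(collection$sc, collection$bulk)
  if (length(sets) == 0L) stop("empty repertoire collection")
  keys <- unlist(sets, use.names = FALSE)
  cnt <- table(keys)
  level <- ifelse(cnt >= 2L, as.integer(cnt), 0L)
  parts <- strsplit(names(cnt), "|", fixed = TRUE)
  out <- data.frame(
    locus = vapply(parts, `[`, "", 1L),
    junction_aa = vapply(parts, function(p) paste(p[-1], collapse = "|"), ""),
    publicity_level = as.integer(level),
    stringsAsFactors = FALSE)
  class(out) <- c("publicity_table", "data.frame")
  out
}

#' Look up publicity levels for chains
#'
#' @param publicity A [compute_publicity()] table.
#' @param locus,junction_aa Vectors of keys.
#' @return Integer publicity levels (`NA` for sequences absent from the
#'   collection).
#' @export
publicity_lookup <- function(publicity, locus, junction_aa) {
  key <- paste(locus, junction_aa, sep = "|")
  tab <- stats::setNames(publicity$publicity_level,
                         paste(publicity$locus, publicity$junction_aa,
                               sep = "|"))
  unname(tab[key])
}

#' Classify cells as Vg9Vd2, non-Vg9Vd2 or unpaired
#'
#' A cell is `vg9vd2` when it carries at least one productive TRD chain using
#' TRDV2 and at least one productive TRG chain using TRGV9; `non_vg9vd2` when
#' both loci are detected but that pairing condition fails; and `unpaired`
#' when one of the two loci is missing. The call is symmetric in chain order
#' and unaffected by additional chains.
#'
#' @param cells A `gdtcr_cells` object.
#' @return A data.frame with `cell_id` and `vg9vd2_class`.
#' @export
classify_vg9vd2 <- function(cells) {
  stopifnot(inherits(cells, "gdtcr_cells"))
  ch <- cells$chains
  gene <- sub("\\*.*$", "", ch$v_call)
  d2 <- unique(ch$cell_id[ch$locus == "TRD" & gene == "TRDV2"])
  g9 <- unique(ch$cell_id[ch$locus == "TRG" & gene == "TRGV9"])
  has_d <- cells$cells$n_delta > 0L
  has_g <- cells$cells$n_gamma > 0L
  cls <- ifelse(!has_d | !has_g, "unpaired",
         ifelse(cells$cells$cell_id %in% d2 & cells$cells$cell_id %in% g9,
                "vg9vd2", "non_vg9vd2"))
  data.frame(cell_id = cells$cells$cell_id, vg9vd2_class = cls,
             stringsAsFactors = FALSE)
}

#' V gene segment usage per subject and group
#'
#' Computes, per subject and group, the fraction of chains of the given locus
#' using each V gene category. TRD categories default to TRDV1/TRDV2/TRDV3
#' with everything else (e.g. TRAV38-2DV8) grouped as "Others"; TRG
#' categories default to TRGV8/TRGV9 plus "Others". Cells without a chain of
#' the locus contribute nothing. Fractions sum to 1 within each
#' subject-group stratum.
#'
#' @param cells A `gdtcr_cells` object.
#' @param locus `"TRD"` or `"TRG"`.
#' @param grouping Name of the grouping column in the chain table (e.g.
#'   `"group_label"` or `"effector_type"`).
#' @param categories Character vector of V gene categories; other genes are
#'   pooled as `"Others"`.
#' @return A data.frame with columns `subject_id`, `group`, `gene`,
#'   `fraction`, `n_chains`.
#' @export
v_usage <- function(cells, locus = c("TRD", "TRG"), grouping = "group_label",
                    categories = NULL) {
  locus <- match.arg(locus)
  stopifnot(inherits(cells, "gdtcr_cells"))
  if (is.null(categories))
    categories <- if (locus == "TRD") c("TRDV1", "TRDV2", "TRDV3")
                  else c("TRGV8", "TRGV9")
  ch <- cells$chains[cells$chains$locus == locus, , drop = FALSE]
  if (nrow(ch) == 0L) stop("no productive ", locus, " chains")
  gene <- sub("\\*.*$", "", ch$v_call)
  cat <- ifelse(gene %in% categories, gene, "Others")
  cat <- factor(cat, levels = c(categories, "Others"))
  grp <- ch[[grouping]]
  out <- list()
  for (sid in unique(ch$subject_id)) {
    for (g in unique(grp[ch$subject_id == sid])) {
      sel <- ch$subject_id == sid & grp == g
      n <- sum(sel)
      tabs <- table(cat[sel]) / n
      out[[paste(sid, g)]] <- data.frame(
        subject_id = sid, group = g, gene = names(tabs),
        fraction = as.numeric(tabs), n_chains = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Hydrophobicity of the CDR3 position-5 residue
#'
#' Position 5 is counted with the leading conserved cysteine excluded, i.e.
#' the 6th residue of the printed junction (the only convention consistent
#' with the canonical public sequences: glycine at position 5 of
#' CACDTGGYWDTRQMFF, valine/leucine at position 5 of the LGDT family).
#'
#' @param junction_aa Character vector of junction amino-acid sequences.
#' @param hydrophobic_set Residues counted as hydrophobic (default
#'   V, L, I, M, F, W).
#' @return Logical vector; `NA` for junctions shorter than 6 residues or not
#'   starting with C (excluded from frequency statistics).
#' @export
position5_hydrophobic <- function(junction_aa,
                                  hydrophobic_set = c("V", "L", "I", "M",
                                                      "F", "W")) {
  res <- substr(junction_aa, 6L, 6L)
  ok <- nchar(junction_aa) >= 6L & substr(junction_aa, 1L, 1L) == "C"
  ifelse(ok, res %in% hydrophobic_set, NA)
}

#' Chain detection and double-delta rates
#'
#' Per dataset, the fraction of cells with at least one productive delta
#' chain, at least one productive gamma chain, and with two productive delta
#' chains; returns the mean over datasets together with the per-dataset
#' values.
#'
#' @param cells A `gdtcr_cells` object.
#' @return A list with `frac_delta`, `frac_gamma`, `frac_double_delta` and
#'   `per_dataset`.
#' @export
chain_detection_rates <- function(cells) {
  stopifnot(inherits(cells, "gdtcr_cells"))
  cc <- cells$cells
  if (nrow(cc) == 0L) stop("empty dataset")
  per <- do.call(rbind, lapply(split(cc, cc$dataset_id), function(d)
    data.frame(dataset_id = d$dataset_id[1],
               frac_delta = mean(d$n_delta > 0L),
               frac_gamma = mean(d$n_gamma > 0L),
               frac_double_delta = mean(d$n_delta == 2L),
               n_cells = nrow(d), stringsAsFactors = FALSE)))
  list(frac_delta = mean(per$frac_delta), frac_gamma = mean(per$frac_gamma),
       frac_double_delta = mean(per$frac_double_delta), per_dataset = per)
}

#' Display-scale quantile limits for CDR3 length colour scales
#'
#' Returns the lower/upper colour-scale clamps computed as the 0.2 and 0.8
#' quantiles of the supplied per-chain CDR3 nucleotide lengths (all TRDV2
#' chains pooled), the rule used for length UMAP colour scales.
#'
#' @param lengths Numeric vector of CDR3 nucleotide lengths.
#' @param probs Two quantile probabilities (default `c(0.2, 0.8)`).
#' @return Named numeric vector `c(lower=, upper=)`.
#' @export
cdr3_length_display_limits <- function(lengths, probs = c(0.2, 0.8)) {
  stopifnot(length(probs) == 2L, probs[1] < probs[2])
  q <- stats::quantile(lengths, probs = probs, na.rm = TRUE, names = FALSE)
  c(lower = q[1], upper = q[2])
}
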