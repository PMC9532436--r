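#' Read an AIRR Rearrangement TSV into a chain table
#'
#' Requires the AIRR columns `sequence_id`, `v_call`, `j_call`, `junction`,
#' `junction_aa` and `productive`; `cell_id`, `d_call`, `locus`,
#' `duplicate_count` and `dataset_id` are used when present. The locus is
#' taken from the `locus` column when available, otherwise inferred from the
#' `v_call` prefix (`TRD*` and hybrid `TRAV*DV*` genes map to TRD, `TRG*` to
#' TRG); rows whose locus cannot be parsed are skipped with a warning.
#'
#' @param path Path to a tab-separated AIRR Rearrangement file.
#' @param dataset_id Dataset label attached to every row (default: file name).
#' @return A chain table: one row per rearranged chain with columns
#'   `dataset_id`, `cell_id`, `locus`, `v_call`, `d_call`, `j_call`,
#'   `junction_nt`, `junction_aa`, `productive`, `duplicate_count`.
#' @export
read_airr <- function(path, dataset_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  required <- c("sequence_id", "v_call", "j_call", "junction", "junction_aa",
                "productive")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("AIRR format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(dataset_id))
    dataset_id <- if ("dataset_id" %in% names(df) && nrow(df) > 0L)
      df$dataset_id[1] else basename(path)
  loc <- if ("locus" %in% names(df)) df$locus else .infer_locus(df$v_call)
  bad <- is.na(loc) | !loc %in% c("TRD", "TRG")
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparsable or non-TRD/TRG locus skipped")
    df <- df[!bad, , drop = FALSE]
    loc <- loc[!bad]
  }
  data.frame(
    dataset_id = rep(dataset_id, nrow(df)),
    cell_id = if ("cell_id" %in% names(df)) df$cell_id else rep("", nrow(df)),
    locus = loc,
    v_call = df$v_call,
    d_call = if ("d_call" %in% names(df)) df$d_call else rep("", nrow(df)),
    j_call = df$j_call,
    junction_nt = toupper(df$junction),
    junction_aa = df$junction_aa,
    productive = .as_flag(df$productive),
    duplicate_count = if ("duplicate_count" %in% names(df))
      suppressWarnings(as.integer(df$duplicate_count)) else rep(NA_integer_, nrow(df)),
    stringsAsFactors = FALSE)
}

.infer_locus <- function(v_call) {
  ifelse(grepl("^TRD", v_call), "TRD",
  ifelse(grepl("^TRG", v_call), "TRG",
  ifelse(grepl("^TRAV.*DV", v_call), "TRD", NA_character_)))
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  toupper(as.character(x)) %in% c("T", "TRUE", "1")
}

#' Write a chain table as AIRR Rearrangement TSV
#'
#' Inverse of [read_airr()]: populated fields round-trip byte-identically
#' (junction strings included).
#'
#' @param chains A chain table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(chains, path) {
  out <- data.frame(
    sequence_id = if ("sequence_id" %in% names(chains)) chains$sequence_id
                  else sprintf("seq%06d", seq_len(nrow(chains))),
    cell_id = chains$cell_id,
    dataset_id = chains$dataset_id,
    locus = chains$locus,
    v_call = chains$v_call,
    d_call = chains$d_call,
    j_call = chains$j_call,
    junction = chains$junction_nt,
    junction_aa = chains$junction_aa,
    productive = ifelse(chains$productive, "T", "F"),
    duplicate_count = chains$duplicate_count,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a 10x filtered_contig_annotations.csv-style table
#'
#' Maps the CellRanger vdj contig-annotation dialect (columns `barcode`,
#' `chain`, `v_gene`, `d_gene`, `j_gene`, `cdr3`, `cdr3_nt`, `productive`,
#' `high_confidence`) to a chain table. Only TRD/TRG rows that are both
#' productive and high-confidence are kept; TRA/TRB/Multi rows are silently
#' excluded (gamma-delta-sorted design) and unknown chain values are skipped
#' with a warning. Literal `"True"`/`"False"` strings and logicals are
#' treated interchangeably.
#'
#' @param path Path to the CSV file.
#' @param dataset_id Dataset label (default: file name).
#' @return A chain table (see [read_airr()]).
#' @export
read_tenx_contigs <- function(path, dataset_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
                "productive", "high_confidence")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("10x contig format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(dataset_id)) dataset_id <- basename(path)
  known <- c("TRA", "TRB", "TRD", "TRG", "Multi")
  unknown <- !df$chain %in% known
  if (any(unknown)) {
    warning(sum(unknown), " row(s) with unknown chain value skipped: ",
            paste(unique(df$chain[unknown]), collapse = ", "))
    df <- df[!unknown, , drop = FALSE]
  }
  keep <- df$chain %in% c("TRD", "TRG") & .as_flag(df$productive) &
    .as_flag(df$high_confidence)
  df <- df[keep, , drop = FALSE]
  data.frame(
    dataset_id = rep(dataset_id, nrow(df)),
    cell_id = df$barcode,
    locus = df$chain,
    v_call = df$v_gene,
    d_call = if ("d_gene" %in% names(df)) df$d_gene else rep("", nrow(df)),
    j_call = df$j_gene,
    junction_nt = toupper(df$cdr3_nt),
    junction_aa = df$cdr3,
    productive = rep(TRUE, nrow(df)),
    duplicate_count = if ("umis" %in% names(df))
      suppressWarnings(as.integer(df$umis)) else rep(NA_integer_, nrow(df)),
    stringsAsFactors = FALSE)
}

#' Read a cell metadata table
#'
#' Expects a CSV with columns `cell_id`, `dataset_id`, `subject_id`,
#' `age_value`, `age_unit`, `compartment`, `cluster_label`, `group_label`,
#' `effector_type` (additional columns such as `lineage_label` are kept).
#'
#' @param path Path to the CSV.
#' @return A data.frame.
#' @export
read_cell_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "dataset_id", "subject_id", "age_value",
                "compartment", "cluster_label", "group_label")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Assemble per-cell paired records from chains and metadata
#'
#' Matches chains to cell metadata by cell barcode. Non-productive chains are
#' dropped; duplicate (cell_id, locus, junction_nt) rows are deduplicated
#' with a warning; when a cell carries more than two productive chains of one
#' locus, the two with the highest read/UMI support are kept (ties broken by
#' lexicographic junction order). Chains whose barcode is absent from the
#' metadata are dropped with a logged count. Cells present in the metadata
#' but lacking any productive chain are retained in the cell table (they are
#' excluded from TCR feature statistics downstream).
#'
#' @param chains A chain table (see [read_airr()]).
#' @param metadata A cell metadata table (see [read_cell_metadata()]).
#' @return An object of class `gdtcr_cells`: a list with `cells` (one row per
#'   metadata cell, with `n_delta`/`n_gamma` chain counts appended) and
#'   `chains` (the filtered chain table joined with cell metadata).
#' @export
assemble_cells <- function(chains, metadata) {
  stopifnot(is.data.frame(chains), is.data.frame(metadata))
  ch <- chains[chains$productive, , drop = FALSE]
  dup <- duplicated(ch[, c("cell_id", "locus", "junction_nt")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (cell_id, locus, junction) row(s) removed")
    ch <- ch[!dup, , drop = FALSE]
  }
  known <- ch$cell_id %in% metadata$cell_id
  if (any(!known))
    message(sum(!known), " chain(s) with barcode absent from metadata dropped")
  ch <- ch[known, , drop = FALSE]
  # keep at most 2 chains per cell x locus, highest support first
  support <- ifelse(is.na(ch$duplicate_count), 0L, ch$duplicate_count)
  ord <- order(ch$cell_id, ch$locus, -support, ch$junction_nt)
  ch <- ch[ord, , drop = FALSE]
  grp <- paste(ch$cell_id, ch$locus)
  rank_in_grp <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  ch <- ch[rank_in_grp <= 2L, , drop = FALSE]
  ch$chain_rank <- rank_in_grp[rank_in_grp <= 2L]
  # join metadata onto chains
  mcols <- setdiff(names(metadata), c("dataset_id"))
  ch <- merge(ch, metadata[, mcols, drop = FALSE], by = "cell_id",
              sort = FALSE)
  nd <- table(factor(ch$cell_id[ch$locus == "TRD"], levels = metadata$cell_id))
  ng <- table(factor(ch$cell_id[ch$locus == "TRG"], levels = metadata$cell_id))
  cells <- metadata
  cells$n_delta <- as.integer(nd[cells$cell_id])
  cells$n_gamma <- as.integer(ng[cells$cell_id])
  structure(list(cells = cells, chains = ch), class = "gdtcr_cells")
}

#' @export
print.gdtcr_cells <- function(x, ...) {
  cat("gdtcr cell set: ", nrow(x$cells), " cells, ", nrow(x$chains),
      " productive chains (", sum(x$chains$locus == "TRD"), " TRD / ",
      sum(x$chains$locus == "TRG"), " TRG)\n", sep = "")
  cat("  datasets:", paste(unique(x$cells$dataset_id), collapse = ", "), "\n")
  invisible(x)
}
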