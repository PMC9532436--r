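.revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Public clonotype recipe table
#'
#' The germline-convergent public CDR3 sequences used by the simulator and
#' the default tag table, together with their recombination recipes against
#' the synthetic germline fixture (see [synthetic_germline()]). Every recipe
#' uses at most one non-templated nucleotide (`n_ledger <= 1`): these
#' sequences are public precisely because convergent recombination can
#' produce them with little or no TdT activity. Per-row effector bias weights
#' multiply the age-dependent effector-type shares when a simulated cell
#' carries the clonotype, and `partner_v8`/`partner_v9` give the gamma-chain
#' pairing weights applied to public delta chains.
#'
#' @return A data.frame with columns `name`, `tag_group`, `locus`,
#'   `junction_aa`, `junction_nt`, `v_call`, `d_call`, `j_call`, `n_ledger`,
#'   `weight`, `w_immature`, `w_type1`, `w_type3`, `w_type2`, `partner_v8`,
#'   `partner_v9`.
#' @export
public_clonotype_table <- function() {
  g <- synthetic_germline()
  tmpl <- function(nm) g$junction_template_nt[g$name == nm]
  suffix <- function(nm, k) {
    s <- tmpl(nm); substr(s, nchar(s) - k + 1L, nchar(s))
  }
  v2 <- tmpl("TRDV2")                       # CACDT
  v2_4 <- substr(v2, 1, 12)                 # CACD
  j3 <- suffix("TRDJ3", 24)                 # WDTRQMFF
  j2 <- suffix("TRDJ2", 27)                 # WDTTRQMFF
  j1 <- suffix("TRDJ1", 15)                 # DKLIF
  d1 <- tmpl("TRDD1"); d2 <- tmpl("TRDD2"); d3 <- tmpl("TRDD3")
  row <- function(name, tag_group, locus, nt, v, d, j, n_ledger, weight,
                  wi, w1, w3, w2, p8 = NA_real_, p9 = NA_real_) {
    aa <- translate_junction(nt)
    stopifnot(aa$productive)
    data.frame(name = name, tag_group = tag_group, locus = locus,
               junction_aa = aa$junction_aa, junction_nt = nt,
               v_call = v, d_call = d, j_call = j,
               n_ledger = n_ledger, weight = weight,
               w_immature = wi, w_type1 = w1, w_type3 = w3, w_type2 = w2,
               partner_v8 = p8, partner_v9 = p9, stringsAsFactors = FALSE)
  }
  rbind(
    # type-1-associated delta publics (glycine at position 5)
    row("TGGY",  "type1_delta", "TRD",
        paste0(v2, substr(d3, 4, 12), j3), "TRDV2", "TRDD3", "TRDJ3",
        0L, 0.28, 0.55, 3.0, 1.0, 0.3, p8 = 0.8, p9 = 0.2),
    row("TGGYS", "type1_delta", "TRD",
        paste0(v2, substr(d3, 4, 15), j3), "TRDV2", "TRDD3", "TRDJ3",
        0L, 0.14, 0.55, 3.0, 1.0, 0.3, p8 = 0.8, p9 = 0.2),
    # type-2-associated delta publics
    row("WGSS",  "type2_delta", "TRD",
        paste0(v2_4, substr(d1, 4, 15), j3), "TRDV2", "TRDD1", "TRDJ3",
        0L, 0.12, 0.55, 0.3, 1.0, 3.0, p8 = 0.8, p9 = 0.2),
    row("YWGSS", "type2_delta", "TRD",
        paste0(v2_4, d1, j3), "TRDV2", "TRDD1", "TRDJ3",
        0L, 0.10, 0.55, 0.3, 1.0, 3.0, p8 = 0.2, p9 = 0.8),
    # hydrophobic-position-5 delta publics (pair preferentially with Vg9)
    row("VLGDT_J1", "lgdt_delta", "TRD",
        paste0(v2_4, "G", d2, j1), "TRDV2", "TRDD2", "TRDJ1",
        1L, 0.06, 0.55, 2.0, 1.5, 0.5, p8 = 0.2, p9 = 0.8),
    row("ILGDT_J1", "lgdt_delta", "TRD",
        paste0(v2_4, "A", d2, j1), "TRDV2", "TRDD2", "TRDJ1",
        1L, 0.06, 0.55, 2.0, 1.5, 0.5, p8 = 0.2, p9 = 0.8),
    row("TVLGDT_J3", "lgdt_delta", "TRD",
        paste0(v2, "G", d2, j2), "TRDV2", "TRDD2", "TRDJ2",
        1L, 0.06, 0.55, 2.0, 1.5, 0.5, p8 = 0.2, p9 = 0.8),
    row("ILGDT_J3", "lgdt_delta", "TRD",
        paste0(v2_4, "A", d2, j2), "TRDV2", "TRDD2", "TRDJ2",
        1L, 0.06, 0.55, 2.0, 1.5, 0.5, p8 = 0.2, p9 = 0.8),
    # public gamma chains
    row("G9", "public_gamma_v9", "TRG",
        paste0(tmpl("TRGV9"), tmpl("TRGJP")), "TRGV9", "", "TRGJP",
        0L, 0.60, 0.7, 1.5, 1.2, 1.0),
    row("G8", "public_gamma_v8", "TRG",
        paste0(tmpl("TRGV8"), tmpl("TRGJP1")), "TRGV8", "", "TRGJP1",
        0L, 0.40, 0.7, 1.5, 1.2, 1.0))
}

#' Default public CDR3 tag table
#'
#' The named public-sequence variant groups used for cell tagging and pairing
#' analysis: the type-1-associated and type-2-associated TRDV2 delta groups
#' (both printed spellings of the WGSS family are accepted), the
#' hydrophobic-position-5 LGDT delta group, and the two public gamma chains
#' (TRGV8-TRGJP1 and TRGV9-TRGJP). A tag matches a chain when locus,
#' junction amino-acid sequence and the required V gene (and J gene, where
#' stated) all agree.
#'
#' @return A data.frame with columns `tag`, `locus`, `junction_aa`, `v_gene`,
#'   `j_gene` (`NA` when the J gene is not part of the tag definition).
#' @export
default_public_tags <- function() {
  t1 <- c("CACDTGGYWDTRQMFF", "CACDTGGYSWDTRQMFF")
  t2 <- c("CACDWGSSWDTRQMFF", "CACDYWGSSWDTRQMFF",
          "CACDWGSSDTRQMFF", "CACDYWGSSDTRQMFF", "CACDTWGSSDTRQMFF")
  lg <- c("CACDTVLGDTWDTTRQMFF", "CACDILGDTWDTTRQMFF",
          "CACDVLGDTDKLIF", "CACDILGDTDKLIF")
  rbind(
    data.frame(tag = "type1_delta", locus = "TRD", junction_aa = t1,
               v_gene = "TRDV2", j_gene = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(tag = "type2_delta", locus = "TRD", junction_aa = t2,
               v_gene = "TRDV2", j_gene = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(tag = "lgdt_delta", locus = "TRD", junction_aa = lg,
               v_gene = "TRDV2", j_gene = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(tag = "public_gamma_v8", locus = "TRG",
               junction_aa = "CATWDTTGWFKIF", v_gene = "TRGV8",
               j_gene = "TRGJP1", stringsAsFactors = FALSE),
    data.frame(tag = "public_gamma_v9", locus = "TRG",
               junction_aa = "CALWEVQELGKKIKVF", v_gene = "TRGV9",
               j_gene = "TRGJP", stringsAsFactors = FALSE))
}

#' Tag cells carrying public CDR3 sequences
#'
#' Annotates every chain with the tags whose (locus, junction amino-acid
#' sequence, required V gene, optional required J gene) match, and appends
#' one logical `tag_<name>` column per tag to the cell table.
#'
#' @param cells A `gdtcr_cells` object (see [assemble_cells()]).
#' @param tag_table A tag table (default [default_public_tags()]).
#' @return `cells` with tag annotations.
#' @export
tag_public_sequences <- function(cells, tag_table = default_public_tags()) {
  stopifnot(inherits(cells, "gdtcr_cells"))
  if (!all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", tag_table$junction_aa)))
    stop("tag config error: malformed amino-acid alphabet in tag table")
  ch <- cells$chains
  ch$tags <- ""
  gene <- sub("\\*.*$", "", ch$v_call)
  jgene <- sub("\\*.*$", "", ch$j_call)
  for (k in seq_len(nrow(tag_table))) {
    hit <- ch$locus == tag_table$locus[k] &
      ch$junction_aa == tag_table$junction_aa[k] &
      gene == tag_table$v_gene[k]
    if (!is.na(tag_table$j_gene[k]))
      hit <- hit & jgene == tag_table$j_gene[k]
    already <- grepl(paste0("\\b", tag_table$tag[k], "\\b"), ch$tags)
    add <- hit & !already
    ch$tags[add] <- ifelse(nzchar(ch$tags[add]),
                           paste0(ch$tags[add], ",", tag_table$tag[k]),
                           tag_table$tag[k])
  }
  cells$chains <- ch
  for (tg in unique(tag_table$tag)) {
    tagged_cells <- unique(ch$cell_id[grepl(paste0("\\b", tg, "\\b"), ch$tags)])
    cells$cells[[paste0("tag_", tg)]] <- cells$cells$cell_id %in% tagged_cells
  }
  cells
}
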