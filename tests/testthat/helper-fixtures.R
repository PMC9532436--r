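# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

# small simulated study: full 9-subject + 10-bulk design at reduced depth
small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- simulation_config(seed = 303L, cells_per_subject = 300L,
                             bulk_clones_per_subject = 150L)
    .fixture_cache$sim <- simulate_repertoire(cfg)
  }
  .fixture_cache$sim
}

small_cells <- function() {
  if (is.null(.fixture_cache$cells)) {
    sim <- small_sim()
    .fixture_cache$cells <-
      tag_public_sequences(assemble_cells(do.call(rbind, sim$sc),
                                          sim$metadata))
  }
  .fixture_cache$cells
}

# hand-built toy: a chain table plus matching metadata -> gdtcr_cells
toy_cells <- function(chain_rows, meta_extra = NULL) {
  ch <- do.call(rbind, lapply(chain_rows, function(r) {
    data.frame(dataset_id = "TOY", cell_id = r$cell_id, locus = r$locus,
               v_call = r$v_call,
               d_call = if (is.null(r$d_call)) "" else r$d_call,
               j_call = if (is.null(r$j_call)) "" else r$j_call,
               junction_nt = if (is.null(r$junction_nt)) "TGTGCCTTC"
                             else r$junction_nt,
               junction_aa = if (is.null(r$junction_aa)) "CAF"
                             else r$junction_aa,
               productive = if (is.null(r$productive)) TRUE else r$productive,
               duplicate_count = if (is.null(r$count)) NA_integer_
                                 else r$count,
               stringsAsFactors = FALSE)
  }))
  ids <- unique(ch$cell_id)
  meta <- data.frame(cell_id = ids, dataset_id = "TOY",
                     subject_id = "S1", age_value = 17, age_unit = "weeks",
                     compartment = "fetal", cluster_label = "c1",
                     group_label = "immature_maturing",
                     effector_type = "none", stringsAsFactors = FALSE)
  if (!is.null(meta_extra))
    for (nm in names(meta_extra)) meta[[nm]] <- meta_extra[[nm]]
  assemble_cells(ch, meta)
}

# per-subject two-group feature table for contrast tests
make_features <- function(imm, eff, subjects = sprintf("S%d", seq_along(imm))) {
  rbind(data.frame(subject_id = subjects, group_label = "immature_maturing",
                   metric = imm, stringsAsFactors = FALSE),
        data.frame(subject_id = subjects, group_label = "effector",
                   metric = eff, stringsAsFactors = FALSE))
}

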