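#' Simulation configuration
#'
#' Parameters of the paired gamma-delta repertoire generator. Defaults
#' emulate the study design the analysis assumes: 6 fetal thymus subjects
#' spanning 14-22.9 weeks of gestation and 3 pediatric subjects (4, 4.5 and
#' 11 years), single-cell chain detection in 68% (delta) and 52% (gamma) of
#' cells, 2.3% double-productive-delta cells, gestation-dependent TdT
#' activity (mean N additions increasing with fetal age), germline-convergent
#' public clonotypes with effector bias and gamma/delta pairing preferences,
#' an effector fraction that decreases with gestation age, a type-3 effector
#' share that decreases and a type-1 share that increases with gestation age
#' (type-2-like roughly stable), and 10 bulk repertoires.
#'
#' @param seed Integer RNG seed.
#' @param fetal_ages_weeks Gestational ages of the fetal subjects (weeks).
#' @param postnatal_ages_years Ages of the pediatric subjects (years).
#' @param cells_per_subject Cells simulated per single-cell subject.
#' @param delta_detect_rate,gamma_detect_rate Probability that a cell has at
#'   least one detected productive delta / gamma chain.
#' @param double_delta_rate Fraction of all cells with two productive delta
#'   chains.
#' @param n_rate_intercept,n_rate_slope Mean N additions for a fetal chain is
#'   `n_rate_intercept + n_rate_slope * (age_weeks - 14)` (Poisson).
#' @param n_mean_postnatal Mean N additions for postnatal chains.
#' @param trim_geom_p Geometric parameter for V/D/J trimming.
#' @param p_pal Probability of a palindromic extension at an untrimmed V or J
#'   end.
#' @param max_p_sim Maximum simulated P length per end.
#' @param tandem_d_rate Probability a TRD rearrangement samples two D
#'   segments.
#' @param public_rate_fetal,public_rate_postnatal Probability a chain is
#'   drawn from the public clonotype table.
#' @param effector_intercept,effector_slope Effector fraction for a fetal
#'   subject is `effector_intercept + effector_slope * (age_weeks - 14)`
#'   (negative slope: earlier gestation, more effector cells).
#' @param effector_postnatal Effector fraction for pediatric subjects.
#' @param type3_intercept,type3_slope,type1_intercept,type1_slope Effector
#'   type shares as affine functions of `(age_weeks - 14)`; the type-2-like
#'   share is the remainder.
#' @param v_usage_trd_fetal,v_usage_trd_postnatal Named TRD V-gene usage.
#' @param v_usage_trg_fetal,v_usage_trg_postnatal Named TRG V-gene usage.
#' @param j_usage_trd,j_usage_trg Named J-gene usage probabilities.
#' @param bulk_subject_count,bulk_clones_per_subject,bulk_ages Bulk
#'   repertoire design (3 fetal + 7 pediatric subjects by default).
#' @param public_table Public clonotype recipe table
#'   (default [public_clonotype_table()]).
#' @param lineage_bias_tag,lineage_bias_weight Immature TRDV2 cells carrying
#'   `lineage_bias_tag` sample lineage L1 with this multiplicative weight.
#' @param immature_clusters,effector_cluster_map Cluster label vocabulary.
#' @return A `gdtcr_sim_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    fetal_ages_weeks = c(14, 15.8, 17.5, 19.3, 21.1, 22.9),
    postnatal_ages_years = c(4, 4.5, 11),
    cells_per_subject = 2000L,
    delta_detect_rate = 0.68,
    gamma_detect_rate = 0.52,
    double_delta_rate = 0.023,
    n_rate_intercept = 1.0,
    n_rate_slope = 0.45,
    n_mean_postnatal = 8,
    trim_geom_p = 0.45,
    p_pal = 0.25,
    max_p_sim = 2L,
    tandem_d_rate = 0.12,
    public_rate_fetal = 0.22,
    public_rate_postnatal = 0.05,
    effector_intercept = 0.50,
    effector_slope = -0.020,
    effector_postnatal = 0.10,
    type3_intercept = 0.60,
    type3_slope = -0.040,
    type1_intercept = 0.15,
    type1_slope = 0.040,
    v_usage_trd_fetal = c(TRDV1 = 0.10, TRDV2 = 0.74, TRDV3 = 0.08,
                          `TRAV38-2DV8` = 0.08),
    v_usage_trd_postnatal = c(TRDV1 = 0.45, TRDV2 = 0.30, TRDV3 = 0.15,
                              `TRAV38-2DV8` = 0.10),
    v_usage_trg_fetal = c(TRGV8 = 0.38, TRGV9 = 0.40, TRGV2 = 0.22),
    v_usage_trg_postnatal = c(TRGV8 = 0.30, TRGV9 = 0.25, TRGV2 = 0.45),
    j_usage_trd = c(TRDJ1 = 0.35, TRDJ2 = 0.15, TRDJ3 = 0.50),
    j_usage_trg = c(TRGJP = 0.30, TRGJP1 = 0.25, TRGJ1 = 0.25, TRGJ2 = 0.20),
    bulk_subject_count = 10L,
    bulk_clones_per_subject = 800L,
    bulk_ages = c(16, 18, 20, 0.5, 1, 2, 4, 6, 9, 12),
    public_table = public_clonotype_table(),
    lineage_bias_tag = "type1_delta",
    lineage_bias_weight = 3,
    immature_clusters = c("c1", "c2", "c5", "c7", "c8", "c9", "c10", "c11"),
    effector_cluster_map = c(type1 = "c4", type3 = "c3", type2like = "c6")) {
  cfg <- as.list(environment())
  rates <- c(delta_detect_rate, gamma_detect_rate, double_delta_rate,
             p_pal, tandem_d_rate, public_rate_fetal, public_rate_postnatal,
             effector_postnatal, trim_geom_p)
  if (any(rates < 0 | rates > 1))
    stop("config validation error: rates must be in [0, 1]")
  if (any(c(fetal_ages_weeks, postnatal_ages_years) <= 0))
    stop("config validation error: ages must be strictly positive")
  for (a in fetal_ages_weeks) {
    s <- .effector_shares(cfg, a, "fetal")
    if (any(s < 0) || abs(sum(s) - 1) > 1e-9)
      stop("config validation error: effector type shares do not sum to 1 ",
           "(or go negative) at age ", a)
    e <- effector_intercept + effector_slope * (a - 14)
    if (e < 0 || e > 1)
      stop("config validation error: effector fraction outside [0,1] at age ", a)
  }
  class(cfg) <- "gdtcr_sim_config"
  cfg
}

.effector_shares <- function(cfg, age, compartment) {
  if (compartment == "postnatal")
    return(c(type1 = 0.5, type3 = 0.5, type2like = 0))
  t3 <- cfg$type3_intercept + cfg$type3_slope * (age - 14)
  t1 <- cfg$type1_intercept + cfg$type1_slope * (age - 14)
  c(type1 = t1, type3 = t3, type2like = 1 - t1 - t3)
}

.sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

# one de novo rearrangement as a plain list, or error after max_tries
.sim_denovo_chain <- function(locus, n_mean, cfg, gdb, max_tries = 500L) {
  vs <- if (locus == "TRD") cfg$.vd_usage else cfg$.vg_usage
  js <- if (locus == "TRD") cfg$j_usage_trd else cfg$j_usage_trg
  dpool <- gdb$name[gdb$segment_type == "D"]
  for (try in seq_len(max_tries)) {
    vname <- .sample1(names(vs), vs)
    jname <- .sample1(names(js), js)
    vt <- gdb$junction_template_nt[gdb$name == vname]
    jt <- gdb$junction_template_nt[gdb$name == jname]
    v_trim <- min(stats::rgeom(1, cfg$trim_geom_p), nchar(vt) - 3L)
    j_trim <- min(stats::rgeom(1, cfg$trim_geom_p), nchar(jt) - 6L)
    vpart <- substr(vt, 1L, nchar(vt) - v_trim)
    jpart <- substr(jt, j_trim + 1L, nchar(jt))
    dparts <- character(0); dnames <- character(0)
    if (locus == "TRD") {
      nd <- if (stats::runif(1) < cfg$tandem_d_rate) 2L else 1L
      for (k in seq_len(nd)) {
        dn <- .sample1(dpool)
        dt <- gdb$junction_template_nt[gdb$name == dn]
        d5 <- stats::rgeom(1, cfg$trim_geom_p)
        d3 <- stats::rgeom(1, cfg$trim_geom_p)
        rem <- nchar(dt) - d5 - d3
        if (rem >= 4L) {   # shorter remnants are indistinguishable from N
          dparts <- c(dparts, substr(dt, d5 + 1L, nchar(dt) - d3))
          dnames <- c(dnames, dn)
        }
      }
    }
    pv <- pj <- ""
    if (v_trim == 0L && stats::runif(1) < cfg$p_pal) {
      k <- sample.int(cfg$max_p_sim, 1L)
      pv <- .revcomp(substr(vt, nchar(vt) - k + 1L, nchar(vt)))
    }
    if (j_trim == 0L && stats::runif(1) < cfg$p_pal) {
      k <- sample.int(cfg$max_p_sim, 1L)
      pj <- .revcomp(substr(jt, 1L, k))
    }
    n_total <- stats::rpois(1, n_mean)
    ngap <- length(dparts) + 1L
    alloc <- if (n_total > 0)
      tabulate(sample.int(ngap, n_total, replace = TRUE), nbins = ngap)
    else integer(ngap)
    nstr <- vapply(alloc, function(m)
      paste0(sample(c("A", "C", "G", "T"), m, replace = TRUE), collapse = ""),
      character(1))
    mid <- nstr[1]
    for (k in seq_along(dparts)) mid <- paste0(mid, dparts[k], nstr[k + 1L])
    junction <- paste0(vpart, pv, mid, pj, jpart)
    if (nchar(junction) %% 3L != 0L) next
    tr <- translate_junction(junction)
    if (!tr$productive) next
    return(list(v_call = vname, d_call = paste(dnames, collapse = ","),
                j_call = jname, junction_nt = junction,
                junction_aa = tr$junction_aa,
                n_ledger = n_total, p_ledger = nchar(pv) + nchar(pj),
                v_trim = v_trim, j_trim = j_trim,
                templated_ledger = nchar(vpart) + nchar(jpart) +
                  sum(nchar(dparts)),
                is_public = FALSE, public_name = NA_character_))
  }
  stop("rejection sampling failed to produce a productive ", locus, " chain")
}

.sim_public_chain <- function(cfg, rows) {
  r <- rows[sample.int(nrow(rows), 1L, prob = rows$weight), , drop = FALSE]
  list(v_call = r$v_call, d_call = r$d_call, j_call = r$j_call,
       junction_nt = r$junction_nt, junction_aa = r$junction_aa,
       n_ledger = r$n_ledger, p_ledger = 0L, v_trim = NA_integer_,
       j_trim = NA_integer_,
       templated_ledger = nchar(r$junction_nt) - r$n_ledger,
       is_public = TRUE, public_name = r$name)
}

# column-accumulating store for chain + ledger rows (speed: no per-row data.frames)
.new_store <- function(n) {
  list(i = 0L,
       dataset_id = character(n), cell_id = character(n), locus = character(n),
       v_call = character(n), d_call = character(n), j_call = character(n),
       junction_nt = character(n), junction_aa = character(n),
       duplicate_count = rep(NA_integer_, n),
       n_ledger = integer(n), p_ledger = integer(n),
       templated_ledger = integer(n),
       v_trim = rep(NA_integer_, n), j_trim = rep(NA_integer_, n),
       is_public = logical(n), public_name = character(n))
}

.store_add <- function(st, ch, ds, cell, locus, count = NA_integer_) {
  i <- st$i + 1L
  st$i <- i
  st$dataset_id[i] <- ds; st$cell_id[i] <- cell; st$locus[i] <- locus
  st$v_call[i] <- ch$v_call; st$d_call[i] <- ch$d_call
  st$j_call[i] <- ch$j_call
  st$junction_nt[i] <- ch$junction_nt; st$junction_aa[i] <- ch$junction_aa
  st$duplicate_count[i] <- count
  st$n_ledger[i] <- ch$n_ledger; st$p_ledger[i] <- ch$p_ledger
  st$templated_ledger[i] <- ch$templated_ledger
  st$v_trim[i] <- ch$v_trim; st$j_trim[i] <- ch$j_trim
  st$is_public[i] <- ch$is_public
  st$public_name[i] <- if (is.na(ch$public_name)) NA_character_ else ch$public_name
  st
}

.store_chains <- function(st) {
  k <- seq_len(st$i)
  data.frame(dataset_id = st$dataset_id[k], cell_id = st$cell_id[k],
             locus = st$locus[k], v_call = st$v_call[k],
             d_call = st$d_call[k], j_call = st$j_call[k],
             junction_nt = st$junction_nt[k], junction_aa = st$junction_aa[k],
             productive = rep(TRUE, st$i),
             duplicate_count = st$duplicate_count[k], stringsAsFactors = FALSE)
}

.store_ledger <- function(st) {
  k <- seq_len(st$i)
  data.frame(dataset_id = st$dataset_id[k], cell_id = st$cell_id[k],
             locus = st$locus[k], v_call = st$v_call[k],
             d_call = st$d_call[k], j_call = st$j_call[k],
             junction_nt = st$junction_nt[k],
             n_ledger = st$n_ledger[k], p_ledger = st$p_ledger[k],
             templated_ledger = st$templated_ledger[k],
             v_trim = st$v_trim[k], j_trim = st$j_trim[k],
             is_public = st$is_public[k], public_name = st$public_name[k],
             stringsAsFactors = FALSE)
}

#' Simulate paired single-cell and bulk gamma-delta repertoires
#'
#' Generates, per single-cell subject, cells with age- and publicity-biased
#' chain content: chains are drawn either de novo (V/D/J sampled by
#' configured usage, geometric trims, Poisson N additions with age-dependent
#' mean, palindromic extensions at untrimmed ends, rejection sampling to
#' productivity) or from the public clonotype table; effector labels are
#' sampled from age-dependent shares re-weighted by the public-clonotype bias
#' of the cell's chains; public delta chains draw their gamma partner
#' according to the configured pairing weights; chain dropout and
#' double-delta duplication are applied per cell. Bulk repertoires pool extra
#' simulated chains per bulk subject, and every public clonotype is seeded
#' into each bulk dataset (public sequences are shared across repertoires by
#' construction). A full ground-truth ledger covering every emitted chain is
#' returned.
#'
#' @param config A [simulation_config()].
#' @param germline_db Germline database (default [synthetic_germline()]).
#' @return A `gdtcr_sim` list: `sc` (named list of chain tables), `metadata`
#'   (cell metadata across all sc datasets), `bulk` (named list of bulk
#'   clonotype tables), `ledger`, `cell_truth`, `config`.
#' @export
simulate_repertoire <- function(config = simulation_config(),
                                germline_db = synthetic_germline()) {
  stopifnot(inherits(config, "gdtcr_sim_config"))
  set.seed(config$seed)
  cfg <- unclass(config)
  subjects <- data.frame(
    dataset_id = c(sprintf("FT%d", seq_along(cfg$fetal_ages_weeks)),
                   sprintf("PNT%d", seq_along(cfg$postnatal_ages_years))),
    subject_id = c(sprintf("F%02d", seq_along(cfg$fetal_ages_weeks)),
                   sprintf("P%02d", seq_along(cfg$postnatal_ages_years))),
    age_value = c(cfg$fetal_ages_weeks, cfg$postnatal_ages_years),
    age_unit = c(rep("weeks", length(cfg$fetal_ages_weeks)),
                 rep("years", length(cfg$postnatal_ages_years))),
    compartment = c(rep("fetal", length(cfg$fetal_ages_weeks)),
                    rep("postnatal", length(cfg$postnatal_ages_years))),
    stringsAsFactors = FALSE)
  pt <- cfg$public_table
  pub_d <- pt[pt$locus == "TRD", , drop = FALSE]
  pub_g <- pt[pt$locus == "TRG", , drop = FALSE]
  pub_g8 <- pt[pt$tag_group == "public_gamma_v8", , drop = FALSE]
  pub_g9 <- pt[pt$tag_group == "public_gamma_v9", , drop = FALSE]
  labels <- c("immature", "type1", "type3", "type2like")

  sc <- list(); bulk <- list(); meta_all <- list(); ledgers <- list()
  truth_all <- list()
  for (s in seq_len(nrow(subjects))) {
    ds <- subjects$dataset_id[s]
    fetal <- subjects$compartment[s] == "fetal"
    age <- subjects$age_value[s]
    cfg$.vd_usage <- if (fetal) cfg$v_usage_trd_fetal else cfg$v_usage_trd_postnatal
    cfg$.vg_usage <- if (fetal) cfg$v_usage_trg_fetal else cfg$v_usage_trg_postnatal
    n_mean <- if (fetal)
      max(0, cfg$n_rate_intercept + cfg$n_rate_slope * (age - 14))
    else cfg$n_mean_postnatal
    p_pub <- if (fetal) cfg$public_rate_fetal else cfg$public_rate_postnatal
    eff_frac <- if (fetal)
      min(1, max(0, cfg$effector_intercept + cfg$effector_slope * (age - 14)))
    else cfg$effector_postnatal
    shares <- .effector_shares(cfg, age, subjects$compartment[s])

    n_cells <- cfg$cells_per_subject
    st <- .new_store(3L * n_cells)
    m_cluster <- character(n_cells); m_group <- character(n_cells)
    m_type <- character(n_cells); m_lineage <- rep(NA_character_, n_cells)
    m_truth <- character(n_cells); m_pairing <- rep(NA_character_, n_cells)
    cell_ids <- sprintf("%s_c%05d", ds, seq_len(n_cells))
    for (i in seq_len(n_cells)) {
      has_d <- stats::runif(1) < cfg$delta_detect_rate
      dbl_d <- has_d &&
        stats::runif(1) < cfg$double_delta_rate / cfg$delta_detect_rate
      has_g <- stats::runif(1) < cfg$gamma_detect_rate
      dchains <- list(); gchain <- NULL
      if (has_d) {
        for (k in seq_len(if (dbl_d) 2L else 1L)) {
          for (redraw in 1:25) {   # the two chains of a double-delta cell differ
            ch <- if (stats::runif(1) < p_pub) .sim_public_chain(cfg, pub_d)
                  else .sim_denovo_chain("TRD", n_mean, cfg, germline_db)
            if (k == 1L || ch$junction_nt != dchains[[1]]$junction_nt) break
          }
          dchains[[k]] <- ch
        }
      }
      if (has_g) {
        lead <- if (length(dchains)) dchains[[1]] else NULL
        if (!is.null(lead) && lead$is_public &&
            !is.na(pt$partner_v8[pt$name == lead$public_name])) {
          w8 <- pt$partner_v8[pt$name == lead$public_name]
          gchain <- if (stats::runif(1) < w8) .sim_public_chain(cfg, pub_g8)
                    else .sim_public_chain(cfg, pub_g9)
          m_pairing[i] <- paste0(lead$public_name, ">", gchain$public_name)
        } else {
          gchain <- if (stats::runif(1) < p_pub) .sim_public_chain(cfg, pub_g)
                    else .sim_denovo_chain("TRG", n_mean, cfg, germline_db)
        }
      }
      w <- c(immature = 1 - eff_frac, eff_frac * shares)
      for (ch in c(dchains, list(gchain))) {
        if (!is.null(ch) && ch$is_public) {
          r <- pt[pt$name == ch$public_name, ]
          w <- w * c(r$w_immature, r$w_type1, r$w_type3, r$w_type2)
        }
      }
      lab <- .sample1(labels, w / sum(w))
      effector <- lab != "immature"
      m_truth[i] <- lab
      m_group[i] <- if (effector) "effector" else "immature_maturing"
      m_type[i] <- if (effector) lab else "none"
      m_cluster[i] <- if (effector) unname(cfg$effector_cluster_map[lab])
                      else .sample1(cfg$immature_clusters)
      if (!effector) {
        lw <- c(L1 = 1, L2 = 1, L3 = 1)
        tagged <- any(vapply(dchains, function(ch) ch$is_public &&
            pt$tag_group[pt$name == ch$public_name] == cfg$lineage_bias_tag,
          logical(1)))
        if (tagged) lw["L1"] <- cfg$lineage_bias_weight
        m_lineage[i] <- .sample1(names(lw), lw / sum(lw))
      }
      for (ch in dchains) st <- .store_add(st, ch, ds, cell_ids[i], "TRD")
      if (!is.null(gchain)) st <- .store_add(st, gchain, ds, cell_ids[i], "TRG")
    }
    sc[[ds]] <- .store_chains(st)
    ledgers[[ds]] <- .store_ledger(st)
    meta_all[[ds]] <- data.frame(
      cell_id = cell_ids, dataset_id = ds,
      subject_id = subjects$subject_id[s], age_value = age,
      age_unit = subjects$age_unit[s], compartment = subjects$compartment[s],
      cluster_label = m_cluster, group_label = m_group,
      effector_type = m_type, lineage_label = m_lineage,
      stringsAsFactors = FALSE)
    truth_all[[ds]] <- data.frame(
      cell_id = cell_ids, dataset_id = ds, true_label = m_truth,
      pairing_recipe = m_pairing, stringsAsFactors = FALSE)
  }

  for (b in seq_len(cfg$bulk_subject_count)) {
    ds <- sprintf("BULK%d", b)
    age <- cfg$bulk_ages[((b - 1L) %% length(cfg$bulk_ages)) + 1L]
    fetal <- b <= 3L
    cfg$.vd_usage <- if (fetal) cfg$v_usage_trd_fetal else cfg$v_usage_trd_postnatal
    cfg$.vg_usage <- if (fetal) cfg$v_usage_trg_fetal else cfg$v_usage_trg_postnatal
    n_mean <- if (fetal)
      max(0, cfg$n_rate_intercept + cfg$n_rate_slope * (age - 14))
    else cfg$n_mean_postnatal
    p_pub <- if (fetal) cfg$public_rate_fetal else cfg$public_rate_postnatal
    st <- .new_store(cfg$bulk_clones_per_subject + nrow(pt))
    for (i in seq_len(cfg$bulk_clones_per_subject)) {
      locus <- if (stats::runif(1) < 0.5) "TRD" else "TRG"
      ch <- if (stats::runif(1) < p_pub)
        .sim_public_chain(cfg, pt[pt$locus == locus, , drop = FALSE])
      else .sim_denovo_chain(locus, n_mean, cfg, germline_db)
      st <- .store_add(st, ch, ds, "", locus, count = 1L + stats::rpois(1, 2))
    }
    for (k in seq_len(nrow(pt))) {      # guaranteed sharing across datasets
      ch <- .sim_public_chain(cfg, pt[k, , drop = FALSE])
      st <- .store_add(st, ch, ds, "", pt$locus[k], count = 1L)
    }
    bulk[[ds]] <- .store_chains(st)
    ledgers[[ds]] <- .store_ledger(st)
  }

  structure(list(sc = sc, metadata = do.call(rbind, meta_all), bulk = bulk,
                 ledger = do.call(rbind, ledgers),
                 cell_truth = do.call(rbind, truth_all), config = config),
            class = "gdtcr_sim")
}

#' @export
print.gdtcr_sim <- function(x, ...) {
  cat("gdtcr simulated study: ", length(x$sc), " sc dataset(s), ",
      length(x$bulk), " bulk dataset(s), ", nrow(x$metadata), " cells, ",
      nrow(x$ledger), " ledger chains\n", sep = "")
  invisible(x)
}

#' Write a reproducible fixture bundle
#'
#' Materialises a simulated study as a file tree: one AIRR Rearrangement TSV
#' per single-cell dataset, one TSV per bulk dataset, the cell metadata CSV,
#' the ground-truth ledger TSV and the synthetic germline FASTA. Re-running
#' with the same configuration seed reproduces every file byte-identically.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @param germline_db Germline database.
#' @return Invisibly, the simulated object with `$files` listing the paths.
#' @export
write_fixture_bundle <- function(outdir, config = simulation_config(),
                                 germline_db = synthetic_germline()) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", outdir)
  sim <- simulate_repertoire(config, germline_db)
  files <- character(0)
  for (ds in names(sim$sc)) {
    f <- file.path(outdir, paste0(ds, ".airr.tsv"))
    write_airr(sim$sc[[ds]], f)
    files <- c(files, f)
  }
  bulkdir <- file.path(outdir, "bulk")
  dir.create(bulkdir, showWarnings = FALSE)
  for (ds in names(sim$bulk)) {
    f <- file.path(bulkdir, paste0(ds, ".airr.tsv"))
    write_airr(sim$bulk[[ds]], f)
    files <- c(files, f)
  }
  f <- file.path(outdir, "metadata.csv")
  utils::write.csv(sim$metadata, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, "ledger.tsv")
  utils::write.table(sim$ledger, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, "germline_synthetic.fasta")
  write_germline_fasta(germline_db, f)
  files <- c(files, f)
  sim$files <- files
  invisible(sim)
}
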