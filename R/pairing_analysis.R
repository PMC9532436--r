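#' Public gamma/delta pairing fractions
#'
#' Quantifies the pairing preference of public delta CDR3 groups for the two
#' canonical public gamma chains. Per subject and per delta tag group, the
#' percentage is computed over gamma-anchored denominators: the total number
#' of cells containing a TRDV2 delta chain paired with the public
#' TRGV9-TRGJP gamma chain (or, respectively, the public TRGV8-TRGJP1 gamma
#' chain). A delta-anchored partner split (`partner_frac_v8`: among tagged
#' cells paired with either public gamma, the fraction paired with the TRGV8
#' one) is also reported for simulation-recovery checks. Cells without a
#' detected gamma chain are excluded; cells carrying both public gamma chains
#' are counted in both denominators and flagged, unless
#' `exclude_double_gamma`.
#'
#' @param cells A `gdtcr_cells` object previously passed through
#'   [tag_public_sequences()].
#' @param delta_tags Names of the delta tag groups to quantify.
#' @param gamma_v8_tag,gamma_v9_tag Names of the gamma tags.
#' @param exclude_double_gamma Drop cells tagged with both gamma publics.
#' @return A `pairing_table` data.frame with one row per subject x delta tag:
#'   `pct_v8`, `pct_v9` (gamma-anchored percentages), `n_v8`, `n_v9`,
#'   `den_v8`, `den_v9`, `partner_frac_v8`, `n_double_gamma`.
#' @export
pairing_fractions <- function(cells,
                              delta_tags = c("type1_delta", "type2_delta",
                                             "lgdt_delta"),
                              gamma_v8_tag = "public_gamma_v8",
                              gamma_v9_tag = "public_gamma_v9",
                              exclude_double_gamma = FALSE) {
  stopifnot(inherits(cells, "gdtcr_cells"))
  cc <- cells$cells
  needed <- paste0("tag_", c(delta_tags, gamma_v8_tag, gamma_v9_tag))
  missing <- setdiff(needed, names(cc))
  if (length(missing))
    stop("tag config error: unknown tag name(s): ",
         paste(sub("^tag_", "", missing), collapse = ", "),
         " (run tag_public_sequences first)")
  ch <- cells$chains
  gene <- sub("\\*.*$", "", ch$v_call)
  d2_cells <- unique(ch$cell_id[ch$locus == "TRD" & gene == "TRDV2"])
  has_g <- cc$n_gamma > 0L
  v8 <- cc[[paste0("tag_", gamma_v8_tag)]]
  v9 <- cc[[paste0("tag_", gamma_v9_tag)]]
  dbl <- v8 & v9
  keep <- has_g & (!exclude_double_gamma | !dbl)
  base <- keep & cc$cell_id %in% d2_cells
  out <- list()
  for (sid in unique(cc$subject_id)) {
    s <- cc$subject_id == sid
    den8 <- sum(base & s & v8); den9 <- sum(base & s & v9)
    if (den8 == 0L && den9 == 0L) {
      message("subject ", sid, " omitted: no public-gamma-paired TRDV2 cells")
      next
    }
    for (tg in delta_tags) {
      tagged <- cc[[paste0("tag_", tg)]]
      n8 <- sum(base & s & v8 & tagged); n9 <- sum(base & s & v9 & tagged)
      out[[paste(sid, tg)]] <- data.frame(
        subject_id = sid, delta_tag = tg,
        pct_v8 = if (den8 > 0) 100 * n8 / den8 else NA_real_,
        pct_v9 = if (den9 > 0) 100 * n9 / den9 else NA_real_,
        n_v8 = n8, n_v9 = n9, den_v8 = den8, den_v9 = den9,
        partner_frac_v8 = if (n8 + n9 > 0) n8 / (n8 + n9) else NA_real_,
        n_double_gamma = sum(base & s & dbl & tagged),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("pairing_table", "data.frame")
  res
}

#' Paired t-test on pairing percentages
#'
#' For each delta tag group, a two-tailed paired t-test across subjects
#' between the V8-paired and V9-paired percentages. With fewer than 3 paired
#' observations the test is reported as not computable.
#'
#' @param table A [pairing_fractions()] table.
#' @return A data.frame with `delta_tag`, `n_subjects`, `mean_diff`
#'   (V8 minus V9, percentage points), `t`, `p_value`, `computable`.
#' @export
pairing_test <- function(table) {
  out <- lapply(split(table, table$delta_tag), function(d) {
    ok <- !is.na(d$pct_v8) & !is.na(d$pct_v9)
    x <- d$pct_v8[ok]; y <- d$pct_v9[ok]
    n <- length(x)
    if (n < 3L)
      return(data.frame(delta_tag = d$delta_tag[1], n_subjects = n,
                        mean_diff = NA_real_, t = NA_real_,
                        p_value = NA_real_, computable = FALSE,
                        stringsAsFactors = FALSE))
    dd <- x - y
    sdd <- stats::sd(dd)
    if (sdd == 0) {
      tstat <- if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf
      p <- if (mean(dd) == 0) 1 else 0
    } else {
      tstat <- mean(dd) / (sdd / sqrt(n))
      p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    }
    data.frame(delta_tag = d$delta_tag[1], n_subjects = n,
               mean_diff = mean(dd), t = tstat, p_value = p,
               computable = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
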