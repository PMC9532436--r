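#' Per-subject group means of a chain-level metric
#'
#' The subject is the experimental unit throughout: cell- or chain-level
#' values are first averaged within subject x group, and all tests below run
#' on those subject-level means (so duplicating every cell of one subject
#' leaves every statistic unchanged).
#'
#' @param features Chain- or cell-level data.frame with `subject_id`, the
#'   grouping column and the metric column.
#' @param metric Name of the metric column.
#' @param group_col Name of the grouping column.
#' @return A data.frame `subject_id`, `group`, `mean`, `n`.
#' @export
subject_group_means <- function(features, metric, group_col = "group_label") {
  ok <- !is.na(features[[metric]]) & !is.na(features[[group_col]])
  f <- features[ok, , drop = FALSE]
  agg <- stats::aggregate(f[[metric]],
                          by = list(subject_id = f$subject_id,
                                    group = f[[group_col]]),
                          FUN = mean)
  cnt <- stats::aggregate(f[[metric]],
                          by = list(subject_id = f$subject_id,
                                    group = f[[group_col]]),
                          FUN = length)
  data.frame(subject_id = agg$subject_id, group = agg$group, mean = agg$x,
             n = cnt$x, stringsAsFactors = FALSE)
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

# exact Wilcoxon signed-rank by sign-flip enumeration: the null distribution
# of the positive-rank sum is built by convolution over midranks (handles
# ties), zero differences are dropped; two-sided p as 2 * min(tail), capped.
.exact_signed_rank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w <- as.integer(round(2 * r))          # midranks doubled -> integers
  tot <- sum(w)
  f <- c(1, numeric(tot))                # f[s + 1] = #sign vectors with sum s
  for (wi in w) {
    g <- f
    g[(wi + 1L):(tot + 1L)] <- g[(wi + 1L):(tot + 1L)] + f[1L:(tot - wi + 1L)]
    f <- g
  }
  v2 <- as.integer(round(2 * sum(r[d > 0])))
  m <- 2^length(w)
  p_le <- sum(f[seq_len(v2 + 1L)]) / m
  p_ge <- sum(f[(v2 + 1L):(tot + 1L)]) / m
  list(statistic = v2 / 2, p_value = min(1, 2 * min(p_le, p_ge)))
}

#' Immature/maturing vs effector contrast (paired Wilcoxon)
#'
#' Per-subject means of the metric are compared between the
#' immature/maturing and effector groups with a Wilcoxon matched-pairs
#' signed-rank test (exact null distribution for n <= 25 when there are no
#' ties or zero differences). Subjects missing either group are dropped from
#' the pairing with a log message; fewer than 3 complete pairs yields a
#' not-computable sentinel.
#'
#' @param features Chain-level data.frame (see [subject_group_means()]).
#' @param metric Metric column name.
#' @param groups Two group labels, compared as `groups[1]` vs `groups[2]`.
#' @param group_col Grouping column name.
#' @return A list with `per_subject` (wide data.frame), `statistic`,
#'   `p_value`, `n_subjects`, `means`, `sems`, `computable`, `test`.
#' @export
maturation_contrast <- function(features, metric,
                                groups = c("immature_maturing", "effector"),
                                group_col = "group_label") {
  sm <- subject_group_means(features, metric, group_col)
  sm <- sm[sm$group %in% groups, , drop = FALSE]
  wide <- stats::reshape(sm[, c("subject_id", "group", "mean")],
                         idvar = "subject_id", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  complete <- !is.na(wide[[groups[1]]]) & !is.na(wide[[groups[2]]])
  if (any(!complete))
    message(sum(!complete), " subject(s) dropped from paired test ",
            "(missing group)")
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)
  res <- list(per_subject = wide, n_subjects = n,
              means = c(stats::setNames(mean(wide[[groups[1]]]), groups[1]),
                        stats::setNames(mean(wide[[groups[2]]]), groups[2])),
              sems = c(stats::setNames(.sem(wide[[groups[1]]]), groups[1]),
                       stats::setNames(.sem(wide[[groups[2]]]), groups[2])),
              test = "Wilcoxon matched-pairs signed-rank")
  if (n < 3L) {
    res$statistic <- NA_real_; res$p_value <- NA_real_
    res$computable <- FALSE
    return(res)
  }
  d <- wide[[groups[1]]] - wide[[groups[2]]]
  if (all(d == 0)) {
    res$statistic <- 0; res$p_value <- 1
  } else if (n <= 25L) {
    sr <- .exact_signed_rank(d)
    res$statistic <- sr$statistic
    res$p_value <- sr$p_value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      wide[[groups[1]]], wide[[groups[2]]], paired = TRUE, exact = FALSE))
    res$statistic <- unname(wt$statistic)
    res$p_value <- wt$p.value
  }
  res$computable <- TRUE
  res
}

#' Effector-type contrast (one-way ANOVA with Tukey HSD)
#'
#' Per-subject means of the metric across the three effector types, compared
#' by one-way ANOVA with Tukey's HSD post hoc. In `"matched"` mode the
#' subject enters the model as a blocking factor and subjects missing any
#' type are excluded (logged); in `"ordinary"` mode all available
#' subject-type means are used.
#'
#' @param features Chain-level data.frame.
#' @param metric Metric column name.
#' @param types Effector type labels.
#' @param group_col Column holding the effector type.
#' @param mode `"ordinary"` or `"matched"`.
#' @return A list with `table` (subject x type means), `F`, `p_value`,
#'   `tukey` (pairwise data.frame), `mode`, `computable`.
#' @export
effector_type_contrast <- function(features, metric,
                                   types = c("type1", "type3", "type2like"),
                                   group_col = "effector_type",
                                   mode = c("ordinary", "matched")) {
  mode <- match.arg(mode)
  sm <- subject_group_means(features, metric, group_col)
  sm <- sm[sm$group %in% types, , drop = FALSE]
  present <- unique(sm$group)
  if (length(present) < 2L)
    return(list(table = sm, F = NA_real_, p_value = NA_real_, tukey = NULL,
                mode = mode, computable = FALSE))
  if (mode == "matched") {
    nt <- table(sm$subject_id)
    keep <- names(nt)[nt == length(present)]
    if (length(keep) < length(unique(sm$subject_id)))
      message(length(unique(sm$subject_id)) - length(keep),
              " subject(s) excluded from matched ANOVA (missing a type)")
    sm <- sm[sm$subject_id %in% keep, , drop = FALSE]
  }
  if (nrow(sm) < length(present) + 1L)
    return(list(table = sm, F = NA_real_, p_value = NA_real_, tukey = NULL,
                mode = mode, computable = FALSE))
  sm$group <- factor(sm$group, levels = types[types %in% present])
  sm$subject_id <- factor(sm$subject_id)
  fit <- if (mode == "matched")
    stats::aov(mean ~ group + subject_id, data = sm)
  else stats::aov(mean ~ group, data = sm)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, which = "group")$group
  list(table = sm,
       F = tab["group", "F value"],
       p_value = tab["group", "Pr(>F)"],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE),
       mode = mode, computable = TRUE)
}

#' Spearman rank correlation of a subject metric with age
#'
#' Two-tailed Spearman correlation of per-subject metric values against
#' gestational (weeks) or postnatal (years) age. Requires at least 4
#' subjects; a constant metric (all ranks tied) yields an undefined-rho
#' sentinel.
#'
#' @param subject_summaries Data.frame with one row per subject containing
#'   the age column and the metric column.
#' @param y_metric Metric column name.
#' @param age_col Age column name.
#' @return A list with `rho`, `p_value`, `n`, `computable`.
#' @export
age_trend <- function(subject_summaries, y_metric, age_col = "age_value") {
  ok <- !is.na(subject_summaries[[y_metric]]) &
    !is.na(subject_summaries[[age_col]])
  x <- subject_summaries[[age_col]][ok]
  y <- subject_summaries[[y_metric]][ok]
  if (length(x) < 4L || length(unique(y)) < 2L || length(unique(x)) < 2L)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                computable = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       computable = TRUE)
}

#' Holm-Sidak step-down adjustment
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# matched one-way ANOVA with Holm-Sidak post hoc, plus the Friedman/Dunn
# alternative; a Shapiro-Wilk gate (alpha = 0.05) on residuals picks which
# result is flagged as selected, both are always reported.
.matched_anova_holm_sidak <- function(df, value_col, group_col, subject_col) {
  df[[group_col]] <- factor(df[[group_col]])
  df[[subject_col]] <- factor(df[[subject_col]])
  g <- levels(df[[group_col]])
  fml <- stats::as.formula(paste(value_col, "~", group_col, "+", subject_col))
  fit <- stats::aov(fml, data = df)
  tab <- summary(fit)[[1]]
  resid_ok <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                       error = function(e) NA_real_)
  pairs <- utils::combn(g, 2, simplify = FALSE)
  wide <- stats::reshape(df[, c(subject_col, group_col, value_col)],
                         idvar = subject_col, timevar = group_col,
                         direction = "wide")
  names(wide) <- sub(paste0("^", value_col, "\\."), "", names(wide))
  raw <- vapply(pairs, function(pr) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    d <- d[!is.na(d)]
    if (length(d) < 2L || stats::sd(d) == 0)
      return(if (length(d) && mean(d) != 0) 0 else 1)
    t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    2 * stats::pt(-abs(t), df = length(d) - 1)
  }, numeric(1))
  posthoc <- data.frame(
    comparison = vapply(pairs, paste, "", collapse = "-"),
    p_raw = raw, p_adj = holm_sidak_adjust(raw), stringsAsFactors = FALSE)
  fr <- tryCatch({
    mat <- as.matrix(wide[, g, drop = FALSE])
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    ft <- stats::friedman.test(mat)
    rk <- t(apply(mat, 1, rank))
    nS <- nrow(mat); k <- ncol(mat)
    se <- sqrt(k * (k + 1) / (6 * nS))
    mr <- colMeans(rk)
    dz <- vapply(pairs, function(pr) abs(mr[pr[1]] - mr[pr[2]]) / se,
                 numeric(1))
    dunn <- data.frame(
      comparison = vapply(pairs, paste, "", collapse = "-"),
      p_raw = 2 * stats::pnorm(-dz), stringsAsFactors = FALSE)
    dunn$p_adj <- holm_sidak_adjust(dunn$p_raw)
    list(p_value = ft$p.value, statistic = unname(ft$statistic), dunn = dunn)
  }, error = function(e) NULL)
  normal <- !is.na(resid_ok) && resid_ok >= 0.05
  list(anova_F = tab[group_col, "F value"],
       anova_p = tab[group_col, "Pr(>F)"],
       holm_sidak = posthoc,
       shapiro_p = resid_ok,
       friedman = fr,
       selected = if (normal) "matched_anova_holm_sidak" else "friedman_dunn")
}

#' Public-tag abundance across developmental lineages
#'
#' Per subject and lineage label (effector-cluster cells excluded), the
#' fraction of TRDV2 cells carrying the given public tag, compared across
#' lineages by matched one-way ANOVA with Holm-Sidak post hoc (a Friedman /
#' Dunn alternative is reported alongside, selected when a Shapiro-Wilk gate
#' at alpha 0.05 rejects residual normality).
#'
#' @param cells A tagged `gdtcr_cells` object carrying a `lineage_label`
#'   metadata column.
#' @param tag Tag name (e.g. `"type1_delta"`).
#' @param lineage_col Metadata column with the lineage labels.
#' @return A list with `fractions` (subject x lineage), `anova` (see details)
#'   or `NULL` with a message when lineage labels are absent or the tag is
#'   absent everywhere.
#' @export
lineage_tag_abundance <- function(cells, tag, lineage_col = "lineage_label") {
  stopifnot(inherits(cells, "gdtcr_cells"))
  cc <- cells$cells
  tcol <- paste0("tag_", tag)
  if (!tcol %in% names(cc))
    stop("tag config error: unknown tag name: ", tag)
  if (!lineage_col %in% names(cc) || all(is.na(cc[[lineage_col]]))) {
    message("lineage labels absent: lineage abundance stage skipped ",
            "(trajectory fitting is out of scope)")
    return(NULL)
  }
  ch <- cells$chains
  gene <- sub("\\*.*$", "", ch$v_call)
  d2 <- unique(ch$cell_id[ch$locus == "TRD" & gene == "TRDV2"])
  sel <- cc$group_label != "effector" & !is.na(cc[[lineage_col]]) &
    cc$cell_id %in% d2
  sub <- cc[sel, , drop = FALSE]
  agg <- stats::aggregate(sub[[tcol]],
                          by = list(subject_id = sub$subject_id,
                                    lineage = sub[[lineage_col]]),
                          FUN = mean)
  names(agg)[3] <- "fraction"
  if (all(agg$fraction == 0)) {
    message("tag absent from all lineages: ANOVA skipped")
    return(list(fractions = agg, anova = NULL))
  }
  anova <- .matched_anova_holm_sidak(agg, "fraction", "lineage", "subject_id")
  list(fractions = agg, anova = anova)
}
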