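#' Two-way ANOVA variance partitioning for candidate genes
#'
#' Partitions each gene's expression variance between the maternal factor,
#' the paternal factor, their interaction, and error, reporting every
#' effect's percent of the total (corrected) sum of squares alongside its
#' F statistic and p-value — the "contribution to total expression
#' variation" analysis of a 2x2 factorial cross. Sums of squares are Type
#' II (marginal, respecting marginality) so unbalanced cell counts are
#' handled; on balanced data all SS types coincide and the four components
#' add up to the total.
#'
#' With one replicate per cell the interaction is inseparable from error:
#' it is pooled into the error term and the gene flagged.
#'
#' @param data Long-format data frame with columns `value`, `maternal`,
#'   `paternal` and optionally `gene` (one partition per gene).
#' @param value,maternal,paternal,gene Column names.
#' @return Data frame of class `anova_partition`, one row per gene:
#'   `gene_id`, `ss_maternal`, `ss_paternal`, `ss_interaction`,
#'   `ss_error`, `ss_total`, `pct_maternal`, `pct_paternal`,
#'   `pct_interaction`, `f_*`, `p_*`, `flag`.
#' @export
two_way_anova <- function(data, value = "value", maternal = "maternal",
                          paternal = "paternal", gene = "gene") {
  need <- c(value, maternal, paternal)
  if (!all(need %in% names(data)))
    stopf("'data' must have columns %s", paste(need, collapse = ", "))
  if (gene %in% names(data)) {
    parts <- split(data, data[[gene]])
    out <- do.call(rbind, lapply(names(parts), function(g)
      two_way_anova_one(parts[[g]], g, value, maternal, paternal)))
  } else {
    out <- two_way_anova_one(data, "gene", value, maternal, paternal)
  }
  rownames(out) <- NULL
  class(out) <- c("anova_partition", "data.frame")
  out
}

two_way_anova_one <- function(df, gene_id, value, maternal, paternal) {
  y <- df[[value]]
  A <- factor(df[[maternal]])
  B <- factor(df[[paternal]])
  if (nlevels(A) != 2L || nlevels(B) != 2L)
    stopf("gene '%s': both factors must have exactly 2 levels", gene_id)
  cells <- table(A, B)
  if (any(cells == 0L))
    stopf("gene '%s': empty cell in the 2x2 layout", gene_id)
  if (!all(is.finite(y)))
    stopf("gene '%s': non-finite expression values", gene_id)
  ss_total <- sum((y - mean(y))^2)
  pool_interaction <- all(cells == 1L)
  flag <- ""

  if (ss_total == 0) {
    # all observations equal: every SS is 0 and percentages 0 by convention
    return(data.frame(gene_id = gene_id, ss_maternal = 0, ss_paternal = 0,
                      ss_interaction = 0, ss_error = 0, ss_total = 0,
                      pct_maternal = 0, pct_paternal = 0,
                      pct_interaction = 0,
                      f_maternal = NA_real_, f_paternal = NA_real_,
                      f_interaction = NA_real_,
                      p_maternal = NA_real_, p_paternal = NA_real_,
                      p_interaction = NA_real_, flag = "constant",
                      stringsAsFactors = FALSE))
  }

  # Type II sums of squares by model comparison (marginal, respecting
  # marginality); robust to perfect fits, where generic ANOVA helpers
  # refuse a zero residual sum of squares
  rss <- function(f) sum(stats::lm.fit(stats::model.matrix(f), y)$residuals^2)
  rss_add <- rss(~ A + B)
  ss_a <- max(0, rss(~ B) - rss_add)
  ss_b <- max(0, rss(~ A) - rss_add)
  if (pool_interaction) {
    flag <- "interaction_pooled"
    ss_ab <- NA_real_
    pct_ab <- NA_real_
    ss_err <- rss_add
    df_err <- length(y) - 3L
  } else {
    rss_full <- rss(~ A * B)
    ss_ab <- max(0, rss_add - rss_full)
    pct_ab <- 100 * ss_ab / ss_total
    ss_err <- rss_full
    df_err <- length(y) - 4L
  }
  mse <- ss_err / df_err
  fstat <- function(ss) if (ss == 0 && mse == 0) NA_real_ else ss / mse
  f_a <- fstat(ss_a); f_b <- fstat(ss_b)
  f_ab <- if (pool_interaction) NA_real_ else fstat(ss_ab)
  pval <- function(f) if (is.na(f)) NA_real_ else
    stats::pf(f, 1, df_err, lower.tail = FALSE)
  p_a <- pval(f_a); p_b <- pval(f_b); p_ab <- pval(f_ab)
  data.frame(gene_id = gene_id, ss_maternal = ss_a, ss_paternal = ss_b,
             ss_interaction = ss_ab, ss_error = ss_err, ss_total = ss_total,
             pct_maternal = 100 * ss_a / ss_total,
             pct_paternal = 100 * ss_b / ss_total,
             pct_interaction = pct_ab,
             f_maternal = f_a, f_paternal = f_b, f_interaction = f_ab,
             p_maternal = p_a, p_paternal = p_b, p_interaction = p_ab,
             flag = flag, stringsAsFactors = FALSE)
}

# significance stars matching the reporting convention of the variance
# tables: ** p<0.01, * p<0.05, otherwise (ns)
anova_stars <- function(p) {
  ifelse(is.na(p), "(ns)",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "(ns)")))
}

#' Write an ANOVA partition as a report-shaped TSV
#'
#' Columns: gene and, per factor, `percent (stars)` with the p-value, the
#' layout used for candidate-gene variance tables.
#'
#' @param partition An `anova_partition`.
#' @param path Output file path.
#' @export
write_anova_tsv <- function(partition, path) {
  fmt <- function(pct, p)
    sprintf("%.2f %s (P = %.3g)", pct, anova_stars(p), p)
  out <- data.frame(gene = partition$gene_id,
                    maternal = fmt(partition$pct_maternal,
                                   partition$p_maternal),
                    paternal = fmt(partition$pct_paternal,
                                   partition$p_paternal),
                    interaction = fmt(partition$pct_interaction,
                                      partition$p_interaction),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise post-tests
#'
#' Omnibus one-way ANOVA followed, for each requested pair of groups, by a
#' t-test on the pooled error term with Bonferroni multiplication by the
#' number of requested comparisons.
#'
#' @param data Data frame with columns `value` and `group`.
#' @param comparisons List of length-2 character vectors of group labels;
#'   default: all pairwise comparisons.
#' @param value,group Column names.
#' @return List with `omnibus` (data frame: `f`, `df1`, `df2`, `p`) and
#'   `posthoc` (data frame: `group1`, `group2`, `mean_difference`,
#'   `raw_p`, `adjusted_p`, `n_comparisons`).
#' @export
one_way_bonferroni <- function(data, comparisons = NULL, value = "value",
                               group = "group") {
  if (!all(c(value, group) %in% names(data)))
    stopf("'data' must have columns %s and %s", value, group)
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stopf("need >= 2 groups")
  counts <- table(g)
  if (any(counts < 2L))
    stopf("every group needs >= 2 samples (smallest has %d)", min(counts))
  if (is.null(comparisons))
    comparisons <- utils::combn(levels(g), 2L, simplify = FALSE)
  for (cmp in comparisons) {
    if (length(cmp) != 2L || !all(cmp %in% levels(g)))
      stopf("unknown group label in comparison '%s'",
            paste(cmp, collapse = " vs "))
  }
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  means <- tapply(y, g, mean)
  k <- length(comparisons)
  posthoc <- do.call(rbind, lapply(comparisons, function(cmp) {
    d <- means[[cmp[2]]] - means[[cmp[1]]]
    se <- sqrt(mse * (1 / counts[[cmp[1]]] + 1 / counts[[cmp[2]]]))
    tval <- d / se
    raw <- 2 * stats::pt(-abs(tval), df_err)
    data.frame(group1 = cmp[1], group2 = cmp[2], mean_difference = d,
               raw_p = raw, adjusted_p = min(1, raw * k),
               n_comparisons = k, stringsAsFactors = FALSE)
  }))
  list(omnibus = data.frame(f = an[1, "F value"], df1 = an[1, "Df"],
                            df2 = df_err, p = an[1, "Pr(>F)"]),
       posthoc = posthoc)
}
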