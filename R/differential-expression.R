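#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts raw p-values to FDR q-values by the step-up rule
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in input
#' order (delegates to [stats::p.adjust()] after validation).
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  bad <- which(!is.numeric(p) | !is.finite(p) | p < 0 | p > 1)
  if (length(bad))
    stopf("bh_adjust: p-value outside [0, 1] or non-finite at index %d",
          bad[1])
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Per-gene two-group differential expression
#'
#' Unpaired two-sample t-test per gene (pooled variance by default, Welch
#' via `welch = TRUE`), two-sided p-values, Benjamini-Hochberg q-values and
#' a fully deterministic rank. The log2 fold change is
#' `mean(contrast) - mean(reference)`; the confidence interval on the fold
#' change comes from the t distribution on the contrast of means and is
#' reported on the linear scale.
#'
#' Degenerate genes are kept, not dropped, so gene universes stay aligned
#' across analysis stages: a gene with zero variance in both groups and
#' equal means gets p = 1 by convention; zero variance with unequal means
#' gets the smallest representable positive p, flagged `zero_var_shift`.
#' Genes with missing values are dropped with a warning.
#'
#' @param x An [expression_set()].
#' @param reference,contrast Group labels to compare (both must have >= 2
#'   samples after stratification).
#' @param stratify Optional named list of annotation filters applied before
#'   testing, e.g. `list(sex = "F")` for the sex-stratified analysis.
#' @param welch Use the Welch (unequal-variance) t-test.
#' @param shrink Optional variance-shrinkage weight in [0, 1]: the pooled
#'   per-gene variance is shrunk toward the median pooled variance with
#'   this weight. 0 (default) is the plain t-test.
#' @param conf_level Confidence level for the fold-change interval.
#' @return A data frame of class `de_table` with columns `gene_id`,
#'   `log2fc`, `fc`, `ci_low`, `ci_high`, `statistic`, `p`, `q`, `rank`,
#'   `flag`, in the gene order of `x`.
#' @export
de_test <- function(x, reference, contrast, stratify = NULL, welch = FALSE,
                    shrink = 0, conf_level = 0.95) {
  if (!inherits(x, "expr_set")) stopf("'x' must be an expr_set")
  shrink <- check_number(shrink, "shrink", min = 0, max = 1)
  samples <- x$samples
  keep <- rep(TRUE, nrow(samples))
  for (key in names(stratify)) {
    if (!key %in% names(samples))
      stopf("stratify: no sample annotation column '%s'", key)
    keep <- keep & samples[[key]] %in% stratify[[key]]
  }
  samples <- samples[keep, , drop = FALSE]
  if (identical(reference, contrast))
    stopf("'reference' and 'contrast' must be distinct groups")
  i_ref <- samples$sample_id[samples$group == reference]
  i_con <- samples$sample_id[samples$group == contrast]
  n1 <- length(i_ref); n2 <- length(i_con)
  if (n1 < 2L || n2 < 2L)
    stopf("need >= 2 samples per group after stratification (reference '%s': %d, contrast '%s': %d)",
          reference, n1, contrast, n2)

  vals <- x$values[, c(i_ref, i_con), drop = FALSE]
  miss <- rowSums(!is.finite(vals)) > 0
  if (any(miss)) {
    warning(sprintf("de_test: dropping %d gene(s) with missing values",
                    sum(miss)))
    vals <- vals[!miss, , drop = FALSE]
  }
  vr <- vals[, seq_len(n1), drop = FALSE]
  vc <- vals[, n1 + seq_len(n2), drop = FALSE]
  m1 <- rowMeans(vr); m2 <- rowMeans(vc)
  s1 <- rowSums((vr - m1)^2) / (n1 - 1)
  s2 <- rowSums((vc - m2)^2) / (n2 - 1)
  lfc <- m2 - m1

  if (welch) {
    se2 <- s1 / n1 + s2 / n2
    df <- se2^2 / (s1^2 / (n1^2 * (n1 - 1)) + s2^2 / (n2^2 * (n2 - 1)))
    se <- sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    if (shrink > 0)
      sp2 <- (1 - shrink) * sp2 + shrink * stats::median(sp2)
    df <- rep(n1 + n2 - 2, length(lfc))
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }

  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  flag <- rep("", length(lfc))
  zero <- !is.finite(tstat) | se == 0
  if (any(zero)) {
    same <- zero & lfc == 0
    shift <- zero & lfc != 0
    tstat[same] <- 0; p[same] <- 1
    flag[same] <- "zero_var"
    tstat[shift] <- sign(lfc[shift]) * Inf
    p[shift] <- .Machine$double.xmin
    flag[shift] <- "zero_var_shift"
    df[zero & !is.finite(df)] <- n1 + n2 - 2
  }

  tc <- stats::qt(1 - (1 - conf_level) / 2, df)
  half <- tc * se
  half[zero] <- 0
  out <- data.frame(gene_id = rownames(vals), log2fc = lfc, fc = 2^lfc,
                    ci_low = 2^(lfc - half), ci_high = 2^(lfc + half),
                    statistic = tstat, p = p, q = bh_adjust(p),
                    rank = NA_integer_, flag = flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  rank_by_q(structure(out, class = c("de_table", "data.frame")))
}

#' Deterministic FDR ordering of a DE table
#'
#' Orders genes by ascending q-value; ties are broken by ascending raw p,
#' then descending absolute log2 fold change, then gene identifier (C
#' locale), so the rank is a reproducible permutation of `1..n`.
#'
#' @param table A `de_table` with `q` populated.
#' @return The table with `rank` filled in (row order unchanged).
#' @export
rank_by_q <- function(table) {
  if (!all(c("q", "p", "log2fc", "gene_id") %in% names(table)))
    stopf("rank_by_q: table must have gene_id, log2fc, p, q")
  ord <- order_det(table$q, table$p, -abs(table$log2fc), table$gene_id)
  table$rank[ord] <- seq_len(nrow(table))
  table
}

#' Call significantly perturbed genes at an FDR threshold
#'
#' Partitions genes with `q < q_cut` by the sign of their log2 fold change.
#' Significant genes with exactly zero fold change (possible only through
#' degenerate ties) are counted as up-regulated by convention and reported
#' separately.
#'
#' @param table A `de_table`.
#' @param q_cut FDR threshold in (0, 1]; `q_cut = 1` calls every gene.
#' @return List with `up`, `down` (character vectors of gene ids) and
#'   `zero_lfc` (ids folded into `up` by the convention).
#' @export
call_significant <- function(table, q_cut = 0.05) {
  q_cut <- check_number(q_cut, "q_cut", min = 1e-300, max = 1)
  sig <- if (q_cut == 1) rep(TRUE, nrow(table)) else table$q < q_cut
  up <- table$gene_id[sig & table$log2fc >= 0]
  down <- table$gene_id[sig & table$log2fc < 0]
  list(up = up, down = down,
       zero_lfc = table$gene_id[sig & table$log2fc == 0])
}

#' Power of the two-sample t-test for a fold change
#'
#' Power of the two-sided, two-sample pooled t-test to resolve a linear
#' fold change at a given per-group sample size and residual sd on the log2
#' scale, computed from the noncentral t distribution.
#'
#' @param fold_change Linear fold change (> 0); 1.5 means a 50\% shift.
#' @param alpha Two-sided significance level.
#' @param n_per_group Samples per group (>= 2).
#' @param sd Residual standard deviation on the log2 scale (> 0).
#' @return An object of class `power_estimate`: list with the inputs and
#'   `power`.
#' @export
power_fold_change <- function(fold_change, alpha = 0.05, n_per_group, sd) {
  fold_change <- check_number(fold_change, "fold_change", min = 1e-12)
  alpha <- check_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  n <- check_count(n_per_group, "n_per_group", min = 2L)
  sd <- check_number(sd, "sd", min = 1e-12)
  delta <- abs(log2(fold_change))
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  tc <- stats::qt(1 - alpha / 2, df)
  power <- stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
  structure(list(fold_change = fold_change, alpha = alpha,
                 n_per_group = n, sd = sd, power = power),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power %.3f to resolve a %.3g-fold change (n = %d/group, sd = %.3g log2, alpha = %.3g)\n",
              x$power, x$fold_change, x$n_per_group, x$sd, x$alpha))
  invisible(x)
}

#' Write a DE table as TSV
#'
#' @param table A `de_table`.
#' @param path Output file path.
#' @export
write_de_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
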