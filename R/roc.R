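#' ROC curve of set membership against the FDR ordering
#'
#' Traverses genes from most perturbed (rank 1) to least, treating genes
#' with tied q-values as one block; at each threshold the true-positive
#' rate is the fraction of set members at or above it and the
#' false-positive rate the fraction of non-members. With this block
#' handling the trapezoidal area equals the Mann-Whitney probability with
#' midrank ties.
#'
#' @param ranked A `de_table` with populated ranks and q-values.
#' @param set_members Character vector of member gene identifiers.
#' @param rank_by `"q"` (default: ascending q-value) or `"stat"`
#'   (descending absolute t statistic) as the traversal score.
#' @return Data frame of class `roc_points` with columns `fpr`, `tpr`,
#'   starting at (0, 0) and ending at (1, 1).
#' @export
roc_curve <- function(ranked, set_members, rank_by = c("q", "stat")) {
  rank_by <- match.arg(rank_by)
  memb <- roc_membership(ranked, set_members)
  score <- if (rank_by == "q") -ranked$q else abs(ranked$statistic)
  ord <- order_det(-score, ranked$rank)
  hit <- memb[ord]
  block <- cumsum(!duplicated(score[ord]))
  n1 <- sum(hit); n2 <- sum(!hit)
  tp <- cumsum(tapply(hit, block, sum))
  fp <- cumsum(tapply(!hit, block, sum))
  structure(data.frame(fpr = c(0, fp / n2), tpr = c(0, tp / n1)),
            class = c("roc_points", "data.frame"))
}

# shared validation: membership logical over the table's universe
roc_membership <- function(ranked, set_members) {
  if (!all(c("gene_id", "rank", "q") %in% names(ranked)) ||
      anyNA(ranked$rank))
    stopf("'ranked' must be a de_table with populated ranks")
  memb <- ranked$gene_id %in% unique(as.character(set_members))
  if (!any(memb))
    stopf("the gene set has no members in the ranked universe")
  if (all(memb))
    stopf("the gene set equals the whole universe; ROC is undefined")
  memb
}

#' Area under a ROC curve
#'
#' Trapezoidal area; for curves from [roc_curve()] this equals the
#' Mann-Whitney probability that a member outranks a non-member, with
#' midrank handling of q-value ties.
#'
#' @param curve A `roc_points` data frame.
#' @return Area in [0, 1].
#' @export
roc_auc <- function(curve) {
  if (!all(c("fpr", "tpr") %in% names(curve)))
    stopf("'curve' must have fpr and tpr columns")
  fpr <- curve$fpr; tpr <- curve$tpr
  if (any(diff(fpr) < 0) || any(diff(tpr) < 0))
    stopf("ROC coordinates must be nondecreasing")
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Mann-Whitney AUC straight from scores (higher score = more perturbed),
# midranks for ties; algebraically identical to roc_auc(roc_curve(...))
auc_from_scores <- function(score, memb) {
  r <- rank(score)
  n1 <- sum(memb); n2 <- sum(!memb)
  (sum(r[memb]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Gene-label permutation test of a set's AUC
#'
#' Computes the observed AUC of the set against the fixed ranking, then
#' permutes which genes carry the membership label (equivalently, draws
#' size-matched random sets without replacement) and recomputes the AUC for
#' each of `n_perm` permutations. Reports the exceedance count
#' `k = #{null < observed}` and the add-one empirical p-value
#' `p_emp = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param ranked A `de_table` with populated ranks.
#' @param set_members Character vector of member gene identifiers.
#' @param n_perm Number of label permutations (>= 1; default 100).
#' @param seed Integer RNG seed.
#' @param rank_by `"q"` (default: ascending q-value with the deterministic
#'   tie-break ordering) or `"stat"` (descending absolute t statistic).
#' @param set_name Label carried into the result.
#' @return Object of class `roc_perm`: list with `set_name`, `curve`,
#'   `auc`, `null_aucs`, `exceed_count`, `p_emp`, `n_perm`, `seed`,
#'   `rank_by`.
#' @export
roc_permutation_test <- function(ranked, set_members, n_perm = 100,
                                 seed = 1, rank_by = c("q", "stat"),
                                 set_name = "set") {
  rank_by <- match.arg(rank_by)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  memb <- roc_membership(ranked, set_members)
  score <- if (rank_by == "q") -ranked$q else abs(ranked$statistic)
  obs <- auc_from_scores(score, memb)
  n1 <- sum(memb)
  n <- length(memb)
  set.seed(seed)
  null_aucs <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n1)
    pm <- logical(n); pm[idx] <- TRUE
    auc_from_scores(score, pm)
  }, numeric(1))
  k <- sum(null_aucs < obs)
  p_emp <- (1 + sum(null_aucs >= obs)) / (n_perm + 1)
  structure(list(set_name = set_name,
                 curve = roc_curve(ranked, set_members, rank_by = rank_by),
                 auc = obs, null_aucs = null_aucs, exceed_count = k,
                 p_emp = p_emp, n_perm = n_perm, seed = seed,
                 rank_by = rank_by),
            class = "roc_perm")
}

#' @export
print.roc_perm <- function(x, ...) {
  cat(sprintf("roc_perm '%s': AUC %.4f, higher than %d of %d label permutations (p_emp = %.4f)\n",
              x$set_name, x$auc, x$exceed_count, x$n_perm, x$p_emp))
  invisible(x)
}
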