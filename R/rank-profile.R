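#' Locate a gene set within the FDR-ordered transcriptome
#'
#' Given a DE table with deterministic ranks, records the ranks of a set's
#' members and the cumulative fraction of members found at or below each
#' rank of the full grid — the curve used to compare a focal gene class
#' (e.g. imprinted genes) against random, housekeeping and
#' positive-control classes.
#'
#' @param ranked A `de_table` with `rank` populated (see [rank_by_q()]).
#' @param set_members Character vector of member gene identifiers; members
#'   outside the table's universe are excluded and counted.
#' @param set_name Label carried into the result.
#' @return An object of class `rank_profile`: list with `set_name`,
#'   `ranks` (sorted member ranks), `cumulative` (length `n_universe`),
#'   `n_set`, `n_universe`, `n_dropped`.
#' @export
rank_distribution <- function(ranked, set_members, set_name = "set") {
  if (!all(c("gene_id", "rank") %in% names(ranked)) ||
      anyNA(ranked$rank))
    stopf("'ranked' must be a de_table with populated ranks")
  universe <- ranked$gene_id
  members <- unique(as.character(set_members))
  inside <- members %in% universe
  if (!any(inside))
    stopf("set '%s' has no members in the ranked universe", set_name)
  ranks <- sort(ranked$rank[match(members[inside], universe)])
  n <- length(universe)
  hits <- integer(n)
  hits[ranks] <- 1L
  structure(list(set_name = set_name, ranks = ranks,
                 cumulative = cumsum(hits) / length(ranks),
                 n_set = length(ranks), n_universe = n,
                 n_dropped = sum(!inside)),
            class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  cat(sprintf("rank_profile '%s': %d members in a %d-gene universe (median rank %d, KS departure %.3f)\n",
              x$set_name, x$n_set, x$n_universe,
              as.integer(stats::median(x$ranks)), ks_departure(x)))
  invisible(x)
}

#' Supremum departure of a rank profile from uniformity
#'
#' Kolmogorov-Smirnov-type statistic `max_r |cumulative(r) - r/N|`: how far
#' the set's cumulative rank distribution strays from the diagonal expected
#' of a randomly placed set. 0 for the diagonal; `1 - k/N` for a set
#' occupying exactly the top k of N ranks.
#'
#' @param profile A [rank_distribution()] result.
#' @return Statistic in [0, 1].
#' @export
ks_departure <- function(profile) {
  if (!inherits(profile, "rank_profile")) stopf("'profile' must be a rank_profile")
  n <- profile$n_universe
  max(abs(profile$cumulative - seq_len(n) / n))
}

# signed departure at the supremum: positive when members concentrate at
# low (perturbed) ranks
ks_departure_signed <- function(profile) {
  n <- profile$n_universe
  dev <- profile$cumulative - seq_len(n) / n
  dev[which.max(abs(dev))]
}

#' Random-set envelope for rank profiles
#'
#' Pointwise quantile envelope of cumulative rank curves over size-matched
#' random gene sets drawn without replacement from the ranked universe,
#' plus the null distribution of the KS departure over the same draws
#' (used for a calibrated overall verdict, since pointwise bands alone do
#' not control the familywise crossing rate).
#'
#' @param ranked A `de_table` with populated ranks.
#' @param set_size Size of each random set.
#' @param n_draws Number of random draws (>= 20; default 200).
#' @param quantiles Lower/upper pointwise quantiles (default 0.025/0.975).
#' @param seed Integer RNG seed; the envelope is deterministic given it.
#' @return Object of class `rank_envelope`: list with `lower`, `upper`
#'   (per-rank bounds), `ks_null` (KS departures of the draws),
#'   `set_size`, `n_draws`, `quantiles`, `seed`.
#' @export
random_set_envelope <- function(ranked, set_size, n_draws = 200,
                                quantiles = c(0.025, 0.975), seed = 1) {
  n <- nrow(ranked)
  set_size <- check_count(set_size, "set_size", min = 1L)
  if (set_size > n)
    stopf("set_size = %d exceeds the %d-gene universe", set_size, n)
  n_draws <- check_count(n_draws, "n_draws", min = 20L)
  if (length(quantiles) != 2L || any(quantiles < 0) || any(quantiles > 1) ||
      quantiles[1] >= quantiles[2])
    stopf("'quantiles' must be two increasing values in [0, 1]")
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  grid <- seq_len(n) / n
  curves <- matrix(0, n_draws, n)
  ks_null <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    hits <- integer(n)
    hits[sample.int(n, set_size)] <- 1L  # ranks are a permutation of 1..n
    cum <- cumsum(hits) / set_size
    curves[i, ] <- cum
    ks_null[i] <- max(abs(cum - grid))
  }
  bounds <- apply(curves, 2L, stats::quantile, probs = quantiles,
                  names = FALSE)
  structure(list(lower = bounds[1, ], upper = bounds[2, ],
                 ks_null = ks_null, set_size = set_size,
                 n_draws = n_draws, quantiles = quantiles, seed = seed),
            class = "rank_envelope")
}

#' Verdict: does a gene class behave like randomly chosen genes?
#'
#' Operationalises the visual rank-distribution comparison: the decisive
#' rule is whether the set's KS departure from the diagonal stays within
#' the null 95th percentile over size-matched random draws (an exact-level
#' exchangeability test); the fraction of ranks at which the curve leaves
#' the pointwise envelope is reported as a descriptive companion. When the
#' departure is extreme, its sign names the direction: members crowding
#' the low (most-perturbed) ranks are "susceptible", members pushed toward
#' the high ranks are "protected".
#'
#' @param profile A [rank_distribution()] result.
#' @param envelope A [random_set_envelope()] built on the same ranking with
#'   a matching set size.
#' @param level Exceedance level for the KS rule (default 0.05).
#' @return List with `verdict` (one of `"indistinguishable from random"`,
#'   `"susceptible"`, `"protected"`), `ks`, `ks_p` (permutation p-value of
#'   the KS departure), `ks_null_crit`, `outside_fraction`.
#' @export
rank_profile_verdict <- function(profile, envelope, level = 0.05) {
  if (!inherits(envelope, "rank_envelope")) stopf("'envelope' must be a rank_envelope")
  if (envelope$set_size != profile$n_set)
    stopf("envelope set_size (%d) does not match profile n_set (%d)",
          envelope$set_size, profile$n_set)
  ks <- ks_departure(profile)
  ks_p <- (1 + sum(envelope$ks_null >= ks)) / (envelope$n_draws + 1)
  crit <- stats::quantile(envelope$ks_null, 1 - level, names = FALSE)
  outside <- mean(profile$cumulative < envelope$lower |
                    profile$cumulative > envelope$upper)
  verdict <- if (ks <= crit) "indistinguishable from random"
  else if (ks_departure_signed(profile) > 0) "susceptible"
  else "protected"
  list(verdict = verdict, ks = ks, ks_p = ks_p, ks_null_crit = crit,
       outside_fraction = outside)
}

#' Write a rank profile (with optional envelope) as TSV
#'
#' Columns: `rank`, `cumulative` and, when an envelope is supplied,
#' `lower`, `upper`.
#'
#' @param profile A `rank_profile`.
#' @param path Output file path.
#' @param envelope Optional matching `rank_envelope`.
#' @export
write_rank_profile_tsv <- function(profile, path, envelope = NULL) {
  out <- data.frame(rank = seq_len(profile$n_universe),
                    cumulative = profile$cumulative)
  if (!is.null(envelope)) {
    out$lower <- envelope$lower
    out$upper <- envelope$upper
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
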