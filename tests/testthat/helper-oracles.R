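# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (brute force / enumeration) and never call
# the code paths they check.

# brute-force BH step-up: explicit minimisation over all thresholds j >= i
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) ps[j] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force Mann-Whitney AUC: explicit pairwise comparison with 0.5 for
# ties; score convention: higher score = more perturbed
brute_auc <- function(score, memb) {
  s1 <- score[memb]
  s2 <- score[!memb]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s2) + 0.5 * sum(a == s2)
  tot / (length(s1) * length(s2))
}

# brute-force GSEA running sum: position-by-position enumeration
brute_es <- function(stats, members, exponent = 0) {
  ord <- order(-stats, names(stats), method = "radix")
  s <- stats[ord]
  hit <- names(s) %in% members
  n <- length(s); nh <- sum(hit)
  w <- abs(s)^exponent
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- if (hit[i]) acc + w[i] / sum(w[hit]) else acc - 1 / (n - nh)
    run[i] <- acc
  }
  # signed extreme; positive/negative ties (up to accumulation rounding)
  # resolve to the positive extreme
  d_hi <- max(run); d_lo <- min(run)
  if (d_hi + d_lo >= -1e-12 * max(d_hi, -d_lo, 1)) d_hi else d_lo
}

# model-comparison oracle for Type II two-way ANOVA sums of squares
brute_type2 <- function(y, A, B) {
  rss <- function(f) sum(stats::resid(stats::lm(f))^2)
  full <- stats::lm(y ~ A * B)
  rss_full <- sum(stats::resid(full)^2)
  df_full <- stats::df.residual(full)
  ss_a <- rss(y ~ B) - rss(y ~ A + B)
  ss_b <- rss(y ~ A) - rss(y ~ A + B)
  ss_ab <- rss(y ~ A + B) - rss_full
  mse <- rss_full / df_full
  f <- c(ss_a, ss_b, ss_ab) / mse
  list(ss = c(maternal = ss_a, paternal = ss_b, interaction = ss_ab,
              error = rss_full),
       f = f,
       p = stats::pf(f, 1, df_full, lower.tail = FALSE))
}

# build a minimal ranked DE table from q-values (and optional p / lfc)
make_de_table <- function(q, p = q, lfc = rep(1, length(q)),
                          ids = sprintf("g%03d", seq_along(q))) {
  tab <- data.frame(gene_id = ids, log2fc = lfc, fc = 2^lfc,
                    ci_low = NA_real_, ci_high = NA_real_,
                    statistic = lfc, p = p, q = q, rank = NA_integer_,
                    flag = "", stringsAsFactors = FALSE)
  rank_by_q(structure(tab, class = c("de_table", "data.frame")))
}

# a pure-noise two-group design: no planted effects, no litter or sex
# structure, constant per-gene sd (the calibration reference)
null_design <- function(seed, n_genes = 10000, n_per_group = 10,
                        sd = 0.2, neutral = 90) {
  synthetic_design(n_genes = n_genes,
                   class_sizes = c(neutral = neutral),
                   effect_model = list(),
                   noise_meanlog = log(sd), noise_sdlog = 0,
                   litter_sd = 0, sex_effect = 0,
                   n_per_group = n_per_group, seed = seed)
}

# the planted-responsive study design used throughout: a responsive class
# at +/- log2(1.5), a neutral imprinted-like class, constant sd
responsive_design <- function(seed, n_genes = 10000, n_per_group = 10,
                              sd = 0.2, responsive = 200, neutral = 90) {
  synthetic_design(n_genes = n_genes,
                   class_sizes = c(responsive = responsive,
                                   neutral = neutral),
                   effect_model = list(
                     responsive = list(mean = log2(1.5), sd = 0,
                                       sign = "balanced")),
                   noise_meanlog = log(sd), noise_sdlog = 0,
                   litter_sd = 0, sex_effect = 0,
                   n_per_group = n_per_group, seed = seed)
}
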