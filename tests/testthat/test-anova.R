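cells_df <- function(a0b0, a0b1, a1b0, a1b1) {
  data.frame(value = c(a0b0, a0b1, a1b0, a1b1),
             maternal = rep(c("C", "C", "U", "U"),
                            c(length(a0b0), length(a0b1),
                              length(a1b0), length(a1b1))),
             paternal = rep(c("C", "U", "C", "U"),
                            c(length(a0b0), length(a0b1),
                              length(a1b0), length(a1b1))))
}

test_that("hand-computed 2x2 example is reproduced exactly", {
  out <- two_way_anova(cells_df(c(1, 1), c(1, 1), c(3, 3), c(3, 3)))
  expect_equal(out$ss_maternal, 8)
  expect_equal(out$ss_paternal, 0)
  expect_equal(out$ss_interaction, 0)
  expect_equal(out$ss_error, 0)
  expect_equal(out$pct_maternal, 100)
})

test_that("constant response reports zero sums of squares by convention", {
  out <- two_way_anova(cells_df(c(2, 2), c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(out$ss_total, 0)
  expect_equal(out$pct_maternal, 0)
  expect_equal(out$pct_paternal, 0)
  expect_equal(out$pct_interaction, 0)
  expect_equal(out$flag, "constant")
})

test_that("balanced designs: components sum to the total and SS types agree", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    df <- cells_df(rnorm(n), rnorm(n), rnorm(n), rnorm(n))
    out <- two_way_anova(df)
    expect_equal(out$ss_maternal + out$ss_paternal + out$ss_interaction +
                   out$ss_error, out$ss_total, tolerance = 1e-9)
    # Type I (sequential) and Type III (sum contrasts) agree with Type II
    A <- factor(df$maternal); B <- factor(df$paternal)
    t1 <- anova(lm(df$value ~ A * B))
    expect_equal(out$ss_maternal, t1["A", "Sum Sq"], tolerance = 1e-9)
    expect_equal(out$ss_paternal, t1["B", "Sum Sq"], tolerance = 1e-9)
    t3 <- car::Anova(lm(df$value ~ A * B,
                        contrasts = list(A = "contr.sum", B = "contr.sum")),
                     type = 3)
    expect_equal(out$ss_maternal, t3["A", "Sum Sq"], tolerance = 1e-9)
    expect_equal(out$ss_interaction, t3["A:B", "Sum Sq"], tolerance = 1e-9)
  }
})

test_that("unbalanced designs match the model-comparison oracle", {
  set.seed(5)
  for (i in 1:100) {
    ns <- sample(2:7, 4, replace = TRUE)
    df <- cells_df(rnorm(ns[1]), rnorm(ns[2]), rnorm(ns[3]), rnorm(ns[4]))
    out <- two_way_anova(df)
    oracle <- brute_type2(df$value, factor(df$maternal),
                          factor(df$paternal))
    expect_equal(out$ss_maternal, oracle$ss[["maternal"]], tolerance = 1e-8)
    expect_equal(out$ss_paternal, oracle$ss[["paternal"]], tolerance = 1e-8)
    expect_equal(out$ss_interaction, oracle$ss[["interaction"]],
                 tolerance = 1e-8)
    expect_equal(out$ss_error, oracle$ss[["error"]], tolerance = 1e-8)
    expect_equal(c(out$f_maternal, out$f_paternal, out$f_interaction),
                 unname(oracle$f), tolerance = 1e-8)
    expect_equal(c(out$p_maternal, out$p_paternal, out$p_interaction),
                 unname(oracle$p), tolerance = 1e-8)
  }
})

test_that("percent contributions are invariant to affine rescaling", {
  set.seed(7)
  df <- cells_df(rnorm(5), rnorm(5), rnorm(5, 1), rnorm(5))
  out1 <- two_way_anova(df)
  df$value <- 3.7 * df$value - 12
  out2 <- two_way_anova(df)
  expect_equal(out1$pct_maternal, out2$pct_maternal, tolerance = 1e-9)
  expect_equal(out1$pct_paternal, out2$pct_paternal, tolerance = 1e-9)
  expect_equal(out1$pct_interaction, out2$pct_interaction,
               tolerance = 1e-9)
})

test_that("degenerate layouts are flagged or refused", {
  df <- cells_df(1:2, 3:4, 5:6, numeric(0))
  expect_error(two_way_anova(df), "empty cell")
  one_rep <- cells_df(1, 2, 3, 5)
  out <- two_way_anova(one_rep)
  expect_equal(out$flag, "interaction_pooled")
  expect_true(is.na(out$ss_interaction))
  expect_equal(out$ss_maternal + out$ss_paternal + out$ss_error,
               out$ss_total, tolerance = 1e-9)
})

test_that("a small planted maternal fraction is detected at realistic n", {
  # 8% of variance at n = 12/cell: the rejection rate must match the
  # noncentral-F power of this design
  hits <- vapply(1:200, function(seed) {
    cand <- generate_factorial_candidates(
      c(maternal = 0.08, paternal = 0, interaction = 0),
      n_per_cell = 12, genes = "g", seed = seed)
    out <- two_way_anova(cand)
    c(out$pct_maternal >= 2 && out$pct_maternal <= 16,
      out$p_maternal < 0.05)
  }, logical(2))
  expect_gt(mean(hits[1, ]), 0.6)
  ncp <- 48 * 0.08 / 0.92
  theory <- pf(qf(0.95, 1, 44), 1, 44, ncp = ncp, lower.tail = FALSE)
  expect_lt(abs(mean(hits[2, ]) - theory), 4 * sqrt(theory * (1 - theory) / 200))
})

test_that("Bonferroni post-tests control the familywise error", {
  # single requested comparison: the multiplier is 1
  set.seed(11)
  df <- data.frame(value = rnorm(24), group = rep(letters[1:4], each = 6))
  one <- one_way_bonferroni(df, comparisons = list(c("a", "b")))
  expect_equal(one$posthoc$adjusted_p, one$posthoc$raw_p)
  expect_error(one_way_bonferroni(df, comparisons = list(c("a", "z"))),
               "unknown group")
  # four identical groups: familywise rate over all six comparisons
  set.seed(13)
  fw <- vapply(1:1000, function(i) {
    df <- data.frame(value = rnorm(24), group = rep(letters[1:4], each = 6))
    min(one_way_bonferroni(df)$posthoc$adjusted_p) <= 0.05
  }, logical(1))
  expect_lte(mean(fw), 0.055)
})

test_that("a shifted group is flagged by the post-tests", {
  set.seed(17)
  flagged <- vapply(1:100, function(i) {
    df <- data.frame(value = c(rnorm(72, 0, 0.3), rnorm(24, 1, 0.3)),
                     group = rep(letters[1:4], each = 24))
    ph <- one_way_bonferroni(df)$posthoc
    dcmp <- ph[ph$group1 == "d" | ph$group2 == "d", ]
    all(dcmp$adjusted_p < 0.01)
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
})
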