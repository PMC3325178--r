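test_that("bh_adjust applies the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(c(0.005, 0.02, 0.03, 0.5)),
               c(0.02, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.5)), "index 2")
  expect_error(bh_adjust(c(NA, 0.1)), "index 1")
})

test_that("bh_adjust matches the brute-force threshold minimiser", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    p <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-14)
  }
})

test_that("de_test agrees with t.test gene by gene", {
  set.seed(7)
  n1 <- 5; n2 <- 7
  vals <- matrix(rnorm(30 * (n1 + n2), 8, 1), 30,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("s%02d", 1:(n1 + n2))))
  samples <- data.frame(sample_id = colnames(vals),
                        group = rep(c("C", "UN"), c(n1, n2)))
  x <- expression_set(vals, samples)
  for (welch in c(FALSE, TRUE)) {
    de <- de_test(x, "C", "UN", welch = welch)
    for (g in sample(rownames(vals), 8)) {
      tt <- t.test(vals[g, samples$group == "UN"],
                   vals[g, samples$group == "C"],
                   var.equal = !welch)
      i <- match(g, de$gene_id)
      expect_equal(de$statistic[i], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(de$p[i], tt$p.value, tolerance = 1e-12)
      expect_equal(de$log2fc[i], unname(diff(rev(tt$estimate))),
                   tolerance = 1e-12)
      expect_equal(log2(c(de$ci_low[i], de$ci_high[i])),
                   as.numeric(tt$conf.int), tolerance = 1e-10)
    }
  }
})

test_that("degenerate genes follow the stated conventions", {
  vals <- rbind(flat = rep(5, 6), shifted = rep(c(1, 2), each = 3),
                normal = c(1.2, 0.9, 1.1, 3.2, 2.8, 3.1))
  colnames(vals) <- paste0("s", 1:6)
  x <- expression_set(vals, data.frame(sample_id = colnames(vals),
                                       group = rep(c("C", "UN"), each = 3)))
  de <- de_test(x, "C", "UN")
  flat <- de[de$gene_id == "flat", ]
  expect_equal(flat$log2fc, 0)
  expect_equal(flat$p, 1)
  expect_equal(flat$flag, "zero_var")
  shifted <- de[de$gene_id == "shifted", ]
  expect_equal(shifted$p, .Machine$double.xmin)
  expect_equal(shifted$flag, "zero_var_shift")
  expect_equal(shifted$rank, 1L)
})

test_that("stratified testing restricts to the matching samples", {
  set.seed(21)
  st <- generate_expression(synthetic_design(n_genes = 50,
                                             class_sizes = c(neutral = 5),
                                             n_per_group = 8, seed = 5))
  de_f <- de_test(st$expr, "C", "UN", stratify = list(sex = "F"))
  keep <- st$expr$samples$sex == "F"
  sub <- expression_set(st$expr$values[, keep], st$expr$samples[keep, ])
  expect_equal(de_f$p, de_test(sub, "C", "UN")$p)
  expect_error(de_test(st$expr, "C", "UN", stratify = list(tissue = "liver")),
               "tissue")
  tiny <- st$expr$samples$sample_id[c(1, 2, 9, 10)]
  too_few <- expression_set(st$expr$values[, tiny, drop = FALSE],
                            st$expr$samples[match(tiny, st$expr$samples$sample_id), ])
  expect_error(de_test(too_few, "C", "UN", stratify = list(sex = "F")),
               ">= 2 samples")
})

test_that("planted effects are estimated accurately and called", {
  d <- synthetic_design(n_genes = 1000, class_sizes = c(responsive = 50),
                        effect_model = list(
                          responsive = list(mean = 1, sd = 0,
                                            sign = "positive")),
                        noise_meanlog = log(0.2), noise_sdlog = 0,
                        litter_sd = 0, n_per_group = 10, seed = 31)
  st <- generate_expression(d)
  de <- de_test(st$expr, "C", "UN")
  resp <- de$gene_id %in% st$truth$gene_id[st$truth$class == "responsive"]
  expect_lt(abs(mean(de$log2fc[resp]) - 1), 0.05)
  expect_gte(mean(abs(de$log2fc[resp] - 1) < 0.2), 0.9)
  expect_true(all(de$p[resp] < 1e-4))
})

test_that("null p-values are calibrated at the 5% level", {
  st <- generate_expression(null_design(17))
  de <- de_test(st$expr, "C", "UN")
  frac <- mean(de$p <= 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("parametric p agrees with the exact permutation test in distribution", {
  # n = 4/group: all 70 label splits enumerated; pointwise agreement is
  # limited by the 1/35 two-sided granularity, so the check is
  # distributional
  set.seed(42)
  idx <- utils::combn(8, 4)
  res <- replicate(200, {
    y <- rnorm(8)
    tt <- function(k) {
      a <- y[k]; b <- y[-k]
      (mean(a) - mean(b)) / sqrt(((3 * var(a) + 3 * var(b)) / 6) / 2)
    }
    tobs <- abs(tt(1:4))
    c(2 * pt(-tobs, 6), mean(abs(apply(idx, 2, tt)) >= tobs - 1e-12))
  })
  expect_lt(mean(abs(res[1, ] - res[2, ])), 0.06)
  expect_gt(cor(res[1, ], res[2, ], method = "spearman"), 0.95)
})

test_that("significant calls recover planted genes with controlled FDR", {
  for (seed in 1:5) {
    st <- generate_expression(responsive_design(seed, n_genes = 10000))
    de <- de_test(st$expr, "C", "UN")
    calls <- call_significant(de, 0.05)
    called <- c(calls$up, calls$down)
    resp <- st$truth$gene_id[st$truth$class == "responsive"]
    expect_gte(length(intersect(called, resp)), 180)
    expect_lte(mean(!called %in% resp), 0.10)
  }
})

test_that("call_significant edge conventions hold", {
  tab <- make_de_table(q = c(0.2, 0.3, 0.4), lfc = c(1, -1, 0))
  none <- call_significant(tab, 0.05)
  expect_length(none$up, 0)
  expect_length(none$down, 0)
  all_called <- call_significant(tab, 1)
  expect_length(c(all_called$up, all_called$down), 3)
  expect_equal(all_called$zero_lfc, "g003")
  expect_true("g003" %in% all_called$up)
})

test_that("rank_by_q is a deterministic permutation with stated tie rules", {
  tab <- make_de_table(q = c(0.5, 0.1, 0.1, 0.1, 0.1),
                       p = c(0.5, 0.01, 0.01, 0.005, 0.01),
                       lfc = c(0, 1, 2, 3, 1))
  # order: g004 (lowest p), then among p=0.01: g003 (|lfc| 2) before
  # g002/g005 (|lfc| 1, gene id breaks the tie), then g001
  expect_equal(tab$rank, c(5L, 3L, 2L, 1L, 4L))
  expect_setequal(tab$rank, 1:5)
  same <- make_de_table(q = rep(0.2, 4), p = rep(0.2, 4), lfc = rep(1, 4))
  expect_equal(same$rank, 1:4)
})

test_that("power function matches its null limit and a Monte-Carlo oracle", {
  for (a in c(0.01, 0.05, 0.1))
    expect_equal(power_fold_change(1, a, 10, 0.3)$power, a,
                 tolerance = 1e-6)
  # monotone in n and in fold change
  pw_n <- vapply(2:50, function(n)
    power_fold_change(1.5, 0.05, n, 0.3)$power, numeric(1))
  expect_true(all(diff(pw_n) >= -1e-12))
  pw_fc <- vapply(seq(1, 3, by = 0.1), function(fc)
    power_fold_change(fc, 0.05, 5, 0.3)$power, numeric(1))
  expect_true(all(diff(pw_fc) >= -1e-12))
  # light Monte-Carlo cross-check (the acceptance suite runs 1e5 reps)
  set.seed(8)
  n <- 3; delta <- log2(1.5); sd <- 0.3; reps <- 20000
  a <- matrix(rnorm(reps * n, 0, sd), reps)
  b <- matrix(rnorm(reps * n, delta, sd), reps)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  tstat <- (rowMeans(b) - rowMeans(a)) /
    sqrt(((n - 1) * (va + vb) / (2 * n - 2)) * 2 / n)
  mc <- mean(2 * pt(-abs(tstat), 2 * n - 2) < 0.05)
  expect_equal(power_fold_change(1.5, 0.05, 3, 0.3)$power, mc,
               tolerance = 0.02)
  expect_error(power_fold_change(-1, 0.05, 3, 0.3), "fold_change")
})
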