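test_that("identical (design, seed) pairs reproduce identical output", {
  d <- synthetic_design(n_genes = 500, class_sizes = c(neutral = 30),
                        n_per_group = 4, seed = 11)
  a <- generate_expression(d)
  b <- generate_expression(d)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$expr$samples, b$expr$samples)
  expect_identical(a$truth, b$truth)
  d2 <- synthetic_design(n_genes = 500, class_sizes = c(neutral = 30),
                         n_per_group = 4, seed = 12)
  expect_false(identical(generate_expression(d2)$expr$values, a$expr$values))
})

test_that("truth ledger partitions genes exactly as class_sizes dictate", {
  d <- synthetic_design(n_genes = 1000,
                        class_sizes = c(responsive = 30, housekeeping = 50,
                                        neutral = 20),
                        n_per_group = 3, seed = 2)
  st <- generate_expression(d)
  expect_identical(st$truth$gene_id, rownames(st$expr$values))
  expect_equal(as.list(table(st$truth$class)),
               list(background = 900L, housekeeping = 50L, neutral = 20L,
                    responsive = 30L))
  # only responsive genes carry a planted effect, balanced in sign
  expect_true(all(st$truth$delta[st$truth$class != "responsive"] == 0))
  resp <- st$truth$delta[st$truth$class == "responsive"]
  expect_true(all(abs(resp) == log2(1.5)))
  expect_equal(sum(resp > 0), 15)
})

test_that("invalid designs are rejected with the offending field named", {
  expect_error(synthetic_design(litter_sd = -1), "litter_sd")
  expect_error(synthetic_design(n_per_group = 1), "n_per_group")
  expect_error(synthetic_design(noise_sdlog = -0.1), "noise_sdlog")
  expect_error(synthetic_design(n_genes = 50,
                                class_sizes = c(responsive = 60)),
               "class_sizes")
  expect_error(synthetic_design(class_sizes = c(background = 5)),
               "background")
})

test_that("planted log2 fold changes are recovered without bias", {
  # constant-sign effect, no litter/sex structure: the mean observed lfc
  # over the responsive class must sit on the planted value
  for (seed in c(1, 2, 3)) {
    d <- synthetic_design(n_genes = 2000,
                          class_sizes = c(responsive = 200),
                          effect_model = list(
                            responsive = list(mean = log2(1.5), sd = 0,
                                              sign = "positive")),
                          noise_meanlog = log(0.2), noise_sdlog = 0,
                          litter_sd = 0, n_per_group = 20, seed = seed)
    st <- generate_expression(d)
    de <- de_test(st$expr, "C", "UN")
    resp <- st$truth$class == "responsive"
    expect_lt(abs(mean(de$log2fc[resp]) - log2(1.5)), 0.05)
  }
})

test_that("a pure-noise design yields calibrated t-test p-values", {
  # KS vs uniform non-significant at alpha = 0.01 in nearly all replicate
  # designs (each gene independent under the null, constant sd, no litter)
  reject <- vapply(1:50, function(seed) {
    st <- generate_expression(null_design(seed, n_genes = 800,
                                          n_per_group = 5))
    de <- de_test(st$expr, "C", "UN")
    stats::ks.test(de$p, "punif")$p.value < 0.01
  }, logical(1))
  expect_lte(sum(reject), 3)
})

test_that("litter structure is shared within litters", {
  d <- synthetic_design(n_genes = 100, class_sizes = c(neutral = 10),
                        n_per_group = 6,
                        litters_per_group = 2, litter_sd = 5,
                        noise_meanlog = log(0.01), noise_sdlog = 0,
                        seed = 3)
  st <- generate_expression(d)
  # with huge litter sd and tiny noise, samples cluster by litter
  centred <- sweep(st$expr$values, 1, rowMeans(st$expr$values))
  litter_mean <- tapply(colMeans(centred), st$expr$samples$litter, mean)
  within <- vapply(split(colMeans(centred), st$expr$samples$litter),
                   stats::sd, numeric(1))
  expect_true(stats::sd(litter_mean) > 10 * max(within))
})

test_that("factorial generator recovers planted variance fractions", {
  # nothing planted: percent contributions stay small
  pct0 <- vapply(1:200, function(seed) {
    cand <- generate_factorial_candidates(
      c(maternal = 0, paternal = 0, interaction = 0),
      n_per_cell = 6, genes = "g", seed = seed)
    out <- two_way_anova(cand)
    c(out$pct_maternal, out$pct_paternal, out$pct_interaction)
  }, numeric(3))
  expect_true(all(apply(pct0, 1, stats::median) < 5))

  # planted maternal fraction 0.4 at n = 50/cell: recovered within band
  hit <- vapply(1:50, function(seed) {
    cand <- generate_factorial_candidates(
      c(maternal = 0.4, paternal = 0, interaction = 0),
      n_per_cell = 50, genes = "g", seed = seed)
    out <- two_way_anova(cand)
    out$pct_maternal >= 30 && out$pct_maternal <= 50
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("degenerate factorial requests are rejected", {
  expect_error(generate_factorial_candidates(
    c(maternal = 0.5, paternal = 0.5, interaction = 0.2)), "< 1")
  expect_error(generate_factorial_candidates(
    c(maternal = 0, paternal = 0, interaction = 0.1), n_per_cell = 1),
    "inseparable")
  expect_error(generate_factorial_candidates(c(maternal = 0.1)),
               "planted_fractions")
})

test_that("gene sets mirror the planted classes plus random draws", {
  st <- generate_expression(synthetic_design(n_genes = 500,
                                             class_sizes = c(neutral = 90),
                                             n_per_group = 3, seed = 4))
  gs <- generate_gene_sets(st$truth, random_set_size = 40, n_random = 3,
                           seed = 9)
  expect_length(gs$sets$neutral, 90)
  expect_setequal(names(gs$sets),
                  c("background", "neutral", "random_01", "random_02",
                    "random_03"))
  expect_length(gs$sets$random_01, 40)
  gs2 <- generate_gene_sets(st$truth, random_set_size = 40, n_random = 3,
                            seed = 9)
  expect_identical(gs$sets, gs2$sets)
  expect_error(generate_gene_sets(st$truth, random_set_size = 1000),
               "universe")
  expect_error(generate_gene_sets(st$truth[0, ]), "empty")
})
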