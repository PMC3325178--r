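#' Describe a synthetic expression study
#'
#' Captures the design of a simulated two-condition (or 2x2 factorial)
#' expression study with planted gene classes: a responsive class with
#' nonzero log2 fold changes, a housekeeping-like class with reduced
#' residual variance (the "protected" control), a neutral class that behaves
#' like randomly chosen genes (the imprinted-like focal class under the null
#' of no class effect), and background genes. Samples carry litter and sex
#' structure.
#'
#' Defaults emulate a gestational-undernutrition transcriptome study:
#' two conditions `C` (control) and `UN` (undernourished), responsive genes
#' shifted by +/- log2(1.5), per-gene residual standard deviations drawn
#' log-normally around 0.2 on the log2 scale, housekeeping genes at half
#' that noise, an additive litter intercept of sd 0.1 shared by littermates,
#' and class sizes of 200 responsive, 500 housekeeping and 90 neutral genes
#' in a 10,000-gene transcriptome.
#'
#' @param n_genes Number of genes in the transcriptome.
#' @param class_sizes Named integer vector of planted class sizes; the
#'   remainder of the transcriptome is `background`. Total must not exceed
#'   `n_genes`.
#' @param effect_model Named list, one entry per class that receives a
#'   planted log2 fold change. Each entry is a list with `mean` and `sd`
#'   (distribution of the effect magnitude, log2 units) and `sign`, one of
#'   `"balanced"` (first half up, second half down), `"positive"`,
#'   `"negative"`, `"random"`. Classes without an entry get delta = 0.
#' @param noise_meanlog,noise_sdlog Parameters of the log-normal from which
#'   per-gene residual sds (log2 units) are drawn. `noise_sdlog = 0` gives
#'   every gene the sd `exp(noise_meanlog)`.
#' @param housekeeping_sd_factor Multiplier (< 1 for protection) applied to
#'   the residual sd of the `housekeeping` class.
#' @param n_per_group Samples per condition (>= 2).
#' @param groups Ordered condition labels; the first is the reference. Two
#'   labels give the two-group design, four give the 2x2 factorial crosses.
#' @param group_scores Optional numeric vector, one per group: the multiple
#'   of the planted delta added to samples of that group. Defaults to
#'   `c(0, 1)` for two groups and `c(0, 0.5, 0.5, 1)` for four.
#' @param litter_sd Standard deviation of the additive litter random
#'   intercept (log2 units).
#' @param litters_per_group Number of litters per condition; samples are
#'   assigned round-robin.
#' @param sex_effect Additive log2 shift applied to male samples.
#' @param seed Integer RNG seed; identical designs (including seed)
#'   reproduce byte-identical output.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes = 10000,
                             class_sizes = c(responsive = 200,
                                             housekeeping = 500,
                                             neutral = 90),
                             effect_model = list(
                               responsive = list(mean = log2(1.5), sd = 0,
                                                 sign = "balanced")),
                             noise_meanlog = log(0.2),
                             noise_sdlog = 0.25,
                             housekeeping_sd_factor = 0.5,
                             n_per_group = 10,
                             groups = c("C", "UN"),
                             group_scores = NULL,
                             litter_sd = 0.1,
                             litters_per_group = 3,
                             sex_effect = 0,
                             seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  if (is.null(names(class_sizes)) || any(!nzchar(names(class_sizes))))
    stopf("'class_sizes' must be a named vector")
  class_sizes <- vapply(stats::setNames(seq_along(class_sizes),
                                        names(class_sizes)),
                        function(i) check_count(class_sizes[[i]],
                                                paste0("class_sizes$",
                                                       names(class_sizes)[i]),
                                                min = 0L),
                        integer(1))
  if (sum(class_sizes) > n_genes)
    stopf("'class_sizes' sum to %d, exceeding n_genes = %d",
          sum(class_sizes), n_genes)
  if ("background" %in% names(class_sizes))
    stopf("'background' is reserved for the unassigned remainder")
  for (cls in names(effect_model)) {
    em <- effect_model[[cls]]
    effect_model[[cls]]$mean <- check_number(em$mean %||% 0, paste0("effect_model$", cls, "$mean"))
    effect_model[[cls]]$sd <- check_number(em$sd %||% 0, paste0("effect_model$", cls, "$sd"), min = 0)
    sign <- em$sign %||% "balanced"
    if (!sign %in% c("balanced", "positive", "negative", "random"))
      stopf("effect_model$%s$sign must be balanced/positive/negative/random", cls)
    effect_model[[cls]]$sign <- sign
  }
  noise_meanlog <- check_number(noise_meanlog, "noise_meanlog")
  noise_sdlog <- check_number(noise_sdlog, "noise_sdlog", min = 0)
  housekeeping_sd_factor <- check_number(housekeeping_sd_factor,
                                         "housekeeping_sd_factor", min = 0)
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  if (length(groups) < 2L || anyDuplicated(groups))
    stopf("'groups' must be >= 2 distinct condition labels")
  if (is.null(group_scores)) {
    group_scores <- if (length(groups) == 2L) c(0, 1)
    else if (length(groups) == 4L) c(0, 0.5, 0.5, 1)
    else seq(0, 1, length.out = length(groups))
  }
  if (length(group_scores) != length(groups) || !is.numeric(group_scores))
    stopf("'group_scores' must be numeric, one per group")
  litter_sd <- check_number(litter_sd, "litter_sd", min = 0)
  litters_per_group <- check_count(litters_per_group, "litters_per_group",
                                   min = 1L)
  sex_effect <- check_number(sex_effect, "sex_effect")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_genes = n_genes, class_sizes = class_sizes,
                 effect_model = effect_model,
                 noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog,
                 housekeeping_sd_factor = housekeeping_sd_factor,
                 n_per_group = n_per_group, groups = as.character(groups),
                 group_scores = as.numeric(group_scores),
                 litter_sd = litter_sd,
                 litters_per_group = litters_per_group,
                 sex_effect = sex_effect, seed = seed),
            class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf("synthetic_design: %d genes, %d x %d samples (%s), seed %d\n",
              x$n_genes, length(x$groups), x$n_per_group,
              paste(x$groups, collapse = "/"), x$seed))
  cat("classes:", paste(sprintf("%s=%d", names(x$class_sizes),
                                x$class_sizes), collapse = ", "),
      sprintf("background=%d\n", x$n_genes - sum(x$class_sizes)))
  invisible(x)
}

# draw per-gene planted deltas for one class
class_deltas <- function(em, k) {
  if (k == 0L) return(numeric(0))
  mag <- stats::rnorm(k, em$mean, em$sd)
  sgn <- switch(em$sign,
                positive = rep(1, k),
                negative = rep(-1, k),
                balanced = rep(c(1, -1), length.out = k),
                random = sample(c(-1, 1), k, replace = TRUE))
  mag * sgn
}

#' Simulate an expression study with planted ground truth
#'
#' Draws a genes x samples log2 expression matrix under the design. Each
#' gene has baseline ~ U(6, 12); samples of group g add
#' `group_scores[g] * delta` for that gene, an additive litter intercept
#' shared by littermates, a sex shift for males, and Gaussian residual noise
#' with the gene's own sd. All randomness flows from `design$seed`.
#'
#' @param design A [synthetic_design()].
#' @return A list of class `synthetic_study` with elements `expr` (an
#'   [expression_set()]) and `truth` (data frame `gene_id`, `class`,
#'   `delta` — one record per gene).
#' @export
generate_expression <- function(design) {
  if (!inherits(design, "synthetic_design"))
    stopf("'design' must be a synthetic_design")
  set.seed(design$seed)
  n <- design$n_genes
  gene_id <- sprintf("g%06d", seq_len(n))
  cls <- rep("background", n)
  at <- 1L
  for (i in seq_along(design$class_sizes)) {
    k <- design$class_sizes[[i]]
    if (k > 0L) cls[at:(at + k - 1L)] <- names(design$class_sizes)[i]
    at <- at + k
  }
  delta <- numeric(n)
  for (cname in names(design$effect_model)) {
    idx <- which(cls == cname)
    delta[idx] <- class_deltas(design$effect_model[[cname]], length(idx))
  }

  n_grp <- length(design$groups)
  npg <- design$n_per_group
  n_samp <- n_grp * npg
  group <- rep(design$groups, each = npg)
  score <- rep(design$group_scores, each = npg)
  sample_id <- paste0(group, "_", rep(seq_len(npg), times = n_grp))
  litter <- paste0(group, "_L",
                   rep(rep_len(seq_len(design$litters_per_group), npg),
                       times = n_grp))
  sex <- rep(rep_len(c("F", "M"), npg), times = n_grp)
  cross <- group

  baseline <- stats::runif(n, 6, 12)
  sd_gene <- stats::rlnorm(n, design$noise_meanlog, design$noise_sdlog)
  sd_gene[cls == "housekeeping"] <-
    sd_gene[cls == "housekeeping"] * design$housekeeping_sd_factor
  litter_levels <- unique(litter)
  litter_eff <- stats::setNames(stats::rnorm(length(litter_levels), 0,
                                             design$litter_sd),
                                litter_levels)
  sample_shift <- litter_eff[litter] + design$sex_effect * (sex == "M")

  values <- baseline + outer(delta, score) +
    matrix(stats::rnorm(n * n_samp), n, n_samp) * sd_gene
  values <- sweep(values, 2L, sample_shift, "+")
  dimnames(values) <- list(gene_id, sample_id)

  samples <- data.frame(sample_id = sample_id, group = group, sex = sex,
                        litter = litter, cross = cross,
                        stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id, class = cls, delta = delta,
                      stringsAsFactors = FALSE)
  structure(list(expr = expression_set(values, samples), truth = truth,
                 design = design),
            class = "synthetic_study")
}

#' Simulate factorial candidate-gene measurements
#'
#' Emulates a qPCR panel in a balanced 2x2 cross design (maternal x paternal
#' exposure, groups CC/CU/UC/UU with the first letter the dam). Each gene's
#' expression is `mu + bm*xm + bp*xp + bi*xm*xp + noise` with effect codes
#' xm, xp in {-1, +1}, coefficients chosen so that each factor contributes
#' the requested fraction of total variance and residual noise the
#' remainder (total variance normalised to 1).
#'
#' @param planted_fractions Named numeric vector with entries `maternal`,
#'   `paternal`, `interaction`, each in [0, 1), summing to < 1: the fraction
#'   of total expression variance attributable to each term.
#' @param n_per_cell Replicates per cell of the 2x2 layout (>= 2 when the
#'   interaction fraction is positive, since one replicate per cell leaves
#'   the interaction inseparable from error).
#' @param genes Character vector of candidate gene names.
#' @param baseline Grand mean expression.
#' @param seed Integer RNG seed.
#' @return Long-format data frame: `gene`, `sample`, `value`, `maternal`,
#'   `paternal`, `group`.
#' @export
generate_factorial_candidates <- function(planted_fractions =
                                            c(maternal = 0, paternal = 0,
                                              interaction = 0),
                                          n_per_cell = 6,
                                          genes = paste0("cand", 1:12),
                                          baseline = 10,
                                          seed = 1) {
  need <- c("maternal", "paternal", "interaction")
  if (!all(need %in% names(planted_fractions)))
    stopf("'planted_fractions' must name maternal, paternal, interaction")
  pf <- vapply(need, function(k) check_number(planted_fractions[[k]],
                                              paste0("planted_fractions$", k),
                                              min = 0, max = 1 - 1e-12),
               numeric(1))
  if (sum(pf) >= 1)
    stopf("'planted_fractions' sum to %.3f; must be < 1", sum(pf))
  n_per_cell <- check_count(n_per_cell, "n_per_cell", min = 1L)
  if (n_per_cell < 2L && pf[["interaction"]] > 0)
    stopf("n_per_cell = 1 with a planted interaction: interaction is inseparable from error")
  seed <- check_count(seed, "seed", min = 0L)
  if (!length(genes) || anyDuplicated(genes))
    stopf("'genes' must be distinct and nonempty")

  set.seed(seed)
  bm <- sqrt(pf[["maternal"]])
  bp <- sqrt(pf[["paternal"]])
  bi <- sqrt(pf[["interaction"]])
  sd_res <- sqrt(1 - sum(pf))
  xm <- rep(c(-1, -1, 1, 1), each = n_per_cell)  # C,C,U,U maternal
  xp <- rep(c(-1, 1, -1, 1), each = n_per_cell)  # C,U,C,U paternal
  maternal <- ifelse(xm < 0, "C", "U")
  paternal <- ifelse(xp < 0, "C", "U")
  group <- paste0(maternal, paternal)
  n_obs <- length(xm)
  out <- lapply(genes, function(g) {
    value <- baseline + bm * xm + bp * xp + bi * xm * xp +
      stats::rnorm(n_obs, 0, sd_res)
    data.frame(gene = g,
               sample = paste0(g, "_", group, "_",
                               rep(seq_len(n_per_cell), times = 4)),
               value = value, maternal = maternal, paternal = paternal,
               group = group, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build gene sets from the planted truth
#'
#' Emits one gene set per planted class (including `background`) plus
#' size-matched random sets drawn without replacement from the full gene
#' universe, mirroring the negative/positive/random control sets used to
#' contextualise a focal gene class.
#'
#' @param truth Truth ledger from [generate_expression()] (`gene_id`,
#'   `class`, `delta`).
#' @param random_set_size Size of each random set; defaults to the size of
#'   the smallest planted class.
#' @param n_random Number of random sets (`random_01`, ...).
#' @param seed Integer RNG seed for the random draws.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   identifier vectors) and `universe`.
#' @export
generate_gene_sets <- function(truth, random_set_size = NULL, n_random = 1,
                               seed = 1) {
  if (is.null(truth) || !nrow(truth)) stopf("'truth' is empty")
  universe <- truth$gene_id
  classes <- split(truth$gene_id, truth$class)
  if (is.null(random_set_size))
    random_set_size <- min(lengths(classes))
  random_set_size <- check_count(random_set_size, "random_set_size", min = 1L)
  if (random_set_size > length(universe))
    stopf("random_set_size = %d exceeds the %d-gene universe",
          random_set_size, length(universe))
  n_random <- check_count(n_random, "n_random", min = 0L)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  rand <- lapply(seq_len(n_random), function(i)
    sample(universe, random_set_size))
  names(rand) <- sprintf("random_%02d", seq_len(n_random))
  gene_set_collection(c(classes, rand), universe)
}
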