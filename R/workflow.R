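#' Configuration for a full susceptibility study
#'
#' Bundles every threshold, seed and input needed to run the pipeline
#' simulate/load -> filter -> differential expression -> rank profiles ->
#' ROC permutation -> GSEA -> factorial ANOVA. Per-stage seeds are derived
#' deterministically from the single `seed` unless the corresponding
#' component fixes its own.
#'
#' Either `design` (a [synthetic_design()]; gene sets are then built from
#' the planted truth) or `paths` (named list with `matrix`, `meta`, `gmt`
#' files) must be supplied.
#'
#' @param design Optional [synthetic_design()].
#' @param paths Optional list of input file paths (`matrix`, `meta`,
#'   `gmt`).
#' @param reference,contrast Group labels for the DE contrast; default the
#'   first two groups of the design.
#' @param q_cut FDR threshold for calling significant genes.
#' @param floor Expression floor passed to [filter_unexpressed()].
#' @param n_perm_roc,n_perm_gsea Permutation counts per stage.
#' @param n_envelope Random draws for the rank-profile envelope.
#' @param gsea_exponent Weighting exponent for the enrichment walk.
#' @param stratify Optional named list forwarded to [de_test()].
#' @param welch Use the Welch t-test.
#' @param factorial Optional list with `planted_fractions`, `n_per_cell`,
#'   `genes` for the candidate-gene factorial stage; `NULL` skips it.
#' @param seed Master integer seed.
#' @param out_dir Optional output directory for per-stage files.
#' @return A list of class `study_config`.
#' @export
study_config <- function(design = NULL, paths = NULL, reference = NULL,
                         contrast = NULL, q_cut = 0.05, floor = 0,
                         n_perm_roc = 100, n_perm_gsea = 1000,
                         n_envelope = 200, gsea_exponent = 0,
                         stratify = NULL, welch = FALSE, factorial = NULL,
                         seed = 1, out_dir = NULL) {
  if (is.null(design) && is.null(paths))
    stopf("supply either a synthetic 'design' or input 'paths'")
  if (!is.null(design) && !inherits(design, "synthetic_design"))
    stopf("'design' must be a synthetic_design")
  if (!is.null(paths) && !all(c("matrix", "meta", "gmt") %in% names(paths)))
    stopf("'paths' must name matrix, meta and gmt files")
  q_cut <- check_number(q_cut, "q_cut", min = 1e-300, max = 1 - 1e-12)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(design = design, paths = paths, reference = reference,
                 contrast = contrast, q_cut = q_cut, floor = floor,
                 n_perm_roc = check_count(n_perm_roc, "n_perm_roc", 1L),
                 n_perm_gsea = check_count(n_perm_gsea, "n_perm_gsea", 10L),
                 n_envelope = check_count(n_envelope, "n_envelope", 20L),
                 gsea_exponent = check_number(gsea_exponent,
                                              "gsea_exponent", min = 0),
                 stratify = stratify, welch = isTRUE(welch),
                 factorial = factorial, seed = seed, out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors the arguments of [study_config()]; a `design` block is
#' passed to [synthetic_design()].
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$design)) {
    dsn <- raw$design
    if (!is.null(dsn$class_sizes)) dsn$class_sizes <- unlist(dsn$class_sizes)
    raw$design <- do.call(synthetic_design, dsn)
  }
  do.call(study_config, raw)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full susceptibility study
#'
#' Executes every stage on one dataset and assembles a machine-readable
#' report: significant-gene counts, a rank-profile verdict, ROC
#' permutation result and enrichment statistics per gene set, the
#' factorial candidate-gene variance partition, and a provenance block
#' (config hash, seeds, package version). Identical configurations yield
#' byte-identical reports. All stages share one post-filter gene universe,
#' asserted at assembly.
#'
#' @param config A [study_config()].
#' @return The report as a nested list (class `study_report`); when
#'   `config$out_dir` is set, per-stage TSV/JSON files and `report.json`
#'   are written there as a side effect.
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config")) stopf("'config' must be a study_config")
  seed <- config$seed

  # --- data -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$design)) {
    study <- run_stage("simulate", generate_expression(config$design))
    expr <- study$expr
    truth <- study$truth
    sets <- run_stage("gene_sets",
                      generate_gene_sets(truth, n_random = 1,
                                         seed = derive_seed(seed, 1L)))
    stage_log("simulate", "%d genes x %d samples, %d gene sets",
              nrow(expr$values), ncol(expr$values), length(sets$sets))
  } else {
    for (p in unlist(config$paths))
      if (!file.exists(p)) stopf("stage 'load' failed: input file not found: %s", p)
    expr <- run_stage("load", read_expression_tsv(config$paths$matrix,
                                                  config$paths$meta))
    raw_sets <- run_stage("load", read_gmt(config$paths$gmt))
    sets <- NULL  # intersected with the universe after filtering
    stage_log("load", "%d genes x %d samples", nrow(expr$values),
              ncol(expr$values))
  }

  # --- filter ---------------------------------------------------------
  expr <- run_stage("filter", filter_unexpressed(expr, config$floor))
  stage_log("filter", "%d genes retained above floor %s",
            nrow(expr$values), format(config$floor))
  universe <- rownames(expr$values)
  if (is.null(config$design))
    sets <- run_stage("gene_sets", gene_set_collection(raw_sets, universe))
  else
    sets <- run_stage("gene_sets",
                      gene_set_collection(sets$sets, universe))

  # --- differential expression ---------------------------------------
  groups <- unique(expr$samples$group)
  reference <- config$reference %||% groups[1]
  contrast <- config$contrast %||% groups[2]
  de <- run_stage("de", de_test(expr, reference, contrast,
                                stratify = config$stratify,
                                welch = config$welch))
  calls <- call_significant(de, config$q_cut)
  stage_log("de", "%d up, %d down at q < %s (%s vs %s)",
            length(calls$up), length(calls$down), format(config$q_cut),
            contrast, reference)

  # --- per-set stages -------------------------------------------------
  env_cache <- list()
  set_results <- list()
  stats_vec <- stats::setNames(de$statistic, de$gene_id)
  gsea_tab <- run_stage("gsea", gsea(stats_vec, sets,
                                     n_perm = config$n_perm_gsea,
                                     exponent = config$gsea_exponent,
                                     seed = derive_seed(seed, 4L),
                                     pos_label = contrast,
                                     neg_label = reference))
  stage_log("gsea", "%d sets scored at %d permutations",
            nrow(gsea_tab), config$n_perm_gsea)

  for (nm in names(sets$sets)) {
    members <- sets$sets[[nm]]
    profile <- run_stage("rankprofile",
                         rank_distribution(de, members, set_name = nm))
    key <- as.character(profile$n_set)
    if (is.null(env_cache[[key]]))
      env_cache[[key]] <- run_stage("rankprofile",
                                    random_set_envelope(de, profile$n_set,
                                                        n_draws = config$n_envelope,
                                                        seed = derive_seed(seed, 2L)))
    verdict <- rank_profile_verdict(profile, env_cache[[key]])
    rocres <- run_stage("rocperm",
                        roc_permutation_test(de, members,
                                             n_perm = config$n_perm_roc,
                                             seed = derive_seed(seed, 3L),
                                             set_name = nm))
    stage_log("rankprofile", "%s: %s (KS %.3f), AUC %.3f (p_emp %.4f)",
              nm, verdict$verdict, verdict$ks, rocres$auc, rocres$p_emp)
    set_results[[nm]] <- list(profile = profile, verdict = verdict,
                              roc = rocres)
  }

  # --- factorial candidate genes -------------------------------------
  anova_tab <- NULL
  if (!is.null(config$factorial)) {
    fc <- config$factorial
    cand <- run_stage("anova", do.call(generate_factorial_candidates,
      c(fc[intersect(names(fc), c("planted_fractions", "n_per_cell",
                                  "genes", "baseline"))],
        list(seed = derive_seed(seed, 5L)))))
    anova_tab <- run_stage("anova", two_way_anova(cand))
    stage_log("anova", "%d candidate genes partitioned", nrow(anova_tab))
  }

  # --- assemble -------------------------------------------------------
  for (nm in names(set_results))
    stopifnot(set_results[[nm]]$profile$n_universe == length(universe))

  report <- list(
    significant = list(q_cut = config$q_cut, n_up = length(calls$up),
                       n_down = length(calls$down),
                       n_total = length(calls$up) + length(calls$down)),
    sets = lapply(set_results, function(r) list(
      n_members = r$profile$n_set,
      median_rank = stats::median(r$profile$ranks),
      verdict = r$verdict$verdict,
      ks = r$verdict$ks, ks_p = r$verdict$ks_p,
      auc = r$roc$auc, exceed_count = r$roc$exceed_count,
      p_emp = r$roc$p_emp, n_perm = r$roc$n_perm)),
    gsea = lapply(seq_len(nrow(gsea_tab)), function(i)
      as.list(gsea_tab[i, c("set", "size", "es", "nes", "p_perm",
                            "fdr_q", "direction")])),
    anova = if (!is.null(anova_tab))
      lapply(seq_len(nrow(anova_tab)), function(i)
        as.list(anova_tab[i, c("gene_id", "pct_maternal", "pct_paternal",
                               "pct_interaction", "p_maternal",
                               "p_paternal", "p_interaction")])),
    provenance = list(
      package_version = as.character(utils::packageVersion("classrank")),
      seed = seed,
      stage_seeds = list(gene_sets = derive_seed(seed, 1L),
                         envelope = derive_seed(seed, 2L),
                         rocperm = derive_seed(seed, 3L),
                         gsea = derive_seed(seed, 4L),
                         factorial = derive_seed(seed, 5L)),
      n_genes = length(universe),
      n_samples = ncol(expr$values),
      config_hash = config_hash(config)))
  class(report) <- "study_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(config$out_dir, "rankprofile"), showWarnings = FALSE)
    dir.create(file.path(config$out_dir, "rocperm"), showWarnings = FALSE)
    write_de_tsv(de, file.path(config$out_dir, "de.tsv"))
    write_gsea_tsv(gsea_tab, file.path(config$out_dir, "gsea.tsv"))
    if (!is.null(anova_tab)) {
      utils::write.table(anova_tab, file.path(config$out_dir, "anova.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (nm in names(set_results)) {
      r <- set_results[[nm]]
      write_rank_profile_tsv(r$profile,
                             file.path(config$out_dir, "rankprofile",
                                       paste0(nm, ".tsv")),
                             env_cache[[as.character(r$profile$n_set)]])
      jsonlite::write_json(
        list(set_name = nm, auc = r$roc$auc,
             null_aucs = r$roc$null_aucs,
             exceed_count = r$roc$exceed_count, p_emp = r$roc$p_emp,
             n_perm = r$roc$n_perm, seed = r$roc$seed),
        file.path(config$out_dir, "rocperm", paste0(nm, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# stable fingerprint of a configuration: md5 of its canonical JSON
config_hash <- function(config) {
  clean <- unclass(config)
  clean$out_dir <- NULL
  if (!is.null(clean$design)) clean$design <- unclass(clean$design)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(clean, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d genes, %d significant (%d up / %d down) at q < %s\n",
              x$provenance$n_genes, x$significant$n_total,
              x$significant$n_up, x$significant$n_down,
              format(x$significant$q_cut)))
  for (nm in names(x$sets)) {
    s <- x$sets[[nm]]
    cat(sprintf("  %s (n=%d): %s; AUC %.3f > %d/%d permutations (p_emp %.4f)\n",
                nm, s$n_members, s$verdict, s$auc, s$exceed_count,
                s$n_perm, s$p_emp))
  }
  invisible(x)
}
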