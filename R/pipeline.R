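#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end demo pipeline (simulate ->
#' normalize -> CV -> permutation test -> contrasts -> enrichment ->
#' promoter concordance -> report) into one validated list. A configuration
#' can also be loaded from a YAML file whose keys mirror the arguments.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed driving every stochastic stage.
#' @param cohort a [cohort_config()]; defaults to [demo_cohort_config()], a
#'   4-subject, ten-timepoint cohort with a 2000-analyte RNA modality and a
#'   spiked perturbation-and-recovery design.
#' @param modality which generated modality the statistics run on.
#' @param n_perm permutation count for the variability test (default 10000).
#' @param n_bins,min_per_bin quantile-reference parameters (defaults 100, 10).
#' @param alpha,lfc_threshold DEG thresholds (defaults 0.05, 0.5).
#' @param gsea_n_perm null draws per gene-set size (default 2000).
#' @param gmt optional path to a GMT file; when `NULL` a synthetic
#'   collection over the generated analytes is drawn (seeded).
#' @param n_sets,set_size synthetic gene-set collection shape.
#' @param halfwidth promoter window half-width in bp (default 500).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, cohort = NULL,
                       modality = "rna_counts", n_perm = 10000,
                       n_bins = 100, min_per_bin = 10,
                       alpha = 0.05, lfc_threshold = 0.5,
                       gsea_n_perm = 2000, gmt = NULL,
                       n_sets = 25, set_size = 30, halfwidth = 500) {
  if (is.null(cohort)) cohort <- demo_cohort_config(seed = seed)
  stopifnot(n_perm >= 1, n_bins >= 1, min_per_bin >= 1,
            alpha > 0, alpha < 1, lfc_threshold >= 0, halfwidth >= 0)
  if (!is.null(gmt) && !file.exists(gmt)) abort(paste0("GMT file not found: ", gmt))
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 modality = modality, n_perm = n_perm, n_bins = n_bins,
                 min_per_bin = min_per_bin, alpha = alpha,
                 lfc_threshold = lfc_threshold, gsea_n_perm = gsea_n_perm,
                 gmt = gmt, n_sets = n_sets, set_size = set_size,
                 halfwidth = halfwidth),
            class = "run_config")
}

#' @rdname run_config
#' @param n_analytes,n_spiked demo cohort shape: total analytes and how many
#'   receive a post-flight perturbation (half upregulated 8-fold, half
#'   downregulated 8-fold, decaying with a 10-day half-life and a
#'   full-amplitude homeostatic rebound; one in five additionally gets a
#'   3-fold variability spike).
#' @export
demo_cohort_config <- function(seed = 1L, n_analytes = 2000, n_spiked = 200) {
  ids <- sprintf("gene_%04d", seq_len(n_spiked))
  spikes <- tibble(
    analyte_id = ids, modality = "rna_counts", phase = "post_flight",
    mean_effect = rep(c(8, 1 / 8), length.out = n_spiked),
    disp_effect = ifelse(seq_len(n_spiked) %% 5 == 0, 3, 1),
    halflife_days = 10, rebound = 1)
  cohort_config(modalities = c(rna_counts = n_analytes), spikes = spikes,
                seed = seed)
}

#' @rdname run_config
#' @param path YAML file of configuration keys.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$modalities)) {
    cohort_args$modalities <- unlist(cohort_args$modalities)
  }
  cohort_args$seed <- cohort_args$seed %||% (y$seed %||% 1L)
  y$cohort <- do.call(cohort_config, cohort_args)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

# hash of the scientific configuration (output location excluded)
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  rlang::hash(x)
}

provenance <- function(config) {
  c(paste0("astrovar ", as.character(packageVersion("astrovar"))),
    paste0("seed=", config$seed),
    paste0("config_hash=", config_hash(config)))
}

write_stage_tsv <- function(df, path, config) {
  df <- mutate(df, across(where(is.list), ~ map_chr(.x, paste, collapse = ",")))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ", provenance(config)), con)
  fmt <- vapply(df, function(col) {
    if (is.double(col)) format(col, digits = 17, trim = TRUE)
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, ncol = ncol(df))
  writeLines(c(paste(names(df), collapse = "\t"),
               apply(fmt, 1, paste, collapse = "\t")), con)
  invisible(path)
}

#' Run the full demo pipeline
#'
#' Executes every stage in dependency order on a synthetic cohort and
#' writes one TSV per stage (each with a provenance comment header carrying
#' the package version, seed and config hash) plus a machine-readable JSON
#' summary of per-stage record counts. Identical configurations produce
#' bitwise-identical outputs.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly; outputs land in `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed, config_hash = config_hash(config),
                  version = as.character(packageVersion("astrovar")),
                  stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    inform(paste0("[astrovar] stage ", name, " done"))
    res
  }
  pth <- function(f) file.path(config$out_dir, f)

  cohort <- stage("simulate", generate_cohort(config$cohort))
  tab <- cohort$tables[[config$modality]]
  if (is.null(tab)) abort(paste0("modality not generated: ", config$modality))
  write_feature_table(tab, pth("abundance.tsv"), header_lines = provenance(config))
  write_stage_tsv(cohort$samples, pth("samples.tsv"), config)
  summary$stages$simulate <- list(n_analytes = nrow(tab), n_samples = ncol(tab))

  samples <- cohort$samples
  cvrec <- stage("cv", cv_profile(tab, samples, n_bins = config$n_bins,
                                  min_per_bin = config$min_per_bin))
  write_stage_tsv(cvrec, pth("cv_records.tsv"), config)
  summary$stages$cv <- list(n_records = nrow(cvrec))

  perm <- stage("permtest", permutation_delta_test(
    tab, samples, n_perm = config$n_perm, seed = config$seed,
    n_bins = config$n_bins, min_per_bin = config$min_per_bin))
  write_stage_tsv(perm, pth("permutation.tsv"), config)
  ranked <- rank_for_enrichment(perm)
  write_stage_tsv(ranked, pth("ranked.tsv"), config)
  summary$stages$permtest <- list(n_analytes = nrow(perm), n_perm = attr(perm, "n_perm"))

  registry <- contrast_registry()
  diffs <- stage("contrast", map(registry, function(ct)
    differential_test(tab, samples, ct, pseudocount = 1)))
  iwalk(diffs, function(d, nm)
    write_stage_tsv(d, pth(paste0("contrast_", nm, ".tsv")), config))
  comparison <- compare_profiles(diffs, alpha = config$alpha,
                                 lfc_threshold = config$lfc_threshold)
  write_stage_tsv(comparison, pth("profile_comparison.tsv"), config)
  deg_counts <- map_int(diffs, ~ length(call_degs(.x, config$alpha, config$lfc_threshold)))
  summary$stages$contrast <- list(deg_counts = as.list(deg_counts))

  collection <- if (!is.null(config$gmt)) read_gmt(config$gmt) else {
    withr::with_seed(child_seed_int(config$seed, 991L), {
      sets <- map(seq_len(config$n_sets), ~ sample(rownames(tab), config$set_size))
      setNames(sets, sprintf("SET_%02d", seq_len(config$n_sets)))
    })
  }
  enr <- stage("enrich", gsea_preranked(ranked, collection,
                                        n_perm = config$gsea_n_perm,
                                        seed = config$seed))
  write_stage_tsv(enr, pth("gsea.tsv"), config)
  fp1_degs <- call_degs(diffs$FP1, config$alpha, config$lfc_threshold)
  ora <- if (length(fp1_degs)) {
    stage("ora", ora_hypergeometric(fp1_degs, collection, rownames(tab)))
  } else NULL
  if (!is.null(ora)) write_stage_tsv(filter_pathways(ora), pth("ora.tsv"), config)
  summary$stages$enrich <- list(n_sets = nrow(enr),
                                n_ora = if (is.null(ora)) 0L else nrow(ora))

  conc <- stage("concordance", {
    genes <- rownames(tab)
    tss <- tibble(gene_id = genes, chrom = "chr1",
                  tss = 2000L * seq_along(genes), strand = "+")
    fp1 <- diffs$FP1
    coupling <- tibble(gene_id = fp1$analyte_id,
                       expression_lfc = fp1$log2fc,
                       coupling = as.numeric(fp1$deg))
    frag <- generate_fragment_counts(tss, coupling,
                                     seed = child_seed_int(config$seed, 577L))
    wins <- tss_windows(tss, config$halfwidth)
    counts <- window_accessibility(frag, wins)
    norm <- unclass(cpm(counts))
    deltas <- accessibility_delta(norm[, "baseline"], norm[, "comparison"])
    deg_tab <- filter(fp1, .data$deg)
    if (sum(deg_tab$log2fc > 0) >= 2 && sum(deg_tab$log2fc < 0) >= 2) {
      concordance_test(deltas, deg_tab)
    } else NULL
  })
  if (!is.null(conc)) {
    write_stage_tsv(conc$matched, pth("concordance_genes.tsv"), config)
    summary$stages$concordance <- list(p_value = conc$p_value,
                                       correlation = conc$correlation,
                                       n_up = conc$n_up, n_down = conc$n_down)
  } else {
    summary$stages$concordance <- list(skipped = "too few DEGs per direction")
  }

  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
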