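#' Configure a synthetic longitudinal multi-omic cohort
#'
#' The generator emulates a small crewed-mission cohort: `n_subjects`
#' subjects sampled at a fixed timepoint schedule across several assay
#' modalities. Abundances follow a log-normal model
#' `value = exp(mu_i + b_s + eps)` with analyte baseline `mu_i`, subject
#' random effect `b_s ~ N(0, sigma_subject^2)` and noise `eps` whose variance
#' is chosen so that the coefficient of variation on the abundance scale is
#' approximately `sqrt(1/exp(mu_i) + phi)` — the count-like mean-variance law
#' in which CV falls with mean abundance and flattens at the dispersion
#' floor `phi`.
#'
#' Spike-ins perturb chosen analytes in one phase: the mean is multiplied by
#' `mean_effect` and the coefficient of variation by `disp_effect` (so a
#' `disp_effect` of 3 triples the analyte's variability spread) while the
#' phase lasts. At later timepoints the perturbation relaxes along a damped
#' homeostatic trajectory: the log effect is scaled by
#' `(1 + rebound) * 2^(-dt/h) - rebound * 2^(-dt/(5 h))`, where `dt` is days
#' since the end of the affected phase and `h = halflife_days`. With
#' `rebound = 0` this is plain exponential decay to baseline; with
#' `rebound > 0` the analyte overshoots past baseline before settling, the
#' behaviour needed for recovery-phase directionality reversal.
#'
#' @param n_subjects number of subjects (default 4).
#' @param timepoints tibble with `label` and `day_offset` (days relative to
#'   launch); default is the ten-timepoint mission schedule.
#' @param modalities named integer vector of analyte counts per modality.
#' @param meanlog,sdlog parameters of the baseline log-mean distribution
#'   `mu_i ~ N(meanlog, sdlog^2)`.
#' @param phi dispersion floor of the squared CV (default 0.05).
#' @param sigma_subject standard deviation of the subject random effect on
#'   the log scale (default 0.15).
#' @param spikes tibble with columns `analyte_id`, `modality`, `phase`,
#'   `mean_effect`, `disp_effect`, `halflife_days`, `rebound`; or `NULL`.
#' @param seed integer RNG seed. One global seed expands deterministically to
#'   per-modality child seeds (`seed + 7919 * modality-registry-index`,
#'   mod 2^31 - 1), so adding one modality never perturbs another.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 4,
                          timepoints = default_timepoints(),
                          modalities = c(rna_counts = 2000, protein_intensity = 500,
                                         metabolite_intensity = 300, cytokine = 64,
                                         microbiome_relabund = 150),
                          meanlog = log(100), sdlog = 3,
                          phi = 0.05, sigma_subject = 0.15,
                          spikes = NULL, seed = 1L) {
  stopifnot(n_subjects >= 1, all(modalities >= 1), phi >= 0,
            sigma_subject >= 0, sdlog >= 0)
  bad_mod <- setdiff(names(modalities), ft_modalities())
  if (length(bad_mod)) abort(paste0("unknown modality: ", paste(bad_mod, collapse = ", ")))
  timepoints$label <- canonical_timepoint(timepoints$label)
  if (!is.null(spikes)) {
    need <- c("analyte_id", "modality", "phase", "mean_effect", "disp_effect",
              "halflife_days", "rebound")
    miss <- setdiff(need, names(spikes))
    if (length(miss)) abort(paste0("spikes missing column(s): ", paste(miss, collapse = ", ")))
    if (any(spikes$mean_effect <= 0) || any(spikes$disp_effect <= 0)) {
      abort("spike effects must be > 0")
    }
  }
  structure(list(n_subjects = n_subjects, timepoints = as_tibble(timepoints),
                 modalities = modalities, meanlog = meanlog, sdlog = sdlog,
                 phi = phi, sigma_subject = sigma_subject,
                 spikes = spikes, seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_timepoints <- function() {
  tibble(
    label = c("L-92", "L-44", "L-3", "FD1", "FD2", "FD3",
              "R+1", "R+45", "R+82", "R+194"),
    day_offset = c(-92L, -44L, -3L, 1L, 2L, 3L, 4L, 48L, 85L, 197L)
  )
}

analyte_prefix <- function(modality) {
  switch(modality,
         rna_counts = "gene", protein_intensity = "prot",
         metabolite_intensity = "met", cytokine = "cyt",
         microbiome_relabund = "s__Taxon", fragment_counts = "frag")
}

child_seed <- function(seed, modality) {
  idx <- match(modality, ft_modalities())
  as.integer((as.double(seed) + 7919 * idx) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws one abundance table per configured modality, plus sample metadata
#' and the spike-in ground truth. Identical configs (including seed) give
#' bitwise-identical output; the global RNG state is left untouched.
#'
#' @param config a [cohort_config()].
#' @param scheme the [phase_scheme()] used to place timepoints into phases
#'   when applying spike perturbations.
#' @return list with `tables` (named list of [feature_table()]s, tagged
#'   normalized), `samples` (tibble: `sample_id`, `subject_id`,
#'   `timepoint_label`, `day_offset`) and `spike_truth` (tibble).
#' @examples
#' cfg <- cohort_config(modalities = c(rna_counts = 50), seed = 7)
#' cohort <- generate_cohort(cfg)
#' dim(cohort$tables$rna_counts)
#' @export
generate_cohort <- function(config, scheme = phase_scheme()) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- sprintf("C%03d", seq_len(config$n_subjects))
  samples <- tidyr::expand_grid(subject_id = subjects,
                                timepoint_label = config$timepoints$label) |>
    left_join(rename(config$timepoints, timepoint_label = "label"),
              by = "timepoint_label") |>
    mutate(sample_id = paste(.data$subject_id, .data$timepoint_label, sep = "_")) |>
    select("sample_id", "subject_id", "timepoint_label", "day_offset")
  samples <- assign_phases(samples, scheme)

  tables <- imap(as.list(config$modalities), function(n_analytes, modality) {
    withr::with_seed(child_seed(config$seed, modality), {
      simulate_modality(modality, as.integer(n_analytes), config, samples)
    })
  })
  truth <- config$spikes %||%
    tibble(analyte_id = character(), modality = character(), phase = character(),
           mean_effect = double(), disp_effect = double(),
           halflife_days = double(), rebound = double())
  for (i in seq_len(nrow(truth))) {
    tab <- tables[[truth$modality[i]]]
    if (is.null(tab) || !truth$analyte_id[i] %in% rownames(tab)) {
      abort(paste0("spike references unknown analyte: ", truth$analyte_id[i]))
    }
  }
  list(tables = tables, samples = select(samples, -"phase"), spike_truth = as_tibble(truth))
}

simulate_modality <- function(modality, n_analytes, config, samples) {
  ids <- sprintf("%s_%04d", analyte_prefix(modality), seq_len(n_analytes))
  mu <- rnorm(n_analytes, config$meanlog, config$sdlog)
  subjects <- unique(samples$subject_id)
  b <- setNames(rnorm(length(subjects), 0, config$sigma_subject), subjects)

  spikes <- config$spikes
  if (!is.null(spikes)) spikes <- spikes[spikes$modality == modality, , drop = FALSE]

  vals <- matrix(0, n_analytes, nrow(samples),
                 dimnames = list(ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu_j <- mu
    disp_mult <- rep(1, n_analytes)
    if (!is.null(spikes) && nrow(spikes)) {
      frac <- spike_fraction(spikes, samples$phase[j], samples$day_offset[j],
                             config$timepoints, scheme_phase_days(samples))
      k <- match(spikes$analyte_id, ids)
      ok <- !is.na(k) & frac != 0
      mu_j[k[ok]] <- mu_j[k[ok]] + log(spikes$mean_effect[ok]) * frac[ok]
      disp_mult[k[ok]] <- spikes$disp_effect[ok]^frac[ok]
    }
    m <- exp(mu_j)
    sigma2 <- log1p(disp_mult^2 * (1 / m + config$phi))
    vals[, j] <- exp(mu_j + b[[samples$subject_id[j]]] +
                       rnorm(n_analytes, 0, sqrt(sigma2)))
  }
  feature_table(vals, modality = modality, normalized = TRUE)
}

# last day_offset of each phase actually present in the schedule
scheme_phase_days <- function(samples) {
  tapply(samples$day_offset, as.character(samples$phase), max)
}

# per-spike effect fraction at a given sample phase / day
spike_fraction <- function(spikes, phase, day, timepoints, phase_end_days) {
  vapply(seq_len(nrow(spikes)), function(i) {
    p <- spikes$phase[i]
    end_day <- phase_end_days[[p]]
    if (is.null(end_day) || is.na(end_day)) return(0)
    if (as.character(phase) == p) return(1)
    dt <- day - end_day
    if (dt <= 0) return(0)
    h <- spikes$halflife_days[i]
    r <- spikes$rebound[i]
    (1 + r) * 2^(-dt / h) - r * 2^(-dt / (5 * h))
  }, double(1))
}

#' Generate promoter-window fragment counts coupled to expression changes
#'
#' Builds a gene-by-group table of accessibility fragment counts for two
#' conditions (`baseline`, `comparison`). Each gene's baseline rate is
#' log-normal; for coupled genes the comparison rate is shifted by
#' `2^(coupling * expression_lfc)`, so accessibility tracks the direction of
#' the configured expression change. Counts are Poisson draws at the
#' configured library size.
#'
#' @param tss TSS annotation tibble (see [read_tss_bed()]).
#' @param coupling tibble with `gene_id`, `expression_lfc` and `coupling`
#'   (0 = accessibility independent of expression, 1 = fully coupled).
#' @param library_size expected total fragment count per group.
#' @param meanlog,sdlog log-normal parameters of per-gene baseline rates.
#' @param seed integer RNG seed.
#' @return a [feature_table()] with modality `fragment_counts`, one column
#'   per group.
#' @export
generate_fragment_counts <- function(tss, coupling, library_size = 2e5,
                                     meanlog = log(20), sdlog = 1, seed = 1L) {
  missing_genes <- setdiff(coupling$gene_id, tss$gene_id)
  if (length(missing_genes)) {
    abort(paste0("coupling references gene(s) absent from TSS annotation: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  genes <- tss$gene_id
  withr::with_seed(as.integer(seed), {
    lambda <- exp(rnorm(length(genes), meanlog, sdlog))
    shift <- rep(1, length(genes))
    k <- match(coupling$gene_id, genes)
    shift[k] <- 2^(coupling$coupling * coupling$expression_lfc)
    lam_a <- lambda / sum(lambda) * library_size
    lam_b <- lambda * shift
    lam_b <- lam_b / sum(lam_b) * library_size
    m <- cbind(baseline = rpois(length(genes), lam_a),
               comparison = rpois(length(genes), lam_b))
    rownames(m) <- genes
    feature_table(m, modality = "fragment_counts")
  })
}
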