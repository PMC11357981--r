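#' Mean-abundance vs CV plot with the quantile reference
#'
#' Scatter of raw CV against mean abundance (log10 x-axis) with the
#' per-bin reference means overlaid — the diagnostic for the mean-variance
#' trend the standardization removes.
#'
#' @param cv_records tibble from [interval_cv()] / [cv_profile()].
#' @param reference optional [build_quantile_reference()] object.
#' @return a ggplot.
#' @export
plot_cv_reference <- function(cv_records, reference = NULL) {
  p <- ggplot(filter(cv_records, !.data$flagged),
              aes(x = .data$mean_abundance, y = .data$raw_cv)) +
    geom_point(alpha = 0.3, size = 0.6, colour = "grey40") +
    scale_x_log10() +
    labs(x = "mean abundance", y = "raw CV") +
    theme_minimal()
  if (!is.null(reference)) {
    mid <- mutate(as_tibble(reference), mid = (.data$lower + .data$upper) / 2)
    p <- p + geom_step(data = mid, aes(x = .data$mid, y = .data$cv_mean),
                       colour = "firebrick", linewidth = 0.7)
  }
  p
}

#' @export
autoplot.quantile_reference <- function(object, ...) {
  mid <- mutate(as_tibble(object), mid = (.data$lower + .data$upper) / 2)
  ggplot(mid, aes(x = .data$mid, y = .data$cv_mean)) +
    geom_ribbon(aes(ymin = .data$cv_mean - .data$cv_sd,
                    ymax = .data$cv_mean + .data$cv_sd), alpha = 0.2) +
    geom_line(colour = "firebrick") +
    scale_x_log10() +
    labs(x = "mean abundance (bin midpoint)", y = "bin CV mean +/- sd") +
    theme_minimal()
}

#' @export
autoplot.perm_delta_result <- function(object, alpha = 0.05, ...) {
  df <- filter(as_tibble(object), is.finite(.data$delta_z), !is.na(.data$p_value))
  ggplot(df, aes(x = .data$delta_z, y = -log10(.data$p_value),
                 colour = .data$p_value <= alpha)) +
    geom_point(alpha = 0.6, size = 0.8) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                        guide = "none") +
    labs(x = expression(Delta * z ~ "(standardized CV shift)"),
         y = expression(-log[10] ~ "empirical p")) +
    theme_minimal()
}

#' @export
autoplot.differential_result <- function(object, alpha = 0.05, lfc_threshold = 0.5, ...) {
  df <- as_tibble(object)
  df$called <- deg_flag(df$adj_p, df$log2fc, alpha, lfc_threshold)
  ggplot(df, aes(x = .data$log2fc, y = -log10(.data$adj_p), colour = .data$called)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_vline(xintercept = c(-lfc_threshold, lfc_threshold), linetype = 2,
               colour = "grey50") +
    geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey50") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                        guide = "none") +
    labs(x = expression(log[2] ~ "fold change"), y = expression(-log[10] ~ "adj. p"),
         title = attr(object, "contrast")$name) +
    theme_minimal()
}

#' @export
autoplot.ora_result <- function(object, ...) {
  df <- arrange(as_tibble(object), .data$fdr)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot(df, aes(x = .data$enrichment_ratio, y = .data$set, fill = .data$fdr)) +
    geom_col() +
    scale_fill_gradient(low = "firebrick", high = "grey80", name = "FDR") +
    labs(x = "enrichment ratio", y = NULL) +
    theme_minimal()
}

#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- arrange(as_tibble(object), .data$nes)
  df$set <- factor(df$set, levels = df$set)
  ggplot(df, aes(x = .data$nes, y = .data$set, colour = .data$nes,
                 size = -log10(pmax(.data$q_value, 1e-4)))) +
    geom_point() +
    scale_colour_gradient2(low = "steelblue", mid = "grey85", high = "firebrick",
                           midpoint = 0, name = "NES") +
    scale_size_continuous(name = expression(-log[10] ~ q)) +
    labs(x = "normalized enrichment score", y = NULL) +
    theme_minimal()
}

#' Shared / reversed DEG profile comparison plot
#'
#' @param comparison tibble from [compare_profiles()].
#' @return a ggplot of shared and reversed fractions per target profile.
#' @export
plot_profile_comparison <- function(comparison) {
  df <- tidyr::pivot_longer(
    select(comparison, "target", "shared_fraction", "reversed_fraction"),
    cols = c("shared_fraction", "reversed_fraction"),
    names_to = "metric", values_to = "fraction")
  ggplot(df, aes(x = .data$target, y = .data$fraction, fill = .data$metric)) +
    geom_col(position = "dodge") +
    scale_fill_manual(values = c(shared_fraction = "grey60",
                                 reversed_fraction = "firebrick"),
                      labels = c("reversed (of shared)", "shared with reference")) +
    ylim(0, 1) +
    labs(x = NULL, y = "fraction", fill = NULL) +
    theme_minimal()
}
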