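#' @import ggplot2
NULL

#' Heatmap of all-pairs Morisita overlap
#' @param om An `overlap_matrix`.
#' @return A ggplot object.
#' @export
plot_overlap_heatmap <- function(om) {
  df <- as_tibble(om$matrix, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "morisita")
  lv <- om$sample_ids
  ggplot(df, aes(factor(.data$sample_a, lv), factor(.data$sample_b, lv),
                 fill = .data$morisita)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Morisita") +
    theme_minimal(base_size = 8) +
    theme(axis.text.x = element_text(angle = 90, hjust = 1))
}

#' Stacked-bar longitudinal clonotype tracking plot
#' @param tt A [tracking_table()] tibble (one patient, one compartment).
#' @return A ggplot object; TIL clonotypes coloured, others grey.
#' @export
plot_tracking <- function(tt) {
  ggplot(tt, aes(factor(.data$timepoint_days), .data$abundance,
                 group = .data$key,
                 fill = ifelse(.data$is_til, .data$key, NA))) +
    geom_col(colour = NA, show.legend = FALSE) +
    scale_fill_discrete(na.value = "grey85") +
    labs(x = "day relative to infusion", y = "relative abundance") +
    theme_minimal(base_size = 9)
}

#' Diversity timeline with size-class bars
#' @param dt A [diversity_timeline()] tibble.
#' @return A ggplot object: inverse Simpson line over stacked
#'   large/hyperexpanded abundance bars.
#' @export
plot_diversity_timeline <- function(dt) {
  long <- dt |>
    select("timepoint_days", "frac_large", "frac_hyper") |>
    tidyr::pivot_longer(-"timepoint_days", names_to = "class",
                        values_to = "fraction")
  scale <- max(dt$inv_simpson) / max(1e-9, max(long$fraction))
  ggplot() +
    geom_col(data = long,
             aes(factor(.data$timepoint_days), .data$fraction,
                 fill = .data$class)) +
    geom_line(data = dt,
              aes(factor(.data$timepoint_days), .data$inv_simpson / scale,
                  group = 1)) +
    geom_point(data = dt,
               aes(factor(.data$timepoint_days), .data$inv_simpson / scale)) +
    scale_y_continuous(
      "large/hyperexpanded abundance",
      sec.axis = sec_axis(~ . * scale, name = "inverse Simpson")) +
    labs(x = "day relative to infusion", fill = NULL) +
    theme_minimal(base_size = 9)
}

write_figures <- function(out_dir, om, tracking, diversity) {
  fig_dir <- file.path(out_dir, "figures")
  if (!dir.exists(fig_dir)) dir.create(fig_dir)
  ggsave(file.path(fig_dir, "overlap_heatmap.png"), plot_overlap_heatmap(om),
         width = 7, height = 6, dpi = 120)
  for (pid in unique(tracking$patient_id)) {
    tt <- tracking |> filter(.data$patient_id == pid, .data$cohort == "PBMC_DNA")
    if (nrow(tt) == 0) next
    ggsave(file.path(fig_dir, paste0("tracking_", pid, ".png")),
           plot_tracking(tt), width = 5, height = 4, dpi = 120)
  }
  for (pid in unique(diversity$patient_id)) {
    dt <- diversity |> filter(.data$patient_id == pid, .data$cohort == "PBMC_DNA")
    if (nrow(dt) == 0) next
    ggsave(file.path(fig_dir, paste0("diversity_", pid, ".png")),
           plot_diversity_timeline(dt), width = 5, height = 4, dpi = 120)
  }
  invisible(fig_dir)
}
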