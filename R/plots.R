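# Optional figures (ggplot2 is suggested, not required).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_xct("plot", "ggplot2 is required for plotting")
  }
}

#' Dot plot of a radial profile
#'
#' Component share per radial position (percent of covered xylem area),
#' with a vertical line at the 95% cumulative threshold.
#'
#' @param profile a `radial_profile`.
#' @return a ggplot object.
#' @export
plot_radial_profile <- function(profile) {
  need_ggplot()
  s <- profile$steps
  s$share <- if (profile$component_area_px > 0) {
    100 * s$component_area_in_step_px / profile$component_area_px
  } else 0
  thr <- if (profile$excluded) NA_real_ else threshold95(profile)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = covered_fraction_pct,
                                       y = share,
                                       size = share)) +
    ggplot2::geom_point(alpha = 0.8,
                        colour = if (profile$component_kind == "vessels")
                          "#2166ac" else "#1b7837") +
    ggplot2::labs(x = "covered xylem area (%)",
                  y = "component share per step (%)",
                  title = paste("radial distribution:", profile$component_kind)) +
    ggplot2::guides(size = "none") +
    ggplot2::theme_minimal()
  if (!is.na(thr)) p <- p + ggplot2::geom_vline(xintercept = thr)
  p
}

#' Stacked YES/NO bar chart of vessel-fiber association
#'
#' @param summaries association summary table (rows per replicate and
#'   enlargement; see [fiber_association()]).
#' @param enlargement_px which enlargement radius to plot.
#' @return a ggplot object.
#' @export
plot_association_summary <- function(summaries, enlargement_px = 10) {
  need_ggplot()
  s <- summaries[summaries$enlargement_px == enlargement_px, , drop = FALSE]
  long <- rbind(
    data.frame(sample_id = s$sample_id, class = "yes", n = s$n_yes),
    data.frame(sample_id = s$sample_id, class = "no", n = s$n_no)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = sample_id, y = n,
                                     fill = class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(values = c(yes = "#2166ac", no = "#ef8a62")) +
    ggplot2::labs(x = NULL, y = "fraction of embolized vessels",
                  title = paste0("vessels with air-filled fibers within ",
                                 enlargement_px, " px")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
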