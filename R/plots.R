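# ggplot2 figures for pipeline runs. Cosmetic layer: the numeric tables in
# the run object are the analysis contract.

group_palette <- c(train = "#c0392b", yoked = "#2e6da4", blank = "#7f8c8d")

#' Median CAD curves with confidence bands
#'
#' Cumulative active duration versus time from Train-session start, per
#' group: group medians with bootstrap CI ribbons, one panel per Train
#' session, up to the common cut.
#'
#' @param run An `operant_run`.
#' @return A ggplot.
#' @export
plot_cad_curves <- function(run) {
  df <- run$cad_bands
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$median,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~session) +
    ggplot2::scale_colour_manual(values = group_palette) +
    ggplot2::scale_fill_manual(values = group_palette) +
    ggplot2::labs(x = "Time from Train-session start (s)",
                  y = "Cumulative active duration (s)",
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Activity levels and activity differences across sessions
#'
#' Box plots of per-fly activity levels in the three Test sessions (or of
#' the activity differences relative to Pre-test), split by group.
#'
#' @param run An `operant_run`.
#' @param what `"activity"` or `"ad"`.
#' @return A ggplot.
#' @export
plot_activity_levels <- function(run, what = c("activity", "ad")) {
  what <- match.arg(what)
  fs <- run$fly_summary
  if (what == "activity") {
    df <- tidyr::pivot_longer(
      fs[, c("fly_id", "group", "activity_pretest", "activity_test1",
             "activity_test2")],
      dplyr::starts_with("activity_"), names_to = "session",
      names_prefix = "activity_", values_to = "value")
    ylab <- "Activity level (fraction of session walking)"
  } else {
    df <- tidyr::pivot_longer(
      fs[, c("fly_id", "group", "ad_test1", "ad_test2")],
      dplyr::starts_with("ad_"), names_to = "session",
      names_prefix = "ad_", values_to = "value")
    ylab <- "Activity difference (Test - Pre-test)"
  }
  df$group <- factor(df$group, c("train", "yoked", "blank"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, alpha = 0.8) +
    ggplot2::scale_fill_manual(values = group_palette) +
    ggplot2::labs(x = NULL, y = ylab, fill = "Group") +
    ggplot2::theme_minimal()
}

#' AD scatter plots for yoked flies
#'
#' Activity difference of yoked flies against total heat exposure and
#' against the exposure differential (Train 1 and whole experiment), with
#' least-squares fits and the r / slope / p annotations.
#'
#' @param run An `operant_run`.
#' @return A ggplot (three panels).
#' @export
plot_ad_scatter <- function(run) {
  yoked <- run$fly_summary[run$fly_summary$group == "yoked", ]
  panels <- list(
    c(x = "heat_exposure_total", y = "ad_test2",
      lab = "Total heat exposure (s)"),
    c(x = "ed_train1", y = "ad_test1", lab = "ED, Train 1"),
    c(x = "ed_all", y = "ad_test2", lab = "ED, all Train sessions")
  )
  df <- dplyr::bind_rows(lapply(panels, function(p) {
    tibble::tibble(panel = p[["lab"]], x = yoked[[p[["x"]]]],
                   y = yoked[[p[["y"]]]])
  }))
  ann <- run$correlations
  ann$panel <- vapply(panels, `[[`, character(1), "lab")
  ann$label <- sprintf("r = %.2f, slope = %.3g, p = %.3g %s",
                       ann$r, ann$slope, ann$p_value, ann$stars)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = group_palette[["yoked"]], alpha = 0.7,
                        size = 1.2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.6) +
    ggplot2::geom_text(data = ann,
                       ggplot2::aes(x = -Inf, y = Inf, label = .data$label),
                       hjust = -0.05, vjust = 1.5, size = 3,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Activity difference") +
    ggplot2::theme_minimal()
}

#' Autoplot method for pipeline runs
#'
#' @param object An `operant_run`.
#' @param type Which figure: `"cad"`, `"activity"`, `"ad"`, or `"scatter"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot operant_run
autoplot.operant_run <- function(object, type = c("cad", "activity", "ad",
                                                  "scatter"), ...) {
  type <- match.arg(type)
  switch(type,
         cad = plot_cad_curves(object),
         activity = plot_activity_levels(object, "activity"),
         ad = plot_activity_levels(object, "ad"),
         scatter = plot_ad_scatter(object))
}
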