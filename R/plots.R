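ladder_factor <- function(x) {
  lev <- sort(unique(x))
  factor(signif(x, 3), levels = signif(lev, 3))
}

#' Heatmap of an induction profile
#'
#' Tiles the sugar grid with the normalized high steady-state Gal1p level
#' (the quantity flow-cytometry ON peaks report), optionally overlaying
#' the half-maximum decision front. Masked cells are blanked.
#'
#' @param object an `induction_profile`.
#' @param front optional `decision_front` to overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.induction_profile <- function(object, front = NULL, ...) {
  df <- as_tibble(object)
  df$gal_f <- ladder_factor(df$galactose)
  df$gluc_f <- ladder_factor(df$glucose)
  df$normalized_high[df$masked] <- NA
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$gal_f, .data$gluc_f,
                                        fill = .data$normalized_high)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white",
                                  name = "GAL1\ninduction") +
    ggplot2::labs(x = "galactose (% w/v)", y = "glucose (% w/v)") +
    ggplot2::theme_minimal()
  if (!is.null(front) && nrow(front) > 0) {
    fr <- front
    gal_lev <- sort(unique(df$galactose[df$galactose > 0]))
    fr$xi <- 1 + log2(fr$galactose_crossing / min(gal_lev)) +
      sum(unique(df$galactose) == 0)
    fr$yi <- match(signif(fr$glucose, 3), levels(df$gluc_f))
    p <- p + ggplot2::geom_path(
      data = fr, ggplot2::aes(x = .data$xi, y = .data$yi),
      inherit.aes = FALSE, color = "red", linewidth = 1)
  }
  p
}

#' Modality map of an induction profile
#'
#' @param profile an `induction_profile`.
#' @return a ggplot object with one tile per condition colored by
#'   modality class.
#' @export
plot_modality <- function(profile) {
  df <- as_tibble(profile)
  df$gal_f <- ladder_factor(df$galactose)
  df$gluc_f <- ladder_factor(df$glucose)
  df$modality[df$masked] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$gal_f, .data$gluc_f,
                                   fill = .data$modality)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(unimodal_OFF = "#2166ac",
                                          bimodal = "#fddbc7",
                                          unimodal_ON = "#b2182b"),
                               na.value = "white", name = NULL) +
    ggplot2::labs(x = "galactose (% w/v)", y = "glucose (% w/v)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a perturbation matrix
#'
#' @param object a `perturbation_matrix` (optionally classified).
#' @param metric one of `"delta_on"`, `"delta_full"`, `"delta_level"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.perturbation_matrix <- function(object, metric = "delta_on", ...) {
  cols <- grep(paste0("^", metric, "_"), names(object), value = TRUE)
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, row = paste0(.data$parameter, " x", .data$factor)),
    dplyr::all_of(cols), names_to = "glucose", values_to = "value")
  long$glucose <- sub(paste0(metric, "_g"), "", long$glucose)
  ggplot2::ggplot(long, ggplot2::aes(.data$glucose, .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = metric) +
    ggplot2::labs(x = "glucose (% w/v)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 4))
}

#' Heatmap of a fitting-improvement matrix
#'
#' @param object an `improvement_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.improvement_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$parameter, .data$strain,
                                       fill = .data$delta_obj)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "fitting\nimprovement") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Trace plot of a Metropolis-Hastings chain
#'
#' @param object a `gal_chain`.
#' @param ... unused.
#' @return a ggplot object with one facet per free parameter (log10
#'   scale) plus the log-posterior trace.
#' @export
autoplot.gal_chain <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws,
                              dplyr::all_of(object$config$free),
                              names_to = "parameter", values_to = "log10_value")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$log10_value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "step", y = "log10 parameter value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
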