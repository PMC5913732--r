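#' Plot a root zone evaluation
#'
#' `type = "water"` shows the per-profile root zone water capacity (mm)
#' coloured by limiting factor; `type = "depth"` the rootable depth (cm);
#' `type = "ri"` the depth profiles of the factor rootability indices
#' (interval midpoints, one line per factor) for up to `max_profiles`
#' profiles.
#'
#' @param object An `rz_evaluation` from [evaluate_profiles()].
#' @param type One of "water", "depth", "ri".
#' @param max_profiles Facet limit for `type = "ri"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rz_evaluation <- function(object, type = c("water", "depth", "ri"),
                                   max_profiles = 6, ...) {
  type <- match.arg(type)
  td <- tidy(object)
  if (type == "water") {
    return(
      ggplot2::ggplot(td, ggplot2::aes(x = .data$profile_id,
                                       y = .data$rz_pawhc_mm,
                                       fill = .data$limiting_factor)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = NULL, y = "RZ-PAWHC (mm)",
                      fill = "limiting factor") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
    )
  }
  if (type == "depth") {
    return(
      ggplot2::ggplot(td, ggplot2::aes(x = .data$profile_id, y = .data$rzd,
                                       fill = .data$limiting_factor)) +
        ggplot2::geom_col() +
        ggplot2::scale_y_reverse() +
        ggplot2::labs(x = NULL, y = "rootable depth (cm)",
                      fill = "limiting factor") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
    )
  }
  keep <- utils::head(unique(object$factor_ri$profile_id), max_profiles)
  ri <- object$factor_ri |>
    dplyr::filter(.data$profile_id %in% keep) |>
    dplyr::mutate(mid = (.data$top + .data$bottom) / 2)
  ggplot2::ggplot(ri, ggplot2::aes(x = .data$ri, y = .data$mid,
                                   colour = .data$factor)) +
    ggplot2::geom_path() +
    ggplot2::geom_vline(xintercept = object$config$threshold_index,
                        linetype = "dashed") +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~profile_id) +
    ggplot2::labs(x = "rootability index (%)", y = "depth (cm)",
                  colour = "factor") +
    ggplot2::theme_minimal()
}

#' Plot a rootability rule
#'
#' The piecewise-linear rootability index of one factor against its soil
#' property, with the threshold index marked.
#'
#' @param rules Rule table from [read_rules()].
#' @param factor Factor name to plot.
#' @param threshold Threshold index to mark, %.
#' @return A ggplot object.
#' @export
plot_rule <- function(rules, factor, threshold = 20) {
  rule <- rules[rules$factor == factor, ]
  if (nrow(rule) == 0) stop("unknown factor: ", factor, call. = FALSE)
  ggplot2::ggplot(rule, ggplot2::aes(x = .data$value, y = .data$ri)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = paste0(rule$variable[1], " (", rule$unit[1], ")"),
                  y = "rootability index (%)", title = factor) +
    ggplot2::theme_minimal()
}
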