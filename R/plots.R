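# ggplot2 views of the PSA: incremental cost-effectiveness plane scatter
# and cost-effectiveness acceptability curves.

#' @importFrom ggplot2 .data
NULL

#' Incremental cost-effectiveness plane scatter
#'
#' One point per PSA iteration and comparator: the intervention's effect and
#' cost differences against that comparator (the comparator sits at the
#' origin). A dashed line marks the willingness-to-pay threshold when given.
#'
#' @param psa A [run_psa()] result.
#' @param comparators Comparator labels (default: all non-reference).
#' @param wtp Optional willingness-to-pay threshold (JOD per unit CR) drawn
#'   through the origin.
#' @return A ggplot object.
#' @export
plot_icer_plane <- function(psa,
                            comparators = setdiff(psa$treatments,
                                                  psa$reference),
                            wtp = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  ref <- psa$reference
  df <- do.call(rbind, lapply(comparators, function(cmp) {
    data.frame(
      comparator = cmp,
      delta_effect = psa$effect[, ref] - psa$effect[, cmp],
      delta_cost = psa$cost[, ref] - psa$cost[, cmp],
      stringsAsFactors = FALSE)
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(
          x = .data$delta_effect, y = .data$delta_cost,
          colour = .data$comparator)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = sprintf("Incremental complete response (%s vs comparator)", ref),
      y = "Incremental cost (JOD)",
      colour = "Comparator",
      title = "Incremental cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    gg <- gg + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                    linetype = "dashed")
  }
  gg
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac_df A [ceac()] table.
#' @param wtp Optional threshold to mark with a vertical dashed line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df, wtp = NULL) {
  stopifnot(all(c("wtp", "comparator", "probability") %in% names(ceac_df)))
  gg <- ggplot2::ggplot(ceac_df, ggplot2::aes(
          x = .data$wtp, y = .data$probability,
          colour = .data$comparator)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (JOD per unit CR)",
      y = "Probability cost-effective",
      colour = "Comparator",
      title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    gg <- gg + ggplot2::geom_vline(xintercept = wtp, linetype = "dashed")
  }
  gg
}
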