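# Discounting, pairwise incremental analysis, ICER and dominance
# classification, and net monetary benefit.

#' Year-step discount factor for a model cycle
#'
#' Discounting follows a year-step rule: outcomes arising in the second
#' model year are discounted by one year at the annual rate, first-year
#' outcomes are undiscounted. With 4 cycles per year, cycles 1-4 get factor
#' 1 and cycles 5-8 get `1 / (1 + rate)`; the rule generalizes to later
#' years as `(1 + rate)^-(year - 1)`.
#'
#' @param cycle_index Cycle number, 1-based.
#' @param rate Annual discount rate (default 0.035).
#' @param cycles_per_year Cycles per year (default 4).
#' @return Discount factor in (0, 1\].
#' @export
#' @examples
#' discount_factor(2)            # 1
#' discount_factor(5)            # 1/1.035
discount_factor <- function(cycle_index, rate = 0.035, cycles_per_year = 4) {
  if (!is.numeric(cycle_index) || length(cycle_index) != 1L ||
      cycle_index < 1 || cycle_index != round(cycle_index)) {
    stop_foscea("`cycle_index` must be a whole number >= 1",
                "foscea_validation_error")
  }
  assert_scalar_number(rate, "rate", lower = 0)
  year <- ceiling(cycle_index / cycles_per_year)
  (1 + rate)^-(year - 1)
}

#' A treatment's total discounted cost and effectiveness
#'
#' @param treatment Treatment label.
#' @param cost Total discounted cost, JOD (>= 0).
#' @param effect Proportion achieving complete response, in \[0, 1\].
#' @return An object of class `ce_result`.
#' @export
ce_result <- function(treatment, cost, effect) {
  assert_scalar_number(cost, "cost", lower = 0)
  assert_scalar_number(effect, "effect", lower = 0, upper = 1)
  structure(list(treatment = treatment, cost = cost, effect = effect),
            class = "ce_result")
}

#' Pairwise incremental cost-effectiveness analysis
#'
#' Computes the cost and effect differences of an intervention against a
#' comparator, the incremental cost-effectiveness ratio (ICER), and the
#' cost-effectiveness-plane classification:
#' \describe{
#'   \item{`SAVING_SE`}{more effective, less costly — cost-saving
#'     (south-east quadrant; "dominant").}
#'   \item{`TRADE_OFF_NE`}{more effective, more costly (north-east) — the
#'     ICER is compared against a willingness-to-pay threshold.}
#'   \item{`DOMINATED`}{less effective, more costly (north-west).}
#'   \item{`TRADE_OFF_SW`}{less effective, less costly (south-west).}
#' }
#' The ICER divides the JOD cost difference by the difference in the
#' complete-response proportion; in reports this value is labelled
#' "JOD per 1\% of CR", following the field's convention for this model.
#'
#' @param intervention,comparator [ce_result()] objects.
#' @return An object of class `incremental_result`: list with
#'   `intervention`, `comparator`, `delta_cost`, `delta_effect`, `icer`,
#'   `dominance`.
#' @export
#' @examples
#' icer(ce_result("BRV", 3925, 0.5771), ce_result("ESL", 4139, 0.2870))
icer <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "ce_result"),
            inherits(comparator, "ce_result"))
  dc <- intervention$cost - comparator$cost
  de <- intervention$effect - comparator$effect
  if (de == 0) {
    stop_foscea(
      sprintf("ICER undefined: %s and %s have equal effectiveness (delta cost %s)",
              intervention$treatment, comparator$treatment,
              if (dc > 0) "positive" else if (dc < 0) "negative" else "zero"),
      "foscea_undefined_icer_error", delta_cost = dc)
  }
  dominance <- if (de > 0) {
    if (dc > 0) "TRADE_OFF_NE" else "SAVING_SE"
  } else {
    if (dc > 0) "DOMINATED" else "TRADE_OFF_SW"
  }
  structure(list(intervention = intervention$treatment,
                 comparator = comparator$treatment,
                 delta_cost = dc, delta_effect = de,
                 icer = dc / de, dominance = dominance),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf(
    "<incremental_result> %s vs %s\n  dCost JOD %.2f, dEffect %.2f%% CR, ICER JOD %.0f per 1%% CR [%s]\n",
    x$intervention, x$comparator, x$delta_cost, 100 * x$delta_effect,
    x$icer, x$dominance))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * effect - cost`. With the willingness-to-pay threshold and
#' the effect on matching scales, for a positive effect difference the
#' intervention's NMB exceeds the comparator's exactly when the pairwise
#' ICER falls below the threshold.
#'
#' @param result A [ce_result()].
#' @param wtp Willingness-to-pay per unit of effect (>= 0).
#' @return NMB in JOD.
#' @export
nmb <- function(result, wtp) {
  stopifnot(inherits(result, "ce_result"))
  assert_scalar_number(wtp, "wtp", lower = 0)
  wtp * result$effect - result$cost
}
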