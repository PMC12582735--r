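# File-writing driver behind the command-line interface: runs the
# deterministic analysis, the PSA, or the CEAC, and writes the CSV outputs.

write_csv_out <- function(df, path) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run an analysis mode end to end and write its outputs
#'
#' Modes:
#' \describe{
#'   \item{`deterministic`}{writes `deterministic_results.csv` (per-treatment
#'     cost and effect joined with the pairwise incremental analysis against
#'     the reference), one `trace_<treatment>.csv` per treatment (cycle,
#'     state, proportion, ever_sf) and one `cost_breakdown_<treatment>.csv`.}
#'   \item{`psa`}{runs the probabilistic sensitivity analysis and writes
#'     `psa_iterations.csv` (full precision), `psa_summary.csv` and
#'     `plane_summary.csv` (quadrant fractions per comparator).}
#'   \item{`ceac`}{runs the PSA and writes `ceac.csv` (one row per
#'     willingness-to-pay value and comparator).}
#' }
#' All outputs are deterministic functions of the configuration and seed.
#'
#' @param cfg A `foscea_config` (or path handled by the CLI).
#' @param mode One of `"deterministic"`, `"psa"`, `"ceac"`.
#' @param out_dir Output directory (created if absent).
#' @param seed Optional seed override for the PSA modes.
#' @param n_iterations Optional iteration-count override.
#' @param wtp_grid Optional willingness-to-pay grid override (ceac mode).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the mode's result object (`cea_results` or
#'   `psa_result`), with the written file paths in attribute `"files"`.
#' @export
run_pipeline <- function(cfg, mode = c("deterministic", "psa", "ceac"),
                         out_dir = ".", seed = NULL, n_iterations = NULL,
                         wtp_grid = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  cfg <- validate_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  files <- character(0)

  if (mode == "deterministic") {
    res <- run_deterministic(cfg)
    det <- merge(res$results, res$incremental,
                 by.x = "treatment", by.y = "comparator", all.x = TRUE)
    det <- det[match(res$results$treatment, det$treatment),
               c("treatment", "cost", "effect", "delta_cost",
                 "delta_effect", "icer", "dominance")]
    det$cost <- round(det$cost, 2)
    det$delta_cost <- round(det$delta_cost, 2)
    det$icer <- round(det$icer)
    files <- c(files, write_csv_out(
      det, file.path(out_dir, "deterministic_results.csv")))
    for (trt in names(res$traces)) {
      files <- c(files, write_csv_out(
        trace_as_df(res$traces[[trt]]),
        file.path(out_dir, sprintf("trace_%s.csv", trt))))
      cm <- with(cfg, build_cost_model(
        treatments[[trt]]$dose, treatments[[trt]]$drug_cost_per_mg$mean,
        unlist(services)[.services], state_bundles,
        treatments[[trt]]$ae_annual, ae_management,
        vapply(ae_drug_cost_per_mg, `[[`, numeric(1), "mean"), ae_accrual))
      files <- c(files, write_csv_out(
        cost_breakdown(res$traces[[trt]], cm, cfg$discount$annual_rate),
        file.path(out_dir, sprintf("cost_breakdown_%s.csv", trt))))
    }
  } else {
    seed_used <- seed %||% cfg$psa$seed
    iters <- n_iterations %||% cfg$psa$n_iterations
    say("PSA: %d iterations, seed %s", iters, format(seed_used))
    res <- run_psa(cfg, n_iterations = iters, seed = seed_used)
    if (mode == "psa") {
      files <- c(files, write_csv_out(
        psa_as_df(res), file.path(out_dir, "psa_iterations.csv")))
      summ <- res$summary
      summ$mean_cost <- round(summ$mean_cost, 2)
      files <- c(files, write_csv_out(
        summ, file.path(out_dir, "psa_summary.csv")))
      plane <- do.call(rbind, lapply(
        setdiff(res$treatments, res$reference), function(cmp) {
          q <- icer_plane_quadrants(res, cmp)
          data.frame(intervention = res$reference, comparator = cmp,
                     NE = q[["NE"]], SE = q[["SE"]], NW = q[["NW"]],
                     SW = q[["SW"]], stringsAsFactors = FALSE)
        }))
      files <- c(files, write_csv_out(
        plane, file.path(out_dir, "plane_summary.csv")))
    } else {
      grid <- wtp_grid %||% cfg$wtp_grid
      files <- c(files, write_csv_out(
        ceac(res, grid), file.path(out_dir, "ceac.csv")))
    }
  }
  say("mode %s finished in %.2fs; wrote %d file(s) to %s", mode,
      as.numeric(difftime(Sys.time(), t0, units = "secs")),
      length(files), out_dir)
  attr(res, "files") <- files
  invisible(res)
}
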