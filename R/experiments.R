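# The three computational experiments: the full SSA injection grid, the
# geometric (radius/length) sensitivity analysis, and the random-rewiring
# robustness ensemble. All are seeded-reproducible; per-draw seeds are
# derived from the experiment seed by one `sample.int` stream so that draws
# are independent and any single draw can be replayed.

derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run the full SSA injection grid
#'
#' Simulates superselective angiography through every feeder at each
#' injection pressure, with and without occlusion of all other feeders
#' (4 feeders x 3 pressures x 2 occlusion modes = 24 conditions by default),
#' and detects the hemodynamic compartment for each condition.
#'
#' @param net A calibrated `avm_network`.
#' @param deltas Injection pressures, mm Hg (study grid: 10, 20, 30).
#' @param measure Response measure passed to [detect_compartment()].
#' @return A tibble with one row per condition: `feeder`,
#'   `injection_delta`, `occlude_others`, `threshold`, `size_pct`,
#'   `mean_dp_pct` (mean response over compartment members),
#'   `bimodality_p`, `degenerate`.
#' @export
run_ssa_grid <- function(net, deltas = c(10, 20, 30), measure = "pmean") {
  stopifnot(inherits(net, "avm_network"))
  grid <- tidyr::expand_grid(
    feeder = names(net$feeders),
    injection_delta = deltas,
    occlude_others = c(FALSE, TRUE)
  )
  purrr::pmap_dfr(grid, function(feeder, injection_delta, occlude_others) {
    ssa <- simulate_ssa(net, feeder, injection_delta, occlude_others)
    cmp <- detect_compartment(ssa, measure = measure)
    tibble::tibble(
      feeder = feeder, injection_delta = injection_delta,
      occlude_others = occlude_others,
      threshold = cmp$threshold, size_pct = cmp$size_pct,
      mean_dp_pct = if (cmp$degenerate) NA_real_ else
        mean(cmp$members$value[cmp$members$member]),
      bimodality_p = as.numeric(cmp$bimodality_p),
      degenerate = cmp$degenerate
    )
  })
}

#' Geometric sensitivity analysis
#'
#' Repeatedly perturbs every vessel's radius and length by up to
#' `rel` (uniform, independent) around the canonical values, re-solves the
#' baseline hemodynamics, and summarises the spread of the nidus statistics
#' across draws.
#'
#' @param net A calibrated `avm_network`.
#' @param n_draws Number of perturbation draws (reference analysis: 1000).
#' @param rel Relative half-width of the uniform perturbation (reference:
#'   0.10, i.e. +/-10%).
#' @param seed Experiment seed.
#' @return An object of class `avm_sensitivity`: list with `draws` (tibble,
#'   one row per successful draw: total nidus flow and per-class flow/drop
#'   statistics), `summary` (tibble of min/max/mean across draws for each
#'   statistic), `n_failed`, and the arguments.
#' @export
run_sensitivity <- function(net, n_draws = 1000, rel = 0.10, seed = 1L) {
  stopifnot(inherits(net, "avm_network"))
  seeds <- derive_seeds(seed, n_draws)
  rows <- vector("list", n_draws)
  n_failed <- 0L
  for (i in seq_len(n_draws)) {
    res <- try({
      pert <- perturb_geometry(net, rel, seeds[i])
      sol <- solve_flows(pert)
      sm <- summarize_nidus(sol, pert)
      px <- sm$stats[sm$stats$class == "plexiform", ]
      fi <- sm$stats[sm$stats$class == "fistulous", ]
      tibble::tibble(
        draw = i, seed = seeds[i],
        total_flow = sm$total_nidus_flow,
        plex_flow_min = px$flow_min, plex_flow_max = px$flow_max,
        plex_flow_mean = px$flow_mean,
        plex_drop_mean = px$drop_mean, plex_drop_max = px$drop_max,
        fist_flow_min = if (nrow(fi)) fi$flow_min else NA_real_,
        fist_flow_max = if (nrow(fi)) fi$flow_max else NA_real_,
        fist_flow_mean = if (nrow(fi)) fi$flow_mean else NA_real_,
        fist_drop_max = if (nrow(fi)) fi$drop_max else NA_real_
      )
    }, silent = TRUE)
    if (inherits(res, "try-error")) n_failed <- n_failed + 1L else rows[[i]] <- res
  }
  draws <- dplyr::bind_rows(rows)
  summary <- draws |>
    dplyr::select(-dplyr::all_of(c("draw", "seed"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "statistic") |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(min = min(.data$value), max = max(.data$value),
                     mean = mean(.data$value), .groups = "drop")
  out <- list(draws = draws, summary = summary, n_draws = n_draws,
              n_failed = n_failed, rel = rel, seed = seed)
  class(out) <- "avm_sensitivity"
  out
}

#' Random-rewiring robustness ensemble
#'
#' Generates `n` variants of the network by rewiring one endpoint of
#' `fraction` of the nidus vessels, then for each variant solves the
#' baseline hemodynamics and runs one SSA condition with compartment
#' detection. A variant whose rewiring cannot be made valid within the
#' retry budget is replaced by a freshly-seeded one (recorded in
#' `n_replaced`), so `n` networks are always analysed.
#'
#' @param net A calibrated `avm_network`.
#' @param n Ensemble size (reference analysis: 100).
#' @param fraction Fraction of nidus vessels rewired per variant
#'   (reference: 0.5).
#' @param seed Experiment seed.
#' @param feeder,injection_delta,occlude_others The SSA condition evaluated
#'   on every variant (reference condition: AF1, 20 mm Hg, others occluded).
#' @param measure Response measure passed to [detect_compartment()].
#' @param alpha Significance level for the mean-separation test.
#' @return An object of class `avm_ensemble`: list with `networks` (tibble,
#'   one row per variant: seed, total flow, per-class flow ranges,
#'   compartment size, bimodality p, significance flag), `frac_significant`,
#'   `n_replaced`, and the arguments.
#' @export
run_rewiring_ensemble <- function(net, n = 100, fraction = 0.5, seed = 1L,
                                  feeder = "AF1", injection_delta = 20,
                                  occlude_others = TRUE, measure = "pmean",
                                  alpha = 0.05) {
  stopifnot(inherits(net, "avm_network"))
  seeds <- derive_seeds(seed, 4L * n)
  rows <- vector("list", n)
  n_replaced <- 0L
  si <- 0L
  for (i in seq_len(n)) {
    row <- NULL
    while (is.null(row) && si < length(seeds)) {
      si <- si + 1L
      row <- try({
        rw <- rewire_nidus(net, fraction, seeds[si])
        sol <- solve_flows(rw)
        sm <- summarize_nidus(sol, rw)
        ssa <- simulate_ssa(rw, feeder, injection_delta, occlude_others)
        cmp <- detect_compartment(ssa, measure = measure)
        px <- sm$stats[sm$stats$class == "plexiform", ]
        fi <- sm$stats[sm$stats$class == "fistulous", ]
        tibble::tibble(
          network = i, seed = seeds[si],
          total_flow = sm$total_nidus_flow,
          plex_flow_max = px$flow_max,
          fist_flow_min = if (nrow(fi)) fi$flow_min else NA_real_,
          fist_flow_max = if (nrow(fi)) fi$flow_max else NA_real_,
          threshold = cmp$threshold, size_pct = cmp$size_pct,
          bimodality_p = as.numeric(cmp$bimodality_p),
          significant = !cmp$degenerate && is.finite(cmp$bimodality_p) &&
            cmp$bimodality_p < alpha
        )
      }, silent = TRUE)
      if (inherits(row, "try-error")) {
        row <- NULL
        n_replaced <- n_replaced + 1L
      }
    }
    if (is.null(row)) {
      stop("rewiring ensemble: seed budget exhausted after repeated failures",
           call. = FALSE)
    }
    rows[[i]] <- row
  }
  networks <- dplyr::bind_rows(rows)
  out <- list(
    networks = networks,
    frac_significant = mean(networks$significant),
    n = n, fraction = fraction, seed = seed, n_replaced = n_replaced,
    feeder = feeder, injection_delta = injection_delta,
    occlude_others = occlude_others, alpha = alpha
  )
  class(out) <- "avm_ensemble"
  out
}

#' @export
print.avm_sensitivity <- function(x, ...) {
  tf <- x$draws$total_flow
  cat("<avm_sensitivity> ", nrow(x$draws), " draws (", x$n_failed,
      " failed), +/-", 100 * x$rel, "% geometry\n", sep = "")
  cat("  total nidus flow range: ", format(min(tf), digits = 4), " - ",
      format(max(tf), digits = 4), " mL/min\n", sep = "")
  invisible(x)
}

#' @export
print.avm_ensemble <- function(x, ...) {
  cat("<avm_ensemble> ", x$n, " rewired networks (fraction ", x$fraction,
      "), SSA ", x$feeder, " +", x$injection_delta, " mm Hg",
      if (x$occlude_others) ", others occluded", "\n", sep = "")
  cat("  total nidus flow: ", format(min(x$networks$total_flow), digits = 4),
      " - ", format(max(x$networks$total_flow), digits = 4), " mL/min\n",
      "  significant bimodality: ", 100 * x$frac_significant, "% of networks\n",
      sep = "")
  invisible(x)
}
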