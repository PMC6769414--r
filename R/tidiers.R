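# broom-style tidiers: tidy() returns the per-unit table of a result,
# glance() a one-row summary.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flow solution
#'
#' @param x An `avm_flow`.
#' @param ... Unused.
#' @return One row per vessel: id, class, flow (mL/min), drop (mm Hg),
#'   resistance (dyn s/cm^5), occluded.
#' @export
tidy.avm_flow <- function(x, ...) x$vessels

#' @rdname tidy.avm_flow
#' @export
glance.avm_flow <- function(x, ...) {
  tibble::tibble(total_flow = x$total_flow, residual = x$residual,
                 n_vessels = nrow(x$vessels), n_nodes = nrow(x$nodes))
}

#' Tidy an SSA result
#'
#' @param x An `avm_ssa`.
#' @param ... Unused.
#' @return The per-nidus-vessel delta table.
#' @export
tidy.avm_ssa <- function(x, ...) x$deltas

#' @rdname tidy.avm_ssa
#' @export
glance.avm_ssa <- function(x, ...) {
  tibble::tibble(
    feeder = x$feeder, injection_delta = x$injection_delta,
    occlude_others = x$occlude_others,
    median_dp_pct = stats::median(x$deltas$delta_p_pct),
    max_dp_abs = max(x$deltas$delta_p_abs),
    n_guarded = sum(x$deltas$guarded)
  )
}

#' Tidy a compartment result
#'
#' @param x An `avm_compartments`.
#' @param ... Unused.
#' @return One row per nidus vessel: id, class, response value, membership.
#' @export
tidy.avm_compartments <- function(x, ...) x$members

#' @rdname tidy.avm_compartments
#' @export
glance.avm_compartments <- function(x, ...) {
  tibble::tibble(
    feeder = x$feeder, injection_delta = x$injection_delta,
    occlude_others = x$occlude_others, measure = x$measure,
    threshold = x$threshold, size_pct = x$size_pct,
    bimodality_p = as.numeric(x$bimodality_p), degenerate = x$degenerate
  )
}

#' Tidy a sensitivity experiment
#'
#' @param x An `avm_sensitivity`.
#' @param ... Unused.
#' @return One row per draw.
#' @export
tidy.avm_sensitivity <- function(x, ...) x$draws

#' @rdname tidy.avm_sensitivity
#' @export
glance.avm_sensitivity <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws, n_failed = x$n_failed, rel = x$rel,
    total_flow_min = min(x$draws$total_flow),
    total_flow_max = max(x$draws$total_flow)
  )
}

#' Tidy a rewiring ensemble
#'
#' @param x An `avm_ensemble`.
#' @param ... Unused.
#' @return One row per rewired network.
#' @export
tidy.avm_ensemble <- function(x, ...) x$networks

#' @rdname tidy.avm_ensemble
#' @export
glance.avm_ensemble <- function(x, ...) {
  tibble::tibble(
    n = x$n, fraction = x$fraction, n_replaced = x$n_replaced,
    frac_significant = x$frac_significant,
    total_flow_min = min(x$networks$total_flow),
    total_flow_max = max(x$networks$total_flow),
    size_pct_min = min(x$networks$size_pct, na.rm = TRUE),
    size_pct_max = max(x$networks$size_pct, na.rm = TRUE)
  )
}
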