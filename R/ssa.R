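# Superselective angiography (SSA): an injection pressure increment added in
# series with one arterial feeder, optionally with all other feeders
# occluded, compared vessel-by-vessel against the uninjected baseline.

#' Simulate superselective angiography at one feeder
#'
#' Models a microcatheter contrast injection as a forced elevation of the
#' intravascular pressure within the injected feeder: the feeder inlet is
#' held (as a boundary condition) at its uninjected pressure plus
#' `injection_delta`, the pressure a microcatheter injection superimposes on
#' the arterial inflow. `method = "emf"` instead places an ideal series
#' pressure source of `injection_delta` in the feeder branch behind the
#' systemic tree; the tree impedance then absorbs most of the boost, so the
#' effective pressure rise at the feeder is much smaller than
#' `injection_delta`. The comparison baseline is the uninjected network in
#' the same occlusion state (see `baseline`). For every nidus vessel the
#' result carries:
#'
#' * `pmean`: mean intravascular pressure, the average of the two endpoint
#'   node pressures (mm Hg), at baseline and under injection;
#' * `delta_p_abs` / `delta_p_pct`: change in `pmean`, absolute (mm Hg) and
#'   percent of baseline — the quantity the compartment analysis thresholds;
#' * `delta_drop_pct`, `delta_flow_pct`: percent change of the absolute
#'   pressure drop across the vessel and of the absolute flow.
#'
#' Percent changes are guarded: where the baseline magnitude is below
#' `eps` the denominator is clamped to `eps` and the vessel is flagged
#' (`guarded`); the absolute map is authoritative for flagged vessels.
#'
#' @param net An `avm_network` with the injected feeder patent.
#' @param feeder Feeder name (e.g. `"AF1"`).
#' @param injection_delta Injection pressure increment, mm Hg (> 0 for a real
#'   injection; 0 is allowed and yields identically zero delta maps when
#'   nothing is occluded). The reference study grid is 10, 20, 30 mm Hg.
#' @param occlude_others If `TRUE`, all other feeders are occluded in the
#'   injected solve.
#' @param baseline How the comparison baseline treats occlusion:
#'   `"matched"` (default) solves the same occlusion state without the
#'   injection, so the delta maps isolate the injection response and every
#'   node's pressure change is non-negative (maximum principle);
#'   `"patent"` always compares against the fully patent uninjected
#'   network, mixing the occlusion effect into the deltas.
#' @param method `"pressure"` (default) pins the feeder inlet at
#'   baseline + delta; `"emf"` uses a series pressure source in the feeder
#'   branch.
#' @param eps Denominator guard for percent maps.
#' @return An object of class `avm_ssa`: list with `baseline` and `injected`
#'   [solve_flows()] solutions, a `deltas` tibble over nidus vessels, a
#'   `node_delta` tibble of per-node pressure changes, and the configuration.
#' @export
simulate_ssa <- function(net, feeder, injection_delta,
                         occlude_others = FALSE,
                         baseline = c("matched", "patent"),
                         method = c("pressure", "emf"), eps = 1e-6) {
  baseline <- match.arg(baseline)
  method <- match.arg(method)
  stopifnot(inherits(net, "avm_network"))
  if (injection_delta < 0) {
    stop("`injection_delta` must be non-negative", call. = FALSE)
  }
  fid <- net$feeders[match(feeder, names(net$feeders))]
  if (is.na(fid)) fid <- net$feeders[match(feeder, net$feeders)]
  if (is.na(fid)) stop("unknown feeder: ", feeder, call. = FALSE)
  if (net$vessels$occluded[net$vessels$id == fid]) {
    stop("cannot inject an occluded feeder: ", feeder, call. = FALSE)
  }

  base_net <- net
  if (occlude_others) {
    others <- setdiff(names(net$feeders), names(net$feeders)[net$feeders == fid])
    if (baseline == "matched") base_net <- occlude_feeders(base_net, others)
  }
  base_sol <- solve_flows(base_net)

  inj_net <- net
  if (occlude_others) {
    others <- setdiff(names(net$feeders), names(net$feeders)[net$feeders == fid])
    inj_net <- occlude_feeders(inj_net, others)
  }
  if (method == "emf") {
    inj_net$vessels$emf[inj_net$vessels$id == fid] <- injection_delta
    injected <- solve_flows(inj_net)
  } else {
    inlet <- net$vessels$tail[net$vessels$id == fid]
    p_inlet <- base_sol$nodes$pressure[base_sol$nodes$id == inlet]
    pin <- stats::setNames(p_inlet + injection_delta, inlet)
    injected <- solve_flows(inj_net, pins = pin)
  }

  nidus <- net$vessels$class %in% c("plexiform", "fistulous")
  vb <- base_sol$vessels[nidus, ]
  vi <- injected$vessels[nidus, ]
  pb <- stats::setNames(base_sol$nodes$pressure, base_sol$nodes$id)
  pi_ <- stats::setNames(injected$nodes$pressure, injected$nodes$id)
  tails <- net$vessels$tail[nidus]
  heads <- net$vessels$head[nidus]

  pmean_base <- (pb[tails] + pb[heads]) / 2
  pmean_inj <- (pi_[tails] + pi_[heads]) / 2

  pct <- function(now, base) {
    100 * (now - base) / pmax(abs(base), eps)
  }
  deltas <- tibble::tibble(
    id = vb$id, class = vb$class,
    pmean_base = unname(pmean_base), pmean_inj = unname(pmean_inj),
    delta_p_abs = unname(pmean_inj - pmean_base),
    delta_p_pct = unname(pct(pmean_inj, pmean_base)),
    drop_base = abs(vb$drop), drop_inj = abs(vi$drop),
    delta_drop_pct = pct(abs(vi$drop), abs(vb$drop)),
    flow_base = abs(vb$flow), flow_inj = abs(vi$flow),
    delta_flow_pct = pct(abs(vi$flow), abs(vb$flow)),
    guarded = abs(pmean_base) < eps | abs(vb$drop) < eps | abs(vb$flow) < eps
  )
  node_delta <- tibble::tibble(
    id = names(pb),
    delta_p = unname(pi_[names(pb)] - pb)
  )
  out <- list(
    baseline = base_sol, injected = injected, baseline_mode = baseline,
    deltas = deltas, node_delta = node_delta,
    feeder = names(net$feeders)[net$feeders == fid],
    injection_delta = injection_delta, occlude_others = occlude_others
  )
  class(out) <- "avm_ssa"
  out
}

#' @export
print.avm_ssa <- function(x, ...) {
  cat("<avm_ssa> ", x$feeder, " +", x$injection_delta, " mm Hg",
      if (x$occlude_others) ", other feeders occluded", "\n", sep = "")
  cat("  nidus vessels:", nrow(x$deltas), "\n")
  cat("  median nidus dP%:", format(stats::median(x$deltas$delta_p_pct),
                                    digits = 4), "\n")
  invisible(x)
}
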