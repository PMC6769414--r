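# Steady-flow solver: Hagen-Poiseuille resistances + Kirchhoff nodal analysis.
# Internal units are CGS (dyn, cm, s); pressures are reported in mm Hg and
# flows in mL/min.

#' Unit conversion constants
#'
#' 1 mm Hg = 1333.22 dyn/cm^2; 1 cm^3/s = 60 mL/min; 1 poise = 100 cP.
#' @keywords internal
#' @name units
NULL

MMHG_TO_DYN <- 1333.22
CM3S_TO_MLMIN <- 60

#' Hydraulic resistance of a cylindrical vessel
#'
#' Poiseuille resistance \eqn{R_v = 8 L \eta / (\pi r^4)} in CGS units
#' (dyn s / cm^5). Viscosity is given in centiPoise and converted to poise
#' internally.
#'
#' @param radius Inner radius in cm (> 0).
#' @param length Effective length in cm (>= 0); tortuosity is assumed folded
#'   into the length.
#' @param viscosity Dynamic viscosity in centiPoise (> 0). Default 3.5 cP,
#'   a typical value for whole blood.
#' @return Resistance in dyn s / cm^5 (vectorised over its arguments).
#' @examples
#' vessel_resistance(0.05, 5.0, 3.5) # ~7.13e4, a plexiform nidus vessel
#' @export
vessel_resistance <- function(radius, length, viscosity = 3.5) {
  if (any(radius <= 0)) stop("`radius` must be positive", call. = FALSE)
  if (any(length < 0)) stop("`length` must be non-negative", call. = FALSE)
  if (any(viscosity <= 0)) stop("`viscosity` must be positive", call. = FALSE)
  8 * length * (viscosity / 100) / (pi * radius^4)
}

#' Solve the steady Kirchhoff flow system of a vascular network
#'
#' Treats the network as a resistive electrical circuit (flow = current,
#' pressure = voltage, Poiseuille resistance = resistance) and solves for all
#' node pressures by sparse nodal analysis: flow conservation at every
#' non-boundary node, with the pressure-source and pressure-sink nodes held at
#' their boundary values. Loop (pressure) law satisfaction follows by
#' construction since pressures are the unknowns.
#'
#' Occluded vessels are removed from the system entirely (infinite
#' resistance) and carry exactly zero flow. A vessel may carry a series
#' pressure boost (`emf`, in mm Hg), used to model superselective-angiography
#' injections; for such a vessel the reported `drop` is the pressure
#' difference across its resistive element, `P[tail] + emf - P[head]`, so
#' that `flow = drop / R` holds for every patent vessel.
#'
#' @param net An `avm_network`.
#' @param pins Optional named numeric vector of additional Dirichlet
#'   constraints: node id -> pressure (mm Hg). Used to impose a
#'   superselective-injection pressure at a feeder inlet.
#' @return An object of class `avm_flow`: a list with
#'   * `vessels`: tibble with per-vessel `flow` (mL/min, signed positive
#'     tail to head), `drop` (mm Hg, across the resistive element) and
#'     `resistance` (dyn s/cm^5),
#'   * `nodes`: tibble of node pressures (mm Hg; `NA` for nodes whose
#'     incident vessels are all occluded),
#'   * `residual`: maximum absolute node flow-conservation violation, mL/min,
#'   * `total_flow`: source-to-sink throughput, mL/min.
#' @export
solve_flows <- function(net, pins = NULL) {
  stopifnot(inherits(net, "avm_network"))
  nodes <- net$nodes
  ves <- net$vessels
  nn <- nrow(nodes)
  node_index <- stats::setNames(seq_len(nn), nodes$id)

  patent <- !ves$occluded
  vp <- ves[patent, , drop = FALSE]
  if (nrow(vp) == 0L) stop("network has no patent vessels", call. = FALSE)

  g <- 1 / vessel_resistance(vp$radius, vp$length, net$boundary$viscosity)
  it <- node_index[vp$tail]
  ih <- node_index[vp$head]

  src <- which(nodes$role == "pressure-source")
  snk <- which(nodes$role == "pressure-sink")
  if (length(src) != 1L || length(snk) != 1L) {
    stop("network must have exactly one pressure-source and one pressure-sink node",
         call. = FALSE)
  }
  dirichlet <- c(src, snk)
  p_bound <- c(net$boundary$source_pressure, net$boundary$sink_pressure) * MMHG_TO_DYN
  if (!is.null(pins)) {
    pidx <- node_index[names(pins)]
    if (anyNA(pidx)) {
      stop("pinned node(s) not in network: ",
           paste(names(pins)[is.na(pidx)], collapse = ", "), call. = FALSE)
    }
    dirichlet <- c(dirichlet, unname(pidx))
    p_bound <- c(p_bound, unname(pins) * MMHG_TO_DYN)
  }

  # Connected components of the patent graph: every component that contains a
  # vessel must also contain a pressure anchor, otherwise its pressures are
  # indeterminate and the system is singular.
  comp <- patent_components(nn, it, ih)
  active <- sort(unique(c(it, ih)))
  bad <- setdiff(unique(comp[active]), comp[dirichlet])
  if (length(bad) > 0L) {
    iso <- nodes$id[comp %in% bad]
    stop("singular system: component(s) with no boundary pressure anchor: ",
         paste(utils::head(iso, 10L), collapse = ", "), call. = FALSE)
  }

  emf <- vp$emf * MMHG_TO_DYN

  free <- setdiff(active, dirichlet)
  pressure <- rep(NA_real_, nn)
  pressure[dirichlet] <- p_bound

  if (length(free) > 0L) {
    pos <- rep(NA_integer_, nn)
    pos[free] <- seq_along(free)
    # Laplacian over free nodes; Dirichlet and emf terms move to the RHS.
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    b <- numeric(length(free))
    ft <- pos[it]; fh <- pos[ih]
    tfree <- !is.na(ft); hfree <- !is.na(fh)

    trip_i <- c(ft[tfree], fh[hfree], ft[tfree & hfree], fh[tfree & hfree])
    trip_j <- c(ft[tfree], fh[hfree], fh[tfree & hfree], ft[tfree & hfree])
    trip_x <- c(g[tfree], g[hfree], -g[tfree & hfree], -g[tfree & hfree])

    # RHS: emf contribution (Q = g (P_tail + e - P_head) adds +g*e into the
    # head's balance, -g*e into the tail's) and Dirichlet neighbours. Looped
    # because indexed assignment would not accumulate over repeated nodes.
    for (k in seq_along(g)) {
      if (tfree[k]) {
        b[ft[k]] <- b[ft[k]] - g[k] * emf[k]
        if (!hfree[k]) b[ft[k]] <- b[ft[k]] + g[k] * pressure[ih[k]]
      }
      if (hfree[k]) {
        b[fh[k]] <- b[fh[k]] + g[k] * emf[k]
        if (!tfree[k]) b[fh[k]] <- b[fh[k]] + g[k] * pressure[it[k]]
      }
    }

    A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(length(free), length(free)))
    p_free <- as.numeric(Matrix::solve(A, b))
    pressure[free] <- p_free
  }

  q <- g * (pressure[it] + emf - pressure[ih]) # cm^3/s
  flow <- numeric(nrow(ves))
  flow[patent] <- q
  drop_cgs <- numeric(nrow(ves))
  drop_cgs[patent] <- pressure[it] + emf - pressure[ih]

  # conservation residual over non-boundary active nodes
  net_in <- numeric(nn)
  for (k in seq_along(q)) {
    net_in[it[k]] <- net_in[it[k]] - q[k]
    net_in[ih[k]] <- net_in[ih[k]] + q[k]
  }
  interior <- setdiff(active, dirichlet)
  residual <- if (length(interior)) max(abs(net_in[interior])) else 0

  total_flow <- -net_in[src] # outflow from the source node, cm^3/s

  res <- vessel_resistance(ves$radius, ves$length, net$boundary$viscosity)
  out <- list(
    vessels = tibble::tibble(
      id = ves$id, class = ves$class,
      flow = flow * CM3S_TO_MLMIN,
      drop = drop_cgs / MMHG_TO_DYN,
      resistance = res,
      occluded = ves$occluded
    ),
    nodes = tibble::tibble(
      id = nodes$id, role = nodes$role,
      pressure = pressure / MMHG_TO_DYN
    ),
    residual = residual * CM3S_TO_MLMIN,
    total_flow = total_flow * CM3S_TO_MLMIN
  )
  class(out) <- "avm_flow"
  out
}

# integer connected components over an edge list (union-find)
patent_components <- function(n, it, ih) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(it)) {
    a <- find(it[k]); b <- find(ih[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Summarise nidus hemodynamics of a flow solution
#'
#' Total nidus throughput (sum of arterial-feeder inflows) and per-class
#' (plexiform, fistulous) statistics of absolute vessel flow and pressure
#' drop.
#'
#' @param sol An `avm_flow` from [solve_flows()].
#' @param net The `avm_network` the solution was computed on.
#' @return A list of class `avm_nidus_summary` with `total_nidus_flow`
#'   (mL/min) and a `stats` tibble (one row per vessel class, min/max/mean of
#'   |flow| in mL/min and |drop| in mm Hg).
#' @export
summarize_nidus <- function(sol, net) {
  stopifnot(inherits(sol, "avm_flow"), inherits(net, "avm_network"))
  v <- sol$vessels
  feeder_flow <- v$flow[match(net$feeders, v$id)]
  total <- sum(feeder_flow) # feeders are oriented arterial side -> nidus

  nid <- dplyr::filter(v, .data$class %in% c("plexiform", "fistulous"))
  stats_tbl <- nid |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      flow_min = min(abs(.data$flow)), flow_max = max(abs(.data$flow)),
      flow_mean = mean(abs(.data$flow)),
      drop_min = min(abs(.data$drop)), drop_max = max(abs(.data$drop)),
      drop_mean = mean(abs(.data$drop)),
      .groups = "drop"
    )
  out <- list(total_nidus_flow = total, stats = stats_tbl)
  class(out) <- "avm_nidus_summary"
  out
}

#' @export
print.avm_flow <- function(x, ...) {
  cat("<avm_flow> ", nrow(x$vessels), " vessels, ", nrow(x$nodes), " nodes\n",
      "  total source-to-sink flow: ", format(x$total_flow, digits = 5),
      " mL/min\n",
      "  conservation residual: ", format(x$residual, digits = 3),
      " mL/min\n", sep = "")
  invisible(x)
}

#' @export
print.avm_nidus_summary <- function(x, ...) {
  cat("<avm_nidus_summary> total nidus flow:",
      format(x$total_nidus_flow, digits = 5), "mL/min\n")
  print(x$stats)
  invisible(x)
}
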