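# Construction, validation and perturbation of the AVM vascular network:
# an extranidal arterial/venous tree around a 3-D nidus of 97 interconnected
# plexiform and fistulous vessels fed by four arterial feeders (AF1-AF4) and
# drained by three veins (DV1-DV3).

VESSEL_CLASSES <- c("systemic-artery", "feeder", "plexiform", "fistulous",
                    "drainer", "systemic-vein")
NODE_ROLES <- c("pressure-source", "arterial", "nidus", "venous",
                "pressure-sink")

#' Boundary pressure conditions
#'
#' Mean pressures anchoring the extranidal circulation, in mm Hg, and the
#' blood viscosity in centiPoise. Defaults are literature means for a large
#' cerebral AVM: systemic 74, major feeder 47, minor feeder 50, draining vein
#' 17, central venous pressure 5 mm Hg; viscosity 3.5 cP.
#'
#' @param source_pressure Systemic (source) pressure, mm Hg.
#' @param sink_pressure Central venous (sink) pressure, mm Hg.
#' @param major_feeder_pressure Target pressure at major feeder inlets (AF1,
#'   AF2), mm Hg.
#' @param minor_feeder_pressure Target pressure at minor feeder inlets (AF3,
#'   AF4), mm Hg.
#' @param drainer_pressure Target pressure at draining-vein outlets, mm Hg.
#' @param viscosity Blood viscosity, cP.
#' @return A list of class `avm_boundary`.
#' @export
boundary_conditions <- function(source_pressure = 74, sink_pressure = 5,
                                major_feeder_pressure = 47,
                                minor_feeder_pressure = 50,
                                drainer_pressure = 17, viscosity = 3.5) {
  feeders <- c(major_feeder_pressure, minor_feeder_pressure)
  if (!(source_pressure > max(feeders) && min(feeders) > drainer_pressure &&
        drainer_pressure > sink_pressure && sink_pressure >= 0)) {
    stop("boundary pressures must satisfy source > feeders > drainer > sink >= 0",
         call. = FALSE)
  }
  if (viscosity <= 0) stop("`viscosity` must be positive", call. = FALSE)
  structure(list(
    source_pressure = source_pressure, sink_pressure = sink_pressure,
    major_feeder_pressure = major_feeder_pressure,
    minor_feeder_pressure = minor_feeder_pressure,
    drainer_pressure = drainer_pressure, viscosity = viscosity
  ), class = "avm_boundary")
}

#' Nidus generator configuration
#'
#' Parameters of the seeded generative procedure that realises the canonical
#' 97-vessel nidus: 93 plexiform vessels (radius 0.05 cm, effective length
#' 5.0 cm, tortuosity folded in) and a 4-segment fistula (radius 0.10 cm,
#' segment length 4.0 cm) running from AF2's entry to DV2's exit. The
#' canonical `seed` and `feeder_supply_fractions` are calibration constants
#' of the model: together with the interior-node count and long-range edge
#' fraction they fix the realised angioarchitecture.
#'
#' @param n_plexiform Number of plexiform vessels.
#' @param n_fistulous Number of fistulous vessels (a simple AF2-to-DV2 path).
#' @param plexiform_radius,plexiform_length Plexiform geometry, cm.
#' @param fistula_radius,fistula_segment_length Fistulous geometry, cm.
#' @param n_feeders,n_drainers Number of arterial feeders / draining veins.
#' @param feeder_supply_fractions Per-feeder share of nidus entry
#'   connectivity (positive; normalised internally). This is the knob that
#'   sets how much of the nidus each feeder supplies, and thereby the
#'   compartment size seen on superselective angiography.
#' @param n_interior Number of interior nidus nodes (between the feeder entry
#'   and drainer exit nodes).
#' @param long_range_frac Fraction of interior plexiform vessels drawn
#'   uniformly at random (long-range, 3-D shortcut edges) rather than between
#'   spatial near-neighbours.
#' @param entry_frac,exit_frac Fraction of plexiform vessels attached to
#'   feeder entry nodes (supply spokes) / drainer exit nodes (drainage
#'   bridges).
#' @param n_fistula_branches Number of plexiform branch vessels attached to
#'   the fistula-path nodes.
#' @param locality Spatial decay scale (cube units) of the near-neighbour
#'   edge sampling; smaller values give tighter local wiring.
#' @param feeder_radius,drainer_radius Radii (cm) of the feeder and drainer
#'   vessels connecting the nidus to the extranidal circulation.
#' @param seed RNG seed fixing the realisation.
#' @return A list of class `avm_nidus_config`.
#' @export
nidus_config <- function(n_plexiform = 93, n_fistulous = 4,
                         plexiform_radius = 0.05, plexiform_length = 5.0,
                         fistula_radius = 0.10, fistula_segment_length = 4.0,
                         n_feeders = 4, n_drainers = 3,
                         feeder_supply_fractions = c(7, 9, 24, 5) / 45,
                         n_interior = 24, long_range_frac = 0.149,
                         entry_frac = 45 / 93, exit_frac = 29 / 93,
                         n_fistula_branches = 9, locality = 0.226,
                         feeder_radius = 0.162, drainer_radius = 0.20,
                         seed = 1661L) {
  if (n_plexiform < 0 || n_fistulous < 0) {
    stop("vessel counts must be non-negative", call. = FALSE)
  }
  if (n_fistulous > 0 && n_fistulous < 2) {
    stop("a fistula needs at least 2 segments (entry to exit)", call. = FALSE)
  }
  if (length(feeder_supply_fractions) != n_feeders ||
      any(feeder_supply_fractions <= 0)) {
    stop("`feeder_supply_fractions` needs one positive entry per feeder",
         call. = FALSE)
  }
  structure(list(
    n_plexiform = as.integer(n_plexiform),
    n_fistulous = as.integer(n_fistulous),
    plexiform_radius = plexiform_radius, plexiform_length = plexiform_length,
    fistula_radius = fistula_radius,
    fistula_segment_length = fistula_segment_length,
    n_feeders = as.integer(n_feeders), n_drainers = as.integer(n_drainers),
    feeder_supply_fractions = feeder_supply_fractions /
      sum(feeder_supply_fractions),
    n_interior = as.integer(n_interior), long_range_frac = long_range_frac,
    entry_frac = entry_frac, exit_frac = exit_frac,
    n_fistula_branches = as.integer(n_fistula_branches), locality = locality,
    feeder_radius = feeder_radius, drainer_radius = drainer_radius,
    seed = as.integer(seed)
  ), class = "avm_nidus_config")
}

new_avm_network <- function(nodes, vessels, boundary, feeders, drainers,
                            config = NULL) {
  structure(list(nodes = nodes, vessels = vessels, boundary = boundary,
                 feeders = feeders, drainers = drainers, config = config),
            class = "avm_network")
}

#' @export
print.avm_network <- function(x, ...) {
  cls <- table(x$vessels$class)
  cat("<avm_network> ", nrow(x$nodes), " nodes, ", nrow(x$vessels),
      " vessels\n  ", sep = "")
  cat(paste0(names(cls), ": ", as.integer(cls), collapse = ", "), "\n")
  if (any(x$vessels$occluded)) {
    cat("  occluded:", paste(x$vessels$id[x$vessels$occluded], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Build the canonical AVM network
#'
#' Constructs the full circuit: a fixed extranidal arterial tree (subclavian,
#' carotid, vertebral and cerebral artery segments) from the pressure source
#' to four arterial-feeder inlets, a seeded 3-D nidus realisation, three
#' draining veins collecting into a venous sinus at the central-venous sink,
#' then calibrates the terminal extranidal segments so the baseline solve
#' reproduces the target feeder and drainer pressures (see
#' [calibrate_extranidal()]).
#'
#' The nidus realisation places interior nodes in a unit cube between an
#' arterial face (feeder entry nodes) and a venous face (drainer exit
#' nodes), lays the fistula as a simple path from AF2's entry to DV2's exit,
#' attaches plexiform vessels to feeder entries in proportion to
#' `feeder_supply_fractions`, and connects the remainder between spatial
#' near-neighbours with a fraction of uniformly random long-range edges.
#' The same config (including seed) always yields the identical network.
#'
#' @param config An [nidus_config()].
#' @param boundary A [boundary_conditions()].
#' @param calibrate If `TRUE` (default), run [calibrate_extranidal()] before
#'   returning.
#' @return A calibrated `avm_network`.
#' @export
build_canonical_network <- function(config = nidus_config(),
                                    boundary = boundary_conditions(),
                                    calibrate = TRUE) {
  stopifnot(inherits(config, "avm_nidus_config"),
            inherits(boundary, "avm_boundary"))
  net <- with_local_seed(config$seed, build_network_realization(config, boundary))
  if (calibrate) net <- calibrate_extranidal(net) else net
}

# run expr under a private RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

build_network_realization <- function(config, boundary) {
  nf <- config$n_feeders
  nd <- config$n_drainers
  if (nf < 1 || nd < 1) stop("need at least one feeder and one drainer",
                             call. = FALSE)

  # ---- extranidal arterial tree (fixed geometry, calibrated later) --------
  # E -> SCA -> {CCA, VA}; CCA -> {ICA, ECA}; ICA -> {ACA, MCA}; VA -> PCA.
  # Feeder inlets: AF1 <- ACA, AF2 <- MCA (major); AF3 <- PCA, AF4 <- ECA
  # (minor). Extra feeders beyond four branch off the MCA.
  art_nodes <- tibble::tibble(
    id = c("E", "SCA", "CCA", "VA", "ICA", "ECA", "ACA", "MCA", "PCA"),
    role = c("pressure-source", rep("arterial", 8)),
    x = c(-4, -3.5, -3, -3, -2.5, -2.5, -2, -2, -2),
    y = c(0.5, 0.5, 0.3, 0.7, 0.25, 0.05, 0.3, 0.7, 0.6),
    z = c(0.5, 0.5, 0.4, 0.7, 0.35, 0.9, 0.2, 0.35, 0.8)
  )
  art_edges <- tibble::tribble(
    ~tail, ~head, ~radius, ~length,
    "E",   "SCA", 0.40, 5,
    "SCA", "CCA", 0.30, 10,
    "SCA", "VA",  0.15, 15,
    "CCA", "ICA", 0.20, 10,
    "CCA", "ECA", 0.15, 10,
    "ICA", "ACA", 0.12, 8,
    "ICA", "MCA", 0.14, 8,
    "VA",  "PCA", 0.12, 8
  )
  feeder_parents <- c("ACA", "MCA", "PCA", "ECA")
  if (nf > 4) feeder_parents <- c(feeder_parents, rep("MCA", nf - 4))
  feeder_parents <- feeder_parents[seq_len(nf)]

  af_names <- paste0("AF", seq_len(nf))
  inlet_ids <- paste0(af_names, "in")
  # terminal (calibrated) artery segments into each feeder inlet
  term_art <- tibble::tibble(
    tail = feeder_parents, head = inlet_ids, radius = 0.10, length = 6
  )

  # feeder inlet anchor positions on the arterial face of the nidus cube
  entry_anchor <- cbind(
    x = rep(0, 4), y = c(0.22, 0.78, 0.5, 0.08), z = c(0.25, 0.25, 0.85, 0.8)
  )
  if (nf > 4) {
    entry_anchor <- rbind(entry_anchor,
                          cbind(x = 0, y = stats::runif(nf - 4),
                                z = stats::runif(nf - 4)))
  }
  entry_anchor <- entry_anchor[seq_len(nf), , drop = FALSE]
  inlet_nodes <- tibble::tibble(
    id = inlet_ids, role = "arterial",
    x = -0.8, y = entry_anchor[, 2], z = entry_anchor[, 3]
  )

  # ---- venous side --------------------------------------------------------
  dv_names <- paste0("DV", seq_len(nd))
  outlet_ids <- paste0(dv_names, "out")
  exit_anchor <- cbind(x = rep(1, 3), y = c(0.25, 0.78, 0.5),
                       z = c(0.3, 0.3, 0.85))
  if (nd > 3) {
    exit_anchor <- rbind(exit_anchor,
                         cbind(x = 1, y = stats::runif(nd - 3),
                               z = stats::runif(nd - 3)))
  }
  exit_anchor <- exit_anchor[seq_len(nd), , drop = FALSE]
  ven_nodes <- tibble::tibble(
    id = c(outlet_ids, "VS", "CVP"),
    role = c(rep("venous", nd), "venous", "pressure-sink"),
    x = c(rep(1.8, nd), 2.6, 3.2),
    y = c(exit_anchor[, 2], 0.5, 0.5),
    z = c(exit_anchor[, 3], 0.5, 0.5)
  )
  # terminal (calibrated) vein segments DVout -> VS, plus fixed VS -> CVP
  term_ven <- tibble::tibble(tail = outlet_ids, head = "VS",
                             radius = 0.20, length = 4)
  sinus <- tibble::tibble(tail = "VS", head = "CVP", radius = 0.40, length = 8)

  # ---- nidus nodes --------------------------------------------------------
  entry_ids <- paste0("NE", seq_len(nf))
  exit_ids <- paste0("NX", seq_len(nd))
  entry_nodes <- tibble::tibble(
    id = entry_ids, role = "nidus",
    x = 0, y = entry_anchor[, 2], z = entry_anchor[, 3]
  )
  exit_nodes <- tibble::tibble(
    id = exit_ids, role = "nidus",
    x = 1, y = exit_anchor[, 2], z = exit_anchor[, 3]
  )

  n_int <- config$n_interior
  int_ids <- paste0("N", seq_len(n_int))
  # interior cloud is densest at the nidus core and thins toward the
  # periphery, so near-neighbour wiring gives the core the tightest mesh
  clamp01 <- function(v) pmin(pmax(v, 0.04), 0.96)
  int_nodes <- tibble::tibble(
    id = int_ids, role = "nidus",
    x = clamp01(stats::rnorm(n_int, 0.5, 0.22)),
    y = clamp01(stats::rnorm(n_int, 0.5, 0.22)),
    z = clamp01(stats::rnorm(n_int, 0.5, 0.22))
  )

  # fistula path nodes along the AF2-entry -> DV2-exit line
  n_fist <- config$n_fistulous
  fist_vessels <- NULL
  fist_nodes <- NULL
  if (n_fist > 0) {
    if (nf < 2 || nd < 2) {
      stop("fistula requires at least 2 feeders and 2 drainers (AF2 -> DV2)",
           call. = FALSE)
    }
    n_mid <- n_fist - 1L
    tt <- seq_len(n_mid) / n_fist
    p0 <- c(0, entry_anchor[2, 2], entry_anchor[2, 3])
    p1 <- c(1, exit_anchor[2, 2], exit_anchor[2, 3])
    fist_ids <- paste0("F", seq_len(n_mid))
    fist_nodes <- tibble::tibble(
      id = fist_ids, role = "nidus",
      x = p0[1] + tt * (p1[1] - p0[1]) + stats::runif(n_mid, -0.03, 0.03),
      y = p0[2] + tt * (p1[2] - p0[2]) + stats::runif(n_mid, -0.03, 0.03),
      z = p0[3] + tt * (p1[3] - p0[3]) + stats::runif(n_mid, -0.03, 0.03)
    )
    path <- c("NE2", fist_ids, "NX2")
    fist_vessels <- tibble::tibble(
      id = paste0("fist", seq_len(n_fist)),
      tail = path[-length(path)], head = path[-1],
      class = "fistulous",
      radius = config$fistula_radius,
      length = config$fistula_segment_length
    )
  }

  nidus_nodes <- dplyr::bind_rows(entry_nodes, fist_nodes, int_nodes,
                                  exit_nodes)
  ring_ids <- c(int_ids, if (n_fist > 1) fist_nodes$id) # branch points

  # ---- plexiform vessels --------------------------------------------------
  # Architecture: each feeder directly supplies a spatial "ball" of interior
  # nodes around its territory anchor (one spoke edge per supplied node;
  # ball sizes set by the supply fractions). Balls of different feeders
  # overlap, which is what makes SSA compartments overlap. Interior nodes
  # are cross-linked by predominantly short-range edges (with a long-range
  # 3-D shortcut fraction), giving each territory a densely wired core, and
  # drainage runs through a bridge-edge budget into the three exit nodes.
  npx <- config$n_plexiform
  n_spoke <- round(config$entry_frac * npx)
  n_bridge <- round(config$exit_frac * npx)
  m_ball <- pmax(1L, round(config$feeder_supply_fractions * n_spoke))
  m_ball <- pmin(m_ball, n_int) # a territory cannot exceed the interior
  n_spoke <- sum(m_ball)
  n_fb <- if (n_fist > 1) min(config$n_fistula_branches,
                              (n_fist - 1L) * n_int) else 0L
  n_ring <- npx - n_spoke - n_bridge - n_fb
  if (n_ring < 0) {
    stop("infeasible config: spoke/bridge budget exceeds plexiform count",
         call. = FALSE)
  }

  pos <- as.matrix(nidus_nodes[, c("x", "y", "z")])
  rownames(pos) <- nidus_nodes$id

  edges <- character(0) # "tail|head" with sorted endpoints, for dedup
  tails <- character(0); heads <- character(0)
  add_edge <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "|")
    if (a == b || key %in% edges) return(FALSE)
    edges <<- c(edges, key)
    # orient along the arterial -> venous axis
    if (pos[a, 1] <= pos[b, 1]) {
      tails <<- c(tails, a); heads <<- c(heads, b)
    } else {
      tails <<- c(tails, b); heads <<- c(heads, a)
    }
    TRUE
  }
  if (!is.null(fist_vessels)) {
    edges <- paste(pmin(fist_vessels$tail, fist_vessels$head),
                   pmax(fist_vessels$tail, fist_vessels$head), sep = "|")
  }

  dist_to <- function(p, candidates) {
    sqrt(rowSums((pos[candidates, , drop = FALSE] -
                    matrix(p, length(candidates), 3, byrow = TRUE))^2))
  }
  pick_near <- function(a, candidates, lambda = config$locality) {
    w <- exp(-dist_to(pos[a, ], candidates) / lambda)
    sample(candidates, 1L, prob = w)
  }

  # territory anchors: AF1-AF3 are near-concentric at the nidus core so
  # their supply balls nest (AF1 inside AF2 inside AF3, the widest), while
  # AF4 supplies a peripheral corner of the cloud
  ball_anchor <- rbind(
    c(0.40, 0.25, 0.35), c(0.45, 0.68, 0.32), c(0.50, 0.50, 0.50),
    c(0.12, 0.08, 0.90)
  )
  if (nf > 4) {
    ball_anchor <- rbind(ball_anchor,
                         matrix(stats::runif(3 * (nf - 4)), ncol = 3))
  }
  # spokes: feeder i supplies the m_ball[i] interior nodes nearest its anchor
  for (i in seq_len(nf)) {
    d <- dist_to(ball_anchor[i, ], int_ids)
    ball <- int_ids[order(d)][seq_len(m_ball[i])]
    for (b in ball) add_edge(entry_ids[i], b)
  }
  # bridges: drainage from interior nodes into the exit nodes, sampled by
  # proximity so each drainer serves its own side of the nidus
  bridge_share <- rep(floor(n_bridge / nd), nd)
  extra <- n_bridge - sum(bridge_share)
  if (extra > 0) bridge_share[seq_len(extra)] <- bridge_share[seq_len(extra)] + 1L
  for (j in seq_len(nd)) {
    if (bridge_share[j] > n_int) {
      stop("infeasible config: bridge budget exceeds interior size",
           call. = FALSE)
    }
    # tight proximity weighting concentrates drainage on a few collector
    # nodes near the venous face instead of blanketing the interior
    w <- exp(-dist_to(pos[exit_ids[j], ], int_ids) / (0.6 * config$locality))
    ball <- sample(int_ids, bridge_share[j], prob = w)
    for (b in ball) add_edge(exit_ids[j], b)
  }
  # fistula branches: plexiform vessels hanging off the fistula-path nodes,
  # the "direct connection ... with branching plexiform vessels"; the
  # low-resistance fistula clamps this neighbourhood near venous pressure
  if (n_fb > 0) {
    fids <- fist_nodes$id
    made_fb <- 0L; tries <- 0L
    while (made_fb < n_fb && tries < 1000L) {
      tries <- tries + 1L
      a <- if (length(fids) == 1L) fids else sample(fids, 1L)
      b <- pick_near(a, int_ids)
      if (add_edge(a, b)) made_fb <- made_fb + 1L
    }
    if (made_fb < n_fb) {
      stop("infeasible config: cannot place fistula branch vessels",
           call. = FALSE)
    }
  }
  # rings: first tie in any still-isolated branch-point, then spend the rest
  # on near-neighbour pairs with a long-range fraction
  made <- 0L
  deg0 <- setdiff(ring_ids, c(tails, heads,
                              if (!is.null(fist_vessels)) c(fist_vessels$tail,
                                                            fist_vessels$head)))
  for (a in deg0) {
    if (made >= n_ring) {
      stop("infeasible config: not enough ring edges to connect the interior",
           call. = FALSE)
    }
    if (add_edge(a, pick_near(a, setdiff(ring_ids, a)))) made <- made + 1L
  }
  tries <- 0L
  while (made < n_ring && tries < 6000L) {
    tries <- tries + 1L
    a <- sample(ring_ids, 1L)
    b <- if (stats::runif(1) < config$long_range_frac) {
      sample(setdiff(ring_ids, a), 1L)
    } else {
      pick_near(a, setdiff(ring_ids, a))
    }
    if (add_edge(a, b)) made <- made + 1L
  }
  if (made < n_ring) {
    stop("infeasible config: interior too small for requested plexiform count",
         call. = FALSE)
  }

  plex_vessels <- tibble::tibble(
    id = paste0("plex", seq_along(tails)),
    tail = tails, head = heads, class = "plexiform",
    radius = config$plexiform_radius, length = config$plexiform_length
  )

  feeder_vessels <- tibble::tibble(
    id = af_names, tail = inlet_ids, head = entry_ids,
    class = "feeder", radius = config$feeder_radius, length = 3
  )
  drainer_vessels <- tibble::tibble(
    id = dv_names, tail = exit_ids, head = outlet_ids,
    class = "drainer", radius = config$drainer_radius, length = 3
  )

  art <- dplyr::bind_rows(art_edges, term_art)
  art_vessels <- tibble::tibble(
    id = paste0("art_", art$tail, "_", art$head),
    tail = art$tail, head = art$head, class = "systemic-artery",
    radius = art$radius, length = art$length
  )
  ven <- dplyr::bind_rows(term_ven, sinus)
  ven_vessels <- tibble::tibble(
    id = paste0("ven_", ven$tail, "_", ven$head),
    tail = ven$tail, head = ven$head, class = "systemic-vein",
    radius = ven$radius, length = ven$length
  )

  vessels <- dplyr::bind_rows(art_vessels, feeder_vessels, fist_vessels,
                              plex_vessels, drainer_vessels, ven_vessels)
  vessels$occluded <- FALSE
  vessels$emf <- 0

  nodes <- dplyr::bind_rows(art_nodes, inlet_nodes, nidus_nodes, ven_nodes)

  net <- new_avm_network(
    nodes = nodes, vessels = vessels, boundary = boundary,
    feeders = stats::setNames(af_names, af_names),
    drainers = stats::setNames(dv_names, dv_names),
    config = config
  )
  validate_network(net)
  net
}

#' Validate structural invariants of an AVM network
#'
#' Checks node roles and vessel classes, positivity of patent geometry,
#' absence of self-loops, uniqueness of the pressure source/sink, feeder and
#' drainer bookkeeping, and source-to-sink connectivity of the fully patent
#' graph. Returns the network invisibly; stops with a message otherwise.
#'
#' @param net An `avm_network`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "avm_network"))
  nodes <- net$nodes; ves <- net$vessels
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(ves$id)) stop("duplicate vessel ids", call. = FALSE)
  if (!all(nodes$role %in% NODE_ROLES)) stop("unknown node role", call. = FALSE)
  if (!all(ves$class %in% VESSEL_CLASSES)) {
    stop("unknown vessel class", call. = FALSE)
  }
  if (sum(nodes$role == "pressure-source") != 1L ||
      sum(nodes$role == "pressure-sink") != 1L) {
    stop("need exactly one pressure-source and one pressure-sink node",
         call. = FALSE)
  }
  if (any(ves$tail == ves$head)) stop("self-loop vessel", call. = FALSE)
  if (!all(c(ves$tail, ves$head) %in% nodes$id)) {
    stop("vessel endpoint references unknown node", call. = FALSE)
  }
  patent <- !ves$occluded
  if (any(ves$radius[patent] <= 0) || any(ves$length[patent] <= 0)) {
    stop("patent vessels must have positive radius and length", call. = FALSE)
  }
  if (!all(net$feeders %in% ves$id) || !all(net$drainers %in% ves$id)) {
    stop("feeder/drainer map references unknown vessel", call. = FALSE)
  }
  # connectivity source -> sink on the fully patent graph
  g <- igraph::graph_from_data_frame(
    ves[, c("tail", "head")], directed = FALSE,
    vertices = nodes$id
  )
  src <- nodes$id[nodes$role == "pressure-source"]
  snk <- nodes$id[nodes$role == "pressure-sink"]
  if (is.infinite(igraph::distances(g, src, snk)[1, 1])) {
    stop("network is not connected from pressure-source to pressure-sink",
         call. = FALSE)
  }
  invisible(net)
}

#' Calibrate extranidal resistances to the boundary pressure targets
#'
#' The physiological anchors of the model are pressures (not resistances):
#' 47 mm Hg at major feeder inlets, 50 at minor inlets, 17 at draining-vein
#' outlets. This routine adjusts the lengths (equivalently, resistances) of
#' the terminal extranidal artery segment feeding each AF inlet and the
#' terminal vein segment draining each DV outlet by fixed-point iteration
#' (`R <- (P_parent - P_target) / Q`) until the baseline solve reproduces
#' every target within `tol`.
#'
#' @param net An `avm_network` (fully patent).
#' @param tol Convergence tolerance on the worst pressure residual, mm Hg.
#' @param max_iter Maximum fixed-point iterations.
#' @return The calibrated network.
#' @export
calibrate_extranidal <- function(net, tol = 0.05, max_iter = 60) {
  stopifnot(inherits(net, "avm_network"))
  ves <- net$vessels
  nf <- length(net$feeders)
  nd <- length(net$drainers)
  targets_f <- feeder_pressure_targets(net)
  target_d <- net$boundary$drainer_pressure

  inlet <- ves$tail[match(net$feeders, ves$id)]
  outlet <- ves$head[match(net$drainers, ves$id)]
  term_art_idx <- match_terminal(ves, head_is = inlet)
  term_ven_idx <- match_terminal(ves, tail_is = outlet)

  eta <- net$boundary$viscosity
  for (iter in seq_len(max_iter)) {
    sol <- solve_flows(net)
    pn <- stats::setNames(sol$nodes$pressure, sol$nodes$id)
    qv <- stats::setNames(sol$vessels$flow / CM3S_TO_MLMIN, sol$vessels$id)

    res_f <- pn[inlet] - targets_f
    res_d <- pn[outlet] - target_d
    if (max(abs(c(res_f, res_d))) < tol) {
      return(net)
    }

    for (i in seq_len(nf)) {
      k <- term_art_idx[i]
      parent <- net$vessels$tail[k]
      q <- qv[net$vessels$id[k]] # cm^3/s through the terminal segment
      if (!is.finite(q) || q <= 1e-12) next
      r_new <- (pn[parent] - targets_f[i]) * MMHG_TO_DYN / q
      if (!is.finite(r_new) || r_new <= 0) r_new <- 1
      net$vessels$length[k] <- r_new * pi * net$vessels$radius[k]^4 /
        (8 * eta / 100)
    }
    for (j in seq_len(nd)) {
      k <- term_ven_idx[j]
      child <- net$vessels$head[k]
      q <- qv[net$vessels$id[k]]
      if (!is.finite(q) || q <= 1e-12) next
      r_new <- (target_d - pn[child]) * MMHG_TO_DYN / q
      if (!is.finite(r_new) || r_new <= 0) r_new <- 1
      net$vessels$length[k] <- r_new * pi * net$vessels$radius[k]^4 /
        (8 * eta / 100)
    }
  }
  sol <- solve_flows(net)
  pn <- stats::setNames(sol$nodes$pressure, sol$nodes$id)
  stop("extranidal calibration did not converge; residuals (mm Hg): ",
       paste(format(c(pn[inlet] - targets_f, pn[outlet] - target_d),
                    digits = 3), collapse = ", "), call. = FALSE)
}

# target pressures per feeder: first two feeders are major, the rest minor
feeder_pressure_targets <- function(net) {
  nf <- length(net$feeders)
  tf <- ifelse(seq_len(nf) <= 2, net$boundary$major_feeder_pressure,
               net$boundary$minor_feeder_pressure)
  names(tf) <- net$vessels$tail[match(net$feeders, net$vessels$id)]
  tf
}

match_terminal <- function(ves, head_is = NULL, tail_is = NULL) {
  if (!is.null(head_is)) {
    idx <- match(head_is, ves$head)
    cls <- "systemic-artery"
  } else {
    idx <- match(tail_is, ves$tail)
    cls <- "systemic-vein"
  }
  # the terminal segment must be the extranidal one (feeder/drainer vessels
  # share these nodes)
  key <- if (!is.null(head_is)) head_is else tail_is
  col <- if (!is.null(head_is)) "head" else "tail"
  vapply(key, function(nd) {
    j <- which(ves[[col]] == nd & ves$class == cls)
    if (length(j) != 1L) {
      stop("cannot identify unique terminal ", cls, " segment at node ", nd,
           call. = FALSE)
    }
    j
  }, integer(1))
}

#' Occlude arterial feeders
#'
#' Marks the given feeder vessels occluded; the solver removes them from the
#' linear system (exactly infinite resistance). Pure: the input network is
#' unchanged. Occlusion composes: occluding A then B equals occluding
#' \{A, B\}.
#'
#' @param net An `avm_network`.
#' @param feeder_ids Character vector of feeder names (e.g. `"AF1"`) or
#'   feeder vessel ids; may be empty.
#' @return A copy of the network with the listed feeders occluded.
#' @export
occlude_feeders <- function(net, feeder_ids) {
  stopifnot(inherits(net, "avm_network"))
  if (length(feeder_ids) == 0) return(net)
  ids <- net$feeders[match(feeder_ids, names(net$feeders))]
  ids[is.na(ids)] <- feeder_ids[is.na(ids)]
  if (!all(ids %in% net$feeders)) {
    stop("unknown feeder id(s): ",
         paste(feeder_ids[!ids %in% net$feeders], collapse = ", "),
         call. = FALSE)
  }
  net$vessels$occluded[net$vessels$id %in% ids] <- TRUE
  net
}

#' Randomly perturb vessel geometry
#'
#' Independently resamples every vessel's radius and length uniformly within
#' `[v (1 - rel_halfwidth), v (1 + rel_halfwidth)]` around its current
#' ("typical") value, across the whole network. Topology is untouched; the
#' input network is unchanged; the same seed reproduces the same perturbation.
#'
#' @param net An `avm_network`.
#' @param rel_halfwidth Relative half-width of the uniform interval, in
#'   `[0, 1)`; the reference sensitivity analysis uses 0.10.
#' @param seed RNG seed.
#' @return The perturbed network.
#' @export
perturb_geometry <- function(net, rel_halfwidth, seed) {
  stopifnot(inherits(net, "avm_network"))
  if (rel_halfwidth < 0 || rel_halfwidth >= 1) {
    stop("`rel_halfwidth` must be in [0, 1)", call. = FALSE)
  }
  if (rel_halfwidth == 0) return(net)
  n <- nrow(net$vessels)
  with_local_seed(seed, {
    net$vessels$radius <- net$vessels$radius *
      stats::runif(n, 1 - rel_halfwidth, 1 + rel_halfwidth)
    net$vessels$length <- net$vessels$length *
      stats::runif(n, 1 - rel_halfwidth, 1 + rel_halfwidth)
  })
  net
}

#' Randomly rewire intranidal connections
#'
#' Reassigns one endpoint of `round(fraction * n_nidus)` randomly chosen
#' nidus vessels to a uniformly chosen different nidus node, resampling on
#' self-loops, duplicate edges, or loss of source-to-sink connectivity
#' (bounded retries). Vessel count, classes, radii and lengths are preserved
#' (fistulous vessels keep their geometry even when reconnected). Pure and
#' seeded-reproducible.
#'
#' @param net An `avm_network`.
#' @param fraction Proportion of nidus vessels to rewire, in `[0, 1]`.
#' @param seed RNG seed.
#' @param max_attempts Whole-rewire retry budget for the connectivity check.
#' @return The rewired network.
#' @export
rewire_nidus <- function(net, fraction, seed, max_attempts = 50) {
  stopifnot(inherits(net, "avm_network"))
  if (fraction < 0 || fraction > 1) {
    stop("`fraction` must be in [0, 1]", call. = FALSE)
  }
  nidus_v <- which(net$vessels$class %in% c("plexiform", "fistulous"))
  n_target <- round(fraction * length(nidus_v))
  if (n_target == 0) return(net)
  nidus_nodes <- net$nodes$id[net$nodes$role == "nidus"]

  out <- with_local_seed(seed, {
    cand <- NULL
    for (attempt in seq_len(max_attempts)) {
      cand <- try_rewire_once(net, nidus_v, n_target, nidus_nodes)
      if (!is.null(cand)) break
    }
    cand
  })
  if (is.null(out)) {
    stop("rewire_nidus: retry budget exhausted without a connected rewiring",
         call. = FALSE)
  }
  out
}

try_rewire_once <- function(net, nidus_v, n_target, nidus_nodes) {
  ves <- net$vessels
  chosen <- sample(nidus_v, n_target)
  keys <- function(v) paste(pmin(v$tail, v$head), pmax(v$tail, v$head),
                            sep = "|")
  existing <- keys(ves)
  for (k in chosen) {
    ok <- FALSE
    for (r in seq_len(60)) {
      move_tail <- stats::runif(1) < 0.5
      keep <- if (move_tail) ves$head[k] else ves$tail[k]
      old <- if (move_tail) ves$tail[k] else ves$head[k]
      new <- sample(setdiff(nidus_nodes, c(keep, old)), 1L)
      key_new <- paste(min(keep, new), max(keep, new), sep = "|")
      if (key_new %in% existing) next
      existing[match(keys(ves[k, ]), existing)] <- key_new
      if (move_tail) ves$tail[k] <- new else ves$head[k] <- new
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  out <- net
  out$vessels <- ves
  g <- igraph::graph_from_data_frame(ves[!ves$occluded, c("tail", "head")],
                                     directed = FALSE,
                                     vertices = net$nodes$id)
  src <- net$nodes$id[net$nodes$role == "pressure-source"]
  snk <- net$nodes$id[net$nodes$role == "pressure-sink"]
  if (is.infinite(igraph::distances(g, src, snk)[1, 1])) return(NULL)
  out
}
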