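# Serialization and export: versioned network JSON (the source of truth),
# GraphML export for interoperability, tidy CSV tables for solutions and
# results, YAML/JSON run configuration, and a run manifest with checksums.

NETWORK_SCHEMA_VERSION <- "1.0"

#' Write / read a vascular network as JSON
#'
#' The JSON schema (version 1.0) has top-level fields `schema_version`,
#' `nodes` (id, role, x, y, z), `vessels` (id, tail, head, class, radius,
#' length, occluded, emf), `boundary`, `feeders`, `drainers`. The round trip
#' `read_network(write_network(net))` reproduces the network exactly.
#'
#' @param net An `avm_network`.
#' @param path File path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   the `avm_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "avm_network"))
  obj <- list(
    schema_version = NETWORK_SCHEMA_VERSION,
    nodes = net$nodes,
    vessels = net$vessels,
    boundary = unclass(net$boundary),
    feeders = as.list(net$feeders),
    drainers = as.list(net$drainers)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("schema_version", "nodes", "vessels", "boundary",
                  "feeders", "drainers")) {
    if (is.null(obj[[field]])) {
      stop("network file violates schema: missing field \"", field, "\"",
           call. = FALSE)
    }
  }
  for (field in c("source_pressure", "sink_pressure", "major_feeder_pressure",
                  "minor_feeder_pressure", "drainer_pressure", "viscosity")) {
    if (is.null(obj$boundary[[field]])) {
      stop("network file violates schema: missing field \"boundary.", field,
           "\"", call. = FALSE)
    }
  }
  boundary <- do.call(boundary_conditions, obj$boundary)
  vessels <- tibble::as_tibble(obj$vessels)
  vessels$occluded <- as.logical(vessels$occluded)
  if (is.null(vessels$emf)) vessels$emf <- 0
  net <- new_avm_network(
    nodes = tibble::as_tibble(obj$nodes),
    vessels = vessels,
    boundary = boundary,
    feeders = unlist(obj$feeders),
    drainers = unlist(obj$drainers)
  )
  validate_network(net)
  net
}

#' Convert a network to an igraph object / export GraphML
#'
#' Vessels become edges with `class`, `radius`, `length` and `occluded`
#' attributes; nodes keep `role` and 3-D coordinates.
#'
#' @param net An `avm_network`.
#' @param path GraphML output path.
#' @return `as_igraph` returns an igraph graph; `write_network_graphml`
#'   returns `path` invisibly.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "avm_network"))
  igraph::graph_from_data_frame(
    d = net$vessels[, c("tail", "head", "id", "class", "radius", "length",
                        "occluded")],
    directed = TRUE,
    vertices = net$nodes
  )
}

#' @rdname as_igraph
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export a flow solution as tidy CSV
#'
#' Writes two tables: `<stem>_vessels.csv` (one row per vessel: id, class,
#' flow in mL/min, pressure drop in mm Hg) and `<stem>_nodes.csv` (per-node
#' pressures in mm Hg).
#'
#' @param sol An `avm_flow`.
#' @param stem Output path stem (without extension).
#' @return The two file paths, invisibly.
#' @export
export_flow_csv <- function(sol, stem) {
  stopifnot(inherits(sol, "avm_flow"))
  p1 <- paste0(stem, "_vessels.csv")
  p2 <- paste0(stem, "_nodes.csv")
  utils::write.csv(sol$vessels, p1, row.names = FALSE)
  utils::write.csv(sol$nodes, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Export an SSA result as tidy CSV
#'
#' Writes `<stem>_vessels.csv` with per-nidus-vessel baseline/injected
#' values and all delta maps (including the guard flag), and
#' `<stem>_nodes.csv` with per-node pressure changes.
#'
#' @param ssa An `avm_ssa`.
#' @param stem Output path stem (without extension).
#' @return The two file paths, invisibly.
#' @export
export_ssa_csv <- function(ssa, stem) {
  stopifnot(inherits(ssa, "avm_ssa"))
  p1 <- paste0(stem, "_vessels.csv")
  p2 <- paste0(stem, "_nodes.csv")
  utils::write.csv(ssa$deltas, p1, row.names = FALSE)
  utils::write.csv(ssa$node_delta, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Export a compartment result as CSV
#'
#' Writes `<stem>_members.csv` (vessel id, response value, member flag) and
#' `<stem>_summary.csv` (one row: threshold, size_pct, bimodality p).
#'
#' @param cmp An `avm_compartments`.
#' @param stem Output path stem (without extension).
#' @return The two file paths, invisibly.
#' @export
export_compartments_csv <- function(cmp, stem) {
  stopifnot(inherits(cmp, "avm_compartments"))
  p1 <- paste0(stem, "_members.csv")
  p2 <- paste0(stem, "_summary.csv")
  utils::write.csv(cmp$members, p1, row.names = FALSE)
  utils::write.csv(glance(cmp), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a run configuration file
#'
#' YAML or JSON file with optional blocks `nidus` (fields of
#' [nidus_config()]) and `boundary` (fields of [boundary_conditions()]);
#' unknown fields are rejected. Returns the two constructed objects.
#'
#' @param path Config file path.
#' @return List with elements `config` and `boundary`.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  check_fields <- function(given, fn, block) {
    allowed <- names(formals(fn))
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      stop("unknown field(s) in config block \"", block, "\": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  nid <- obj$nidus %||% list()
  bnd <- obj$boundary %||% list()
  check_fields(nid, nidus_config, "nidus")
  check_fields(bnd, boundary_conditions, "boundary")
  list(config = do.call(nidus_config, nid),
       boundary = do.call(boundary_conditions, bnd))
}

#' Write a run manifest
#'
#' JSON snapshot of a completed run: package version, timestamp, the
#' configuration used, all seeds, per-stage timings, and an inventory of
#' output files with md5 checksums.
#'
#' @param path Manifest output path.
#' @param config The [nidus_config()] used.
#' @param seeds Named list/vector of seeds used by each stage.
#' @param files Character vector of output file paths.
#' @param timings Named numeric vector of per-stage elapsed seconds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds, files, timings = NULL) {
  inventory <- lapply(files, function(f) {
    list(path = f, md5 = unname(tools::md5sum(f)),
         bytes = file.info(f)$size)
  })
  obj <- list(
    package = "nidusflow",
    version = as.character(utils::packageVersion("nidusflow")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    seeds = as.list(seeds),
    timings = as.list(timings),
    files = inventory
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
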