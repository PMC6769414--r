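# Figures: network maps colored by hemodynamic quantities (flow, pressure,
# SSA response, compartment overlay) and the response histogram with the
# Otsu threshold line. Layouts are deterministic: nodes are drawn at their
# stored (x, y) coordinates (the first two of the 3-D position).

network_segments <- function(net, vessel_values = NULL) {
  nodes <- net$nodes
  v <- net$vessels
  seg <- tibble::tibble(
    id = v$id, class = v$class, occluded = v$occluded,
    x = nodes$x[match(v$tail, nodes$id)],
    y = nodes$y[match(v$tail, nodes$id)],
    xend = nodes$x[match(v$head, nodes$id)],
    yend = nodes$y[match(v$head, nodes$id)]
  )
  if (!is.null(vessel_values)) {
    seg$value <- vessel_values[match(seg$id, names(vessel_values))]
  }
  seg
}

#' Plot the network colored by a per-vessel quantity
#'
#' @param net An `avm_network`.
#' @param values Named numeric vector (names = vessel ids) to color by, or
#'   `NULL` for a plain structural plot.
#' @param label Legend title.
#' @param nidus_only Restrict drawing to nidus vessels and nodes.
#' @return A ggplot.
#' @export
plot_network_map <- function(net, values = NULL, label = "value",
                             nidus_only = FALSE) {
  seg <- network_segments(net, values)
  if (nidus_only) {
    seg <- dplyr::filter(seg, .data$class %in% c("plexiform", "fistulous"))
  }
  p <- ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                         xend = .data$xend,
                                         yend = .data$yend))
  if (is.null(values)) {
    p <- p + ggplot2::geom_segment(ggplot2::aes(color = .data$class),
                                   linewidth = 0.6)
  } else {
    p <- p + ggplot2::geom_segment(ggplot2::aes(color = .data$value),
                                   linewidth = 0.9) +
      ggplot2::scale_color_viridis_c(name = label)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void()
}

#' Baseline flow and pressure maps of a solution
#'
#' `autoplot.avm_flow` draws the nidus colored by either absolute vessel
#' flow (mL/min) or absolute pressure drop (mm Hg).
#'
#' @param object An `avm_flow`.
#' @param net The network the solution was computed on.
#' @param what `"flow"` or `"drop"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.avm_flow <- function(object, net, what = c("flow", "drop"), ...) {
  what <- match.arg(what)
  vals <- abs(object$vessels[[what]])
  names(vals) <- object$vessels$id
  lab <- if (what == "flow") "|flow| (mL/min)" else "|dP| (mm Hg)"
  plot_network_map(net, vals, label = lab, nidus_only = TRUE)
}

#' SSA response map
#'
#' Draws the nidus colored by the per-vessel SSA response (percent change
#' in mean intravascular pressure by default).
#'
#' @param object An `avm_ssa`.
#' @param net The network the SSA was simulated on.
#' @param measure `"pmean"`, `"drop"` or `"flow"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.avm_ssa <- function(object, net, measure = "pmean", ...) {
  col <- switch(measure, pmean = "delta_p_pct", drop = "delta_drop_pct",
                flow = "delta_flow_pct")
  vals <- object$deltas[[col]]
  names(vals) <- object$deltas$id
  plot_network_map(net, vals, label = paste0(col, " (%)"), nidus_only = TRUE)
}

#' Compartment histogram and overlay map
#'
#' The default (`type = "histogram"`) mirrors the compartment-detection
#' figure: a histogram of the per-vessel SSA responses with a red vertical
#' line at the Otsu threshold. `type = "map"` draws the nidus with the
#' compartment members highlighted in red over the remaining vessels in
#' blue; for a degenerate result the overlay is omitted with a warning.
#'
#' @param object An `avm_compartments`.
#' @param type `"histogram"` or `"map"`.
#' @param net Required for `type = "map"`: the network.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.avm_compartments <- function(object, type = c("histogram", "map"),
                                      net = NULL, bins = 30, ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    p <- ggplot2::ggplot(object$members, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_histogram(bins = bins, fill = "grey40") +
      ggplot2::labs(x = "response (% increase)", y = "nidus vessels") +
      ggplot2::theme_minimal()
    if (!object$degenerate) {
      p <- p + ggplot2::geom_vline(xintercept = object$threshold,
                                   color = "red", linewidth = 0.8)
    }
    return(p)
  }
  if (is.null(net)) stop("`net` is required for the map plot", call. = FALSE)
  seg <- network_segments(net)
  seg <- dplyr::filter(seg, .data$class %in% c("plexiform", "fistulous"))
  if (object$degenerate) {
    warning("degenerate compartment result: drawing structure only")
    seg$member <- FALSE
  } else {
    seg$member <- object$members$member[match(seg$id, object$members$id)]
  }
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                    xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_segment(ggplot2::aes(color = .data$member),
                          linewidth = 0.9) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "steelblue",
                                           `TRUE` = "red"),
                                name = "compartment") +
    ggplot2::coord_equal() + ggplot2::theme_void()
}

#' Render the standard figure set for a result
#'
#' Writes baseline flow and pressure-drop maps, the SSA response map, and
#' the compartment histogram + overlay as PNG files.
#'
#' @param net An `avm_network`.
#' @param ssa An `avm_ssa` computed on `net`.
#' @param cmp An `avm_compartments` for `ssa`.
#' @param dir Output directory (created if missing).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Character vector of the files written, invisibly.
#' @export
render_maps <- function(net, ssa, cmp, dir, width = 6, height = 5,
                        dpi = 150) {
  stopifnot(inherits(net, "avm_network"), inherits(ssa, "avm_ssa"),
            inherits(cmp, "avm_compartments"))
  if (!all(ssa$deltas$id %in% net$vessels$id)) {
    stop("SSA result does not match the network's vessel ids", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  save_one <- function(name, plot) {
    f <- file.path(dir, name)
    ggplot2::ggsave(f, plot, width = width, height = height, dpi = dpi)
    files <<- c(files, f)
  }
  save_one("baseline_flow_map.png", autoplot(ssa$baseline, net, "flow"))
  save_one("baseline_drop_map.png", autoplot(ssa$baseline, net, "drop"))
  save_one("ssa_response_map.png", autoplot(ssa, net))
  save_one("compartment_histogram.png", autoplot(cmp, "histogram"))
  if (!cmp$degenerate) {
    save_one("compartment_map.png", autoplot(cmp, "map", net = net))
  }
  invisible(files)
}
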