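# Fixture builders and independent oracles used across the suite.

MMHG <- 1333.22 # dyn/cm^2 per mm Hg

# assemble a bare network from node/vessel tables
toy_net <- function(nodes, vessels, boundary = boundary_conditions(),
                    feeders = character(0), drainers = character(0)) {
  vessels$occluded <- vessels$occluded %||% FALSE
  if (is.null(vessels$emf)) vessels$emf <- 0
  if (is.null(nodes$x)) {
    nodes$x <- seq_len(nrow(nodes))
    nodes$y <- 0
    nodes$z <- 0
  }
  nidusflow:::new_avm_network(nodes, vessels, boundary, feeders, drainers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

node_tbl <- function(ids, roles) {
  tibble::tibble(id = ids, role = roles, x = seq_along(ids), y = 0, z = 0)
}

vessel_tbl <- function(tail, head, radius = 0.05, length = 5,
                       class = "plexiform", id = NULL) {
  tibble::tibble(
    id = id %||% paste0("v", seq_along(tail)),
    tail = tail, head = head, class = class,
    radius = radius, length = length, occluded = FALSE, emf = 0
  )
}

make_single <- function(radius = 0.05, length = 5) {
  toy_net(node_tbl(c("S", "K"), c("pressure-source", "pressure-sink")),
          vessel_tbl("S", "K", radius, length))
}

make_series <- function(n = 3, radius = 0.05, length = 5) {
  ids <- c("S", paste0("N", seq_len(n - 1)), "K")
  toy_net(
    node_tbl(ids, c("pressure-source", rep("nidus", n - 1), "pressure-sink")),
    vessel_tbl(ids[-length(ids)], ids[-1], radius, length)
  )
}

make_parallel <- function(k = 2, radius = 0.05, length = 5) {
  # k identical vessels between source and an intermediate node, then a
  # common outlet vessel so that the parallel vessels join at a free node
  nodes <- node_tbl(c("S", "M", "K"),
                    c("pressure-source", "nidus", "pressure-sink"))
  v <- vessel_tbl(c(rep("S", k), "M"), c(rep("M", k), "K"),
                  radius = c(rep(radius, k), 2 * radius),
                  length = c(rep(length, k), length))
  toy_net(nodes, v)
}

# Wheatstone bridge: S -> A, S -> B, A -> K, B -> K, A -> B (bridge arm)
make_bridge <- function(radii = c(0.05, 0.06, 0.055, 0.045, 0.05),
                        lengths = c(5, 4, 6, 5, 3)) {
  nodes <- node_tbl(c("S", "A", "B", "K"),
                    c("pressure-source", "nidus", "nidus", "pressure-sink"))
  v <- vessel_tbl(c("S", "S", "A", "B", "A"), c("A", "B", "K", "K", "B"),
                  radius = radii, length = lengths)
  toy_net(nodes, v)
}

# random connected small network with random geometry
random_small_net <- function(seed, n_nodes = NULL) {
  set.seed(seed)
  n <- n_nodes %||% sample(4:20, 1)
  ids <- c("S", paste0("N", seq_len(n - 2)), "K")
  roles <- c("pressure-source", rep("nidus", n - 2), "pressure-sink")
  # spanning-tree backbone guarantees connectivity, then extra random edges
  tail <- character(0); head <- character(0)
  for (i in 2:n) {
    j <- sample(seq_len(i - 1), 1)
    tail <- c(tail, ids[j]); head <- c(head, ids[i])
  }
  n_extra <- sample(0:(2 * n), 1)
  for (k in seq_len(n_extra)) {
    ab <- sample(n, 2)
    key <- paste(sort(ids[ab]), collapse = "|")
    if (!key %in% paste(pmin(tail, head), pmax(tail, head), sep = "|")) {
      tail <- c(tail, ids[ab[1]]); head <- c(head, ids[ab[2]])
    }
  }
  v <- vessel_tbl(tail, head,
                  radius = runif(length(tail), 0.03, 0.12),
                  length = runif(length(tail), 2, 8))
  toy_net(node_tbl(ids, roles), v)
}

# Independent oracle: dense nodal analysis with plain base-R matrices,
# assembled entry by entry from Kirchhoff's current law.
dense_oracle_solve <- function(net) {
  nodes <- net$nodes
  ves <- net$vessels[!net$vessels$occluded, ]
  n <- nrow(nodes)
  idx <- stats::setNames(seq_len(n), nodes$id)
  g <- 1 / (8 * ves$length * (net$boundary$viscosity / 100) /
              (pi * ves$radius^4))
  A <- matrix(0, n, n)
  b <- rep(0, n)
  for (k in seq_len(nrow(ves))) {
    i <- idx[ves$tail[k]]; j <- idx[ves$head[k]]
    A[i, i] <- A[i, i] + g[k]; A[j, j] <- A[j, j] + g[k]
    A[i, j] <- A[i, j] - g[k]; A[j, i] <- A[j, i] - g[k]
    e <- ves$emf[k] * MMHG
    b[i] <- b[i] - g[k] * e
    b[j] <- b[j] + g[k] * e
  }
  src <- idx[nodes$id[nodes$role == "pressure-source"]]
  snk <- idx[nodes$id[nodes$role == "pressure-sink"]]
  for (d in c(src, snk)) {
    A[d, ] <- 0; A[d, d] <- 1
  }
  b[src] <- net$boundary$source_pressure * MMHG
  b[snk] <- net$boundary$sink_pressure * MMHG
  p <- solve(A, b)
  q <- g * (p[idx[ves$tail]] + ves$emf * MMHG - p[idx[ves$head]])
  list(pressure = p / MMHG,
       flow = stats::setNames(q * 60, ves$id))
}

# Independent oracle for Otsu: brute force minimisation of the pooled
# within-class variance over every split of the sorted values.
brute_otsu <- function(values) {
  x <- sort(values)
  n <- length(x)
  u <- unique(x)
  best <- Inf; thr <- NA_real_
  for (k in seq_len(length(u) - 1L)) {
    cand <- (u[k] + u[k + 1L]) / 2
    lo <- x[x <= cand]; hi <- x[x > cand]
    wcv <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wcv < best - 1e-12) {
      best <- wcv; thr <- cand
    }
  }
  thr
}

# canonical network cached once per test run (build + calibration)
canonical_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_canonical_network()
    net
  }
})
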