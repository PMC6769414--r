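# Compartment detection: exact Otsu thresholding of the per-vessel SSA
# response distribution, membership and size, and a Welch test of mean
# separation between the two Otsu classes as the bimodality statistic.

#' Exact Otsu threshold of a one-dimensional value set
#'
#' Histogram-free Otsu: considers every midpoint between consecutive sorted
#' unique values as a candidate split and returns the one maximising the
#' between-class variance \eqn{w_0 w_1 (m_0 - m_1)^2}. Ties are broken
#' toward the lowest qualifying threshold. With only 97 nidus vessels this
#' avoids the bin-count free parameter of the image-histogram variant; see
#' [otsu_threshold_binned()] for that variant.
#'
#' @param values Numeric vector of at least 2 finite, not-all-equal values.
#' @return The threshold (numeric scalar).
#' @export
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L || diff(range(values)) == 0) {
    stop("otsu_threshold: need >= 2 values that are not all equal",
         call. = FALSE)
  }
  x <- sort(values)
  u <- unique(x)
  # class sizes and sums for splits after each unique value
  cnt <- cumsum(tabulate(match(x, u), nbins = length(u)))
  sums <- cumsum(x)
  csum <- sums[cnt] # cumulative sum up to each unique value
  k <- seq_len(length(u) - 1L)
  w0 <- cnt[k] / n
  w1 <- 1 - w0
  m0 <- csum[k] / cnt[k]
  m1 <- (sums[n] - csum[k]) / (n - cnt[k])
  bcv <- w0 * w1 * (m0 - m1)^2
  best <- which.max(bcv) # which.max takes the first (lowest) maximiser
  (u[best] + u[best + 1L]) / 2
}

#' Binned (image-histogram) Otsu threshold
#'
#' Classical Otsu on a fixed-width histogram, for comparison with the exact
#' variant.
#'
#' @param values Numeric vector.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (a bin edge midpoint).
#' @export
otsu_threshold_binned <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || diff(range(values)) == 0) {
    stop("otsu_threshold_binned: need >= 2 values that are not all equal",
         call. = FALSE)
  }
  edges <- seq(min(values), max(values), length.out = n_bins + 1L)
  h <- graphics::hist(values, breaks = edges, plot = FALSE)
  p <- h$counts / sum(h$counts)
  m <- h$mids
  w0 <- cumsum(p)
  mu0 <- cumsum(p * m)
  mu_t <- mu0[length(mu0)]
  k <- seq_len(n_bins - 1L)
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * w1[valid])
  edges[which.max(bcv) + 1L]
}

#' Welch p-value of mean separation between Otsu classes
#'
#' Splits `values` at the (exact) Otsu threshold and runs a two-sided Welch
#' two-sample t test between the upper and lower classes. Used as the
#' bimodality significance of an SSA response distribution. Returns `NA`
#' (with attribute `reason`) when either class has fewer than 2 members; if
#' both classes have zero variance but distinct means the separation is
#' perfect and the p-value is 0.
#'
#' @param values Numeric vector.
#' @param threshold Optional pre-computed threshold; defaults to
#'   [otsu_threshold()] of `values`.
#' @return p-value in `[0, 1]`, or `NA`.
#' @export
bimodality_pvalue <- function(values, threshold = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 4L || diff(range(values)) == 0) {
    return(structure(NA_real_, reason = "degenerate distribution"))
  }
  if (is.null(threshold)) threshold <- otsu_threshold(values)
  upper <- values[values > threshold]
  lower <- values[values <= threshold]
  if (length(upper) < 2L || length(lower) < 2L) {
    return(structure(NA_real_, reason = "class with < 2 members"))
  }
  if (stats::var(upper) == 0 && stats::var(lower) == 0) {
    return(if (mean(upper) != mean(lower)) 0 else
      structure(NA_real_, reason = "degenerate distribution"))
  }
  stats::t.test(upper, lower, alternative = "two.sided")$p.value
}

#' Detect a hemodynamic compartment from an SSA result
#'
#' Applies exact Otsu thresholding to the per-nidus-vessel SSA response
#' distribution; vessels strictly above the threshold form the compartment
#' supplied by the injected feeder. Compartment size is expressed as percent
#' of all nidus vessels, and the Welch mean-separation p-value between the
#' two classes is attached as the bimodality statistic.
#'
#' @param ssa An `avm_ssa` from [simulate_ssa()].
#' @param measure Which per-vessel response to threshold: `"pmean"`
#'   (default) uses `delta_p_pct`, the percent change in mean intravascular
#'   pressure; `"drop"` uses `delta_drop_pct`; `"flow"` uses
#'   `delta_flow_pct`.
#' @return An object of class `avm_compartments`: list with `threshold`,
#'   `members` tibble (vessel id, class, value, member flag), `size_pct`,
#'   `bimodality_p`, `degenerate`, and the SSA condition.
#' @export
detect_compartment <- function(ssa, measure = c("pmean", "drop", "flow")) {
  stopifnot(inherits(ssa, "avm_ssa"))
  measure <- match.arg(measure)
  col <- switch(measure, pmean = "delta_p_pct", drop = "delta_drop_pct",
                flow = "delta_flow_pct")
  values <- ssa$deltas[[col]]
  n <- length(values)

  # a spread below numerical noise (e.g. a zero-strength injection) cannot
  # support a two-class split
  degenerate <- n < 2L || !any(is.finite(values)) ||
    diff(range(values[is.finite(values)])) < 1e-9
  if (degenerate) {
    out <- list(threshold = NA_real_,
                members = tibble::tibble(id = ssa$deltas$id,
                                         class = ssa$deltas$class,
                                         value = values, member = NA),
                size_pct = NA_real_, bimodality_p = NA_real_,
                degenerate = TRUE, measure = measure,
                feeder = ssa$feeder, injection_delta = ssa$injection_delta,
                occlude_others = ssa$occlude_others)
    class(out) <- "avm_compartments"
    return(out)
  }

  thr <- otsu_threshold(values)
  member <- values > thr
  out <- list(
    threshold = thr,
    members = tibble::tibble(id = ssa$deltas$id, class = ssa$deltas$class,
                             value = values, member = member),
    size_pct = 100 * sum(member) / n,
    bimodality_p = bimodality_pvalue(values, thr),
    degenerate = FALSE, measure = measure,
    feeder = ssa$feeder, injection_delta = ssa$injection_delta,
    occlude_others = ssa$occlude_others
  )
  class(out) <- "avm_compartments"
  out
}

#' @export
print.avm_compartments <- function(x, ...) {
  if (x$degenerate) {
    cat("<avm_compartments> degenerate response distribution (no split)\n")
    return(invisible(x))
  }
  cat("<avm_compartments> ", x$feeder, " +", x$injection_delta, " mm Hg",
      if (x$occlude_others) ", others occluded", "\n", sep = "")
  cat("  threshold: ", format(x$threshold, digits = 4),
      "  size: ", format(x$size_pct, digits = 3), "% of nidus vessels",
      "  p(mean separation): ", format(x$bimodality_p, digits = 3), "\n",
      sep = "")
  invisible(x)
}
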