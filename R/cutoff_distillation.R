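# Cutoff distillation: compare the kernel density of the forest's split
# thresholds for a continuous predictor against the kernel density of the
# training values; candidate cutoffs are the local maxima of the difference
# (regions where the forest splits more often than the data alone would
# suggest), and cutoffs that would create minor groups are excluded.

#' Gaussian kernel density on a fixed grid
#'
#' Wraps [stats::density()] with Silverman's rule-of-thumb bandwidth
#' (`bw.nrd0`) and an explicit evaluation grid, so that two samples can be
#' compared point-by-point on a shared grid.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param weights optional nonnegative weights (normalized internally).
#' @param from,to grid range; defaults to the sample range extended by three
#'   bandwidths so the curve integrates to ~1.
#' @param n_grid number of equally spaced grid points (default 512).
#' @param bandwidth optional numeric bandwidth override.
#' @return an object of class `density_curve`: list with `grid`, `density`,
#'   `bandwidth`.
#' @export
estimate_density <- function(values, weights = NULL, from = NULL, to = NULL,
                             n_grid = 512, bandwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stop("density estimation needs at least 2 finite values", call. = FALSE)
  bw <- bandwidth %||% stats::bw.nrd0(values)
  if (bw <= 0) bw <- max(1e-8, stats::sd(values) / 10, abs(values[1]) * 1e-6)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(values), all(weights >= 0))
    weights <- weights / sum(weights)
  }
  from <- from %||% (min(values) - 3 * bw)
  to <- to %||% (max(values) + 3 * bw)
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      weights = weights, from = from, to = to, n = n_grid)
  structure(list(grid = d$x, density = d$y, bandwidth = bw),
            class = "density_curve")
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Local maxima of a curve on a grid
#'
#' A grid point is a local maximum when its value is strictly greater than
#' both neighbouring values; plateaus report their midpoint. Endpoints are
#' excluded. For difference curves, only maxima with positive value are
#' retained (`positive_only = TRUE`); maxima whose height is below
#' `1e-8` of the curve's largest absolute value are floating-point ripples
#' in regions where both densities vanish, and are discarded.
#'
#' @param curve a `density_curve` (the density may be negative for
#'   difference curves).
#' @param positive_only keep only maxima with value > 0 (default TRUE).
#' @return data.frame with `position` and `height` (possibly zero rows).
#' @export
find_local_maxima <- function(curve, positive_only = TRUE) {
  y <- curve$density; x <- curve$grid
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  pos <- numeric(0); height <- numeric(0)
  if (k >= 3) {
    for (i in 2:(k - 1)) {
      if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1]) {
        mid <- (starts[i] + ends[i]) / 2
        pos <- c(pos, (x[floor(mid)] + x[ceiling(mid)]) / 2)
        height <- c(height, r$values[i])
      }
    }
  }
  out <- data.frame(position = pos, height = height)
  floor_h <- 1e-8 * max(abs(y), 0)
  if (positive_only) out <- out[out$height > floor_h, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# proportions of values in the left-closed intervals induced by cutoffs
interval_proportions <- function(values, cutoffs) {
  as.numeric(table(cut(values, c(-Inf, sort(cutoffs), Inf), right = FALSE))) /
    length(values)
}

new_cutoff_set <- function(variable, cutoffs, candidates = NULL,
                           split_density = NULL, data_density = NULL,
                           diff_curve = NULL, min_group_proportion = NA,
                           status = "ok") {
  structure(list(variable = variable, cutoffs = sort(cutoffs),
                 candidates = candidates,
                 split_density = split_density, data_density = data_density,
                 diff_curve = diff_curve,
                 min_group_proportion = min_group_proportion,
                 status = status),
            class = "cutoff_set")
}

#' Distill forest split rules into cutoffs for one continuous variable
#'
#' Pipeline: extract all split thresholds the forest used for the variable;
#' estimate the Gaussian kernel density of the thresholds and of the
#' training values on a shared 512-point grid (Silverman bandwidth per
#' sample); take the difference (split density minus data density); select
#' its positive local maxima as candidate cutoffs; then drop candidates, in
#' increasing order of difference height, until every interval of the
#' induced partition of the training values holds at least
#' `min_group_proportion` of subjects.
#'
#' @param forest a fitted [fit_forest()] object, or a numeric vector of
#'   split thresholds (for direct use with pre-extracted rules).
#' @param variable variable name (required for a forest).
#' @param values training values of the variable; defaults to the forest's
#'   training column.
#' @param min_group_proportion minimal admissible group proportion
#'   (default 0.10).
#' @param weight_by_node_size weight each threshold by the in-bag size of
#'   the node that produced it (default FALSE: each split counts once).
#' @param n_grid shared grid resolution (default 512).
#' @param ... passed between methods.
#' @return an object of class `cutoff_set`; `status` is `"empty"` (with a
#'   warning) when the forest never splits on the variable.
#' @export
distill_cutoffs <- function(forest, ...) UseMethod("distill_cutoffs")

#' @rdname distill_cutoffs
#' @export
distill_cutoffs.survival_forest <- function(forest, variable, values = NULL,
                                            min_group_proportion = 0.10,
                                            weight_by_node_size = FALSE,
                                            n_grid = 512, ...) {
  splits <- extract_split_thresholds(forest, variable)
  values <- values %||% as.numeric(forest$train_data[[variable]])
  distill_cutoffs.numeric(splits$threshold, variable = variable,
                          values = values,
                          min_group_proportion = min_group_proportion,
                          weights = if (weight_by_node_size) splits$node_size,
                          n_grid = n_grid)
}

#' @rdname distill_cutoffs
#' @param weights optional per-threshold weights (numeric method).
#' @export
distill_cutoffs.numeric <- function(forest, variable = "x", values,
                                    min_group_proportion = 0.10,
                                    weights = NULL, n_grid = 512, ...) {
  thresholds <- forest
  if (length(values) < 20)
    stop("cutoff distillation needs at least 20 training values", call. = FALSE)
  if (length(thresholds) < 2) {
    warning(sprintf("no split thresholds for '%s'; returning empty cutoff set",
                    variable), call. = FALSE)
    return(new_cutoff_set(variable, numeric(0), status = "empty",
                          min_group_proportion = min_group_proportion))
  }
  bw_s <- stats::bw.nrd0(thresholds)
  bw_d <- stats::bw.nrd0(values)
  pad <- 3 * max(bw_s, bw_d, 1e-8)
  lo <- min(thresholds, values) - pad
  hi <- max(thresholds, values) + pad
  d_split <- estimate_density(thresholds, weights = weights,
                              from = lo, to = hi, n_grid = n_grid)
  d_data <- estimate_density(values, from = lo, to = hi, n_grid = n_grid)
  diff_curve <- structure(list(grid = d_split$grid,
                               density = d_split$density - d_data$density,
                               bandwidth = NA_real_),
                          class = "density_curve")
  cand <- find_local_maxima(diff_curve, positive_only = TRUE)
  cand <- cand[order(cand$position), , drop = FALSE]
  keep <- cand
  # minor-group filter: drop the weakest candidate and re-check
  while (nrow(keep) > 0 &&
         any(interval_proportions(values, keep$position) < min_group_proportion)) {
    keep <- keep[-which.min(keep$height), , drop = FALSE]
  }
  new_cutoff_set(variable, keep$position, candidates = cand,
                 split_density = d_split, data_density = d_data,
                 diff_curve = diff_curve,
                 min_group_proportion = min_group_proportion,
                 status = if (nrow(keep)) "ok" else "no-admissible-cutoff")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("Distilled cutoffs for '%s' [%s]\n", x$variable, x$status))
  if (length(x$cutoffs))
    cat("  cutoffs:", paste(signif(x$cutoffs, 4), collapse = ", "), "\n")
  if (!is.null(x$candidates) && nrow(x$candidates))
    cat("  candidates considered:", nrow(x$candidates), "\n")
  cat("  min group proportion:", x$min_group_proportion, "\n")
  invisible(x)
}

#' Diagnostic plot of a distilled cutoff set
#'
#' Shows the split-threshold density, the training-value density, their
#' difference, and the selected cutoffs.
#'
#' @param x a `cutoff_set` with provenance curves.
#' @param ... passed to [plot()].
#' @export
plot.cutoff_set <- function(x, ...) {
  if (is.null(x$split_density)) stop("cutoff set has no provenance curves")
  g <- x$split_density$grid
  ylim <- range(x$split_density$density, x$data_density$density,
                x$diff_curve$density)
  plot(g, x$split_density$density, type = "l", col = "steelblue",
       xlab = x$variable, ylab = "density", ylim = ylim, ...)
  graphics::lines(g, x$data_density$density, col = "grey40")
  graphics::lines(g, x$diff_curve$density, col = "firebrick")
  graphics::abline(v = x$cutoffs, lty = 2)
  graphics::abline(h = 0, col = "grey80")
  graphics::legend("topright", c("splits", "data", "difference"), lty = 1,
                   col = c("steelblue", "grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Serialize a cutoff set (with its density curves) to JSON
#'
#' @param x a `cutoff_set`.
#' @param path file path.
#' @export
write_cutoff_set <- function(x, path) {
  stopifnot(inherits(x, "cutoff_set"))
  jsonlite::write_json(list(
    variable = x$variable, status = x$status, cutoffs = x$cutoffs,
    min_group_proportion = x$min_group_proportion,
    candidates = x$candidates,
    split_density = x$split_density[c("grid", "density", "bandwidth")],
    data_density = x$data_density[c("grid", "density", "bandwidth")],
    difference = x$diff_curve[c("grid", "density")]),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
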