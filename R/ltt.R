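## Lineage-through-time curves and the null-envelope comparison between an
## empirical curve and a set of simulated, pruned trees.

#' Lineage-through-time curve of a chronogram
#'
#' A step function from age (Ma before present) to the number of
#' reconstructed lineages: 2 at the crown, +1 at each branching, ending at
#' \code{n_tips} at the present.
#'
#' @param tree a chronogram (or a \code{branching_times} object).
#' @return object of class \code{ltt_curve}: list with \code{breakpoints}
#'   (descending ages) and \code{counts} (count on the interval starting at
#'   each breakpoint), plus \code{n_tips}.
#' @export
ltt_curve <- function(tree) {
  bt <- as_branching_times(tree)
  ages <- bt$times                       # descending, ties allowed
  uq <- unique(ages)
  counts <- 1L + vapply(uq, function(a) sum(ages >= a), integer(1))
  structure(list(breakpoints = uq, counts = counts, n_tips = bt$n_tips),
            class = "ltt_curve")
}

## Lineage count of a curve at arbitrary ages (1 above the crown).
ltt_count_at <- function(curve, age) {
  vapply(age, function(a) {
    i <- which(curve$breakpoints >= a)
    if (!length(i)) 1L else curve$counts[max(i)]
  }, integer(1))
}

#' LTT curves for a set of trees
#'
#' @param trees non-empty list of chronograms.
#' @return list of \code{ltt_curve}, in input order.
#' @export
ltt_envelope <- function(trees) {
  if (!length(trees)) stop2("need at least one tree")
  lapply(trees, ltt_curve)
}

#' Compare an empirical LTT curve against a simulated envelope
#'
#' On a regular age grid from the oldest breakpoint (over all curves) down
#' to 0, flags ages where the empirical lineage count is strictly below the
#' minimum, or strictly above the maximum, over every envelope curve
#' (pointwise envelope of extremes, the default) or over a central quantile
#' band. Contiguous flagged ages are merged into intervals.
#'
#' @param empirical an \code{ltt_curve}.
#' @param envelope non-empty list of \code{ltt_curve}.
#' @param grid_step age grid resolution in Myr (default 0.01).
#' @param band \code{"extremes"} (default: outside all curves) or
#'   \code{"quantile"}.
#' @param probs lower/upper quantiles for \code{band = "quantile"}.
#' @return object of class \code{envelope_result}: lists
#'   \code{intervals_below} and \code{intervals_above} of (older, younger)
#'   age pairs, plus \code{n_sims} and the grid step.
#' @export
envelope_compare <- function(empirical, envelope, grid_step = 0.01,
                             band = c("extremes", "quantile"),
                             probs = c(0.025, 0.975)) {
  band <- match.arg(band)
  if (!length(envelope)) stop2("envelope must be non-empty")
  if (grid_step <= 0) stop2("grid_step must be > 0")
  oldest <- max(c(empirical$breakpoints[1],
                  vapply(envelope, function(c) c$breakpoints[1], numeric(1))))
  grid <- seq(oldest, 0, by = -grid_step)
  emp <- ltt_count_at(empirical, grid)
  sim <- vapply(envelope, ltt_count_at, integer(length(grid)), age = grid)
  if (is.null(dim(sim))) sim <- matrix(sim, nrow = length(grid))
  if (band == "extremes") {
    lo <- apply(sim, 1, min)
    hi <- apply(sim, 1, max)
  } else {
    lo <- apply(sim, 1, stats::quantile, probs = probs[1], type = 1)
    hi <- apply(sim, 1, stats::quantile, probs = probs[2], type = 1)
  }
  below <- emp < lo
  above <- emp > hi
  runs_to_intervals <- function(flag) {
    if (!any(flag)) return(list())
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- list()
    for (i in which(r$values))
      out[[length(out) + 1L]] <- c(older = grid[starts[i]],
                                   younger = grid[ends[i]])
    out
  }
  structure(list(intervals_below = runs_to_intervals(below),
                 intervals_above = runs_to_intervals(above),
                 n_sims = length(envelope), grid_step = grid_step,
                 oldest_age = oldest),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  cat("LTT envelope comparison against", x$n_sims, "simulated curves\n")
  fmt <- function(iv) if (!length(iv)) "  (none)\n" else
    paste0(vapply(iv, function(p)
      sprintf("  %.3f - %.3f Ma\n", p[["older"]], p[["younger"]]),
      character(1)), collapse = "")
  cat("empirical strictly below all simulated curves:\n", fmt(x$intervals_below),
      sep = "")
  cat("empirical strictly above all simulated curves:\n", fmt(x$intervals_above),
      sep = "")
  invisible(x)
}

#' Plot an empirical LTT curve over a simulated envelope
#'
#' Counts are drawn on a log scale (plotting only; comparisons always use
#' raw counts).
#'
#' @param empirical an \code{ltt_curve}.
#' @param envelope list of \code{ltt_curve}.
#' @param ... passed to \code{plot}.
#' @export
plot_ltt_envelope <- function(empirical, envelope, ...) {
  oldest <- max(c(empirical$breakpoints[1],
                  vapply(envelope, function(c) c$breakpoints[1], numeric(1))))
  plot(NULL, xlim = c(oldest, 0), ylim = c(1, max(empirical$n_tips,
       vapply(envelope, function(c) c$n_tips, integer(1)))),
       log = "y", xlab = "age (Ma)", ylab = "lineages", ...)
  step_xy <- function(cv) {
    x <- c(cv$breakpoints, 0)
    y <- c(cv$counts, cv$counts[length(cv$counts)])
    list(x = x, y = y)
  }
  for (cv in envelope) {
    s <- step_xy(cv)
    graphics::lines(s$x, s$y, type = "s", col = "grey70")
  }
  s <- step_xy(empirical)
  graphics::lines(s$x, s$y, type = "s", col = "black", lwd = 2)
  invisible(NULL)
}
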