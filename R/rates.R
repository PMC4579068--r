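## Speciation-rate estimators: the Baldwin-Sanderson whole-clade formula
## (ln N - ln N0)/T and the Magallon-Sanderson estimator
## ln(N(1 - eps) + eps)/T at a relative extinction fraction eps = mu/lambda.
## "log" is the natural log throughout: at eps = 0 the two formulas must
## agree (both reduce to ln N / T with N0 = 1), which is what makes rate
## profiles at different eps comparable.

new_rate_estimate <- function(rate, N, N0, T, epsilon, method) {
  structure(list(rate = rate, N = N, N0 = N0, T = T, epsilon = epsilon,
                 method = method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s rate: %.3f species/Myr (N = %g, N0 = %s, T = %g Myr, eps = %s)\n",
              x$method, x$rate, x$N, x$N0 %||% "-", x$T, x$epsilon %||% "-"))
  invisible(x)
}

#' Baldwin-Sanderson diversification rate
#'
#' \code{rate = (ln N - ln N0) / T}: net diversification from \code{N0}
#' initial lineages to \code{N} species over \code{T} Myr, assuming no
#' extinction.
#'
#' @param N final species count (\code{N >= N0}).
#' @param N0 initial lineage count (>= 1).
#' @param T elapsed time in Myr (> 0).
#' @return a \code{rate_estimate} (species/Myr).
#' @export
rate_baldwin_sanderson <- function(N, N0, T) {
  if (T <= 0) stop2("T must be > 0")
  if (N0 < 1) stop2("N0 must be >= 1")
  if (N < N0) stop2("N must be >= N0")
  new_rate_estimate((log(N) - log(N0)) / T, N, N0, T, epsilon = 0,
                    method = "baldwin_sanderson")
}

#' Magallon-Sanderson diversification rate with relative extinction
#'
#' \code{rate = ln(N (1 - eps) + eps) / T} with relative extinction
#' \code{eps = mu/lambda} in [0, 1]. When the argument of the log is below
#' 1 the (negative) rate is reported with a warning rather than clamped.
#'
#' @param N species count (>= 1).
#' @param T elapsed time in Myr (> 0).
#' @param eps relative extinction in [0, 1].
#' @return a \code{rate_estimate} (species/Myr).
#' @export
rate_magallon_sanderson <- function(N, T, eps) {
  if (T <= 0) stop2("T must be > 0")
  if (N < 1) stop2("N must be >= 1")
  if (eps < 0 || eps > 1) stop2("eps must be in [0, 1]")
  arg <- N * (1 - eps) + eps
  if (arg < 1)
    warning("log argument below 1: negative rate reported", call. = FALSE)
  new_rate_estimate(log(arg) / T, N, N0 = NA_real_, T, epsilon = eps,
                    method = "magallon_sanderson")
}

#' Whole-clade speciation rate from a crown age
#'
#' Baldwin-Sanderson with the crown convention \code{N0 = 2}: a crown
#' group starts from the two daughter lineages of its most recent common
#' ancestor.
#'
#' @param n_species total described species in the clade (>= 2).
#' @param crown_age crown age in Ma (> 0).
#' @return a \code{rate_estimate}.
#' @export
whole_clade_rate <- function(n_species, crown_age) {
  if (n_species < 2) stop2("n_species must be >= 2")
  rate_baldwin_sanderson(N = n_species, N0 = 2, T = crown_age)
}

#' Per-node speciation-rate profile
#'
#' For every internal node: \code{T} is the node age, \code{N} the number
#' of sampled descendant tips (optionally scaled by
#' \code{total_species / n_tips} as a proportional sampling correction).
#' At \code{eps = 0} the rate is Baldwin-Sanderson with the crown
#' convention \code{N0 = 2}; otherwise Magallon-Sanderson at \code{eps}.
#'
#' @param tree a chronogram.
#' @param eps relative extinction in [0, 1].
#' @param total_species optional total described species count for the
#'   proportional correction; NULL (default) uses raw sampled counts.
#' @return object of class \code{node_rate_profile}: a data.frame with one
#'   row per internal node, sorted old to young, with columns \code{node}
#'   (ape node number), \code{age}, \code{N}, \code{eps} and \code{rate}.
#' @export
per_node_rates <- function(tree, eps = 0, total_species = NULL) {
  stopifnot(inherits(tree, "chronogram"))
  if (eps < 0 || eps > 1) stop2("eps must be in [0, 1]")
  n <- n_tips(tree)
  nodes <- (n + 1L):(n + tree$Nnode)
  ndesc <- tabulate_descendant_tips(tree)
  scale <- if (is.null(total_species)) 1 else total_species / n
  rows <- lapply(nodes, function(nd) {
    T <- tree$node_age[nd]
    N <- ndesc[nd] * scale
    est <- if (eps == 0) rate_baldwin_sanderson(max(N, 2), 2, T)
           else rate_magallon_sanderson(max(N, 1), T, eps)
    data.frame(node = nd, age = T, N = N, eps = eps, rate = est$rate)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$age, out$node), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("node_rate_profile", "data.frame")
  out
}

## number of descendant tips per node (vector indexed by ape node number)
tabulate_descendant_tips <- function(tree) {
  n <- n_tips(tree)
  cnt <- c(rep(1L, n), integer(tree$Nnode))
  po <- stats::reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) cnt[po[i, 1]] <- cnt[po[i, 1]] + cnt[po[i, 2]]
  cnt
}
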