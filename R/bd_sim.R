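## Forward birth-death simulators conditioned on tip count, and random tip
## pruning. Conventions:
##   * Simulations start from 2 lineages at the crown.
##   * Conditioning on n tips uses the stop-at-next-birth convention: the
##     present is the instant of the birth event that would create the
##     (n+1)-th coexisting lineage; the n lineages extant just before it
##     form the returned (reconstructed, extant-only) tree. Under this
##     convention the inter-event waits while k lineages exist are Exp(k*lambda)
##     for a Yule process, so the crown age of a 2-tip tree is Exp(2*lambda).
##   * Piecewise (shifted) rates are specified as ages before the present,
##     which requires a fixed present: multi-epoch simulations condition
##     jointly on n extant tips and a fixed crown-to-present duration by
##     rejection (see simulate_piecewise).

#' Specification of a (piecewise) birth-death simulation
#'
#' Epochs are ordered oldest to youngest; \code{shift_times} are the ages
#' (Ma before present) at which rates change, strictly descending, one
#' fewer than the number of epochs.
#'
#' @param n_tips number of extant tips to condition on (>= 2).
#' @param lambda per-lineage speciation rates /Myr, one per epoch (oldest
#'   first), all > 0.
#' @param mu per-lineage extinction rates /Myr, same length, all >= 0.
#' @param shift_times ages of the rate shifts, Ma, strictly descending.
#' @param seed integer seed.
#' @param crown_age optional fixed crown-to-present duration (Ma) used to
#'   anchor multi-epoch simulations; when NULL it is solved from
#'   E[N(crown_age)] = n_tips.
#' @param max_retries cap on whole-simulation retries.
#' @return object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_tips, lambda, mu = rep(0, length(lambda)),
                            shift_times = numeric(0), seed = 1L,
                            crown_age = NULL, max_retries = 1e5) {
  if (n_tips < 2) stop2("n_tips must be >= 2")
  if (length(lambda) != length(mu)) stop2("lambda and mu must have equal length")
  if (length(shift_times) != length(lambda) - 1L)
    stop2("need one fewer shift time than epochs")
  if (any(lambda <= 0)) stop2("all speciation rates must be > 0")
  if (any(mu < 0)) stop2("extinction rates must be >= 0")
  if (length(shift_times) &&
      (any(shift_times <= 0) || any(diff(shift_times) >= 0)))
    stop2("shift_times must be positive and strictly descending")
  structure(list(n_tips = as.integer(n_tips), lambda = lambda, mu = mu,
                 shift_times = shift_times, seed = as.integer(seed),
                 crown_age = crown_age, max_retries = max_retries),
            class = "simulation_spec")
}

## ---- internal machinery ----------------------------------------------------

## Lineage table -> ape phylo. Each lineage is one edge; its end is a tip
## (dead or extant) or a split node. Lineages with parent 0 hang off the
## crown node.
build_phylo_from_lineages <- function(parent, t_start, t_end, end_type) {
  is_tip <- end_type != "split"
  ntip <- sum(is_tip)
  node_num <- integer(length(parent))
  node_num[is_tip] <- seq_len(ntip)
  node_num[!is_tip] <- ntip + 1L + seq_len(sum(!is_tip))
  root_num <- ntip + 1L
  parent_node <- rep(root_num, length(parent))
  has_parent <- parent > 0L
  parent_node[has_parent] <- node_num[parent[has_parent]]
  lab <- character(ntip)
  lab[node_num[is_tip & end_type == "extant"]] <-
    paste0("t", seq_len(sum(end_type == "extant")))
  if (any(end_type == "dead"))
    lab[node_num[is_tip & end_type == "dead"]] <-
      paste0("x", seq_len(sum(end_type == "dead")))
  phy <- list(edge = cbind(parent_node, node_num),
              edge.length = t_end - t_start,
              tip.label = lab,
              Nnode = sum(!is_tip) + 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy <- ape::collapse.singles(phy)
  stats::reorder(phy, "cladewise")
}

## Pure-birth topology from forward birth times (crown at 0); present T_end.
yule_tree_from_birth_times <- function(birth_times, T_end) {
  n_final <- length(birth_times) + 2L
  parent <- c(0L, 0L, integer(length(birth_times) * 2L))
  t_start <- c(0, 0, numeric(length(birth_times) * 2L))
  t_end <- numeric(2L + length(birth_times) * 2L)
  end_type <- character(2L + length(birth_times) * 2L)
  active <- c(1L, 2L)
  nxt <- 3L
  for (b in seq_along(birth_times)) {
    tb <- birth_times[b]
    j <- active[sample.int(length(active), 1L)]
    t_end[j] <- tb; end_type[j] <- "split"
    for (c in 0:1) {
      parent[nxt + c] <- j; t_start[nxt + c] <- tb
    }
    active <- c(active[active != j], nxt, nxt + 1L)
    nxt <- nxt + 2L
  }
  t_end[active] <- T_end
  end_type[active] <- "extant"
  keep <- seq_len(nxt - 1L)
  stopifnot(length(active) == n_final)
  build_phylo_from_lineages(parent[keep], t_start[keep], t_end[keep],
                            end_type[keep])
}

## One general birth-death attempt with rates switching at fixed forward
## times. Runs until `stop_fun` says stop or extinction. Returns NULL on
## extinction, else the lineage table and stop time.
## lams/mus: per (forward) interval; bounds: forward times of the switches
## (ascending), length = intervals - 1. If T_end is finite the attempt runs
## to exactly T_end (no stop_fun).
sim_bd_attempt <- function(lams, mus, bounds, T_end = Inf, n_stop = NULL) {
  parent <- c(0L, 0L); t_start <- c(0, 0); t_end <- c(NA_real_, NA_real_)
  end_type <- c("open", "open")
  active <- c(1L, 2L)
  t <- 0
  interval <- 1L
  repeat {
    k <- length(active)
    if (k == 0L) return(NULL)
    lam <- lams[interval]; mu <- mus[interval]
    wait <- rexp(1L, rate = k * (lam + mu))
    nb <- if (interval <= length(bounds)) bounds[interval] else Inf
    if (nb < T_end && t + wait >= nb) {
      t <- nb; interval <- interval + 1L
      next  # memoryless: redraw under the new rates
    }
    if (t + wait >= T_end) {  # only reachable when T_end is finite
      t <- T_end
      break
    }
    t <- t + wait
    j <- active[sample.int(k, 1L)]
    if (runif(1L) < lam / (lam + mu)) {
      ## birth: stop BEFORE realising it if it would create lineage n_stop+1
      if (!is.null(n_stop) && k == n_stop) break
      t_end[j] <- t; end_type[j] <- "split"
      m <- length(parent)
      parent <- c(parent, j, j); t_start <- c(t_start, t, t)
      t_end <- c(t_end, NA_real_, NA_real_); end_type <- c(end_type, "open", "open")
      active <- c(active[active != j], m + 1L, m + 2L)
    } else {
      t_end[j] <- t; end_type[j] <- "dead"
      active <- active[active != j]
    }
  }
  t_end[active] <- t
  end_type[active] <- "extant"
  list(parent = parent, t_start = t_start, t_end = t_end,
       end_type = end_type, T_stop = t, n_extant = length(active))
}

reconstructed_tree <- function(att) {
  phy <- build_phylo_from_lineages(att$parent, att$t_start, att$t_end,
                                   att$end_type)
  dead <- grep("^x", phy$tip.label, value = TRUE)
  if (length(dead)) phy <- ape::drop.tip(phy, dead)
  as_chronogram(phy)
}

## ---- exported simulators ---------------------------------------------------

#' Simulate a Yule (pure-birth) chronogram with n tips
#'
#' Forward simulation from 2 lineages; the present is anchored at the birth
#' event that would create the (n+1)-th lineage, so waits while k lineages
#' exist are Exp(k lambda).
#'
#' @param n number of tips (>= 2).
#' @param lam speciation rate /Myr (> 0).
#' @param seed integer seed.
#' @return a chronogram with exactly \code{n} tips.
#' @export
simulate_yule <- function(n, lam, seed = 1L) {
  if (n < 2) stop2("n must be >= 2")
  if (lam <= 0) stop2("lam must be > 0")
  with_seed(seed, {
    waits <- rexp(n - 1L, rate = lam * (2:n))
    T_end <- sum(waits)
    births <- if (n > 2) cumsum(waits[seq_len(n - 2L)]) else numeric(0)
    as_chronogram(yule_tree_from_birth_times(births, T_end))
  })
}

#' Simulate a birth-death chronogram conditioned on n surviving tips
#'
#' Forward simulation retried until n extant lineages are reached (the
#' present is the birth that would create the (n+1)-th coexisting lineage);
#' extinct lineages are pruned and the reconstructed extant-only tree is
#' returned. Requires a supercritical process (lam > mu).
#'
#' @param n number of surviving tips (>= 2).
#' @param lam speciation rate /Myr.
#' @param mu extinction rate /Myr, \code{0 <= mu < lam}.
#' @param seed integer seed.
#' @param max_retries cap on whole-simulation retries.
#' @return a chronogram with exactly \code{n} tips.
#' @export
simulate_bd <- function(n, lam, mu = 0, seed = 1L, max_retries = 1e5) {
  if (n < 2) stop2("n must be >= 2")
  if (lam <= mu) stop2("requires lam > mu (supercritical process)")
  if (mu < 0) stop2("mu must be >= 0")
  with_seed(seed, {
    for (i in seq_len(max_retries)) {
      att <- sim_bd_attempt(lam, mu, numeric(0), T_end = Inf, n_stop = n)
      if (!is.null(att)) return(reconstructed_tree(att))
    }
    stop2("no surviving simulation in ", max_retries, " retries")
  })
}

## Expected crown-to-present duration solving E[N(T)] = n under the
## piecewise rates (epochs oldest-first, shifts as ages).
solve_anchor_age <- function(n, lambda, mu, shift_times) {
  r <- lambda - mu
  s <- c(shift_times, 0)           # epoch e spans ages [s[e], older boundary)
  ## integral of r over ages [0, s_max] (all epochs but the oldest)
  lens <- -diff(s)                 # durations of epochs 2..E (young side)
  C <- sum(r[-1] * lens)
  target <- log(n / 2)
  r1 <- r[1]
  if (r1 <= 0 || target - C <= 0) {
    ## the younger epochs alone already reach the expected count: anchor
    ## the crown just above the oldest shift (conditioning still enforces
    ## exactly n tips)
    return(shift_times[1] * 1.05)
  }
  shift_times[1] + (target - C) / r1
}

#' Simulate a chronogram under piecewise-constant birth-death rates
#'
#' Rates switch for every lineage at the shift ages (Ma before present).
#' A single-epoch spec delegates to \code{\link{simulate_bd}}. With two or
#' more epochs the shift ages require a fixed present, so the simulation is
#' anchored: the crown-to-present duration is fixed at
#' \code{spec$crown_age} (default: the age at which the expected number of
#' lineages equals \code{n_tips}) and whole simulations are retried until
#' exactly \code{n_tips} lineages are extant at the present.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return a chronogram with exactly \code{spec$n_tips} tips; its
#'   \code{sim_anchor_age} attribute records the anchored duration.
#' @export
simulate_piecewise <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  E <- length(spec$lambda)
  if (any(spec$lambda <= spec$mu))
    stop2("each epoch requires lam > mu")
  if (E == 1L)
    return(simulate_bd(spec$n_tips, spec$lambda, spec$mu, seed = spec$seed,
                       max_retries = spec$max_retries))
  T_end <- spec$crown_age %||%
    solve_anchor_age(spec$n_tips, spec$lambda, spec$mu, spec$shift_times)
  if (T_end <= max(spec$shift_times))
    stop2("crown_age must exceed the oldest shift time")
  bounds <- T_end - spec$shift_times   # forward times, ascending
  pure_birth <- all(spec$mu == 0)
  n <- spec$n_tips
  with_seed(spec$seed, {
    for (i in seq_len(spec$max_retries)) {
      if (pure_birth) {
        bt <- pure_birth_fixed_T(n, spec$lambda, bounds, T_end)
        if (is.null(bt)) next
        tree <- as_chronogram(yule_tree_from_birth_times(bt, T_end))
      } else {
        att <- sim_bd_attempt(spec$lambda, spec$mu, bounds, T_end = T_end)
        if (is.null(att) || att$n_extant != n) next
        tree <- reconstructed_tree(att)
        if (n_tips(tree) != n) next
      }
      attr(tree, "sim_anchor_age") <- T_end
      return(tree)
    }
    stop2("no accepted simulation in ", spec$max_retries,
          " retries; consider supplying crown_age")
  })
}

## Vectorised fixed-duration pure-birth count process: returns forward birth
## times if exactly n lineages are extant at T_end, else NULL.
pure_birth_fixed_T <- function(n, lams, bounds, T_end) {
  births <- numeric(n - 1L)   # room for the early-reject (n-1)th birth
  k <- 2L; t <- 0; interval <- 1L
  nb <- c(bounds, Inf)
  while (k <= n) {
    w <- rexp(1L, rate = k * lams[interval])
    if (t + w >= nb[interval] && nb[interval] < T_end) {
      t <- nb[interval]; interval <- interval + 1L; next
    }
    t <- t + w
    if (t >= T_end) break
    if (k == n) return(NULL)       # (n+1)-th lineage before the present
    births[k - 1L] <- t
    k <- k + 1L
  }
  if (k != n) return(NULL)
  births[seq_len(n - 2L)]
}

#' Randomly prune tips from a chronogram
#'
#' Removes \code{k} tips chosen uniformly without replacement, suppressing
#' the resulting degree-2 nodes (branch lengths summed), which emulates
#' incomplete taxon sampling. All pairwise divergence ages among surviving
#' tips are unchanged.
#'
#' @param tree a chronogram.
#' @param k number of tips to remove (\code{0 <= k <= n_tips - 2}).
#' @param seed integer seed.
#' @return a chronogram with \code{n_tips - k} tips.
#' @export
prune_random_tips <- function(tree, k, seed = 1L) {
  stopifnot(inherits(tree, "chronogram"))
  n <- n_tips(tree)
  if (k < 0 || k > n - 2L)
    stop2("k must be between 0 and n_tips - 2 (= ", n - 2L, ")")
  if (k == 0L) return(tree)
  drop <- with_seed(seed, sample(tree$tip.label, k))
  as_chronogram(ape::drop.tip(tree, drop))
}
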