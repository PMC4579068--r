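## Piecewise-constant reconstructed birth-death likelihood with a present-day
## sampling probability rho, conditioned on survival of both crown lineages,
## plus grid-search shift fitting and likelihood-ratio model selection.
##
## Model: epochs are numbered present-to-past; epoch j spans ages
## [s_{j-1}, s_j) with s_0 = 0 and the shift times s_1 < s_2 < ... (an age
## exactly at a shift belongs to the older epoch). Let p(t) be the
## probability that a lineage alive at age t leaves no sampled descendant
## and q(t) the density factor for a lineage represented by exactly one
## reconstructed lineage. Within an epoch with rates (lambda, mu):
##     p' = mu - (lambda + mu) p + lambda p^2,       p(0) = 1 - rho
##     q' = (2 lambda p - (lambda + mu)) q,          q(0) = rho
## whose closed forms are propagated across epoch boundaries. Writing
## c = lambda - mu and K = (p0 - 1)/(p0 - mu/lambda) for the value p0 at the
## epoch start,
##     p(dt)     = (1 - (mu/lambda) K e^{c dt}) / (1 - K e^{c dt})
##     log q(dt) = log q0 + 2 [log(1 - p(dt)) - log(1 - p0)] - c dt
## (the lambda = mu and p0 = mu/lambda degenerate cases are handled
## separately). The log-density of the branching times x1 >= ... >= x_{n-1}
## of a crown tree, conditioned on both crown lineages surviving to be
## sampled, is
##     2 log q(x1) - 2 log(1 - p(x1)) +
##         sum_{i=2}^{n-1} [log lambda(x_i) + log q(x_i)].

#' Piecewise-constant birth-death model with sampling fraction
#'
#' Epochs are ordered present-to-past: \code{lambdas[1]} applies on
#' \code{[0, shift_times[1])}. An age exactly at a shift time belongs to
#' the older epoch.
#'
#' @param lambdas speciation rates /Myr per epoch (present-to-past), > 0.
#' @param mus extinction rates /Myr per epoch, >= 0.
#' @param shift_times shift ages in Ma, strictly ascending, one fewer than
#'   the number of epochs.
#' @param rho sampling probability at present, in (0, 1].
#' @return object of class \code{shift_model}.
#' @export
shift_model <- function(lambdas, mus = rep(0, length(lambdas)),
                        shift_times = numeric(0), rho = 1) {
  if (length(lambdas) != length(mus)) stop2("lambdas and mus length mismatch")
  if (length(shift_times) != length(lambdas) - 1L)
    stop2("need one fewer shift time than epochs")
  if (any(lambdas <= 0)) stop2("speciation rates must be > 0")
  if (any(mus < 0)) stop2("extinction rates must be >= 0")
  if (length(shift_times) &&
      (any(shift_times <= 0) || any(diff(shift_times) <= 0)))
    stop2("shift_times must be positive and strictly ascending")
  if (rho <= 0 || rho > 1) stop2("rho must be in (0, 1]")
  structure(list(lambdas = lambdas, mus = mus, shift_times = shift_times,
                 rho = rho),
            class = "shift_model")
}

## Propagate p across a duration dt within one epoch.
pq_step_p <- function(lam, mu, p0, dt) {
  if (dt <= 0) return(p0)
  if (abs(lam - mu) < 1e-12) {
    inv <- 1 / (1 - p0) + lam * dt
    return(1 - 1 / inv)
  }
  ratio <- mu / lam
  if (abs(p0 - ratio) < 1e-15) return(p0)   # fixed point (e.g. rho=1, mu=0)
  K <- (p0 - 1) / (p0 - ratio)
  e <- exp((lam - mu) * dt)
  (1 - ratio * K * e) / (1 - K * e)
}

## Epoch-start values of p, log(1-p), log q for a shift_model.
pq_epoch_starts <- function(m) {
  E <- length(m$lambdas)
  starts <- c(0, m$shift_times)
  p <- numeric(E); l1p <- numeric(E); lq <- numeric(E)
  p[1] <- 1 - m$rho; l1p[1] <- log(m$rho); lq[1] <- log(m$rho)
  if (E > 1) for (j in seq_len(E - 1)) {
    dt <- starts[j + 1] - starts[j]
    pj <- pq_step_p(m$lambdas[j], m$mus[j], p[j], dt)
    if (!is.finite(pj) || pj < 0 || pj >= 1) return(NULL)
    l1pj <- log1p(-pj)
    lq[j + 1] <- lq[j] + 2 * (l1pj - l1p[j]) - (m$lambdas[j] - m$mus[j]) * dt
    p[j + 1] <- pj; l1p[j + 1] <- l1pj
  }
  list(starts = starts, p = p, l1p = l1p, lq = lq)
}

## p, log(1-p), log q and the epoch rate at arbitrary ages (vectorised).
pq_eval <- function(m, t) {
  st <- pq_epoch_starts(m)
  if (is.null(st)) return(NULL)
  j <- findInterval(t, m$shift_times) + 1L   # boundary -> older epoch
  dt <- t - st$starts[j]
  p <- mapply(pq_step_p, m$lambdas[j], m$mus[j], st$p[j], dt)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) return(NULL)
  l1p <- log1p(-p)
  lq <- st$lq[j] + 2 * (l1p - st$l1p[j]) - (m$lambdas[j] - m$mus[j]) * dt
  list(p = p, l1p = l1p, lq = lq, lam = m$lambdas[j])
}

#' Log-likelihood of branching times under a birth-death-shift model
#'
#' Log probability density of the branching times of an ultrametric crown
#' tree under the piecewise-constant reconstructed birth-death process with
#' uniform present-day sampling probability \code{rho}, conditioned on both
#' crown lineages surviving to be sampled. Returns \code{-Inf} where the
#' density is zero or parameters are inadmissible.
#'
#' @param bt a \code{branching_times} object (or chronogram, or numeric
#'   vector of node ages).
#' @param model a \code{\link{shift_model}}.
#' @return log-likelihood in nats.
#' @export
bd_shift_loglik <- function(bt, model) {
  stopifnot(inherits(model, "shift_model"))
  bt <- as_branching_times(bt)
  x <- bt$times
  ev <- pq_eval(model, x)
  if (is.null(ev)) return(-Inf)
  ll <- 2 * ev$lq[1] - 2 * ev$l1p[1]
  if (length(x) > 1)
    ll <- ll + sum(log(ev$lam[-1]) + ev$lq[-1])
  if (!is.finite(ll)) return(-Inf)
  ll
}

new_fit_result <- function(model, loglik, n_free, converged) {
  structure(list(model = model, loglik = loglik, n_free_params = n_free,
                 converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  m <- x$model
  cat(sprintf("birth-death-shift fit: %d epoch(s), loglik = %.4f, %d free parameter(s)\n",
              length(m$lambdas), x$loglik, x$n_free_params))
  cat("  lambda (present-to-past):", paste(signif(m$lambdas, 4), collapse = ", "), "\n")
  if (any(m$mus > 0))
    cat("  mu     (present-to-past):", paste(signif(m$mus, 4), collapse = ", "), "\n")
  if (length(m$shift_times))
    cat("  shift times (Ma):", paste(signif(m$shift_times, 4), collapse = ", "), "\n")
  invisible(x)
}

## ---- sufficient statistics and the Yule/rho=1 profile fast path ------------

## Per-epoch birth counts B_e (branchings excluding the crown) and
## reconstructed lineage-time A_e for epochs delimited by ascending shifts.
epoch_stats <- function(x, shifts) {
  bounds <- c(0, shifts, Inf)
  E <- length(shifts) + 1L
  B <- integer(E); A <- numeric(E)
  for (e in seq_len(E)) {
    lo <- bounds[e]; hi <- bounds[e + 1]
    B[e] <- sum(x[-1] >= lo & x[-1] < hi)
    len <- pmin(x, hi) - lo
    len[len < 0] <- 0
    A[e] <- sum(len) + max(min(x[1], hi) - lo, 0)  # crown counted twice
  }
  list(B = B, A = A)
}

## Closed-form profile maximum for a pure-birth (mu = 0, rho = 1) model
## with fixed shifts: lambda_e = B_e / A_e, profiled loglik
## sum_e B_e (log(B_e/A_e) - 1). Epochs with no births get a tiny floor.
yule_profile_fit <- function(x, shifts, floor = 1e-8) {
  st <- epoch_stats(x, shifts)
  lam <- ifelse(st$B > 0, st$B / st$A, floor)
  ll <- sum(ifelse(st$B > 0, st$B * (log(lam) - 1), -floor * st$A))
  list(ll = ll, lambdas = lam)
}

## ---- rate optimisation at fixed shift times --------------------------------

## Deterministic multi-start optimisation of rates for given shift times.
## extra_starts: list of list(lambdas, mus) seeds (e.g. the nested fit).
opt_rates <- function(x, shifts, rho, process, extra_starts = list(),
                      quick = FALSE) {
  E <- length(shifts) + 1L
  n <- length(x) + 1L
  S <- 2 * x[1] + sum(x[-1])
  lam0 <- max(n - 2L, 1L) / S          # whole-tree pure-birth scale
  bd <- process == "birthdeath"
  obj <- function(theta) {
    lams <- exp(theta[seq_len(E)])
    mus <- if (bd) exp(theta[E + seq_len(E)]) else rep(0, E)
    m <- tryCatch(shift_model(lams, mus, shifts, rho), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ll <- bd_shift_loglik_x(x, m)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- list()
  mults <- if (quick) 1 else c(0.3, 1, 3)
  epss <- if (!bd) 0 else if (quick) 0.25 else c(0.05, 0.5)
  for (mm in mults) for (ee in epss) {
    lams <- rep(lam0 * mm / max(1 - ee, 0.1), E)
    th <- log(lams)
    if (bd) th <- c(th, log(pmax(lams * ee, 1e-8)))
    starts[[length(starts) + 1L]] <- th
  }
  for (s in extra_starts) {
    th <- log(pmax(s$lambdas, 1e-10))
    if (bd) th <- c(th, log(pmax(s$mus, 1e-8)))
    if (length(th) == E * (1L + bd)) starts[[length(starts) + 1L]] <- th
  }
  best <- NULL
  ctrl <- if (quick) list(maxit = 500, reltol = 1e-8)
          else list(maxit = 5000, reltol = 1e-10)
  for (th in starts) {
    fit <- if (length(th) == 1L) {
      o <- optimise(function(z) obj(z), interval = th + c(-8, 8), tol = 1e-9)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(th, obj, method = "Nelder-Mead", control = ctrl)
    }
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  lams <- exp(best$par[seq_len(E)])
  mus <- if (bd) exp(best$par[E + seq_len(E)]) else rep(0, E)
  list(ll = -best$value, lambdas = lams, mus = mus,
       converged = (best$convergence %||% 0L) == 0L && best$value < 1e9)
}

## loglik from a raw descending age vector (skips re-validation)
bd_shift_loglik_x <- function(x, model) {
  ev <- pq_eval(model, x)
  if (is.null(ev)) return(-Inf)
  ll <- 2 * ev$lq[1] - 2 * ev$l1p[1]
  if (length(x) > 1) ll <- ll + sum(log(ev$lam[-1]) + ev$lq[-1])
  if (!is.finite(ll)) return(-Inf)
  ll
}

#' Maximum-likelihood constant-rate fit
#'
#' Maximises \code{\link{bd_shift_loglik}} over lambda (and mu for the
#' birth-death process) with a single epoch and fixed sampling probability
#' \code{rho}. Deterministic: multi-start from a fixed grid scaled by the
#' whole-tree pure-birth estimate, with derivative-free refinement.
#'
#' @param bt branching times (>= 2 entries).
#' @param rho sampling probability in (0, 1].
#' @param process \code{"yule"} (mu fixed at 0, 1 free parameter) or
#'   \code{"birthdeath"} (2 free parameters).
#' @return a \code{fit_result}.
#' @export
fit_constant <- function(bt, rho = 1, process = c("yule", "birthdeath")) {
  process <- match.arg(process)
  bt <- as_branching_times(bt)
  x <- bt$times
  if (length(x) < 2) stop2("need at least 2 branching times")
  opt <- opt_rates(x, numeric(0), rho, process)
  n_free <- if (process == "yule") 1L else 2L
  new_fit_result(shift_model(opt$lambdas, opt$mus, numeric(0), rho),
                 opt$ll, n_free, opt$converged)
}

## Admissible shift-time grid: multiples of grid_step with at least
## `margin` branching events strictly older and strictly younger.
shift_grid <- function(x, grid_step, margin = 2L) {
  cand <- seq(grid_step, floor(x[1] / grid_step) * grid_step, by = grid_step)
  keep <- vapply(cand, function(a)
    sum(x > a) >= margin && sum(x < a) >= margin, logical(1))
  cand[keep]
}

#' Maximum-likelihood fit with k diversification-rate shifts
#'
#' Shift times are searched over a regular age grid (multiples of
#' \code{grid_step}, bounded away from both ends of the branching times by
#' \code{margin} branching events), maximising over the epoch rates at each
#' candidate. The first shift is searched exhaustively; further shifts are
#' added greedily conditional on the shifts already placed (re-optimising
#' all rates). Ties in log-likelihood are broken toward the older shift
#' time. For a pure-birth process with complete sampling the per-epoch
#' rate maximisation uses its closed form; otherwise numerical
#' optimisation seeded with the nested model is used, which guarantees
#' \code{loglik(k) >= loglik(k-1)}.
#'
#' @param bt branching times.
#' @param rho sampling probability in (0, 1].
#' @param k number of shifts (>= 1).
#' @param grid_step grid resolution in Myr (default 0.1).
#' @param process \code{"yule"} or \code{"birthdeath"}.
#' @param margin minimum branching events on each side of a shift.
#' @return a \code{fit_result} with \code{k + 1} epochs.
#' @export
fit_k_shifts <- function(bt, rho = 1, k = 1L, grid_step = 0.1,
                         process = c("yule", "birthdeath"), margin = 2L) {
  process <- match.arg(process)
  if (k < 1) stop2("k must be >= 1")
  if (grid_step <= 0) stop2("grid_step must be > 0")
  bt <- as_branching_times(bt)
  x <- bt$times
  grid <- shift_grid(x, grid_step, margin)
  if (!length(grid)) stop2("no admissible shift time on the grid")
  fast <- process == "yule" && rho == 1
  prev <- if (k == 1L) fit_constant(bt, rho, process)
          else fit_k_shifts(bt, rho, k - 1L, grid_step, process, margin)
  prev_shifts <- prev$model$shift_times
  cand <- setdiff(grid, prev_shifts)
  best_ll <- -Inf; best_shifts <- NULL; best_opt <- NULL
  for (a in sort(cand, decreasing = TRUE)) {   # oldest first: ties keep older
    shifts <- sort(c(prev_shifts, a))
    if (fast) {
      pf <- yule_profile_fit(x, shifts)
      opt <- list(ll = pf$ll, lambdas = pf$lambdas,
                  mus = rep(0, length(pf$lambdas)), converged = TRUE)
    } else {
      seeds <- list(list(lambdas = nested_seed(prev$model$lambdas,
                                               prev_shifts, shifts),
                         mus = nested_seed(prev$model$mus,
                                           prev_shifts, shifts)))
      opt <- opt_rates(x, shifts, rho, process, extra_starts = seeds,
                       quick = TRUE)
    }
    if (opt$ll > best_ll + 1e-12) {
      best_ll <- opt$ll; best_shifts <- shifts; best_opt <- opt
    }
  }
  if (!fast) {
    ## polish the winning shift placement with the full multi-start
    seeds <- list(list(lambdas = best_opt$lambdas, mus = best_opt$mus),
                  list(lambdas = nested_seed(prev$model$lambdas, prev_shifts,
                                             best_shifts),
                       mus = nested_seed(prev$model$mus, prev_shifts,
                                         best_shifts)))
    best_opt <- opt_rates(x, best_shifts, rho, process, extra_starts = seeds)
    best_ll <- best_opt$ll
  }
  E <- k + 1L
  n_free <- E * (if (process == "yule") 1L else 2L) + k
  new_fit_result(shift_model(best_opt$lambdas, best_opt$mus, best_shifts, rho),
                 best_ll, n_free, best_opt$converged)
}

## Duplicate the nested model's per-epoch values onto the refined epochs.
nested_seed <- function(vals, old_shifts, new_shifts) {
  vals[findInterval(c(0, new_shifts), c(0, old_shifts))]
}

#' Likelihood-ratio test between nested birth-death fits
#'
#' @param null_fit,alt_fit \code{fit_result}s; \code{alt_fit} must have
#'   strictly more free parameters.
#' @return list with \code{chi2}, \code{df} and \code{p}.
#' @export
lrt <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "fit_result"), inherits(alt_fit, "fit_result"))
  df <- alt_fit$n_free_params - null_fit$n_free_params
  if (df <= 0) stop2("models are not nested: free-parameter count must increase")
  d <- alt_fit$loglik - null_fit$loglik
  if (d < -1e-6)
    warning("alternative fit has lower log-likelihood than the null ",
            "(optimiser failure?); chi2 clamped at 0", call. = FALSE)
  chi2 <- max(2 * d, 0)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df = df, lower.tail = FALSE))
}
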