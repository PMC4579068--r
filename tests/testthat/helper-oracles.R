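## Independent oracles and small fixture builders. Everything here is
## deliberately written from first principles, not by calling the package
## internals it is used to check.

## ---- area-table builder ----------------------------------------------------

area_table_fixture <- function(ranges, alphabet = c("A", "B", "C", "D")) {
  structure(lapply(ranges, function(r) sort(strsplit(r, "")[[1]])),
            class = "area_table", alphabet = alphabet)
}

## ---- Yule branching-time density (symbolic closed form) --------------------

## log density of the branching times of a crown-conditioned pure-birth
## tree with complete sampling: each of the n-2 non-crown branchings
## contributes lambda e^{-lambda x}; the two crown lineages contribute
## e^{-lambda x1} each.
yule_loglik_oracle <- function(x, lam) {
  (length(x) - 1) * log(lam) - lam * (2 * x[1] + sum(x[-1]))
}

## ---- textbook constant-rate birth-death density (rho = 1) ------------------

## Nee-style closed forms, an independent algebra path from the package's
## general Riccati propagation: p0(t) = mu(1-e^{-ct})/(lambda - mu e^{-ct}),
## q(t) = c^2 e^{-ct}/(lambda - mu e^{-ct})^2 with c = lambda - mu.
bd_loglik_oracle_rho1 <- function(x, lam, mu) {
  cc <- lam - mu
  p0 <- function(t) mu * (1 - exp(-cc * t)) / (lam - mu * exp(-cc * t))
  lq <- function(t) 2 * log(cc) - cc * t - 2 * log(lam - mu * exp(-cc * t))
  2 * lq(x[1]) - 2 * log(1 - p0(x[1])) +
    sum(log(lam) + sapply(x[-1], lq))
}

## ---- RK4 integration of the p/q ODEs (piecewise, any rho) ------------------

## Numerical first-principles evaluation of the same log-density: integrates
## p' = mu - (lambda+mu) p + lambda p^2 and (log q)' = 2 lambda p -
## (lambda + mu) from the present with p(0) = 1 - rho, log q(0) = log rho.
pq_rk4_oracle <- function(lams, mus, shifts, rho, t_max, h = 2e-4) {
  lam_at <- function(t) lams[findInterval(t, shifts) + 1L]
  mu_at <- function(t) mus[findInterval(t, shifts) + 1L]
  fp <- function(t, p) mu_at(t) - (lam_at(t) + mu_at(t)) * p + lam_at(t) * p^2
  fq <- function(t, p) 2 * lam_at(t) * p - (lam_at(t) + mu_at(t))
  n <- ceiling(t_max / h); h <- t_max / n
  p <- 1 - rho; lq <- log(rho); t <- 0
  for (i in seq_len(n)) {
    k1 <- fp(t, p)
    p2 <- p + h / 2 * k1; k2 <- fp(t + h / 2, p2)
    p3 <- p + h / 2 * k2; k3 <- fp(t + h / 2, p3)
    p4 <- p + h * k3;     k4 <- fp(t + h, p4)
    lq <- lq + h / 6 * (fq(t, p) + 2 * fq(t + h / 2, p2) +
                          2 * fq(t + h / 2, p3) + fq(t + h, p4))
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  c(p = p, lq = lq)
}

bd_loglik_rk4_oracle <- function(x, lams, mus, shifts, rho, h = 2e-4) {
  ev <- lapply(x, function(t) pq_rk4_oracle(lams, mus, shifts, rho, t, h))
  lam_at <- function(t) lams[findInterval(t, shifts) + 1L]
  ll <- 2 * ev[[1]]["lq"] - 2 * log(1 - ev[[1]]["p"])
  for (i in seq_along(x)[-1])
    ll <- ll + log(lam_at(x[i])) + ev[[i]]["lq"]
  unname(ll)
}

## ---- exhaustive DIVA oracle ------------------------------------------------

## Set-based reimplementation of the DIVA cost model: states are character
## vectors of areas; the per-node speciation cost table is built by explicit
## enumeration of vicariance/duplication splits, and the global optimum by
## enumerating every assignment of states to internal nodes.
diva_oracle <- function(tree, areas, alphabet) {
  K <- length(alphabet)
  states <- unlist(lapply(seq_len(K), function(k)
    combn(alphabet, k, paste, collapse = "", simplify = FALSE)))
  as_set <- function(s) strsplit(s, "")[[1]]
  trans_cost <- function(a, b) length(setdiff(as_set(a), as_set(b))) +
    length(setdiff(as_set(b), as_set(a)))
  split_sets <- function(s) {
    ss <- as_set(s)
    if (length(ss) == 1L) return(list(list(s, s)))
    out <- list()
    for (k in seq_len(length(ss) - 1L)) {
      for (sub in combn(ss, k, simplify = FALSE)) {
        out[[length(out) + 1L]] <- list(paste(sub, collapse = ""),
                                        paste(setdiff(ss, sub), collapse = ""))
      }
    }
    out
  }
  ## memoised node cost: pc[s, t1, t2] = min over splits of s of the
  ## transformation costs to realised child states t1, t2
  ns <- length(states)
  pc <- array(Inf, dim = c(ns, ns, ns), dimnames = list(states, states, states))
  for (s in states) {
    for (sp in split_sets(s)) {
      c1 <- vapply(states, trans_cost, numeric(1), a = sp[[1]])
      c2 <- vapply(states, trans_cost, numeric(1), a = sp[[2]])
      pc[s, , ] <- pmin(pc[s, , ], outer(c1, c2, `+`))
    }
  }
  n <- length(tree$tip.label)
  internal <- (n + 1L):(n + tree$Nnode)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tip_state <- vapply(tree$tip.label,
                      function(t) paste(areas[[t]], collapse = ""), character(1))
  ## states, tip ranges and grid rows are all in canonical sorted-letter
  ## form, so strings index pc's dimnames directly
  grid <- expand.grid(rep(list(states), length(internal)),
                      stringsAsFactors = FALSE)
  costs <- apply(grid, 1, function(row) {
    st <- function(nd) if (nd <= n) tip_state[[nd]] else
      row[[match(nd, internal)]]
    tot <- 0
    for (v in internal) {
      ch <- kids[[as.character(v)]]
      tot <- tot + pc[st(v), st(ch[1]), st(ch[2])]
    }
    tot
  })
  best <- min(costs)
  opt <- grid[costs == best, , drop = FALSE]
  node_states <- lapply(seq_along(internal), function(i) {
    canon <- vapply(unique(opt[[i]]), function(s)
      paste(sort(as_set(s)), collapse = ""), character(1))
    sort(unique(canon))
  })
  names(node_states) <- as.character(internal)
  list(cost = best, node_states = node_states)
}

## random tip ranges over an alphabet
random_area_table <- function(tips, alphabet, max_size = 2) {
  at <- lapply(tips, function(t)
    sort(sample(alphabet, sample.int(max_size, 1L))))
  names(at) <- tips
  structure(at, class = "area_table", alphabet = alphabet)
}

## the 8-tip two-B-clades-in-an-A-backbone fixture (two areas)
dispersal_fixture <- function() {
  nwk <- "((((b1:1,b2:1):1,a1:2):1,a2:3):3,(((b3:1,b4:1):1,a3:2):1,a4:3):3);"
  tree <- parse_newick(nwk)
  ranges <- setNames(c(rep("B", 4), rep("A", 4)),
                     c("b1", "b2", "b3", "b4", "a1", "a2", "a3", "a4"))
  areas <- area_table_fixture(as.list(ranges[tree$tip.label]),
                              alphabet = c("A", "B"))
  list(tree = tree, areas = areas)
}

## vectorised sampler of Yule branching AGES under the package's stated
## convention (waits Exp(k lambda), k = 2..n; present at the last wait's
## end): one tree per row, independent of the package's tree builder.
yule_branching_ages_matrix <- function(reps, n, lam) {
  waits <- matrix(rexp(reps * (n - 1L), rate = 1), nrow = reps) /
    matrix(lam * (2:n), nrow = reps, ncol = n - 1L, byrow = TRUE)
  total <- rowSums(waits)
  ## ages of the crown and of births 3..n
  ages <- total - cbind(0, t(apply(waits[, seq_len(n - 2L), drop = FALSE],
                                   1, cumsum)))
  ages
}

## small-step (Bernoulli per dt) forward birth-death simulator, conditioned
## like simulate_bd: present at the first birth that would create lineage
## n+1; returns the crown age of the reconstructed (extant-only) tree, or
## NULL if the process dies. The genealogy is tracked explicitly so the
## reconstructed crown (MRCA of survivors) is computed from first
## principles.
smallstep_bd_crown <- function(n, lam, mu, dt = 0.004, max_steps = 2e5) {
  parent <- c(0L, 0L); t_split <- c(NA_real_, NA_real_)
  alive <- c(TRUE, TRUE); active <- c(1L, 2L)
  t <- 0
  for (s in seq_len(max_steps)) {
    k <- length(active)
    if (k == 0L) return(NULL)
    u <- stats::runif(1)
    if (u < k * lam * dt) {
      if (k == n) {
        ## present reached: reconstructed crown = MRCA of extant lineages.
        ## has_extant per lineage (children were appended after parents, so
        ## a reverse index sweep is a valid postorder)
        has_ext <- alive
        for (i in rev(seq_along(parent))) if (has_ext[i] && parent[i] > 0L)
          has_ext[parent[i]] <- TRUE
        ## descend from the original crown while only one side survives
        node <- 0L; crown_time <- 0
        repeat {
          ch <- which(parent == node & has_ext)
          if (length(ch) == 2L) break
          node <- ch
          crown_time <- t_split[ch]
        }
        return(t - crown_time)
      }
      j <- active[sample.int(k, 1L)]
      alive[j] <- FALSE; t_split[j] <- t
      parent <- c(parent, j, j); t_split <- c(t_split, NA, NA)
      alive <- c(alive, TRUE, TRUE)
      active <- c(active[active != j], length(parent) - 1L, length(parent))
    } else if (u < k * (lam + mu) * dt) {
      j <- active[sample.int(k, 1L)]
      alive[j] <- FALSE
      active <- active[active != j]
    }
    t <- t + dt
  }
  NULL
}
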