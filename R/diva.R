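## Dispersal-vicariance (DIVA) ancestral-range optimisation by dynamic
## programming over area subsets, and S-DIVA frequency profiles over a
## posterior tree sample.
##
## Cost model (the canonical DIVA one): speciation by vicariance (a disjoint
## split of a widespread parent range into two non-empty subsets) or by
## duplication (a single-area parent inherited by both daughters) costs 0;
## each unit-area dispersal (area gained along a branch) and each unit-area
## extinction (area lost along a branch) costs 1. Ranges are non-empty
## subsets of the coded alphabet, optionally capped at `maxareas` areas.
## Area sets are bitmasks over the alphabet internally.

range_to_mask <- function(range, alphabet) {
  idx <- match(range, alphabet)
  if (anyNA(idx)) stop2("range contains areas outside the alphabet: ",
                        paste(range[is.na(idx)], collapse = ", "))
  sum(bitwShiftL(1L, idx - 1L))
}

mask_to_range <- function(mask, alphabet) {
  paste(alphabet[bitwAnd(bitwShiftR(mask, seq_along(alphabet) - 1L), 1L) == 1L],
        collapse = "")
}

popcount <- function(m) {
  n <- 0L
  while (any(m > 0L)) { n <- n + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }
  n
}

## ordered vicariance/duplication splits of every state: list indexed by
## state mask, each element a 2-column matrix of (child1, child2) masks
make_splits <- function(K) {
  nstates <- bitwShiftL(1L, K) - 1L
  out <- vector("list", nstates)
  for (s in seq_len(nstates)) {
    if (popcount(s) == 1L) {
      out[[s]] <- cbind(s, s)
    } else {
      subs <- Filter(function(a) a != 0L && a != s,
                     lapply(seq_len(nstates), function(a)
                       if (bitwAnd(a, s) == a) a else 0L))
      subs <- unlist(subs)
      out[[s]] <- cbind(subs, bitwAnd(s, bitwXor(subs, nstates)))
    }
  }
  out
}

## transformation cost matrix T[x, y] = |y \ x| + |x \ y|
make_trans <- function(K) {
  nstates <- bitwShiftL(1L, K) - 1L
  outer(seq_len(nstates), seq_len(nstates),
        function(x, y) popcount(bitwAnd(x, bitwNot(y)) %% bitwShiftL(1L, K)) +
          popcount(bitwAnd(y, bitwNot(x)) %% bitwShiftL(1L, K)))
}

BIGCOST <- 1e9

#' DIVA ancestral-range reconstruction
#'
#' Minimises the total dispersal + extinction event count over ancestral
#' range assignments under the DIVA cost model, and returns, for every
#' internal node, the full set of ranges that occur in at least one
#' globally cost-optimal reconstruction (computed exactly by a post-order
#' cost pass and a pre-order outside-cost pass).
#'
#' @param tree a chronogram (topology only is used).
#' @param areas an \code{area_table} covering every tip.
#' @param maxareas maximum ancestral range size; default: unconstrained
#'   (the alphabet size).
#' @return object of class \code{diva_reconstruction}: \code{total_cost},
#'   \code{node_states} (named list, ape internal node number to character
#'   vector of optimal range strings), \code{multiplicity} (number of
#'   optimal ranges per node), \code{tip_states}, \code{alphabet}.
#' @export
diva_reconstruct <- function(tree, areas, maxareas = NULL) {
  stopifnot(inherits(tree, "chronogram"), inherits(areas, "area_table"))
  alphabet <- attr(areas, "alphabet")
  K <- length(alphabet)
  maxareas <- maxareas %||% K
  if (maxareas < 1 || maxareas > K) stop2("maxareas must be in 1..", K)
  n <- n_tips(tree)
  missing <- setdiff(tree$tip.label, names(areas))
  if (length(missing))
    stop2("tips missing from the area table: ", paste(missing, collapse = ", "))
  nstates <- bitwShiftL(1L, K) - 1L
  states <- seq_len(nstates)
  sizes <- popcount(states)
  admissible <- sizes <= maxareas
  splits <- make_splits(K)
  TR <- make_trans(K)

  tip_mask <- vapply(tree$tip.label, function(t) {
    m <- range_to_mask(areas[[t]], alphabet)
    if (popcount(m) > maxareas)
      stop2("tip '", t, "' has a range larger than maxareas")
    m
  }, integer(1))

  root <- n + 1L
  po <- stats::reorder(tree, "postorder")$edge
  children <- split(po[, 2], po[, 1])

  ## down pass: subtree cost per node state, and per-child inherited-range
  ## minima M_c[s] = min_t (down_c[t] + TR[s, t])
  down <- matrix(BIGCOST, nrow = n + tree$Nnode, ncol = nstates)
  Mc <- vector("list", n + tree$Nnode)
  for (tip in seq_len(n)) down[tip, tip_mask[tip]] <- 0
  node_order <- unique(po[, 1])              # postorder: children first
  for (v in node_order) {
    ch <- children[[as.character(v)]]
    for (c in ch) {
      dc <- down[c, ]
      Mc[[c]] <- vapply(states, function(s) min(dc + TR[s, ]), numeric(1))
    }
    m1 <- Mc[[ch[1]]]; m2 <- Mc[[ch[2]]]
    for (s in states[admissible]) {
      sp <- splits[[s]]
      down[v, s] <- min(m1[sp[, 1]] + m2[sp[, 2]])
    }
  }
  total <- min(down[root, ])

  ## up pass: outside cost per internal node state
  up <- matrix(BIGCOST, nrow = n + tree$Nnode, ncol = nstates)
  up[root, ] <- 0
  pre <- node_order[length(node_order):1]    # preorder over internal nodes
  for (v in pre) {
    ch <- children[[as.character(v)]]
    outv <- up[v, ]
    for (i in 1:2) {
      c <- ch[i]; sib <- ch[3L - i]
      if (c <= n) next
      msib <- Mc[[sib]]
      h <- rep(BIGCOST, nstates)
      for (s in states[admissible]) {
        if (outv[s] >= BIGCOST) next
        sp <- splits[[s]]
        mine <- sp[, i]; theirs <- sp[, 3L - i]
        val <- outv[s] + msib[theirs]
        for (j in seq_along(mine))
          if (val[j] < h[mine[j]]) h[mine[j]] <- val[j]
      }
      up[c, ] <- vapply(states, function(t) min(h + TR[, t]), numeric(1))
    }
  }

  internal <- (n + 1L):(n + tree$Nnode)
  node_states <- lapply(internal, function(v) {
    opt <- states[down[v, ] + up[v, ] <= total + 1e-9]
    vapply(opt, mask_to_range, character(1), alphabet = alphabet)
  })
  names(node_states) <- internal
  tip_states <- vapply(tip_mask, mask_to_range, character(1),
                       alphabet = alphabet)
  names(tip_states) <- tree$tip.label
  structure(list(total_cost = as.integer(round(total)),
                 node_states = node_states,
                 multiplicity = lengths(node_states),
                 tip_states = tip_states,
                 alphabet = alphabet, maxareas = maxareas),
            class = "diva_reconstruction")
}

#' S-DIVA: DIVA frequencies over a posterior tree sample
#'
#' For every internal node of the representative tree, finds the sample
#' trees containing the identical clade (same descendant tip-label set),
#' runs DIVA on each, and pools that node's optimal ranges with each
#' range weighted by 1/(number of optimal ranges in that tree), normalised
#' over the contributing trees.
#'
#' @param sample list of chronograms sharing the representative's tips.
#' @param representative the representative (e.g. MCC) chronogram.
#' @param areas an \code{area_table}.
#' @param maxareas see \code{\link{diva_reconstruct}}.
#' @return object of class \code{range_profile}: named list (ape node
#'   number) of lists with \code{freqs} (named numeric, summing to 1 when
#'   covered) and \code{coverage} (fraction of sample trees containing the
#'   clade); plus \code{n_sample}.
#' @export
sdiva <- function(sample, representative, areas, maxareas = NULL) {
  stopifnot(inherits(representative, "chronogram"), length(sample) >= 1)
  rep_tips <- sort(representative$tip.label)
  for (tr in sample)
    if (!identical(sort(tr$tip.label), rep_tips))
      stop2("all sample trees must share the representative's tip labels")
  rep_keys <- clade_key_strings(representative)
  acc <- lapply(rep_keys, function(k) numeric(0))
  hits <- setNames(integer(length(rep_keys)), names(rep_keys))
  for (tr in sample) {
    rec <- diva_reconstruct(tr, areas, maxareas)
    keys <- clade_key_strings(tr)
    lut <- setNames(names(keys), keys)      # key string -> node number
    for (nd in names(rep_keys)) {
      tnode <- unname(lut[rep_keys[[nd]]])
      if (is.na(tnode)) next
      st <- rec$node_states[[tnode]]
      w <- 1 / length(st)
      a <- acc[[nd]]
      for (s in st) a[s] <- (if (is.na(a[s])) 0 else a[s]) + w
      acc[[nd]] <- a
      hits[[nd]] <- hits[[nd]] + 1L
    }
  }
  profile <- lapply(names(rep_keys), function(nd) {
    cov <- hits[[nd]] / length(sample)
    freqs <- acc[[nd]]
    if (hits[[nd]] > 0) freqs <- freqs / hits[[nd]]
    list(freqs = freqs, coverage = cov)
  })
  names(profile) <- names(rep_keys)
  structure(list(nodes = profile, n_sample = length(sample)),
            class = "range_profile")
}

#' @export
print.range_profile <- function(x, ...) {
  cat("S-DIVA range profile over", x$n_sample, "sample trees\n")
  for (nd in names(x$nodes)) {
    p <- x$nodes[[nd]]
    top <- sort(p$freqs, decreasing = TRUE)
    top <- head(top, 3)
    cat(sprintf("  node %s (coverage %.2f): %s\n", nd, p$coverage,
                if (length(top)) paste(sprintf("%s=%.3f", names(top), top),
                                       collapse = ", ") else "-"))
  }
  invisible(x)
}

#' Count dispersal events into an area under a chosen reconstruction
#'
#' Given one optimal range per internal node, counts parent-to-child
#' transitions in which \code{to_area} enters the lineage's range (present
#' in the child-side state, absent from the parent-side state) while the
#' parent-side state contains \code{from_area}.
#'
#' @param tree a chronogram.
#' @param reconstruction a \code{diva_reconstruction} of \code{tree}.
#' @param chosen named character vector or list: ape internal node number
#'   to a range string, each of which must be among that node's optimal
#'   ranges.
#' @param from_area,to_area single area letters.
#' @return integer event count.
#' @export
count_dispersals <- function(tree, reconstruction, chosen, from_area, to_area) {
  stopifnot(inherits(reconstruction, "diva_reconstruction"))
  n <- n_tips(tree)
  chosen <- unlist(chosen)
  for (nd in names(reconstruction$node_states)) {
    if (is.na(chosen[nd]))
      stop2("no chosen state for internal node ", nd)
    if (!(chosen[nd] %in% reconstruction$node_states[[nd]]))
      stop2("chosen state '", chosen[nd], "' at node ", nd,
            " is not among the optimal states")
  }
  state_of <- function(nd) {
    if (nd <= n) reconstruction$tip_states[[tree$tip.label[nd]]]
    else chosen[[as.character(nd)]]
  }
  count <- 0L
  for (i in seq_len(nrow(tree$edge))) {
    p <- state_of(tree$edge[i, 1])
    c <- state_of(tree$edge[i, 2])
    ph <- strsplit(p, "")[[1]]; ch <- strsplit(c, "")[[1]]
    if (to_area %in% ch && !(to_area %in% ph) && from_area %in% ph)
      count <- count + 1L
  }
  count
}
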