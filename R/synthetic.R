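## Truth-annotated synthetic study inputs: simulated chronograms, random
## subsampling, and tip ranges evolved by a continuous-time anagenetic
## dispersal/extinction process with recorded ancestral ranges.

#' Scenario: the full recipe for one synthetic study
#'
#' @param sim a \code{\link{simulation_spec}}.
#' @param n_pruned number of tips to prune from the full tree.
#' @param area_alphabet coded area letters.
#' @param root_range character vector of areas at the root.
#' @param dispersal_rate area-gain rate, events/Myr/lineage.
#' @param extinction_rate area-loss rate, events/Myr/lineage.
#' @param seed integer root seed (component substreams are derived from it).
#' @return object of class \code{scenario}.
#' @export
scenario <- function(sim, n_pruned = 0L,
                     area_alphabet = c("A", "B", "C", "D"),
                     root_range = "A",
                     dispersal_rate = 0.02, extinction_rate = 0.01,
                     seed = 1L) {
  stopifnot(inherits(sim, "simulation_spec"))
  if (n_pruned > sim$n_tips - 2L) stop2("n_pruned must be <= n_tips - 2")
  if (dispersal_rate < 0 || extinction_rate < 0) stop2("rates must be >= 0")
  if (!length(root_range) || !all(root_range %in% area_alphabet))
    stop2("root_range must be a non-empty subset of the alphabet")
  structure(list(sim = sim, n_pruned = as.integer(n_pruned),
                 area_alphabet = area_alphabet,
                 root_range = sort(unique(root_range)),
                 dispersal_rate = dispersal_rate,
                 extinction_rate = extinction_rate, seed = as.integer(seed)),
            class = "scenario")
}

#' The study-mimicking preset scenario
#'
#' A Yule tree of 51 extant species at lambda = 0.166/Myr (the whole-clade
#' rate of a 51-species clade with a 19.56 Ma crown), pruned by 28 tips to
#' the 23-species sampled tree (sampling fraction 23/51, about 45 percent),
#' with a 4-area alphabet and an African ({A}) root range. With
#' \code{variant = "shift"} the tree instead carries a speciation-rate
#' shift from 0.03 to 0.32/Myr at 10 Ma, for power studies of the
#' shift-detection stage.
#'
#' @param variant \code{"constant"} (default) or \code{"shift"}.
#' @param seed integer seed.
#' @return a \code{scenario}.
#' @export
zygophyllum_preset <- function(variant = c("constant", "shift"), seed = 1L) {
  variant <- match.arg(variant)
  sim <- if (variant == "constant") {
    simulation_spec(n_tips = 51L, lambda = 0.166, mu = 0, seed = seed)
  } else {
    ## crown anchored at the clade's 19.56 Ma crown age so the slow epoch
    ## (19.56 -> 10 Ma) is long enough to carry the flat-then-steep signal
    simulation_spec(n_tips = 51L, lambda = c(0.03, 0.32), mu = c(0, 0),
                    shift_times = 10, seed = seed, crown_age = 19.56)
  }
  scenario(sim, n_pruned = 28L, area_alphabet = c("A", "B", "C", "D"),
           root_range = "A", dispersal_rate = 0.02, extinction_rate = 0.01,
           seed = seed)
}

#' Evolve tip ranges along a chronogram
#'
#' Anagenetic continuous-time process along every branch: area gains at
#' total rate \code{d_rate} (target uniform over absent areas) and losses
#' at total rate \code{e_rate} (uniform over present areas), with losses
#' suppressed whenever the range has a single area so ranges never empty.
#' Both daughters inherit the parent range unchanged at speciation (no
#' cladogenetic events), keeping the generator model-agnostic relative to
#' DIVA's cladogenetic cost model.
#'
#' @param tree a chronogram.
#' @param root_range character vector of areas at the root.
#' @param d_rate,e_rate gain/loss rates, events/Myr/lineage.
#' @param seed integer seed.
#' @param alphabet the coded area letters.
#' @return list with \code{areas} (an \code{area_table} over the tips) and
#'   \code{node_ranges} (named list, ape node number to range, for every
#'   node including tips: the recorded truth).
#' @export
evolve_areas <- function(tree, root_range, d_rate, e_rate, seed = 1L,
                         alphabet = c("A", "B", "C", "D")) {
  stopifnot(inherits(tree, "chronogram"))
  if (!all(root_range %in% alphabet)) stop2("root_range outside the alphabet")
  n <- n_tips(tree)
  root <- n + 1L
  ranges <- vector("list", n + tree$Nnode)
  ranges[[root]] <- sort(unique(root_range))
  edge_order <- stats::reorder(tree, "cladewise")$edge
  with_seed(seed, {
    for (i in seq_len(nrow(edge_order))) {
      p <- edge_order[i, 1]; c <- edge_order[i, 2]
      len <- tree$node_age[p] - tree$node_age[c]
      r <- ranges[[p]]
      t <- 0
      repeat {
        can_gain <- length(r) < length(alphabet)
        can_lose <- length(r) > 1L
        rate <- d_rate * can_gain + e_rate * can_lose
        if (rate <= 0) break
        t <- t + rexp(1L, rate)
        if (t >= len) break
        if (runif(1L) < d_rate * can_gain / rate) {
          gain <- setdiff(alphabet, r)
          r <- sort(c(r, gain[sample.int(length(gain), 1L)]))
        } else {
          r <- r[-sample.int(length(r), 1L)]
        }
      }
      ranges[[c]] <- r
    }
  })
  areas <- setNames(ranges[seq_len(n)], tree$tip.label)
  names(ranges) <- seq_along(ranges)
  list(areas = structure(areas, class = "area_table", alphabet = alphabet),
       node_ranges = ranges)
}

#' Generate a complete synthetic study with recorded truth
#'
#' Composes the tree simulator (\code{\link{simulate_piecewise}}), random
#' tip pruning and \code{\link{evolve_areas}} on the pruned tree, with all
#' truth recorded and component substream seeds derived from the scenario
#' seed so the study is fully reproducible.
#'
#' @param sc a \code{\link{scenario}}.
#' @return object of class \code{synthetic_study}: \code{full_tree},
#'   \code{pruned_tree}, \code{areas}, \code{true_node_ranges},
#'   \code{truth} (the scenario).
#' @export
generate_study <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  sim <- sc$sim
  sim$seed <- substream_seed(sc$seed, 1L)
  full <- simulate_piecewise(sim)
  pruned <- prune_random_tips(full, sc$n_pruned,
                              seed = substream_seed(sc$seed, 2L))
  ev <- evolve_areas(pruned, sc$root_range, sc$dispersal_rate,
                     sc$extinction_rate, seed = substream_seed(sc$seed, 3L),
                     alphabet = sc$area_alphabet)
  structure(list(full_tree = full, pruned_tree = pruned, areas = ev$areas,
                 true_node_ranges = ev$node_ranges, truth = sc),
            class = "synthetic_study")
}

#' Write a synthetic study to a directory
#'
#' Emits \code{full.nwk}, \code{pruned.nwk}, \code{areas.tsv},
#' \code{truth.json} and \code{manifest.json}.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(study$full_tree, file.path(dir, "full.nwk"))
  write_newick(study$pruned_tree, file.path(dir, "pruned.nwk"))
  write_area_table(study$areas, file.path(dir, "areas.tsv"))
  truth <- list(
    node_ranges = lapply(study$true_node_ranges, paste, collapse = ""),
    lambda = study$truth$sim$lambda, mu = study$truth$sim$mu,
    shift_times = study$truth$sim$shift_times)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  manifest <- list(seed = study$truth$seed, n_tips = study$truth$sim$n_tips,
                   n_pruned = study$truth$n_pruned,
                   crown_age_full = crown_age(study$full_tree),
                   crown_age_pruned = crown_age(study$pruned_tree),
                   dispersal_rate = study$truth$dispersal_rate,
                   extinction_rate = study$truth$extinction_rate)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
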