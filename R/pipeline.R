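## Orchestration: whole-clade rate, LTT null envelope, shift detection with
## sequential LRTs, per-node rate profiles, and S-DIVA, from one config.

#' Analysis configuration
#'
#' @param chronogram_path Newick file with the empirical chronogram.
#' @param tree_sample_path optional NEXUS/multi-Newick posterior sample.
#' @param area_table_path optional tip-to-area TSV.
#' @param total_species total described species in the clade.
#' @param rho sampling probability (sampled/described); in (0, 1].
#' @param epsilons relative extinction values for the per-node profiles.
#' @param envelope_reps number of simulated trees for the LTT envelope.
#' @param grid_step shift-search grid in Myr.
#' @param max_shifts maximum shifts tried by the sequential LRT.
#' @param alpha significance level of the stated decision rule.
#' @param sample_count trees to draw from the posterior sample for S-DIVA.
#' @param seed integer seed.
#' @return object of class \code{analysis_config}.
#' @export
analysis_config <- function(chronogram_path, tree_sample_path = NULL,
                            area_table_path = NULL, total_species,
                            rho = NULL, epsilons = c(0, 0.5, 0.9),
                            envelope_reps = 1000L, grid_step = 0.1,
                            max_shifts = 3L, alpha = 0.05,
                            sample_count = 1000L, seed = 1L) {
  if (envelope_reps < 1) stop2("envelope_reps must be >= 1")
  if (!is.null(rho) && (rho <= 0 || rho > 1)) stop2("rho must be in (0, 1]")
  structure(list(chronogram_path = chronogram_path,
                 tree_sample_path = tree_sample_path,
                 area_table_path = area_table_path,
                 total_species = total_species, rho = rho,
                 epsilons = epsilons, envelope_reps = as.integer(envelope_reps),
                 grid_step = grid_step, max_shifts = as.integer(max_shifts),
                 alpha = alpha, sample_count = as.integer(sample_count),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

run_stage <- function(report, name, fun) {
  res <- tryCatch(list(ok = TRUE, value = fun()),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  if (res$ok) report[[name]] <- res$value
  else report[[name]] <- list(skipped = TRUE, reason = res$value)
  report
}

#' Run the full diversification and biogeography analysis
#'
#' Executes, in order: whole-clade rate from \code{total_species} and the
#' chronogram's crown age; a Yule null envelope at that rate
#' (\code{envelope_reps} trees of \code{total_species} tips, each randomly
#' pruned to the chronogram's tip count) compared with the empirical LTT;
#' constant and k-shift fits with sequential likelihood-ratio tests adding
#' shifts until the first non-significant addition; per-node rate profiles
#' per epsilon; and S-DIVA when a tree sample and area table are provided.
#' A failed stage is recorded with its error and the remaining independent
#' stages still run.
#'
#' @param cfg an \code{\link{analysis_config}}.
#' @return object of class \code{analysis_report}.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  tree <- parse_newick(paste(readLines(cfg$chronogram_path, warn = FALSE),
                             collapse = ""))
  n <- n_tips(tree)
  rho <- cfg$rho %||% (n / cfg$total_species)
  report <- list(config = cfg, n_tips = n, crown_age = crown_age(tree),
                 rho = rho,
                 stamp = list(package = "aridiv",
                              version = as.character(utils::packageVersion("aridiv")),
                              seed = cfg$seed))
  class(report) <- "analysis_report"

  report <- run_stage(report, "whole_clade", function() {
    whole_clade_rate(cfg$total_species, crown_age(tree))
  })

  report <- run_stage(report, "ltt_envelope", function() {
    lam <- report$whole_clade$rate
    sims <- lapply(seq_len(cfg$envelope_reps), function(r) {
      full <- simulate_yule(cfg$total_species, lam,
                            seed = substream_seed(cfg$seed, r))
      prune_random_tips(full, cfg$total_species - n,
                        seed = substream_seed(cfg$seed, r + cfg$envelope_reps))
    })
    envelope_compare(ltt_curve(tree), ltt_envelope(sims),
                     grid_step = max(cfg$grid_step, 0.01))
  })

  report <- run_stage(report, "shifts", function() {
    bt <- branching_times(tree)
    fits <- list(fit_constant(bt, rho, process = "yule"))
    lrt_rows <- list()
    verdict_k <- 0L
    for (k in seq_len(cfg$max_shifts)) {
      fits[[k + 1L]] <- fit_k_shifts(bt, rho, k, cfg$grid_step,
                                     process = "yule")
      test <- lrt(fits[[k]], fits[[k + 1L]])
      lrt_rows[[k]] <- data.frame(k_null = k - 1L, k_alt = k,
                                  chi2 = test$chi2, df = test$df, p = test$p)
      if (test$p < cfg$alpha) verdict_k <- k else break
    }
    list(fits = fits, lrt_table = do.call(rbind, lrt_rows),
         n_shifts = verdict_k, alpha = cfg$alpha,
         shift_times = if (verdict_k > 0)
           fits[[verdict_k + 1L]]$model$shift_times else numeric(0))
  })

  report <- run_stage(report, "node_rates", function() {
    profs <- lapply(cfg$epsilons, function(e)
      per_node_rates(tree, eps = e, total_species = NULL))
    names(profs) <- paste0("eps_", cfg$epsilons)
    profs
  })

  if (is.null(cfg$tree_sample_path) || is.null(cfg$area_table_path)) {
    report$biogeography <- list(skipped = TRUE, reason = "no areas")
  } else {
    report <- run_stage(report, "biogeography", function() {
      areas <- read_area_table(cfg$area_table_path, is_path = TRUE)
      sample <- parse_tree_sample(cfg$tree_sample_path,
                                  count = cfg$sample_count,
                                  seed = substream_seed(cfg$seed, 0L),
                                  is_path = TRUE)
      sdiva(sample, tree, areas)
    })
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== diversification / biogeography analysis report ==\n")
  cat(sprintf("tree: %d tips, crown %.3f Ma; sampling rho = %.3f\n",
              x$n_tips, x$crown_age, x$rho))
  if (!isTRUE(x$whole_clade$skipped))
    cat(sprintf("whole-clade rate: %.3f species/Myr\n", x$whole_clade$rate))
  if (!isTRUE(x$ltt_envelope$skipped)) {
    cat("LTT envelope: ")
    nb <- length(x$ltt_envelope$intervals_below)
    na <- length(x$ltt_envelope$intervals_above)
    if (nb + na == 0) cat("empirical curve inside the simulated envelope\n")
    else cat(nb, "interval(s) below,", na, "interval(s) above the envelope\n")
  }
  if (!isTRUE(x$shifts$skipped)) {
    cat(sprintf("shift detection: %d shift(s) at alpha = %g", x$shifts$n_shifts,
                x$shifts$alpha))
    if (x$shifts$n_shifts > 0)
      cat(" (", paste(signif(x$shifts$shift_times, 4), collapse = ", "), " Ma)",
          sep = "")
    cat("\n")
    print(x$shifts$lrt_table, row.names = FALSE)
  }
  if (isTRUE(x$biogeography$skipped))
    cat("biogeography: skipped:", x$biogeography$reason, "\n")
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report an \code{analysis_report}.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  ser <- list(
    stamp = report$stamp,
    n_tips = report$n_tips, crown_age = report$crown_age, rho = report$rho,
    whole_clade_rate = if (!isTRUE(report$whole_clade$skipped))
      report$whole_clade$rate else NULL,
    ltt_envelope = if (!isTRUE(report$ltt_envelope$skipped)) list(
      intervals_below = report$ltt_envelope$intervals_below,
      intervals_above = report$ltt_envelope$intervals_above,
      n_sims = report$ltt_envelope$n_sims) else report$ltt_envelope,
    shifts = if (!isTRUE(report$shifts$skipped)) list(
      n_shifts = report$shifts$n_shifts,
      shift_times = report$shifts$shift_times,
      lrt_table = report$shifts$lrt_table) else report$shifts,
    node_rates = if (!isTRUE(report$node_rates$skipped))
      report$node_rates else NULL,
    biogeography = if (!isTRUE(report$biogeography$skipped)) lapply(
      report$biogeography$nodes, function(nd) list(
        coverage = nd$coverage,
        freqs = as.list(nd$freqs))) else report$biogeography)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
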