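#' Evolve distractor shapes against a target
#'
#' Runs the full evolutionary loop: an initial pool of random RF-genome
#' distractors is tested in simulated search blocks (one trial per distractor
#' per set size), the fittest distractors survive as parents, and offspring
#' are produced by uniform crossover plus mutation, for `n_generations`
#' generations. Fitness is mean simulated RT (easy direction: fastest
#' survive) or the weighted score `slope - hard_weight * mean_rt` (hard
#' direction: highest survive). Search RTs come from the synthetic observer
#' ([observer_params()]); a pre-recorded trial log can be supplied per
#' generation through the lower-level functions instead.
#'
#' @param target target shape: an `rf_genome` or a `shape_contour` (e.g. a
#'   silhouette from [load_silhouette()]).
#' @param direction `"easy"` or `"hard"`.
#' @param n_generations number of generations (default 8).
#' @param constraint `NULL`, `"include_target"` (target frequencies clamped on
#'   with target amplitudes; genome targets only), `"exclude_target"` (target
#'   frequencies forced off), or a [constraint_mask()].
#' @param metric similarity parameterization driving the observer (default
#'   `"spectrum"`).
#' @param init an [init_config()].
#' @param ga an [ga_config()]; its `direction` and `constraint` are set from
#'   the arguments above.
#' @param observer an [observer_params()].
#' @param schedule a [schedule_config()].
#' @param synth a [synth_config()].
#' @param seed integer seed for the whole run (applied once at entry).
#' @return An object of class `rf_evolution`: list with `populations` (one
#'   `rf_population` per generation), `trials` (all trial records), `scores`
#'   (per-generation fitness tables), `summary` (per-generation mean RT and
#'   pool-mean metric distance to the target), plus the target, direction,
#'   metric and configuration objects.
#' @examples
#' target <- example_targets()$BB
#' run <- rf_evolve(target, "easy", n_generations = 3, seed = 1)
#' summary(run)
#' @export
rf_evolve <- function(target, direction = c("easy", "hard"),
                      n_generations = 8L, constraint = NULL,
                      metric = c("spectrum", "skeleton", "curvature"),
                      init = init_config(), ga = ga_config(),
                      observer = observer_params(),
                      schedule = schedule_config(), synth = synth_config(),
                      seed = NULL) {
  direction <- match.arg(direction)
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(constraint)) {
    constraint <- match.arg(constraint, c("include_target", "exclude_target"))
    if (!inherits(target, "rf_genome"))
      stopf("named constraints need an rf_genome target")
    constraint <- target_constraint(target, include = constraint == "include_target")
  }
  ga$direction <- direction
  ga$constraint <- constraint
  ga$n_generations <- as.integer(n_generations)
  target_genome <- if (inherits(target, "rf_genome")) target else NULL
  pop <- init_population(ga, init, target = target_genome)
  populations <- vector("list", ga$n_generations)
  scores <- vector("list", ga$n_generations)
  trials <- vector("list", ga$n_generations)
  summary_rows <- vector("list", ga$n_generations)
  for (g in seq_len(ga$n_generations)) {
    populations[[g]] <- pop
    recs <- run_generation(pop, target, schedule, observer, metric, synth)
    sc <- score_distractors(recs, ga)
    trials[[g]] <- recs
    scores[[g]] <- sc
    summary_rows[[g]] <- data.frame(
      generation = g,
      mean_rt = mean(recs$rt_ms),
      mean_distance = mean(attr(recs, "distance")),
      stringsAsFactors = FALSE)
    if (g < ga$n_generations) pop <- evolve_population(pop, sc, ga, target_genome)
  }
  structure(list(target = target, direction = direction, metric = metric,
                 populations = populations, scores = scores,
                 trials = do.call(rbind, trials),
                 summary = do.call(rbind, summary_rows),
                 init = init, ga = ga, observer = observer,
                 schedule = schedule, synth = synth, seed = seed),
            class = "rf_evolution")
}

#' @export
print.rf_evolution <- function(x, ...) {
  s <- x$summary
  cat(sprintf("RF distractor evolution: direction %s, %d generations, metric %s\n",
              x$direction, nrow(s), x$metric))
  cat(sprintf("  mean RT: %.0f ms (gen 1) -> %.0f ms (gen %d)\n",
              s$mean_rt[1L], s$mean_rt[nrow(s)], nrow(s)))
  cat(sprintf("  pool-mean %s distance to target: %.2f -> %.2f\n",
              x$metric, s$mean_distance[1L], s$mean_distance[nrow(s)]))
  invisible(x)
}

#' @export
summary.rf_evolution <- function(object, ...) object$summary

#' Plot an evolution run
#'
#' Two base-graphics panels: mean simulated RT by generation, and pool-mean
#' metric distance to the target by generation.
#'
#' @param x an `rf_evolution`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rf_evolution <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$generation, s$mean_rt, type = "b", pch = 19,
                 xlab = "generation", ylab = "mean RT (ms)",
                 main = sprintf("Evolve-%s", tools::toTitleCase(x$direction)), ...)
  graphics::plot(s$generation, s$mean_distance, type = "b", pch = 19,
                 xlab = "generation",
                 ylab = sprintf("pool-mean %s distance", x$metric),
                 main = "target-distractor distance", ...)
  invisible(x)
}

#' Write an evolution run to a directory
#'
#' Writes one population JSON per generation (`population_01.json`, ...), the
#' full trial log as `trials.csv` (columns `generation`, `trial_index`,
#' `distractor_id`, `set_size`, `target_present`, `rt_ms`, `correct`) and the
#' per-generation summary as `summary.csv`.
#'
#' @param x an `rf_evolution`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(x, dir) {
  stopifnot(inherits(x, "rf_evolution"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in seq_along(x$populations))
    write_population(x$populations[[g]],
                     file.path(dir, sprintf("population_%02d.json", g)))
  utils::write.csv(x$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(x$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}

#' Similarity trajectories over generations
#'
#' For each generation, the pool mean of all three target-distractor
#' distances (skeleton, curvature, spectrum) plus the mean simulated RT.
#' Accepts either an `rf_evolution` object or a directory written by
#' [write_run()].
#'
#' @param x an `rf_evolution`, or a run directory path.
#' @param target target shape; taken from the object when `x` is an
#'   `rf_evolution`.
#' @param cfg a [synth_config()].
#' @param align an [alignment_config()] for the skeleton metric.
#' @return Data frame with columns `generation`, `mean_rt`, `skeleton_d`,
#'   `curvature_d`, `spectrum_d`.
#' @export
metrics_over_generations <- function(x, target = NULL, cfg = synth_config(),
                                     align = alignment_config()) {
  if (inherits(x, "rf_evolution")) {
    populations <- x$populations
    trials <- x$trials
    target <- target %||% x$target
  } else {
    files <- sort(list.files(x, pattern = "^population_\\d+\\.json$",
                             full.names = TRUE))
    if (!length(files)) stopf("no population files found in %s", x)
    populations <- lapply(files, read_population)
    trial_file <- file.path(x, "trials.csv")
    if (!file.exists(trial_file)) stopf("missing trial log: %s", trial_file)
    trials <- utils::read.csv(trial_file, stringsAsFactors = FALSE)
    if (is.null(target)) stopf("a target shape is required when reading a run directory")
  }
  tc <- as_contour(target, cfg)
  rows <- lapply(populations, function(pop) {
    ds <- vapply(pop$genomes, function(g) compare_shapes(g, tc, cfg, align),
                 numeric(3))
    tr <- trials[trials$generation == pop$generation, ]
    data.frame(generation = pop$generation,
               mean_rt = mean(tr$rt_ms),
               skeleton_d = mean(ds["skeleton", ]),
               curvature_d = mean(ds["curvature", ]),
               spectrum_d = mean(ds["spectrum", ]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
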