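#' Synthetic observer settings
#'
#' A simple stand-in for a human searcher, used to close the evolutionary
#' loop without collected data. Target-distractor similarity (a normalized
#' value in \[0, 1\], see [similarity_from_distance()]) sets, through a Hill
#' function, the probability that each distractor must be inspected; RT is a
#' base time plus a linear per-item inspection cost plus truncated Gaussian
#' noise. All of this is declared plumbing: none of its parameters are
#' estimates of human behavior, and recorded trial logs can replace the
#' simulation wherever a trial data frame is accepted.
#'
#' @param t0 base (residual) time in ms (default 500).
#' @param t_item time per inspected item in ms (default 50).
#' @param half_sim similarity at which a distractor is inspected with
#'   probability 0.5 (default 0.5).
#' @param steepness Hill exponent (default 4).
#' @param noise_sd RT noise standard deviation in ms (default 60); noise is
#'   clipped below at `-t0/2` so RTs stay positive.
#' @param absent_exhaustive_factor relative exhaustiveness of target-absent
#'   search (default 1.5).
#' @param sim_scale distance scale used to normalize metric distances into
#'   similarities; `NULL` selects a per-metric default
#'   (spectrum 30, skeleton 5, curvature 10).
#' @param seed optional integer seed.
#' @return An object of class `rf_observer_params`.
#' @export
observer_params <- function(t0 = 500, t_item = 50, half_sim = 0.5,
                            steepness = 4, noise_sd = 60,
                            absent_exhaustive_factor = 1.5,
                            sim_scale = NULL, seed = NULL) {
  if (t0 < 0 || t_item < 0 || noise_sd < 0)
    stopf("t0, t_item and noise_sd must be non-negative")
  if (steepness <= 0) stopf("steepness must be > 0")
  if (half_sim <= 0) stopf("half_sim must be > 0")
  structure(list(t0 = t0, t_item = t_item, half_sim = half_sim,
                 steepness = steepness, noise_sd = noise_sd,
                 absent_exhaustive_factor = absent_exhaustive_factor,
                 sim_scale = sim_scale, seed = seed),
            class = "rf_observer_params")
}

#' Default distance scale per similarity metric
#'
#' Chosen so typical evolved-stimulus distances map to similarities spread
#' over the responsive range of the Hill function.
#'
#' @param metric `"spectrum"`, `"skeleton"` or `"curvature"`.
#' @return A positive scale in the metric's units.
#' @export
default_sim_scale <- function(metric = c("spectrum", "skeleton", "curvature")) {
  switch(match.arg(metric), spectrum = 30, skeleton = 5, curvature = 10)
}

#' Normalized similarity from a metric distance
#'
#' `s = 1 / (1 + d / scale)`: 1 at zero distance, decreasing toward 0.
#'
#' @param d non-negative metric distance.
#' @param scale positive distance scale.
#' @return Similarity in (0, 1].
#' @export
similarity_from_distance <- function(d, scale) 1 / (1 + d / scale)

#' Probability that a distractor is inspected
#'
#' Hill function of similarity:
#' `q = s^k / (s^k + half_sim^k)` with exponent `k = steepness`. Zero at
#' `s = 0`, one half at `s = half_sim`, strictly increasing.
#'
#' @param similarity normalized similarity, non-negative.
#' @param p an [observer_params()].
#' @return Probability in \[0, 1).
#' @export
inspection_probability <- function(similarity, p = observer_params()) {
  sk <- similarity^p$steepness
  sk / (sk + p$half_sim^p$steepness)
}

#' Simulate one search trial RT
#'
#' Target present: the expected number of inspected items is
#' `1 + (set_size - 1) * q / 2` (the target is found midway through the
#' inspected subset on average). Target absent: `set_size * q *
#' absent_exhaustive_factor + 1`. RT is `t0 + t_item * inspected + noise`
#' with `noise ~ Normal(0, noise_sd)` clipped below at `-t0/2`, so RT is
#' always positive. One noise value is drawn per call regardless of
#' `noise_sd`, keeping seeded streams aligned across parameterizations.
#'
#' @param set_size number of display items.
#' @param target_present logical.
#' @param similarity normalized target-distractor similarity.
#' @param p an [observer_params()].
#' @return One-row data frame with `set_size`, `target_present`, `rt_ms`,
#'   `correct` (always `TRUE`; accuracy is not modeled).
#' @export
simulate_rt <- function(set_size, target_present, similarity,
                        p = observer_params()) {
  q <- inspection_probability(similarity, p)
  inspected <- if (target_present) 1 + (set_size - 1) * q * 0.5
               else set_size * q * p$absent_exhaustive_factor + 1
  noise <- max(stats::rnorm(1, 0, p$noise_sd), -p$t0 / 2)
  data.frame(set_size = set_size, target_present = target_present,
             rt_ms = p$t0 + p$t_item * inspected + noise, correct = TRUE)
}

#' Simulate one generation of search trials
#'
#' Builds the blocked schedule for the pool (one trial per distractor per set
#' size; see [build_schedule()]), computes each distractor's similarity to the
#' target once under the chosen metric (cached across that distractor's
#' trials), and simulates an RT per trial. The target is present on every
#' trial, as in the evolutionary search blocks.
#'
#' @param pop an `rf_population`.
#' @param target target shape (`rf_genome` or `shape_contour`).
#' @param schedule a [schedule_config()].
#' @param p an [observer_params()].
#' @param metric similarity parameterization (see [shape_distance()]).
#' @param cfg a [synth_config()].
#' @return Data frame of trial records: `generation`, `trial_index`,
#'   `distractor_id`, `set_size`, `target_present`, `rt_ms`, `correct`.
#' @export
run_generation <- function(pop, target, schedule = schedule_config(),
                           p = observer_params(),
                           metric = c("spectrum", "skeleton", "curvature"),
                           cfg = synth_config()) {
  metric <- match.arg(metric)
  scale <- p$sim_scale %||% default_sim_scale(metric)
  sched <- build_schedule(pop, schedule)
  ids <- vapply(pop$genomes, `[[`, character(1), "id")
  dists <- vapply(pop$genomes, shape_distance, numeric(1),
                  b = target, metric = metric, cfg = cfg)
  sims <- stats::setNames(similarity_from_distance(dists, scale), ids)
  recs <- lapply(seq_len(nrow(sched)), function(i) {
    r <- simulate_rt(sched$set_size[i], TRUE, sims[[sched$distractor_id[i]]], p)
    cbind(data.frame(generation = pop$generation, trial_index = i,
                     distractor_id = sched$distractor_id[i],
                     stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, recs)
  attr(out, "similarity") <- sims
  attr(out, "distance") <- stats::setNames(dists, ids)
  out
}
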