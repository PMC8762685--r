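#' GA settings
#'
#' Defaults follow the evolutionary search procedure: pools of 12 distractors,
#' 3 surviving parents per generation, per-element mutation probability 0.02,
#' 8 generations. The Evolve-Hard selection score is
#' `slope - hard_weight * mean_rt` with `hard_weight = 0.15` by default; the
#' weight (including its sign) is configurable because the printed convention
#' penalizes long mean RTs when the score is maximized (see the methods
#' vignette for discussion).
#'
#' @param pool_size distractors per generation (default 12).
#' @param n_parents parents carried over unchanged (default 3).
#' @param mutation_rate per-element mutation probability (default 0.02).
#' @param hard_weight weight of mean RT in the hard score (default 0.15).
#' @param n_generations generations per run (default 8).
#' @param direction `"easy"` (select fastest mean RTs) or `"hard"` (select
#'   highest hard scores).
#' @param constraint optional [constraint_mask()] enforced on every genome.
#' @param seed optional integer seed applied at the start of a run.
#' @return An object of class `rf_ga_config`.
#' @export
ga_config <- function(pool_size = 12L, n_parents = 3L, mutation_rate = 0.02,
                      hard_weight = 0.15, n_generations = 8L,
                      direction = c("easy", "hard"), constraint = NULL,
                      seed = NULL) {
  pool_size <- as.integer(pool_size); n_parents <- as.integer(n_parents)
  if (is.na(pool_size) || is.na(n_parents) || n_parents < 1L ||
      n_parents >= pool_size)
    stopf("need 1 <= n_parents < pool_size")
  if (mutation_rate < 0 || mutation_rate > 1)
    stopf("mutation_rate must be in [0, 1]")
  direction <- match.arg(direction)
  if (!is.null(constraint)) stopifnot(inherits(constraint, "constraint_mask"))
  structure(list(pool_size = pool_size, n_parents = n_parents,
                 mutation_rate = mutation_rate, hard_weight = hard_weight,
                 n_generations = as.integer(n_generations),
                 direction = direction, constraint = constraint, seed = seed),
            class = "rf_ga_config")
}

#' Distractor pools
#'
#' @param genomes list of `rf_genome` objects.
#' @param generation generation index (1-based).
#' @param direction `"easy"` or `"hard"`.
#' @return An object of class `rf_population`.
#' @export
new_population <- function(genomes, generation = 1L, direction = "easy") {
  stopifnot(all(vapply(genomes, inherits, logical(1), "rf_genome")))
  structure(list(genomes = genomes, generation = as.integer(generation),
                 direction = direction),
            class = "rf_population")
}

#' @export
print.rf_population <- function(x, ...) {
  cat(sprintf("population: generation %d, %d genomes, direction %s\n",
              x$generation, length(x$genomes), x$direction))
  invisible(x)
}

#' Initial distractor pool
#'
#' Draws `cfg$pool_size` random genomes and applies the constraint mask (if
#' any) so fixed elements hold from the first generation on.
#'
#' @param cfg an [ga_config()].
#' @param init an [init_config()].
#' @param target target genome supplying clamp amplitudes when a constraint
#'   mask is active (may be `NULL` when the mask carries its own amplitudes).
#' @return An `rf_population` at generation 1.
#' @export
init_population <- function(cfg = ga_config(), init = init_config(), target = NULL) {
  genomes <- lapply(seq_len(cfg$pool_size), function(i) random_genome(init))
  if (!is.null(cfg$constraint))
    genomes <- lapply(genomes, apply_constraints, mask = cfg$constraint,
                      target = target)
  new_population(genomes, generation = 1L, direction = cfg$direction)
}

#' Fitness scores from a trial log
#'
#' For each distractor: `mean_rt` is the mean RT over all of its trials;
#' `slope` is the two-point slope of mean RT against set size,
#' `(rt_large - rt_small) / (set_size_large - set_size_small)`;
#' `score_easy = mean_rt` (lower is fitter for easy evolution) and
#' `score_hard = slope - hard_weight * mean_rt` (higher is fitter for hard
#' evolution).
#'
#' @param trials data frame with columns `distractor_id`, `set_size`, `rt_ms`.
#' @param cfg an [ga_config()] (supplies `hard_weight`).
#' @return Data frame with one row per distractor (in order of first
#'   appearance): `distractor_id`, `mean_rt`, `rt_small`, `rt_large`, `slope`,
#'   `score_easy`, `score_hard`.
#' @export
score_distractors <- function(trials, cfg = ga_config()) {
  stopifnot(is.data.frame(trials),
            all(c("distractor_id", "set_size", "rt_ms") %in% names(trials)))
  sizes <- sort(unique(trials$set_size))
  if (length(sizes) != 2L)
    stopf("scoring needs exactly two set sizes, found %d", length(sizes))
  ids <- unique(trials$distractor_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$distractor_id == id, ]
    for (s in sizes)
      if (!any(tr$set_size == s))
        stopf("distractor %s has no trials at set size %d", id, s)
    rt_small <- mean(tr$rt_ms[tr$set_size == sizes[1L]])
    rt_large <- mean(tr$rt_ms[tr$set_size == sizes[2L]])
    mean_rt <- mean(tr$rt_ms)
    slope <- (rt_large - rt_small) / (sizes[2L] - sizes[1L])
    data.frame(distractor_id = id, mean_rt = mean_rt,
               rt_small = rt_small, rt_large = rt_large, slope = slope,
               score_easy = mean_rt,
               score_hard = slope - cfg$hard_weight * mean_rt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the surviving parents
#'
#' Easy direction: the `n_parents` distractors with the lowest mean RT.
#' Hard direction: the `n_parents` with the highest `score_hard`. Ties are
#' broken stably in favor of the earlier distractor.
#'
#' @param scores data frame from [score_distractors()].
#' @param cfg an [ga_config()].
#' @return Character vector of `n_parents` distractor ids.
#' @export
select_parents <- function(scores, cfg = ga_config()) {
  if (nrow(scores) < cfg$n_parents)
    stopf("need at least %d scored distractors, got %d", cfg$n_parents, nrow(scores))
  key <- switch(cfg$direction, easy = scores$score_easy, hard = -scores$score_hard)
  ord <- order(key, seq_len(nrow(scores)))
  scores$distractor_id[ord[seq_len(cfg$n_parents)]]
}

#' Uniform crossover of two genomes
#'
#' Each of the 3n genome elements (amplitude, phase and gate per frequency)
#' is copied from parent `a` or parent `b` independently with probability
#' one half. The RNG is consumed in a fixed order: amplitudes 1..n, then
#' phases, then gates, then the offspring id. Lineage records both parents.
#'
#' @param a,b parent `rf_genome` objects of equal length.
#' @return Offspring `rf_genome`.
#' @export
crossover <- function(a, b) {
  stopifnot(inherits(a, "rf_genome"), inherits(b, "rf_genome"),
            length(a$amplitudes) == length(b$amplitudes))
  n <- length(a$amplitudes)
  take_a <- stats::runif(3L * n) < 0.5
  amp <- ifelse(take_a[seq_len(n)], a$amplitudes, b$amplitudes)
  ph <- ifelse(take_a[n + seq_len(n)], a$phases, b$phases)
  gt <- ifelse(take_a[2L * n + seq_len(n)], a$gates, b$gates)
  rf_genome(amp, ph, gt, lineage = c(a$id, b$id))
}

#' Per-element mutation
#'
#' Each genome element mutates independently with probability
#' `cfg$mutation_rate`. A mutated gate flips; a mutated amplitude is
#' multiplied by 2 or divided by 2 with equal probability; a mutated phase is
#' redrawn uniformly from (1, 360) degrees. Elements fixed by the active
#' constraint mask (amplitude and gate at non-free frequencies) never mutate.
#' The element scan order is amplitudes 1..n, phases, gates; secondary draws
#' happen in that order for mutated elements only.
#'
#' @param g an `rf_genome`.
#' @param cfg an [ga_config()].
#' @return A (possibly) mutated `rf_genome` with the same id and lineage.
#' @export
mutate_genome <- function(g, cfg = ga_config()) {
  stopifnot(inherits(g, "rf_genome"))
  n <- length(g$amplitudes)
  hit <- stats::runif(3L * n) < cfg$mutation_rate
  if (!is.null(cfg$constraint)) {
    fixed <- cfg$constraint$mode != "free"
    hit[seq_len(n)][fixed] <- FALSE          # amplitudes
    hit[2L * n + seq_len(n)][fixed] <- FALSE # gates
  }
  amp <- g$amplitudes; ph <- g$phases; gt <- g$gates
  ah <- which(hit[seq_len(n)])
  if (length(ah)) {
    up <- stats::runif(length(ah)) < 0.5
    amp[ah] <- amp[ah] * ifelse(up, 2, 0.5)
  }
  phh <- which(hit[n + seq_len(n)])
  if (length(phh)) ph[phh] <- stats::runif(length(phh), 1, 360)
  gh <- which(hit[2L * n + seq_len(n)])
  if (length(gh)) gt[gh] <- 1 - gt[gh]
  rf_genome(amp, ph, gt, id = g$id, lineage = g$lineage)
}

#' Per-frequency constraint masks
#'
#' Each frequency is `"free"`, `"clamp_on"` (gate forced on, amplitude fixed
#' to a given value, phase free to evolve) or `"force_off"` (gate forced off,
#' amplitude zero).
#'
#' @param mode character vector over frequencies with entries `"free"`,
#'   `"clamp_on"` or `"force_off"`.
#' @param amplitude numeric vector of clamp amplitudes (used where
#'   `mode == "clamp_on"`; must be non-negative there).
#' @return An object of class `constraint_mask`.
#' @seealso [target_constraint()] to build the mask from a target genome.
#' @export
constraint_mask <- function(mode, amplitude = rep(0, length(mode))) {
  if (!all(mode %in% c("free", "clamp_on", "force_off")))
    stopf("mask modes must be 'free', 'clamp_on' or 'force_off'")
  if (length(amplitude) != length(mode))
    stopf("amplitude vector must match mode length")
  if (any(mode == "clamp_on" & (!is.finite(amplitude) | amplitude < 0)))
    stopf("clamp_on entries need a non-negative amplitude")
  structure(list(mode = mode, amplitude = as.numeric(amplitude)),
            class = "constraint_mask")
}

#' Constraint mask derived from a target genome
#'
#' For constrained evolution: `include = TRUE` clamps the target's active
#' frequencies on, with the target's amplitudes (distractors must contain the
#' target frequencies; phases stay free); `include = FALSE` forces those
#' frequencies off (distractors can never contain them).
#'
#' @param target an `rf_genome`.
#' @param include clamp target frequencies on (`TRUE`) or off (`FALSE`).
#' @return A `constraint_mask`.
#' @export
target_constraint <- function(target, include = TRUE) {
  amps <- effective_spectrum(target)
  active <- amps > 0
  mode <- rep("free", length(amps))
  mode[active] <- if (include) "clamp_on" else "force_off"
  constraint_mask(mode, ifelse(active & include, amps, 0))
}

#' Enforce a constraint mask on a genome
#'
#' @param g an `rf_genome`.
#' @param mask a [constraint_mask()].
#' @param target optional `rf_genome` whose amplitudes override the mask's
#'   clamp values.
#' @return The constrained `rf_genome` (id and lineage preserved).
#' @export
apply_constraints <- function(g, mask, target = NULL) {
  if (is.null(mask)) return(g)
  stopifnot(inherits(mask, "constraint_mask"),
            length(mask$mode) == length(g$amplitudes))
  amp <- g$amplitudes; gt <- g$gates
  clamp_amp <- mask$amplitude
  if (!is.null(target)) clamp_amp <- target$amplitudes
  on <- mask$mode == "clamp_on"
  off <- mask$mode == "force_off"
  amp[on] <- clamp_amp[on]; gt[on] <- 1
  amp[off] <- 0; gt[off] <- 0
  rf_genome(amp, g$phases, gt, id = g$id, lineage = g$lineage)
}

#' Check a genome against a constraint mask
#'
#' @param g an `rf_genome`.
#' @param mask a `constraint_mask` (or `NULL`, always satisfied).
#' @return `TRUE` when every masked element holds its required value.
#' @export
satisfies_constraints <- function(g, mask) {
  if (is.null(mask)) return(TRUE)
  on <- mask$mode == "clamp_on"; off <- mask$mode == "force_off"
  all(g$gates[on] == 1) && all(g$amplitudes[on] == mask$amplitude[on]) &&
    all(g$gates[off] == 0) && all(g$amplitudes[off] == 0)
}

#' One generation of evolution
#'
#' The selected parents survive unchanged (elitism); the remaining pool slots
#' are filled by offspring, each produced by uniform crossover of two distinct
#' parents drawn uniformly at random, followed by mutation. Constraint masks
#' are enforced on every output genome. The RNG is consumed in the order:
#' pairing, crossover, mutation, per offspring.
#'
#' @param pop current `rf_population`.
#' @param scores data frame from [score_distractors()] covering the pool.
#' @param cfg an [ga_config()].
#' @param target optional target genome for constraint clamp amplitudes.
#' @return The next `rf_population` (generation incremented).
#' @export
evolve_population <- function(pop, scores, cfg = ga_config(), target = NULL) {
  stopifnot(inherits(pop, "rf_population"))
  ids <- vapply(pop$genomes, `[[`, character(1), "id")
  if (!all(ids %in% scores$distractor_id))
    stopf("scores must cover every pool member")
  parent_ids <- select_parents(scores, cfg)
  parents <- pop$genomes[match(parent_ids, ids)]
  n_off <- cfg$pool_size - cfg$n_parents
  offspring <- vector("list", n_off)
  for (k in seq_len(n_off)) {
    pair <- sample.int(cfg$n_parents, 2L, replace = FALSE)
    child <- crossover(parents[[pair[1L]]], parents[[pair[2L]]])
    child <- mutate_genome(child, cfg)
    if (!is.null(cfg$constraint))
      child <- apply_constraints(child, cfg$constraint, target)
    offspring[[k]] <- child
  }
  new_population(c(parents, offspring), generation = pop$generation + 1L,
                 direction = cfg$direction)
}
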