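#' Trial schedule and display settings
#'
#' Standard (evolution) mode runs one trial per distractor per set size, with
#' set-size blocks presented sequentially and the distractor order randomized
#' within each block. Extended search mode (`exp4_mode`) runs
#' target-present/absent blocks over set sizes 8/12/16 with exact
#' counterbalancing, orientation jitter within +/-25 degrees (so an upright
#' target stays upright-looking) and size jitter.
#'
#' @param set_sizes set sizes per generation block (default `c(16, 24)`).
#' @param trials_per_distractor_per_setsize repeats per block (default 1).
#' @param blocked_by_setsize run set sizes sequentially (default TRUE).
#' @param exp4_mode enable the present/absent jittered-display mode.
#' @param exp4_set_sizes set sizes for that mode (default `c(8, 12, 16)`).
#' @param exp4_present_rate target-present rate, counterbalanced exactly
#'   (default 0.5).
#' @param exp4_orientation_jitter max absolute orientation in degrees
#'   (default 25).
#' @param exp4_size_jitter max relative size jitter (default 0.10).
#' @param rt_exclusion_ms RT exclusion threshold in ms (default 10000);
#'   records strictly above it are dropped by [filter_rts()].
#' @param n_trials experimental trials per extended-mode block (default 300).
#' @param array_radius display array radius in pixels (default 150, five times
#'   the 30 px base radius, which keeps items non-overlapping up to set size 24).
#' @param seed optional integer seed.
#' @return An object of class `rf_schedule_config`.
#' @export
schedule_config <- function(set_sizes = c(16L, 24L),
                            trials_per_distractor_per_setsize = 1L,
                            blocked_by_setsize = TRUE,
                            exp4_mode = FALSE,
                            exp4_set_sizes = c(8L, 12L, 16L),
                            exp4_present_rate = 0.5,
                            exp4_orientation_jitter = 25,
                            exp4_size_jitter = 0.10,
                            rt_exclusion_ms = 10000,
                            n_trials = 300L,
                            array_radius = 150,
                            seed = NULL) {
  if (any(set_sizes < 2) || any(exp4_set_sizes < 2))
    stopf("set sizes must be >= 2")
  if (exp4_present_rate < 0 || exp4_present_rate > 1)
    stopf("exp4_present_rate must be in [0, 1]")
  if (exp4_orientation_jitter < 0 || exp4_size_jitter < 0)
    stopf("jitter bounds must be >= 0")
  structure(list(set_sizes = as.integer(set_sizes),
                 trials_per_distractor_per_setsize =
                   as.integer(trials_per_distractor_per_setsize),
                 blocked_by_setsize = isTRUE(blocked_by_setsize),
                 exp4_mode = isTRUE(exp4_mode),
                 exp4_set_sizes = as.integer(exp4_set_sizes),
                 exp4_present_rate = exp4_present_rate,
                 exp4_orientation_jitter = exp4_orientation_jitter,
                 exp4_size_jitter = exp4_size_jitter,
                 rt_exclusion_ms = rt_exclusion_ms,
                 n_trials = as.integer(n_trials),
                 array_radius = array_radius,
                 seed = seed),
            class = "rf_schedule_config")
}

#' Build a generation's trial schedule
#'
#' One trial per distractor per set size. Set-size blocks are sequential
#' (all trials at the first set size, then the next); within each block the
#' distractor order is an independent random permutation.
#'
#' @param pop an `rf_population`.
#' @param cfg a [schedule_config()]; its `seed`, when set, is applied first.
#' @return Data frame with columns `trial_index`, `distractor_id`, `set_size`.
#' @export
build_schedule <- function(pop, cfg = schedule_config()) {
  stopifnot(inherits(pop, "rf_population"))
  ids <- vapply(pop$genomes, `[[`, character(1), "id")
  if (!length(ids)) stopf("empty pool")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  blocks <- lapply(cfg$set_sizes, function(s) {
    reps <- rep(ids, cfg$trials_per_distractor_per_setsize)
    data.frame(distractor_id = sample(reps), set_size = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  if (!cfg$blocked_by_setsize) out <- out[sample.int(nrow(out)), ]
  out <- cbind(trial_index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Compose one search display
#'
#' Items sit equally spaced on a circle around central fixation, with a
#' random global rotation offset. In standard mode distractors take uniform
#' random orientations over the full circle and the target (when present)
#' stays upright; in `exp4_mode` every item's orientation is jittered within
#' `+/-exp4_orientation_jitter` degrees and item sizes within
#' `+/-exp4_size_jitter`. When the target is present it occupies a uniformly
#' random position.
#'
#' @param target_id,distractor_id item id strings.
#' @param set_size number of items (>= 2).
#' @param cfg a [schedule_config()].
#' @param present is the target in the display (default TRUE).
#' @return An object of class `display_spec`: `set_size`, `positions`
#'   (set_size x 2 matrix, pixels from fixation), `orientations` (degrees),
#'   `sizes` (scale factors), `target_index` (`NA` when absent), `item_ids`.
#' @export
compose_display <- function(target_id, distractor_id, set_size,
                            cfg = schedule_config(), present = TRUE) {
  set_size <- as.integer(set_size)
  if (is.na(set_size) || set_size < 2L) stopf("set_size must be >= 2")
  offset <- stats::runif(1, 0, 2 * pi)
  ang <- offset + 2 * pi * (seq_len(set_size) - 1L) / set_size
  positions <- cbind(x = cfg$array_radius * cos(ang),
                     y = cfg$array_radius * sin(ang))
  if (cfg$exp4_mode) {
    j <- cfg$exp4_orientation_jitter
    orientations <- stats::runif(set_size, -j, j)
    sizes <- stats::runif(set_size, 1 - cfg$exp4_size_jitter,
                          1 + cfg$exp4_size_jitter)
  } else {
    orientations <- stats::runif(set_size, 0, 360)
    sizes <- rep(1, set_size)
  }
  item_ids <- rep(distractor_id, set_size)
  target_index <- NA_integer_
  if (present) {
    target_index <- sample.int(set_size, 1L)
    item_ids[target_index] <- target_id
    if (!cfg$exp4_mode) orientations[target_index] <- 0
  }
  structure(list(set_size = set_size, positions = positions,
                 orientations = orientations, sizes = sizes,
                 target_index = target_index, item_ids = item_ids),
            class = "display_spec")
}

#' @export
print.display_spec <- function(x, ...) {
  cat(sprintf("display: %d items, target %s\n", x$set_size,
              if (is.na(x$target_index)) "absent"
              else sprintf("present at position %d", x$target_index)))
  invisible(x)
}

#' Run a present/absent search block over jittered displays
#'
#' Simulates a block of `cfg$n_trials` trials with set sizes balanced exactly
#' across `cfg$exp4_set_sizes` and target presence counterbalanced exactly at
#' `cfg$exp4_present_rate` within each set size. Each trial uses one
#' homogeneous distractor drawn uniformly from `distractors`; similarity to
#' the target is computed once per distractor and cached. Trial order is a
#' random permutation.
#'
#' @param target target shape (`rf_genome` or `shape_contour`).
#' @param distractors list of distractor shapes (genomes or contours).
#' @param cfg a [schedule_config()] (typically with `exp4_mode = TRUE`); its
#'   `seed`, when set, is applied first.
#' @param p an [observer_params()].
#' @param metric similarity parameterization (default `"skeleton"`, suited to
#'   silhouette targets).
#' @param synth a [synth_config()].
#' @return Data frame of trial records: `trial_index`, `distractor_id`,
#'   `set_size`, `target_present`, `rt_ms`, `correct`.
#' @export
run_exp4_block <- function(target, distractors, cfg = schedule_config(exp4_mode = TRUE),
                           p = observer_params(),
                           metric = c("skeleton", "spectrum", "curvature"),
                           synth = synth_config()) {
  metric <- match.arg(metric)
  if (!length(distractors)) stopf("distractor set must be non-empty")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  scale <- p$sim_scale %||% default_sim_scale(metric)
  if (is.null(names(distractors)))
    names(distractors) <- vapply(seq_along(distractors), function(i) {
      d <- distractors[[i]]
      if (inherits(d, "rf_genome")) d$id else sprintf("distractor-%02d", i)
    }, character(1))
  sims <- vapply(distractors, function(d)
    similarity_from_distance(shape_distance(d, target, metric, synth), scale),
    numeric(1))
  per_size <- cfg$n_trials %/% length(cfg$exp4_set_sizes)
  n_present <- round(per_size * cfg$exp4_present_rate)
  plan <- do.call(rbind, lapply(cfg$exp4_set_sizes, function(s)
    data.frame(set_size = s,
               target_present = rep(c(TRUE, FALSE), c(n_present, per_size - n_present)))))
  plan <- plan[sample.int(nrow(plan)), ]
  plan$distractor_id <- sample(names(distractors), nrow(plan), replace = TRUE)
  recs <- lapply(seq_len(nrow(plan)), function(i) {
    r <- simulate_rt(plan$set_size[i], plan$target_present[i],
                     sims[[plan$distractor_id[i]]], p)
    cbind(data.frame(trial_index = i, distractor_id = plan$distractor_id[i],
                     stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Exclude implausibly long RTs
#'
#' Removes records with `rt_ms` strictly greater than the exclusion threshold
#' (boundary records are kept) and reports how many were dropped.
#'
#' @param records trial data frame with an `rt_ms` column.
#' @param cfg a [schedule_config()] supplying `rt_exclusion_ms`.
#' @return The filtered data frame.
#' @export
filter_rts <- function(records, cfg = schedule_config()) {
  keep <- records$rt_ms <= cfg$rt_exclusion_ms
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("filter_rts: removed %d record(s) with RT > %g ms",
                    n_drop, cfg$rt_exclusion_ms))
  records[keep, , drop = FALSE]
}

#' RT-by-set-size slopes
#'
#' Ordinary least-squares line through the per-set-size mean RTs, fitted
#' separately for target-present and target-absent trials. The slope
#' (ms/item) is the standard index of search efficiency.
#'
#' @param records trial data frame with `set_size`, `rt_ms` and (optionally)
#'   `target_present` columns; records lacking `target_present` are treated
#'   as target-present.
#' @return Data frame with columns `condition` (`"present"`/`"absent"`),
#'   `slope` (ms/item) and `intercept` (ms).
#' @export
rt_setsize_slopes <- function(records) {
  stopifnot(all(c("set_size", "rt_ms") %in% names(records)))
  pres <- if ("target_present" %in% names(records)) records$target_present
          else rep(TRUE, nrow(records))
  fit_one <- function(df, label) {
    means <- tapply(df$rt_ms, df$set_size, mean)
    if (length(means) < 2L)
      stopf("condition '%s' has fewer than two set sizes", label)
    ss <- as.numeric(names(means))
    fit <- stats::lm(as.numeric(means) ~ ss)
    data.frame(condition = label,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               stringsAsFactors = FALSE)
  }
  out <- fit_one(records[pres, , drop = FALSE], "present")
  if (any(!pres)) out <- rbind(out, fit_one(records[!pres, , drop = FALSE], "absent"))
  rownames(out) <- NULL
  out
}
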