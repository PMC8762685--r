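#' Radial-frequency genomes
#'
#' An RF genome parameterizes one closed shape as a circle whose radius is
#' modulated by sinusoids at integer angular frequencies 1..n. Each frequency
#' carries an amplitude (internal amplitude units), a phase (degrees), and a
#' binary gate that can switch the frequency off by forcing its effective
#' amplitude to zero. The default genome uses the first 10 frequencies, i.e.
#' 30 elements in total.
#'
#' @param amplitudes numeric vector of non-negative amplitudes, one per frequency.
#' @param phases numeric vector of phases in degrees, each in (0, 360].
#' @param gates vector of 0/1 gate flags, same length as `amplitudes`.
#' @param id opaque identifier string; drawn from the RNG stream when `NULL`.
#' @param lineage optional character vector of parent ids.
#' @return An object of class `rf_genome`.
#' @examples
#' g <- rf_genome(amplitudes = c(40, rep(0, 9)),
#'                phases = rep(90, 10), gates = rep(1, 10))
#' effective_spectrum(g)
#' @export
rf_genome <- function(amplitudes, phases, gates, id = NULL, lineage = NULL) {
  n <- length(amplitudes)
  if (n < 1L) stopf("genome must have at least one frequency")
  if (length(phases) != n || length(gates) != n)
    stopf("amplitudes, phases and gates must have equal length (got %d, %d, %d)",
          n, length(phases), length(gates))
  amplitudes <- as.numeric(amplitudes)
  phases <- as.numeric(phases)
  gates <- as.numeric(gates)
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stopf("amplitudes must be finite and non-negative")
  if (any(!is.finite(phases)) || any(phases <= 0 | phases > 360))
    stopf("phases must lie in (0, 360] degrees")
  if (!all(gates %in% c(0, 1)))
    stopf("gates must be 0 or 1")
  structure(list(amplitudes = amplitudes, phases = phases, gates = gates,
                 id = id %||% new_id(),
                 lineage = as.character(lineage %||% character(0))),
            class = "rf_genome")
}

#' @export
print.rf_genome <- function(x, ...) {
  act <- which(x$gates == 1 & x$amplitudes > 0)
  cat(sprintf("RF genome <%s>: %d frequencies, active: %s\n", x$id,
              length(x$amplitudes),
              if (length(act)) paste(act, collapse = ", ") else "none"))
  invisible(x)
}

#' Initialization settings for random genomes
#'
#' Amplitudes at frequency f are drawn uniformly from
#' `[amp_low, amp_high]` and then divided by f, which approximates the 1/f
#' amplitude fall-off of natural-scene Fourier spectra. Phases are uniform in
#' degrees; gates are independent Bernoulli draws.
#'
#' @param amp_low,amp_high bounds of the pre-division amplitude draw (default 50-150).
#' @param phase_low,phase_high phase bounds in degrees (default 1-360).
#' @param n_freq number of radial frequencies (default 10).
#' @param gate_on_prob probability that a gate initializes "on" (default 0.5).
#' @param seed optional integer seed, applied where a batch of genomes is drawn.
#' @return An object of class `rf_init_config`.
#' @export
init_config <- function(amp_low = 50, amp_high = 150,
                        phase_low = 1, phase_high = 360,
                        n_freq = 10L, gate_on_prob = 0.5, seed = NULL) {
  if (!is_scalar_num(amp_low) || !is_scalar_num(amp_high) || amp_low >= amp_high)
    stopf("need amp_low < amp_high")
  if (!is_scalar_num(phase_low) || !is_scalar_num(phase_high) || phase_low >= phase_high)
    stopf("need phase_low < phase_high")
  if (phase_low <= 0 || phase_high > 360)
    stopf("phase bounds must lie in (0, 360]")
  n_freq <- as.integer(n_freq)
  if (is.na(n_freq) || n_freq < 1L) stopf("n_freq must be >= 1")
  if (gate_on_prob < 0 || gate_on_prob > 1) stopf("gate_on_prob must be in [0, 1]")
  structure(list(amp_low = amp_low, amp_high = amp_high,
                 phase_low = phase_low, phase_high = phase_high,
                 n_freq = n_freq, gate_on_prob = gate_on_prob, seed = seed),
            class = "rf_init_config")
}

#' Draw a random RF genome
#'
#' Amplitude at frequency f is `Uniform(amp_low, amp_high) / f`; phase is
#' `Uniform(phase_low, phase_high)` degrees; gates are Bernoulli(`gate_on_prob`).
#' The function consumes the active RNG stream in a fixed order (amplitudes,
#' phases, gates, then the id), so a seeded stream reproduces identical genomes.
#'
#' @param cfg an [init_config()] object.
#' @return An `rf_genome`.
#' @seealso [random_population()] to draw a seeded batch.
#' @export
random_genome <- function(cfg = init_config()) {
  stopifnot(inherits(cfg, "rf_init_config"))
  f <- seq_len(cfg$n_freq)
  amplitudes <- stats::runif(cfg$n_freq, cfg$amp_low, cfg$amp_high) / f
  phases <- stats::runif(cfg$n_freq, cfg$phase_low, cfg$phase_high)
  gates <- as.numeric(stats::runif(cfg$n_freq) < cfg$gate_on_prob)
  rf_genome(amplitudes, phases, gates)
}

#' Draw a batch of random genomes
#'
#' Sets the seed from `cfg$seed` (when present) once, then draws `n` genomes
#' sequentially from the stream.
#'
#' @param n number of genomes.
#' @inheritParams random_genome
#' @return A list of `rf_genome` objects.
#' @export
random_population <- function(n, cfg = init_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lapply(seq_len(n), function(i) random_genome(cfg))
}

#' Effective amplitude spectrum of a genome
#'
#' The gate vector switches frequencies off by zeroing their amplitude:
#' `amps[f] = gates[f] * amplitudes[f]`.
#'
#' @param g an `rf_genome`.
#' @return Numeric vector of effective amplitudes, indexed by frequency.
#' @export
effective_spectrum <- function(g) {
  stopifnot(inherits(g, "rf_genome"))
  g$gates * g$amplitudes
}

genome_fields <- c("amplitudes", "phases", "gates")

#' Read and write genome files
#'
#' Genomes are stored as JSON objects with keys `amplitudes`, `phases`,
#' `gates`, `id` and `lineage`; populations as JSON arrays of such objects.
#' Reading a file written by [write_genome()] reproduces the genome
#' field-for-field. Unknown keys are ignored with a warning; missing required
#' keys are an error naming the field.
#'
#' @param path file path.
#' @param g an `rf_genome`.
#' @return `read_genome()` returns an `rf_genome`; `write_genome()` returns
#'   `path` invisibly.
#' @export
read_genome <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  genome_from_list(obj, path)
}

genome_from_list <- function(obj, where = "genome") {
  for (fld in genome_fields)
    if (is.null(obj[[fld]]))
      stopf("malformed genome in %s: missing field '%s'", where, fld)
  known <- c(genome_fields, "id", "lineage")
  extra <- setdiff(names(obj), known)
  if (length(extra))
    warning(sprintf("ignoring unknown genome fields: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  g <- tryCatch(
    rf_genome(obj$amplitudes, obj$phases, obj$gates,
              id = obj$id, lineage = obj$lineage),
    error = function(e) stopf("malformed genome in %s: %s", where, conditionMessage(e)))
  g
}

genome_to_list <- function(g) {
  list(amplitudes = g$amplitudes, phases = g$phases, gates = g$gates,
       id = g$id, lineage = g$lineage)
}

#' @rdname read_genome
#' @export
write_genome <- function(g, path) {
  stopifnot(inherits(g, "rf_genome"))
  jsonlite::write_json(genome_to_list(g), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read and write population files
#'
#' A population is one generation's pool of distractor genomes, stored as a
#' JSON object with `generation`, `direction` and a `genomes` array.
#'
#' @param pop an `rf_population` (see [new_population()]).
#' @param path file path.
#' @return `read_population()` returns an `rf_population`; `write_population()`
#'   returns `path` invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "rf_population"))
  jsonlite::write_json(
    list(generation = pop$generation, direction = pop$direction,
         genomes = lapply(pop$genomes, genome_to_list)),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$genomes)) stopf("malformed population in %s: missing 'genomes'", path)
  genomes <- lapply(obj$genomes, function(gl) {
    gl <- lapply(gl, function(v) if (is.list(v)) unlist(v) else v)
    genome_from_list(gl, path)
  })
  new_population(genomes, generation = obj$generation %||% 1L,
                 direction = obj$direction %||% "easy")
}

#' Example search targets
#'
#' Four RF-genome targets in the style used for shape-search evolution: a
#' high-frequency (HF) target, a low-frequency (LF) target whose large
#' low-frequency amplitude produces an internal loop, a "bumpy brick" (BB)
#' active at frequencies 2 and 6, and a four-lobed "twisted plus" (TP).
#' Each target has non-zero amplitude on two to four frequencies with all
#' gates on. The parameter values are the package's own illustrative
#' approximations, not recovered from any published stimulus set.
#'
#' @return Named list of four `rf_genome` objects (`HF`, `LF`, `BB`, `TP`).
#' @export
example_targets <- function() {
  mk <- function(active, amps, phases_deg, id) {
    a <- numeric(10); p <- rep(90, 10)
    a[active] <- amps
    p[active] <- phases_deg
    rf_genome(a, p, rep(1, 10), id = id)
  }
  list(
    HF = mk(c(7L, 9L), c(14, 11), c(90, 210), "target-HF"),
    LF = mk(c(1L, 2L), c(120, 40), c(90, 180), "target-LF"),
    BB = mk(c(2L, 6L), c(45, 18), c(90, 270), "target-BB"),
    TP = mk(c(2L, 4L), c(12, 28), c(180, 90), "target-TP")
  )
}
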