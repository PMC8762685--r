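make_trials <- function(ids, rt_small, rt_large, sizes = c(16L, 24L)) {
  data.frame(distractor_id = rep(ids, 2),
             set_size = rep(sizes, each = length(ids)),
             rt_ms = c(rt_small, rt_large),
             stringsAsFactors = FALSE)
}

test_that("fitness scores combine mean RT and the set-size slope", {
  sc <- score_distractors(make_trials("d1", 1000, 1400))
  expect_equal(sc$mean_rt, 1200)
  expect_equal(sc$slope, 50)                       # (1400-1000)/(24-16)
  expect_equal(sc$score_easy, 1200)
  expect_equal(sc$score_hard, 50 - 0.15 * 1200)    # -130
  # equal RTs at both set sizes: flat slope
  expect_equal(score_distractors(make_trials("d1", 900, 900))$slope, 0)
  # the hard weight is configurable, including its sign
  sc2 <- score_distractors(make_trials("d1", 1000, 1400),
                           ga_config(hard_weight = -0.15))
  expect_equal(sc2$score_hard, 50 + 0.15 * 1200)
})

test_that("scoring demands trials at both set sizes", {
  tr <- make_trials(c("a", "b"), c(900, 1000), c(1100, 1200))
  tr <- tr[!(tr$distractor_id == "b" & tr$set_size == 24L), ]
  expect_error(score_distractors(tr), "b.*set size 24")
})

test_that("parent selection follows direction with stable ties", {
  ids <- paste0("d", 1:5)
  sc <- score_distractors(make_trials(ids,
                                      c(900, 1200, 800, 1500, 1000),
                                      c(900, 1200, 800, 1500, 1000)))
  expect_identical(select_parents(sc, ga_config(direction = "easy")),
                   c("d3", "d1", "d5"))
  # all scores equal: first three ids win
  sc_eq <- score_distractors(make_trials(ids, rep(1000, 5), rep(1000, 5)))
  expect_identical(select_parents(sc_eq, ga_config(direction = "easy")),
                   c("d1", "d2", "d3"))
  expect_identical(select_parents(sc_eq, ga_config(direction = "hard")),
                   c("d1", "d2", "d3"))
  # hard direction maximizes score_hard; tie at rank 3 keeps the earlier id
  sc2 <- sc_eq
  sc2$score_hard <- c(5, 9, 3, 3, 9)
  expect_identical(select_parents(sc2, ga_config(direction = "hard")),
                   c("d2", "d5", "d1"))
  expect_error(select_parents(sc[1:2, ], ga_config()), "at least 3")
})

test_that("crossover copies each element from either parent with probability 1/2", {
  a <- rf_genome(seq(10, 100, by = 10), seq(10, 100, by = 10), rep(1, 10),
                 id = "A")
  b <- rf_genome(seq(110, 200, by = 10), seq(110, 200, by = 10), rep(0, 10),
                 id = "B")
  set.seed(50)
  # identical parents: offspring is that parent
  dup <- crossover(a, a)
  expect_identical(dup$amplitudes, a$amplitudes)
  expect_identical(dup$gates, a$gates)
  expect_identical(dup$lineage, c("A", "A"))

  n_off <- 20000L
  from_a <- 0L
  for (i in seq_len(n_off)) {
    ch <- crossover(a, b)
    from_a <- from_a + sum(ch$amplitudes %in% a$amplitudes) +
      sum(ch$phases %in% a$phases) + sum(ch$gates == 1)
  }
  frac <- from_a / (30 * n_off)
  expect_lt(abs(frac - 0.5), 0.005)

  # seeded determinism
  set.seed(51); c1 <- crossover(a, b)
  set.seed(51); c2 <- crossover(a, b)
  expect_identical(c1$amplitudes, c2$amplitudes)
  expect_identical(c1$id, c2$id)
})

test_that("mutation changes elements at the configured rate in the documented ways", {
  set.seed(60)
  g <- random_genome()
  expect_identical(unclass(mutate_genome(g, ga_config(mutation_rate = 0))),
                   unclass(g))

  cfg <- ga_config(mutation_rate = 0.02)
  n_rep <- 8000L
  changed <- 0L
  for (i in seq_len(n_rep)) {
    m <- mutate_genome(g, cfg)
    da <- m$amplitudes != g$amplitudes
    changed <- changed + sum(da) + sum(m$phases != g$phases) +
      sum(m$gates != g$gates)
    if (any(da)) {
      ratio <- m$amplitudes[da] / g$amplitudes[da]
      expect_true(all(abs(ratio - 2) < 1e-12 | abs(ratio - 0.5) < 1e-12))
    }
  }
  rate <- changed / (30 * n_rep)
  expect_lt(abs(rate - 0.02), 0.002)
})

test_that("one evolve step keeps the three parents verbatim plus nine offspring", {
  set.seed(61)
  cfg <- ga_config(direction = "easy")
  pop <- init_population(cfg)
  ids <- vapply(pop$genomes, `[[`, character(1), "id")
  sc <- score_distractors(make_trials(ids, runif(12, 700, 1300),
                                      runif(12, 800, 1500)))
  nxt <- evolve_population(pop, sc, cfg)
  expect_equal(length(nxt$genomes), 12L)
  expect_equal(nxt$generation, pop$generation + 1L)
  parent_ids <- select_parents(sc, cfg)
  nxt_ids <- vapply(nxt$genomes, `[[`, character(1), "id")
  expect_identical(nxt_ids[1:3], parent_ids)
  for (k in 1:3)
    expect_identical(unclass(nxt$genomes[[k]]),
                     unclass(pop$genomes[[match(parent_ids[k], ids)]]))
  # offspring lineage records two distinct parents
  for (k in 4:12)
    expect_true(all(nxt$genomes[[k]]$lineage %in% parent_ids) &&
                nxt$genomes[[k]]$lineage[1] != nxt$genomes[[k]]$lineage[2])
})

test_that("with no mutation and one effective parent, offspring equal that parent", {
  set.seed(62)
  cfg <- ga_config(mutation_rate = 0)
  pop <- init_population(cfg)
  # make one genome dominate by duplicating it into all parent slots
  ids <- vapply(pop$genomes, `[[`, character(1), "id")
  best <- pop$genomes[[1]]
  pop$genomes <- c(list(best, best, best), pop$genomes[4:12])
  pop$genomes[[2]]$id <- "copy-b"; pop$genomes[[3]]$id <- "copy-c"
  ids <- vapply(pop$genomes, `[[`, character(1), "id")
  rt <- c(500, 500, 500, runif(9, 1000, 1500))
  sc <- score_distractors(make_trials(ids, rt, rt))
  nxt <- evolve_population(pop, sc, cfg)
  for (k in 4:12) {
    expect_identical(nxt$genomes[[k]]$amplitudes, best$amplitudes)
    expect_identical(nxt$genomes[[k]]$phases, best$phases)
    expect_identical(nxt$genomes[[k]]$gates, best$gates)
  }
})

test_that("evolution is reproducible from the seed", {
  run_once <- function() {
    set.seed(63)
    cfg <- ga_config()
    pop <- init_population(cfg)
    ids <- vapply(pop$genomes, `[[`, character(1), "id")
    sc <- score_distractors(make_trials(ids, runif(12, 700, 1300),
                                        runif(12, 800, 1500)))
    evolve_population(pop, sc, cfg)
  }
  expect_identical(lapply(run_once()$genomes, unclass),
                   lapply(run_once()$genomes, unclass))
})

test_that("constraint masks clamp target frequencies and survive the whole loop", {
  target <- example_targets()$BB       # active at frequencies 2 and 6
  inc <- target_constraint(target, include = TRUE)
  exc <- target_constraint(target, include = FALSE)
  expect_identical(which(inc$mode == "clamp_on"), c(2L, 6L))
  expect_identical(which(exc$mode == "force_off"), c(2L, 6L))

  set.seed(64)
  g <- random_genome()
  gi <- apply_constraints(g, inc, target)
  expect_equal(gi$gates[c(2, 6)], c(1, 1))
  expect_equal(gi$amplitudes[c(2, 6)], target$amplitudes[c(2, 6)])
  expect_identical(gi$phases, g$phases)   # phases stay free
  ge <- apply_constraints(g, exc, target)
  expect_equal(ge$amplitudes[c(2, 6)], c(0, 0))
  expect_equal(ge$gates[c(2, 6)], c(0, 0))
  # empty mask is the identity
  free <- constraint_mask(rep("free", 10))
  expect_identical(unclass(apply_constraints(g, free)), unclass(g))

  # masks hold exactly across generations, with mutation active
  for (mask in list(inc, exc)) {
    cfg <- ga_config(direction = "easy", constraint = mask,
                     mutation_rate = 0.2)
    pop <- init_population(cfg, target = target)
    for (gen in 1:4) {
      expect_true(all(vapply(pop$genomes, satisfies_constraints, logical(1),
                             mask)))
      ids <- vapply(pop$genomes, `[[`, character(1), "id")
      sc <- score_distractors(make_trials(ids, runif(12, 700, 1300),
                                          runif(12, 800, 1500)))
      pop <- evolve_population(pop, sc, cfg, target)
    }
    expect_true(all(vapply(pop$genomes, satisfies_constraints, logical(1), mask)))
  }
})

test_that("elitism never worsens the best score under a fixed deterministic fitness", {
  # deterministic surrogate fitness: spectrum distance to a fixed target
  target <- example_targets()$TP
  surrogate_scores <- function(pop) {
    ids <- vapply(pop$genomes, `[[`, character(1), "id")
    d <- vapply(pop$genomes, shape_distance, numeric(1), b = target,
                metric = "spectrum")
    # feed distances through the easy channel (lower mean_rt = fitter),
    # so selection maximizes distance when we negate
    data.frame(distractor_id = ids, mean_rt = -d, rt_small = -d, rt_large = -d,
               slope = 0, score_easy = -d, score_hard = 0.15 * d,
               stringsAsFactors = FALSE)
  }
  cfg <- ga_config(direction = "easy")
  improved <- 0L
  n_runs <- 50L
  for (s in seq_len(n_runs)) {
    set.seed(200 + s)
    pop <- init_population(cfg)
    best <- -Inf; gen_mean <- numeric(8)
    for (gen in 1:8) {
      sc <- surrogate_scores(pop)
      d <- -sc$mean_rt
      expect_gte(max(d), best - 1e-12)    # elitism: best never decreases
      best <- max(best, max(d))
      gen_mean[gen] <- mean(d)
      if (gen < 8) pop <- evolve_population(pop, sc, cfg)
    }
    improved <- improved + (gen_mean[8] >= gen_mean[1])
  }
  expect_gte(improved / n_runs, 0.95)
})
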