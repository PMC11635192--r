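#' Genetic-algorithm hyperparameters
#'
#' The evolutionary loop's configuration.  The defaults are the standard
#' operating point used throughout: population 50, 5 elites, 30 generations,
#' one-point crossover with probability 0.5, individual mutation probability
#' 0.1 with per-gene probability 0.5, tournament size 3.
#'
#' @param n_individuals population size per generation.
#' @param n_elites number of fittest individuals copied unchanged into the
#'   next generation (`0 <= n_elites < n_individuals`).
#' @param n_generations number of generations (the hard stop criterion).
#' @param p_cx probability that a consecutive pair of selected individuals is
#'   recombined by one-point crossover.
#' @param p_mut probability that an individual is selected for mutation.
#' @param p_gen probability that a gene is mutated given its individual was
#'   selected for mutation.
#' @param tournament_k tournament size for selection.
#' @param fitness_mode one of `"lambda_only"`, `"lambda_and_h0"`,
#'   `"multisite"`; recorded for provenance and used by [make_evaluator()].
#' @param reevaluate_elites if `TRUE`, elites are re-measured every
#'   generation; with a noisy evaluator this reproduces the fluctuation of
#'   the recorded best fitness despite elitism.  Default `FALSE`: elites keep
#'   their cached fitness.
#' @param seed master seed for the GA stream.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(n_individuals = 50L, n_elites = 5L, n_generations = 30L,
                      p_cx = 0.5, p_mut = 0.1, p_gen = 0.5, tournament_k = 3L,
                      fitness_mode = c("lambda_only", "lambda_and_h0",
                                       "multisite"),
                      reevaluate_elites = FALSE, seed = 0L) {
  fitness_mode <- match.arg(fitness_mode)
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_elites = as.integer(n_elites),
              n_generations = as.integer(n_generations),
              p_cx = p_cx, p_mut = p_mut, p_gen = p_gen,
              tournament_k = as.integer(tournament_k),
              fitness_mode = fitness_mode,
              reevaluate_elites = isTRUE(reevaluate_elites),
              seed = seed)
  if (cfg$n_elites < 0 || cfg$n_elites >= cfg$n_individuals)
    config_error("need 0 <= n_elites < n_individuals")
  for (p in c("p_cx", "p_mut", "p_gen"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      config_error(paste0(p, " must lie in [0, 1]"))
  if (cfg$tournament_k < 1) config_error("tournament_k must be >= 1")
  if (cfg$n_generations < 1) config_error("n_generations must be >= 1")
  structure(cfg, class = "ga_config")
}

individual <- function(genes, fitness = NA_real_) {
  genes <- as.integer(genes)
  if (any(genes < 0L) || any(genes > DAC_MAX))
    stop(errorCondition("genes must lie in [0, 1022]",
                        class = c("evochain_bounds_error", "evochain_error")))
  list(genes = genes, fitness = fitness)
}

pop_fitness <- function(pop) vapply(pop, `[[`, numeric(1), "fitness")

#' Length-constant fitness (single objective)
#'
#' `f = |lambda_emp - lambda_hat|`: the absolute deviation of the measured
#' length constant from the target; smaller is better.
#'
#' @param obs an `observation` (or anything with a `lambda_emp` field).
#' @param target a [target_observation()] with `lambda_hat` set.
#' @return non-negative scalar fitness.
#' @examples
#' fitness_lambda(list(lambda_emp = 1.12), target_observation(lambda_hat = 1.07))
#' @export
fitness_lambda <- function(obs, target) {
  stopifnot(is.finite(obs$lambda_emp), obs$lambda_emp > 0,
            is.finite(target$lambda_hat), target$lambda_hat > 0)
  abs(obs$lambda_emp - target$lambda_hat)
}

#' Length-constant plus amplitude fitness (multi-objective scalarization)
#'
#' `f2 = ((lambda_hat - lambda_emp) / lambda_hat)^2 +
#'       ((h0_hat - h0) / h0_hat)^2`:
#' the sum of squared relative errors of the two observables, so a solution
#' must match both the target length constant and the target
#' first-compartment amplitude.
#'
#' @param obs an `observation` with `lambda_emp` and `h0`.
#' @param target a [target_observation()] with `lambda_hat` and `h0_hat` set.
#' @return non-negative scalar fitness.
#' @export
fitness_lambda_amplitude <- function(obs, target) {
  stopifnot(target$lambda_hat > 0, target$h0_hat > 0)
  ((target$lambda_hat - obs$lambda_emp) / target$lambda_hat)^2 +
    ((target$h0_hat - obs$h0) / target$h0_hat)^2
}

#' Multi-site amplitude fitness (nine-dimensional problem)
#'
#' `f3 = sum_{i,j} (h_hat[i,j] - h[i,j])^2`: the summed squared deviation of
#' the measured EPSP amplitude matrix from the target matrix.
#'
#' @param h measured `amplitude_matrix` (bits).
#' @param h_hat target matrix of the same shape (bits).
#' @return non-negative scalar fitness.
#' @export
fitness_multisite <- function(h, h_hat) {
  if (!all(dim(h) == dim(h_hat)))
    stop(errorCondition("amplitude matrices must have the same shape",
                        class = c("evochain_shape_error", "evochain_error")))
  sum((h_hat - h)^2)
}

#' Initialize a random population
#'
#' Every gene is drawn uniformly from the integer DAC range `[0, 1022]`.
#'
#' @param ga_cfg a [ga_config()] (supplies `n_individuals`).
#' @param gene_count genes per individual (2 or 9).
#' @param seed optional stream seed; `NULL` draws from the current RNG state.
#' @return a list of individuals (`genes`, `fitness = NA`).
#' @export
init_population <- function(ga_cfg, gene_count, seed = NULL) {
  with_stream(seed, {
    lapply(seq_len(ga_cfg$n_individuals), function(i)
      individual(sample.int(DAC_MAX + 1L, gene_count, replace = TRUE) - 1L))
  })
}

#' Select the elites of a population
#'
#' Returns copies of the `n_elites` individuals with the smallest fitness.
#' Ties are broken by stable population order.
#'
#' @param pop list of evaluated individuals.
#' @param n_elites number of elites.
#' @return list of `n_elites` individuals.
#' @export
select_elites <- function(pop, n_elites) {
  f <- pop_fitness(pop)
  if (any(is.na(f)))
    stop(errorCondition("all individuals must be evaluated before elitism",
                        class = c("evochain_ga_error", "evochain_error")))
  pop[order(f)[seq_len(n_elites)]] # order() is stable: ties keep pop order
}

#' Tournament selection
#'
#' Each of `n_select` winners is the fittest of `k` individuals drawn
#' uniformly from the population (elites included); draws are without
#' replacement within one tournament and independent across tournaments.
#'
#' @param pop list of evaluated individuals (including elites).
#' @param k tournament size (`k <= length(pop)`).
#' @param n_select number of winners to return (copies).
#' @param seed optional stream seed; `NULL` draws from the current RNG state.
#' @return list of `n_select` selected individuals.
#' @export
tournament_select <- function(pop, k, n_select, seed = NULL) {
  if (length(pop) == 0)
    stop(errorCondition("cannot select from an empty population",
                        class = c("evochain_ga_error", "evochain_error")))
  stopifnot(k >= 1, k <= length(pop))
  f <- pop_fitness(pop)
  with_stream(seed, {
    lapply(seq_len(n_select), function(i) {
      contenders <- sample.int(length(pop), k, replace = FALSE)
      pop[[contenders[which.min(f[contenders])]]]
    })
  })
}

#' One-point crossover of two genomes
#'
#' Cuts both genomes at `cut_point` and swaps the leading segments: offspring
#' 1 takes parent 2's first `cut_point` genes and parent 1's remainder;
#' offspring 2 the converse.
#'
#' @param parent1,parent2 individuals with equal gene counts (>= 2).
#' @param cut_point cut position, `1 <= cut_point <= length - 1`.
#' @return list of two offspring individuals with unevaluated fitness.
#' @examples
#' one_point_crossover(list(genes = c(408L, 139L)),
#'                     list(genes = c(364L, 975L)), 1)
#' @export
one_point_crossover <- function(parent1, parent2, cut_point) {
  g1 <- parent1$genes
  g2 <- parent2$genes
  len <- length(g1)
  stopifnot(length(g2) == len, len >= 2)
  if (cut_point < 1 || cut_point > len - 1 || cut_point != round(cut_point))
    stop(errorCondition("cut_point must be an integer in [1, length - 1]",
                        class = c("evochain_ga_error", "evochain_error")))
  head_idx <- seq_len(cut_point)
  list(individual(c(g2[head_idx], g1[-head_idx])),
       individual(c(g1[head_idx], g2[-head_idx])))
}

#' Power-of-two point mutation of one gene
#'
#' The new value is the old one plus or minus `2^x`, with `x` uniform on the
#' integers 0..9 and the sign uniform; draws that leave the DAC range
#' `[0, 1022]` are rejected and redrawn (both `x` and the sign) until the
#' result is in bounds.  The mutation never returns the input value.
#'
#' @param g integer gene in `[0, 1022]`.
#' @param seed optional stream seed; `NULL` draws from the current RNG state.
#' @return the mutated gene.
#' @export
mutate_gene <- function(g, seed = NULL) {
  if (g < 0 || g > DAC_MAX)
    stop(errorCondition("gene out of bounds",
                        class = c("evochain_bounds_error", "evochain_error")))
  with_stream(seed, {
    repeat {
      step <- 2L^(sample.int(10L, 1L) - 1L)
      v <- g + sample(c(-1L, 1L), 1L) * step
      if (v >= 0L && v <= DAC_MAX) return(as.integer(v))
    }
  })
}

#' Mutate an individual gene-wise
#'
#' Each gene is independently mutated with probability `p_gen` via
#' [mutate_gene()]; the fitness is marked unevaluated if any gene changed.
#'
#' @param ind an individual.
#' @param p_gen per-gene mutation probability.
#' @param seed optional stream seed; `NULL` draws from the current RNG state.
#' @return the (possibly) mutated individual.
#' @export
mutate_individual <- function(ind, p_gen, seed = NULL) {
  with_stream(seed, {
    genes <- ind$genes
    hit <- runif(length(genes)) < p_gen
    for (i in which(hit)) genes[i] <- mutate_gene(genes[i])
    if (any(hit)) individual(genes) else ind
  })
}

#' Run the genetic algorithm
#'
#' The evolutionary loop with elitism: evaluate every unevaluated individual,
#' record the generation, copy the `n_elites` fittest unchanged, fill the
#' remaining `n_individuals - n_elites` slots by tournament selection,
#' recombine consecutive selected pairs with probability `p_cx` (one-point
#' crossover at a uniform cut), mutate each with probability `p_mut` (each
#' gene with `p_gen`), and repeat for exactly `n_generations` generations.
#' Offspring that were not touched keep their parents' cached fitness;
#' changed offspring are re-measured.  All randomness derives from
#' `ga_cfg$seed` (GA stream) so equal configurations give identical runs.
#'
#' @param evaluator function `genes -> fitness` (non-negative scalar; it must
#'   be total, returning a worst-case sentinel for degenerate observations —
#'   see [make_evaluator()]).
#' @param ga_cfg a [ga_config()].
#' @param gene_count genes per individual (2 or 9).
#' @return an object of class `ga_result`: `history` (one record per
#'   generation with the population's gene matrix, fitnesses, best individual
#'   and mean fitness), `best` (best individual of the final generation),
#'   `best_overall` (best recorded in any generation), and provenance
#'   (`config`, seeds).
#' @examples
#' toy <- function(genes) abs(genes[1] - 400) + abs(genes[2] - 600)
#' res <- evolve(toy, ga_config(n_generations = 10, seed = 1), gene_count = 2)
#' res$best$fitness
#' @export
evolve <- function(evaluator, ga_cfg, gene_count = 2L) {
  stopifnot(is.function(evaluator))
  ga_seed <- derive_seed(ga_cfg$seed, "ga")
  history <- vector("list", ga_cfg$n_generations)
  withr::with_seed(ga_seed, {
    pop <- init_population(ga_cfg, gene_count)
    for (gen in seq_len(ga_cfg$n_generations)) {
      for (i in seq_along(pop)) {
        if (is.na(pop[[i]]$fitness))
          pop[[i]]$fitness <- evaluator(pop[[i]]$genes)
      }
      f <- pop_fitness(pop)
      best_i <- which.min(f)
      history[[gen]] <- list(
        generation = gen,
        genes = do.call(rbind, lapply(pop, `[[`, "genes")),
        fitness = f,
        best = pop[[best_i]],
        best_fitness = f[best_i],
        mean_fitness = mean(f))
      if (gen == ga_cfg$n_generations) break
      elites <- select_elites(pop, ga_cfg$n_elites)
      if (ga_cfg$reevaluate_elites)
        elites <- lapply(elites, function(e) { e$fitness <- NA_real_; e })
      selected <- tournament_select(pop, ga_cfg$tournament_k,
                                    ga_cfg$n_individuals - ga_cfg$n_elites)
      # crossover on consecutive pairs (1,2), (3,4), ...
      i <- 1L
      while (i + 1L <= length(selected)) {
        if (runif(1) < ga_cfg$p_cx) {
          cut <- if (gene_count > 2L) sample.int(gene_count - 1L, 1L) else 1L
          off <- one_point_crossover(selected[[i]], selected[[i + 1L]], cut)
          selected[[i]] <- off[[1L]]
          selected[[i + 1L]] <- off[[2L]]
        }
        i <- i + 2L
      }
      for (i in seq_along(selected)) {
        if (runif(1) < ga_cfg$p_mut)
          selected[[i]] <- mutate_individual(selected[[i]], ga_cfg$p_gen)
      }
      pop <- c(elites, selected)
    }
  })
  best_fitness_per_gen <- vapply(history, `[[`, numeric(1), "best_fitness")
  best_gen <- which.min(best_fitness_per_gen)
  structure(list(history = history,
                 best = history[[ga_cfg$n_generations]]$best,
                 best_overall = history[[best_gen]]$best,
                 config = ga_cfg, gene_count = gene_count,
                 ga_seed = ga_seed),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d generations, population %d, %d genes\n",
              length(x$history), x$config$n_individuals, x$gene_count))
  cat(sprintf("  final best: genes (%s), fitness %.6g\n",
              paste(x$best$genes, collapse = ", "), x$best$fitness))
  invisible(x)
}

#' Summarize a GA run per generation
#'
#' @param object a `ga_result`.
#' @param ... unused.
#' @return data frame with one row per generation: best and mean fitness and
#'   the best individual's genes.
#' @export
summary.ga_result <- function(object, ...) {
  do.call(rbind, lapply(object$history, function(h)
    data.frame(generation = h$generation, best_fitness = h$best_fitness,
               mean_fitness = h$mean_fitness,
               best_genes = paste(h$best$genes, collapse = ";"))))
}

#' Build a substrate-backed fitness evaluator
#'
#' Wraps the measurement protocol into a total `genes -> fitness` function
#' for [evolve()].  Each call runs one experiment on the virtual substrate
#' with a fresh recording-noise seed (derived from `seed` and an internal
#' call counter, so runs are reproducible yet trials are independent) and
#' scores it against the target.  Degenerate observations (unidentifiable
#' attenuation fits at extreme parameter corners) are mapped to the
#' worst-case sentinel fitness `1e6` instead of raising.
#'
#' @param fitness_mode `"lambda_only"` ([fitness_lambda()]),
#'   `"lambda_and_h0"` ([fitness_lambda_amplitude()]), or `"multisite"`
#'   ([fitness_multisite()]).
#' @param target a [target_observation()] with the fields the mode needs.
#' @param substrate_cfg a [substrate_config()].
#' @param protocol_cfg a [protocol_config()].
#' @param seed master seed for the evaluation-noise stream.
#' @return a function `genes -> fitness`.
#' @export
make_evaluator <- function(fitness_mode, target,
                           substrate_cfg = substrate_config(),
                           protocol_cfg = protocol_config(), seed = 0L) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  function(genes) {
    counter$i <- counter$i + 1L
    eval_seed <- derive_seed(seed, paste0("eval", counter$i))
    tryCatch({
      if (fitness_mode == "multisite") {
        h <- run_multisite_experiment(genes, substrate_cfg, protocol_cfg,
                                      seed = eval_seed)
        fitness_multisite(h, target$h_hat)
      } else {
        obs <- run_attenuation_experiment(genes, substrate_cfg, protocol_cfg,
                                          seed = eval_seed)
        switch(fitness_mode,
               lambda_only = fitness_lambda(obs, target),
               lambda_and_h0 = fitness_lambda_amplitude(obs, target),
               config_error(paste0("unknown fitness mode: ", fitness_mode)))
      }
    }, evochain_degenerate_fit = function(e) WORST_FITNESS)
  }
}
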