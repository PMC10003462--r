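#' Genetic-algorithm configuration
#'
#' The search optimizes fixed-size SNP subsets (chromosomes of exactly `k`
#' SNP ids) against a neural-network goodness-of-fit. Defaults follow the
#' protocol: population and cycle counts of 30; operator settings
#' (tournament size 2, subset-preserving crossover at rate 0.9, per-gene
#' replacement mutation at rate 0.05, elitism 1) are conventional values for
#' fixed-size subset search and all configurable.
#'
#' @param subset_size chromosome size k (the study used 3, 10 or 16).
#' @param population_size individuals per generation (default 30).
#' @param cycles generations (default 30).
#' @param tournament_size parents drawn per tournament (default 2).
#' @param crossover_rate probability a child is produced by crossover rather
#'   than cloning (default 0.9).
#' @param mutation_rate per-gene probability of replacement by an unused SNP
#'   (default 0.05).
#' @param elitism number of best individuals carried unchanged (default 1).
#' @param epochs,batch_size,lr,decay training protocol for the fitness
#'   network (defaults as in [train_ann()]).
#' @return A `ga_config` list.
#' @export
ga_config <- function(subset_size, population_size = 30L, cycles = 30L,
                      tournament_size = 2L, crossover_rate = 0.9,
                      mutation_rate = 0.05, elitism = 1L,
                      epochs = 100L, batch_size = 32L, lr = 5e-3,
                      decay = 1e-5) {
  stopifnot(population_size >= 2, subset_size >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism >= 0, elitism < population_size)
  structure(list(subset_size = as.integer(subset_size),
                 population_size = as.integer(population_size),
                 cycles = as.integer(cycles),
                 tournament_size = as.integer(tournament_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, decay = decay),
            class = "ga_config")
}

#' Initialize a GA population
#'
#' Individual #1 is seeded with the top-k SNPs of the association-analysis
#' subset (ascending p), which accelerates convergence toward good minima;
#' the rest are uniform random k-subsets of the pool, each without internal
#' replacement.
#'
#' @param config a [ga_config()].
#' @param snp_pool character vector of candidate SNP ids (QC-passed).
#' @param seeded_ids SNP ids ordered by ascending association p (at least k).
#' @param seed integer seed.
#' @return list of character vectors, each of length k.
#' @export
init_population <- function(config, snp_pool, seeded_ids, seed = 1L) {
  k <- config$subset_size
  if (length(snp_pool) < k)
    stop("SNP pool (", length(snp_pool), ") smaller than subset size ", k)
  if (length(seeded_ids) < k)
    stop("seeded subset has fewer than k = ", k, " SNPs")
  pop <- vector("list", config$population_size)
  pop[[1]] <- seeded_ids[seq_len(k)]
  with_seed(seed, {
    for (i in seq_len(config$population_size)[-1])
      pop[[i]] <- sample(snp_pool, k)
  })
  pop
}

# canonical cache key of an individual
individual_key <- function(snp_ids) paste(sort(snp_ids), collapse = "|")

#' Fitness of a SNP subset
#'
#' Trains the network (width from [ann_width()] on k) on the individual's
#' genotype columns and returns restored-checkpoint training loss plus
#' validation loss; lower is better. Evaluations are memoized per
#' (subset, network seed) in `cache` so duplicate individuals cost nothing.
#'
#' @param snp_ids the individual (character vector of SNP ids).
#' @param matrix a complete `genotype_matrix`.
#' @param split a [make_split()] result.
#' @param config a [ga_config()].
#' @param ann_seed seed for network initialization/shuffling (one per GA
#'   run, so fitness differences reflect subsets rather than init noise).
#' @param cache an environment used for memoization (optional).
#' @return Non-negative fitness (train loss + validation loss); `Inf` with a
#'   warning if training diverges.
#' @export
ga_fitness <- function(snp_ids, matrix, split, config, ann_seed = 1L,
                       cache = NULL) {
  key <- paste0(individual_key(snp_ids), "@", ann_seed)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  cols <- match(snp_ids, matrix$snp_ids)
  if (anyNA(cols))
    stop("individual refers to SNPs absent from the matrix: ",
         paste(snp_ids[is.na(cols)], collapse = ", "))
  X <- matrix$values[, cols, drop = FALSE]
  y <- matrix$phenotypes
  fit <- tryCatch(
    train_ann(X[split$train, , drop = FALSE], y[split$train],
              X[split$val, , drop = FALSE], y[split$val],
              hidden = ann_width(length(snp_ids)), seed = ann_seed,
              epochs = config$epochs, batch_size = config$batch_size,
              lr = config$lr, decay = config$decay),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("fitness evaluation failed (", conditionMessage(fit),
            "); assigning +Inf")
    val <- Inf
  } else {
    val <- fit$train_loss + fit$val_loss
  }
  if (!is.null(cache)) cache[[key]] <- val
  val
}

# subset-preserving crossover: keep the parents' shared SNPs, fill to size k
# from the symmetric difference uniformly without replacement
crossover_subsets <- function(p1, p2, k) {
  shared <- intersect(p1, p2)
  if (length(shared) >= k) return(shared[seq_len(k)])
  pool <- setdiff(union(p1, p2), shared)
  c(shared, sample(pool, k - length(shared)))
}

# per-gene replacement mutation from the unused pool
mutate_subset <- function(ind, snp_pool, rate) {
  hit <- which(runif(length(ind)) < rate)
  if (length(hit) == 0) return(ind)
  unused <- setdiff(snp_pool, ind)
  if (length(unused) == 0) return(ind)
  repl <- sample(unused, min(length(hit), length(unused)))
  ind[hit[seq_along(repl)]] <- repl
  ind
}

#' Evolve a population of SNP subsets
#'
#' Standard generational loop: elitism carries the best individual(s)
#' unchanged, parents are chosen by tournament, children by
#' subset-preserving crossover and per-gene replacement mutation (all
#' operators conserve subset size exactly), for `config$cycles` generations.
#' Returns the best individual ever evaluated, so best-ever fitness is
#' non-increasing in cycle.
#'
#' @param population from [init_population()].
#' @param config a [ga_config()].
#' @param matrix a complete `genotype_matrix`.
#' @param split a [make_split()] result.
#' @param seed integer seed for selection/crossover/mutation randomness; the
#'   same seed is used for the fitness networks.
#' @param cache memoization environment (created internally if NULL).
#' @return list with `snp_ids` (best individual), `fitness`, `trajectory`
#'   (data.frame: cycle, best_fitness, mean_fitness, cumulative best-ever),
#'   and `n_evaluations` (unique networks trained).
#' @export
ga_evolve <- function(population, config, matrix, split, seed = 1L,
                      cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  snp_pool <- matrix$snp_ids
  k <- config$subset_size
  eval_pop <- function(pop) vapply(
    pop, ga_fitness, numeric(1),
    matrix = matrix, split = split, config = config,
    ann_seed = seed, cache = cache)

  fit <- eval_pop(population)
  best_ids <- population[[which.min(fit)]]
  best_fit <- min(fit)
  traj <- data.frame(cycle = 0L, best_fitness = min(fit),
                     mean_fitness = mean(fit), best_ever = best_fit)
  with_seed(seed, {
    for (cycle in seq_len(config$cycles)) {
      ord <- order(fit)
      new_pop <- population[ord[seq_len(config$elitism)]]
      while (length(new_pop) < config$population_size) {
        p1 <- population[[tournament_pick(fit, config$tournament_size)]]
        p2 <- population[[tournament_pick(fit, config$tournament_size)]]
        child <- if (runif(1) < config$crossover_rate)
          crossover_subsets(p1, p2, k) else p1
        child <- mutate_subset(child, snp_pool, config$mutation_rate)
        stopifnot(length(child) == k, !anyDuplicated(child))
        new_pop[[length(new_pop) + 1]] <- child
      }
      population <- new_pop
      fit <- eval_pop(population)
      if (min(fit) < best_fit) {
        best_fit <- min(fit)
        best_ids <- population[[which.min(fit)]]
      }
      traj <- rbind(traj, data.frame(cycle = cycle, best_fitness = min(fit),
                                     mean_fitness = mean(fit),
                                     best_ever = best_fit))
    }
  })
  list(snp_ids = sort(best_ids), fitness = best_fit, trajectory = traj,
       n_evaluations = length(ls(cache)))
}

tournament_pick <- function(fit, size) {
  idx <- sample.int(length(fit), size)
  idx[which.min(fit[idx])]
}

#' Random subset search (budget-matched reference for the GA)
#'
#' Evaluates `n_evals` uniform random k-subsets with the same fitness
#' function and returns the best, providing a like-for-like comparison with
#' an equal network-training budget.
#'
#' @inheritParams ga_evolve
#' @param n_evals number of random subsets to evaluate.
#' @return list with `snp_ids` and `fitness`.
#' @export
random_subset_search <- function(config, matrix, split, n_evals, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  snp_pool <- matrix$snp_ids
  best_fit <- Inf
  best_ids <- NULL
  with_seed(seed, {
    for (i in seq_len(n_evals)) {
      ids <- sample(snp_pool, config$subset_size)
      f <- ga_fitness(ids, matrix, split, config, ann_seed = seed,
                      cache = cache)
      if (f < best_fit) { best_fit <- f; best_ids <- ids }
    }
  })
  list(snp_ids = sort(best_ids), fitness = best_fit)
}

#' Run the full GA-optimized neural-network ensemble
#'
#' For one subset size k: five independent GA searches (seeds
#' `seed + 0 .. seed + 4`) each contribute their best SNP subset; the top-k
#' subset from the association analysis is always member #6. One network is
#' trained per subset (seeded deterministically) and predictions are later
#' averaged by [ensemble_predict()].
#'
#' @param matrix a complete `genotype_matrix` of all QC-passed SNPs.
#' @param split a [make_split()] result.
#' @param assoc_ids SNP ids ordered by ascending association p (>= k of
#'   them), as from the matching [select_snp_subsets()] entry or the pruned
#'   ranking.
#' @param config a [ga_config()] (its `subset_size` is k).
#' @param seed base seed; member g's GA uses `seed + g - 1`.
#' @return An `ensemble_model`: `members` (6 lists with `snp_ids`, `source`,
#'   `fitness`, `model`, `trajectory`), `subset_size`, `seed`.
#' @export
run_gannet <- function(matrix, split, assoc_ids, config, seed = 1L) {
  k <- config$subset_size
  if (length(assoc_ids) < k)
    stop("association subset has fewer than k = ", k, " SNPs")
  members <- vector("list", 6L)
  for (g in seq_len(5L)) {
    run_seed <- seed + g - 1L
    pop <- init_population(config, matrix$snp_ids, assoc_ids, seed = run_seed)
    res <- ga_evolve(pop, config, matrix, split, seed = run_seed)
    members[[g]] <- list(snp_ids = res$snp_ids, source = "ga",
                         fitness = res$fitness, trajectory = res$trajectory,
                         seed = run_seed)
  }
  members[[6]] <- list(snp_ids = sort(assoc_ids[seq_len(k)]),
                       source = "association", fitness = NA_real_,
                       trajectory = NULL, seed = seed + 5L)
  y <- matrix$phenotypes
  for (g in seq_len(6L)) {
    cols <- match(members[[g]]$snp_ids, matrix$snp_ids)
    X <- matrix$values[, cols, drop = FALSE]
    members[[g]]$model <- train_ann(
      X[split$train, , drop = FALSE], y[split$train],
      X[split$val, , drop = FALSE], y[split$val],
      hidden = ann_width(k), seed = members[[g]]$seed,
      epochs = config$epochs, batch_size = config$batch_size,
      lr = config$lr, decay = config$decay)
    if (members[[g]]$source == "association")
      members[[g]]$fitness <- members[[g]]$model$train_loss +
        members[[g]]$model$val_loss
  }
  structure(list(members = members, subset_size = k, seed = seed,
                 config = config),
            class = "ensemble_model")
}

#' Ensemble prediction
#'
#' The case probability of each sample is the unweighted arithmetic mean of
#' the six member networks' sigmoid outputs; the classification label uses
#' the >= 0.5 rule.
#'
#' @param model an `ensemble_model` from [run_gannet()].
#' @param matrix a complete `genotype_matrix` containing every member's
#'   SNPs.
#' @return data.frame with `sample_id`, `probability`, `label` and one
#'   column per member (`member1` .. `member6`).
#' @export
ensemble_predict <- function(model, matrix) {
  probs <- matrix(NA_real_, length(matrix$sample_ids), 6L)
  for (g in seq_len(6L)) {
    cols <- match(model$members[[g]]$snp_ids, matrix$snp_ids)
    if (anyNA(cols))
      stop("matrix lacks SNPs of member ", g, ": ",
           paste(model$members[[g]]$snp_ids[is.na(cols)], collapse = ", "))
    probs[, g] <- predict(model$members[[g]]$model,
                          matrix$values[, cols, drop = FALSE])
  }
  avg <- rowMeans(probs)
  out <- data.frame(sample_id = matrix$sample_ids, probability = avg,
                    label = as.integer(avg >= 0.5),
                    stringsAsFactors = FALSE)
  colnames(probs) <- paste0("member", 1:6)
  cbind(out, probs)
}

#' Ensemble manifest
#'
#' A JSON-serializable description of a fitted ensemble (member subsets,
#' sources, fitness, seeds, configuration) sufficient to re-execute the run.
#'
#' @param model an `ensemble_model`.
#' @return A list ready for `jsonlite::toJSON()`.
#' @export
ensemble_manifest <- function(model) {
  list(
    subset_size = model$subset_size,
    seed = model$seed,
    config = unclass(model$config),
    members = lapply(model$members, function(m)
      list(snp_ids = m$snp_ids, source = m$source, fitness = m$fitness,
           seed = m$seed, best_epoch = m$model$best_epoch,
           val_loss = m$model$val_loss)))
}

#' Exact size of the k-of-n subset search space
#'
#' The number of distinct SNP subsets the GA searches over, as an exact
#' binomial coefficient computed in integer arithmetic (no floating-point
#' rounding until the final conversion).
#'
#' @param n pool size.
#' @param k subset size.
#' @return The exact value of choose(n, k) as a double (exact while below
#'   2^53).
#' @export
subset_search_space <- function(n, k) {
  k <- min(k, n - k)
  if (k < 0) return(0)
  num <- 1
  for (i in seq_len(k)) {
    num <- num * (n - k + i) / i   # always integer at each step
  }
  num
}
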