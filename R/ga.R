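# Genetic-algorithm descriptor selection for the PLS model.  Binary
# chromosomes encode descriptor subsets; fitness is the leave-one-out RMSEcv
# of a PLS fit on the encoded subset with a cross-validation-chosen number
# of latent vectors (lower is better), optionally penalized by subset size.

#' Genetic algorithm configuration
#'
#' Defaults (population 64, 100 generations, tournament selection of size 2,
#' single-point crossover at rate 0.8, bit-flip mutation at rate 1/p,
#' elitism 2) are sized for reliable recovery of a small informative subset
#' among ~26 candidate descriptors with ~24 training compounds.
#'
#' @param population_size Even number of chromosomes per generation.
#' @param n_generations Number of generations.
#' @param crossover_rate Probability of single-point crossover per pair.
#' @param mutation_rate Per-bit flip probability; default `NULL` means 1/p.
#' @param elitism_count Number of best chromosomes copied unchanged.
#' @param subset_size_penalty Added to the fitness per selected descriptor
#'   (0 = pure RMSEcv, the default).
#' @param max_lv Cap on the latent-vector counts explored when scoring a
#'   subset (the effective cap is `min(max_lv, subset size, n - 2)`).
#' @param seed Integer seed for the GA's randomness.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 64L, n_generations = 100L,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      elitism_count = 2L, subset_size_penalty = 0.1,
                      max_lv = 8L, seed = 42L) {
  stopifnot(population_size >= 2L, population_size %% 2L == 0L,
            n_generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1),
            elitism_count >= 0L, subset_size_penalty >= 0, max_lv >= 1L)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 subset_size_penalty = subset_size_penalty,
                 max_lv = as.integer(max_lv),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Internal: fitness of one chromosome (logical vector over descriptors).
# Cached in `cache` (an environment) keyed by the selected column indices.
.ga_fitness <- function(chrom, X, y, config, cache) {
  sel <- which(chrom)
  if (!length(sel)) return(Inf)
  key <- paste(sel, collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  A_max <- min(config$max_lv, length(sel), length(y) - 2L)
  f <- tryCatch({
    pred <- .loo_predictions(X[, sel, drop = FALSE], y, A_max)
    press <- colSums((y - pred)^2)
    sqrt(min(press) / length(y)) + config$subset_size_penalty * length(sel)
  }, error = function(e) Inf)
  cache[[key]] <- f
  f
}

#' Select descriptors with a genetic algorithm
#'
#' Runs a seeded binary-chromosome GA over subsets of the candidate
#' descriptors.  Fitness is the leave-one-out RMSEcv of a PLS fit on the
#' subset, with the latent-vector count chosen by cross-validation inside
#' the fitness evaluation.  Elitism guarantees the returned subset is never
#' worse than the best member of the initial population.
#'
#' @param X Matrix or data frame of candidate descriptors (named columns).
#' @param y Response vector.
#' @param config A [ga_config()].
#' @param cache Environment memoising fitness values by descriptor subset.
#'   Fitness is a pure function of the subset for fixed `X` and `y`, so a
#'   cache may be shared across repeated runs on the same data (e.g. when
#'   varying only the GA seed); never reuse it across data sets.
#' @return List with `selected` (descriptor names in canonical column
#'   order), `fitness` (best achieved), `n_lv` (the CV-chosen LV count of
#'   the winning subset) and `history` (best fitness per generation).
#' @export
ga_select_descriptors <- function(X, y, config = ga_config(),
                                  cache = new.env(parent = emptyenv())) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  y <- as.numeric(y)
  p <- ncol(X)
  if (p < 1L) stop("no candidate descriptors")
  if (p == 1L) {
    A <- min(config$max_lv, 1L, length(y) - 2L)
    cv <- loo_cv(X, y, A)
    return(list(selected = colnames(X), fitness = cv$rmse_cv, n_lv = A,
                history = cv$rmse_cv))
  }
  npop <- config$population_size
  if (npop <= config$elitism_count) {
    stop("population_size must exceed elitism_count")
  }
  mut <- if (is.null(config$mutation_rate)) 1 / p else config$mutation_rate
  set.seed(config$seed)
  pop <- matrix(stats::runif(npop * p) < 0.5, npop, p)
  empty <- rowSums(pop) == 0L
  if (any(empty)) {  # ensure every chromosome encodes at least one descriptor
    pop[cbind(which(empty), sample.int(p, sum(empty), replace = TRUE))] <- TRUE
  }
  history <- numeric(config$n_generations)
  fit <- apply(pop, 1L, function(ch) .ga_fitness(ch, X, y, config, cache))
  for (gen in seq_len(config$n_generations)) {
    ord <- order(fit)
    history[gen] <- fit[ord[1L]]
    nextpop <- matrix(FALSE, npop, p)
    nelite <- min(config$elitism_count, npop)
    if (nelite > 0L) nextpop[seq_len(nelite), ] <- pop[ord[seq_len(nelite)], ]
    i <- nelite
    while (i < npop) {
      # tournament selection, size 2
      c1 <- sample.int(npop, 2L)
      p1 <- pop[c1[which.min(fit[c1])], ]
      c2 <- sample.int(npop, 2L)
      p2 <- pop[c2[which.min(fit[c2])], ]
      if (stats::runif(1L) < config$crossover_rate && p > 1L) {
        cut <- sample.int(p - 1L, 1L)
        o1 <- c(p1[seq_len(cut)], p2[(cut + 1L):p])
        o2 <- c(p2[seq_len(cut)], p1[(cut + 1L):p])
      } else {
        o1 <- p1
        o2 <- p2
      }
      for (o in list(o1, o2)) {
        if (i >= npop) break
        flip <- stats::runif(p) < mut
        o <- xor(o, flip)
        if (!any(o)) o[sample.int(p, 1L)] <- TRUE
        i <- i + 1L
        nextpop[i, ] <- o
      }
    }
    pop <- nextpop
    fit <- apply(pop, 1L, function(ch) .ga_fitness(ch, X, y, config, cache))
  }
  best <- which.min(fit)
  sel <- which(pop[best, ])
  A_max <- min(config$max_lv, length(sel), length(y) - 2L)
  A <- select_n_lvs(X[, sel, drop = FALSE], y, A_max)
  list(selected = colnames(X)[sel],
       fitness = fit[best],
       n_lv = A,
       history = history)
}
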