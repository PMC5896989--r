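#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Search interval for the bandwidth
#'
#' @param x0,xn Positive finite endpoints with `x0 < xn`.
#' @return A list of class `search_interval`.
#' @export
search_interval <- function(x0, xn) {
  if (!is.finite(x0) || !is.finite(xn) || x0 <= 0 || xn <= x0) {
    stop_user("need finite 0 < x0 < xn")
  }
  structure(list(x0 = x0, xn = xn), class = "search_interval")
}

#' Genetic-algorithm configuration
#'
#' The constants mirror the conventional small-budget setup for
#' one-dimensional bandwidth search: population 10, 10 outer dichotomous
#' iterations, selection / crossover / mutation probabilities 0.5 / 0.7 /
#' 0.1, and 10 inner GA generations per subinterval.
#'
#' @param population_size Individuals per population (>= 2).
#' @param iterations Outer dichotomous iterations.
#' @param p_select Fraction of each generation filled by roulette-selected
#'   parents (the remainder carried over by rank); 1-elitism is always on.
#' @param p_cross Probability an offspring undergoes arithmetic crossover.
#' @param p_mutate Probability an offspring is mutated (uniform resample in
#'   the current interval).
#' @param inner_generations GA generations per subinterval per outer
#'   iteration.
#' @param seed Integer RNG seed; `NULL` to use the current RNG state.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 10L, iterations = 10L,
                      p_select = 0.5, p_cross = 0.7, p_mutate = 0.1,
                      inner_generations = 10L, seed = NULL) {
  if (population_size < 2L) stop_user("`population_size` must be >= 2")
  if (iterations < 1L || inner_generations < 1L) {
    stop_user("iteration counts must be positive")
  }
  for (p in c(p_select, p_cross, p_mutate)) {
    if (!is.finite(p) || p < 0 || p > 1) stop_user("probabilities must lie in [0, 1]")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      iterations = as.integer(iterations),
      p_select = p_select, p_cross = p_cross, p_mutate = p_mutate,
      inner_generations = as.integer(inner_generations),
      seed = seed
    ),
    class = "ga_config"
  )
}

#' Draw an initial population of bandwidth candidates
#'
#' Uniform draws in `[x0, xn]`, using the current RNG state.
#'
#' @param interval A [search_interval()].
#' @param size Number of individuals.
#' @return Numeric vector of candidate sigmas.
#' @export
init_population <- function(interval, size) {
  stopifnot(inherits(interval, "search_interval"))
  runif(size, interval$x0, interval$xn)
}

# fitness-proportional selection weights that tolerate -Inf/+Inf sentinels
roulette_weights <- function(fit) {
  w <- rep(0, length(fit))
  if (any(is.infinite(fit) & fit > 0)) {
    w[is.infinite(fit) & fit > 0] <- 1
    return(w)
  }
  ok <- is.finite(fit)
  if (!any(ok)) return(rep(1, length(fit)))
  shifted <- fit[ok] - min(fit[ok])
  if (all(shifted == 0)) shifted <- rep(1, sum(ok))
  w[ok] <- shifted + max(shifted) * 1e-6
  w
}

eval_fitness <- function(fitness_fn, sigmas) {
  vapply(sigmas, function(s) {
    v <- tryCatch(fitness_fn(s), error = function(e) -Inf)
    if (length(v) != 1L || is.na(v)) -Inf else as.numeric(v)
  }, numeric(1))
}

#' Run a real-coded genetic algorithm on a population of bandwidths
#'
#' Each of `inner_generations` rounds applies 1-elitism (best individual
#' copied unchanged), roulette parent selection for a `p_select` fraction of
#' the remaining slots (the rest carried over by fitness rank), arithmetic
#' crossover (`child = lambda * a + (1 - lambda) * b`,
#' `lambda ~ Uniform(0,1)`) with probability `p_cross`, and uniform-resample
#' mutation within the interval with probability `p_mutate` per offspring.
#' Offspring are clamped to the interval. Uses the current RNG state.
#'
#' @param population Numeric vector of candidate sigmas.
#' @param fitness_fn Function sigma -> fitness; may return `+Inf` (sentinel
#'   for perfect separation). Errors and `NA` evaluate to `-Inf`.
#' @param interval The [search_interval()] the candidates live in.
#' @param config A [ga_config()] (its `seed` field is ignored here).
#' @return List with `population`, `fitness`, `best_sigma`, `best_fitness`.
#' @export
ga_run <- function(population, fitness_fn, interval, config = ga_config()) {
  stopifnot(inherits(interval, "search_interval"))
  if (length(population) == 0L) stop_user("population must be nonempty")
  pop <- pmin(pmax(population, interval$x0), interval$xn)
  fit <- eval_fitness(fitness_fn, pop)
  if (all(fit == -Inf)) stop_user("all fitness evaluations failed (-Inf/NaN)")
  n <- length(pop)
  for (gen in seq_len(config$inner_generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[1]]
    elite_fit <- fit[ord[1]]
    n_off <- n - 1L
    n_sel <- min(n_off, round(config$p_select * n))
    sel <- if (n_sel > 0L) {
      sample.int(n, n_sel, replace = TRUE, prob = roulette_weights(fit))
    } else integer(0)
    carried <- ord[seq_len(n_off - n_sel)] # best-ranked carried over
    offspring <- pop[c(sel, carried)]
    if (length(offspring) >= 2L) {
      do_cross <- runif(length(offspring)) < config$p_cross
      for (i in which(do_cross)) {
        j <- sample(setdiff(seq_along(offspring), i), 1L)
        lambda <- runif(1)
        offspring[i] <- lambda * offspring[i] + (1 - lambda) * offspring[j]
      }
    }
    do_mut <- runif(length(offspring)) < config$p_mutate
    offspring[do_mut] <- runif(sum(do_mut), interval$x0, interval$xn)
    offspring <- pmin(pmax(offspring, interval$x0), interval$xn)
    pop <- c(elite, offspring)
    fit <- c(elite_fit, eval_fitness(fitness_fn, offspring))
  }
  best <- which.max(fit)
  list(population = pop, fitness = fit,
       best_sigma = pop[best], best_fitness = fit[best])
}

#' Dichotomous greedy genetic algorithm for bandwidth selection
#'
#' An interval-halving outer loop around the real-coded GA: draw an initial
#' population on `[x0, xn]` and let `x_max` be its best point; then, for
#' each outer iteration, run the GA on the two subintervals
#' `[x0, x_max]` and `[x_max, xn]`, keep the subinterval with the larger
#' best fitness (ties keep the left one), move the discarded endpoint to
#' `x_max` and `x_max` to the winner's best point, and repeat. A subinterval
#' of zero width is skipped and the other used. The reported best is the
#' global best over all evaluations, so best fitness is non-decreasing
#' across outer iterations.
#'
#' @param interval A [search_interval()].
#' @param fitness_fn Function sigma -> fitness (larger is better; `+Inf`
#'   allowed as a perfect-separation sentinel).
#' @param config A [ga_config()]; `config$seed`, when non-`NULL`, seeds the
#'   RNG so the whole trace is reproducible.
#' @return An object of class `dgga_trace`: list with `best_sigma`,
#'   `best_fitness`, `n_evaluations`, and `iterations`, a tibble with one
#'   row per outer iteration (`iteration`, `x0`, `xn`, `x_max`, `side`,
#'   `best_sigma`, `best_fitness`).
#' @export
#' @examples
#' tr <- dgga_optimize(search_interval(0.5, 16),
#'                     function(s) -(s - 3)^2,
#'                     ga_config(seed = 5))
#' tr$best_sigma
dgga_optimize <- function(interval, fitness_fn, config = ga_config()) {
  stopifnot(inherits(interval, "search_interval"), inherits(config, "ga_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_eval <- 0L
  counted_fn <- function(s) {
    n_eval <<- n_eval + 1L
    fitness_fn(s)
  }
  pop <- init_population(interval, config$population_size)
  fit <- eval_fitness(counted_fn, pop)
  if (all(fit == -Inf)) stop_user("all fitness evaluations failed (-Inf/NaN)")
  x_max <- pop[which.max(fit)]
  best_sigma <- x_max
  best_fitness <- max(fit)
  x0 <- interval$x0
  xn <- interval$xn
  rows <- vector("list", config$iterations)

  for (it in seq_len(config$iterations)) {
    run_side <- function(lo, hi) {
      if (hi <= lo) return(NULL)
      p <- init_population(search_interval(lo, hi), config$population_size)
      ga_run(p, counted_fn, search_interval(lo, hi), config)
    }
    left <- run_side(x0, x_max)
    right <- run_side(x_max, xn)
    if (is.null(left) && is.null(right)) break
    maxfit1 <- if (is.null(left)) -Inf else left$best_fitness
    maxfit2 <- if (is.null(right)) -Inf else right$best_fitness
    if (maxfit1 >= maxfit2) { # equal fitness keeps the left subinterval
      xn <- x_max
      x_max <- left$best_sigma
      side <- "left"
      it_best <- left
    } else {
      x0 <- x_max
      x_max <- right$best_sigma
      side <- "right"
      it_best <- right
    }
    if (it_best$best_fitness > best_fitness ||
        (it_best$best_fitness == best_fitness && is.infinite(best_fitness))) {
      best_fitness <- it_best$best_fitness
      best_sigma <- it_best$best_sigma
    }
    rows[[it]] <- tibble(
      iteration = it, x0 = x0, xn = xn, x_max = x_max, side = side,
      best_sigma = best_sigma, best_fitness = best_fitness
    )
  }
  structure(
    list(
      best_sigma = best_sigma,
      best_fitness = best_fitness,
      n_evaluations = n_eval,
      interval = interval,
      config = config,
      iterations = dplyr::bind_rows(rows)
    ),
    class = "dgga_trace"
  )
}

#' @export
print.dgga_trace <- function(x, ...) {
  cat(sprintf(
    "<dgga_trace> best sigma = %.6g (fitness %.6g) after %d evaluations, %d outer iterations\n",
    x$best_sigma, x$best_fitness, x$n_evaluations, nrow(x$iterations)
  ))
  invisible(x)
}

#' Tidy a DGGA trace: one row per outer iteration
#'
#' @param x A `dgga_trace`.
#' @param ... Unused.
#' @return The per-iteration tibble.
#' @export
tidy.dgga_trace <- function(x, ...) x$iterations

#' One-row summary of a DGGA run
#'
#' @param x A `dgga_trace`.
#' @param ... Unused.
#' @return Tibble with `best_sigma`, `best_fitness`, `n_evaluations`,
#'   `n_iterations`.
#' @export
glance.dgga_trace <- function(x, ...) {
  tibble(
    best_sigma = x$best_sigma,
    best_fitness = x$best_fitness,
    n_evaluations = x$n_evaluations,
    n_iterations = nrow(x$iterations)
  )
}

#' Plot best fitness and interval shrinkage across DGGA iterations
#'
#' @param object A `dgga_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dgga_trace <- function(object, ...) {
  df <- object$iterations
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$x0, ymax = .data$xn),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_sigma)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$best_sigma)) +
    ggplot2::labs(y = "sigma", title = "DGGA interval halving and best bandwidth")
}

#' Select the KLDA bandwidth by DGGA
#'
#' Wires the full bandwidth-selection pipeline: the fitness of a candidate
#' sigma is the between/within dispersion ratio ([dispersion_criterion()])
#' of the KLDA projections of the training data fitted with that sigma.
#' The default search interval is `[0.01 m, 100 m]` where `m` is the median
#' pairwise distance of the features, covering both under- and
#' over-smoothing regimes.
#'
#' @param data Feature tibble or matrix.
#' @param labels Class labels (default: `data$label`).
#' @param d Reduced dimension (default: number of classes).
#' @param interval Optional [search_interval()] override.
#' @param config A [ga_config()].
#' @param weighted Use the class-size-weighted between-class dispersion.
#' @return A `dgga_trace`; its `best_sigma` is the selected bandwidth.
#' @export
select_bandwidth <- function(data, labels = NULL, d = NULL, interval = NULL,
                             config = ga_config(), weighted = FALSE) {
  fm <- as_feature_matrix(data, labels)
  check_labels(fm$labels, nrow(fm$x))
  if (is.null(d)) d <- length(unique(fm$labels))
  if (is.null(interval)) {
    m <- median_pairwise_distance(fm$x)
    interval <- search_interval(1e-2 * m, 1e2 * m)
  }
  fitness <- klda_criterion_fitness(fm$x, fm$labels, d = d, weighted = weighted)
  dgga_optimize(interval, fitness, config)
}

#' Fitness function: KLDA dispersion ratio as a function of sigma
#'
#' @inheritParams select_bandwidth
#' @return A function `sigma -> ratio` suitable for [dgga_optimize()]; KLDA
#'   failures evaluate to `-Inf`.
#' @export
klda_criterion_fitness <- function(data, labels = NULL, d = NULL,
                                   weighted = FALSE) {
  fm <- as_feature_matrix(data, labels)
  check_labels(fm$labels, nrow(fm$x))
  if (is.null(d)) d <- length(unique(fm$labels))
  function(sigma) {
    model <- suppressWarnings(klda_fit(fm$x, fm$labels, sigma = sigma, d = d))
    dispersion_criterion(model$projections, fm$labels, weighted = weighted)$ratio
  }
}
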