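# Bounded stochastic optimizers used by the global fits. No DE package is
# installed in the analysis environment, so a plain rand/1/bin differential
# evolution is implemented here; it is deterministic given the RNG seed set
# by the calling fit (fit_settings$rng_seed).

# fn: objective taking a numeric vector; lower/upper: bounds (same length).
# Returns list(par, value, iterations, converged).
.de_optimize <- function(fn, lower, upper, pop_size = NULL, max_iter = 100,
                         F = 0.7, CR = 0.9, tol = 1e-9) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  if (is.null(pop_size)) pop_size <- max(15L, 10L * d)
  # initial population: uniform within bounds, plus the midpoint
  pop <- matrix(stats::runif(pop_size * d, rep(lower, each = pop_size),
                             rep(upper, each = pop_size)),
                nrow = pop_size)
  pop[1, ] <- (lower + upper) / 2
  cost <- apply(pop, 1, fn)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(pop_size)) {
      idx <- sample.int(pop_size, 3L)
      while (any(idx == i)) idx <- sample.int(pop_size, 3L)
      mutant <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
      # reflect out-of-bounds components back into the box
      below <- mutant < lower; mutant[below] <- 2 * lower[below] - mutant[below]
      above <- mutant > upper; mutant[above] <- 2 * upper[above] - mutant[above]
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      tc <- fn(trial)
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
    spread <- max(cost) - min(cost)
    if (is.finite(spread) && spread <= tol * (abs(min(cost)) + tol)) {
      converged <- TRUE
      break
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], iterations = it,
       converged = converged || it < max_iter)
}

# Deterministic 1-D minimizer on a bounded interval (golden-section via
# stats::optimize), standing in for the single-parameter annealing scans.
.scan_optimize <- function(fn, lower, upper, tol = 1e-8) {
  # coarse grid guards against multiple local minima along the scan
  grid <- seq(lower, upper, length.out = 41L)
  vals <- vapply(grid, fn, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(fn, lower = lo, upper = hi, tol = tol)
  list(par = opt$minimum, value = opt$objective)
}
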