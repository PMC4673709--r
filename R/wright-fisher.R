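# Shared Wright-Fisher engine: one generation for a vector of replicate
# frequencies. Recurrent gain (mu) and loss (delta) are applied
# deterministically before genic (haploid) selection and binomial sampling
# of 2*Ne allele copies.
wf_generation <- function(p, ne, s = 0, mu = 0, loss = 0) {
  p <- p + mu * (1 - p) - loss * p
  p <- p * (1 + s) / (1 + p * s)
  rbinom(length(p), 2 * ne, p) / (2 * ne)
}

#' Simulate Wright-Fisher allele-frequency trajectories
#'
#' Forward simulation of a CNV allele in a diploid population of effective
#' size `ne` (binomial sampling of `2*ne` allele copies per generation).
#' Selection is genic: a carrier haplotype has relative fitness `1 + s`, so
#' the deterministic update is \eqn{p' = p(1+s)/(1+ps)}. Recurrent gain
#' `mu` and loss `delta` are applied deterministically each generation; with
#' `mu = delta = 0` the boundaries 0 and 1 are absorbing.
#'
#' @param ne effective population size (>= 1).
#' @param p0 initial allele frequency.
#' @param generations number of generations to simulate.
#' @param n_reps number of independent replicate trajectories.
#' @param s selection coefficient (genic).
#' @param mu per-generation recurrent gain rate.
#' @param delta per-generation loss rate.
#' @param seed integer seed.
#' @return tibble with columns rep, generation (0 ... `generations`) and
#'   frequency.
#' @examples
#' traj <- simulate_wright_fisher(ne = 50, p0 = 0.5, generations = 10,
#'                                n_reps = 100, seed = 1)
#' @export
simulate_wright_fisher <- function(ne, p0, generations, n_reps = 1,
                                   s = 0, mu = 0, delta = 0, seed = NULL) {
  assert_scalar_number(ne, "ne", lower = 1)
  assert_scalar_number(p0, "p0", lower = 0, upper = 1)
  assert_scalar_number(generations, "generations", lower = 1)
  assert_scalar_number(n_reps, "n_reps", lower = 1)
  ne <- as.integer(ne); generations <- as.integer(generations)
  n_reps <- as.integer(n_reps)

  with_seed_or_not(seed, {
    freq <- matrix(NA_real_, nrow = n_reps, ncol = generations + 1)
    freq[, 1] <- p0
    p <- rep(p0, n_reps)
    absorbing <- (mu == 0 && delta == 0)
    for (g in seq_len(generations)) {
      active <- if (absorbing) p > 0 & p < 1 else rep(TRUE, n_reps)
      if (any(active)) {
        p[active] <- wf_generation(p[active], ne, s, mu, loss = delta)
      }
      freq[, g + 1] <- p
    }
    tibble(
      rep = rep(seq_len(n_reps), times = generations + 1),
      generation = rep(0:generations, each = n_reps),
      frequency = as.vector(freq)
    ) |>
      arrange(.data$rep, .data$generation)
  })
}

#' Neutral fixation statistics from Wright-Fisher replicates
#'
#' Memory-light companion to [simulate_wright_fisher()] for absorption
#' questions: runs neutral (`s = mu = delta = 0`) replicates until loss or
#' fixation and reports the fixation fraction and the mean time to fixation
#' among the replicates that fixed. Diffusion theory predicts a fixation
#' probability of `p0` and, for a new mutation, a conditional mean fixation
#' time near `4 * ne` generations.
#'
#' @inheritParams simulate_wright_fisher
#' @param max_generations safety cap; replicates not absorbed by then are
#'   dropped with a warning.
#' @return one-row tibble: n_reps, n_fixed, n_lost, fixation_fraction,
#'   mean_fixation_time, mean_loss_time.
#' @export
wf_fixation_summary <- function(ne, p0, n_reps = 10000, seed = NULL,
                                max_generations = 400L * as.integer(ne)) {
  assert_scalar_number(ne, "ne", lower = 1)
  assert_scalar_number(p0, "p0", lower = 0, upper = 1)
  ne <- as.integer(ne); n_reps <- as.integer(n_reps)

  with_seed_or_not(seed, {
    p <- rep(p0, n_reps)
    state <- rep(NA_character_, n_reps)   # "fixed" / "lost"
    t_abs <- rep(NA_integer_, n_reps)
    active <- seq_len(n_reps)
    g <- 0L
    while (length(active) > 0 && g < max_generations) {
      g <- g + 1L
      p[active] <- wf_generation(p[active], ne)
      done_fix <- active[p[active] == 1]
      done_loss <- active[p[active] == 0]
      state[done_fix] <- "fixed"; t_abs[done_fix] <- g
      state[done_loss] <- "lost"; t_abs[done_loss] <- g
      active <- active[p[active] > 0 & p[active] < 1]
    }
    if (length(active) > 0) {
      warn(sprintf("%d replicate(s) not absorbed after %d generations; dropped",
                   length(active), max_generations))
    }
    fixed <- which(state == "fixed"); lost <- which(state == "lost")
    tibble(
      n_reps = n_reps,
      n_fixed = length(fixed),
      n_lost = length(lost),
      fixation_fraction = length(fixed) / n_reps,
      mean_fixation_time = if (length(fixed)) mean(t_abs[fixed]) else NA_real_,
      mean_loss_time = if (length(lost)) mean(t_abs[lost]) else NA_real_
    )
  })
}
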