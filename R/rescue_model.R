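#' Cross progeny counts for the genetic-rescue survival model
#'
#' Observed adult counts from two fly crosses (arms). In each arm the
#' balancer-marked class carries a dominant visible marker and is the
#' viable-nonmutant reference; the experimental class is the rescue
#' genotype in one arm and the unrescued mutant in the other (typically
#' zero adult survivors, since the null is pupal lethal). The theoretical
#' Mendelian class frequencies default to 1:2:1 — one quarter
#' balancer-homozygous (lethal, never observed), one half balancer-marked,
#' one quarter experimental.
#'
#' @param rescue_balancer,rescue_survivors Adult counts in the rescue arm.
#' @param mutant_balancer,mutant_survivors Adult counts in the mutant arm.
#' @param freqs Mendelian class frequencies, named lethal/balancer/
#'   experimental, summing to 1.
#' @return A `cross_counts` object.
#' @export
cross_counts <- function(rescue_balancer, rescue_survivors,
                         mutant_balancer, mutant_survivors,
                         freqs = c(lethal = 0.25, balancer = 0.5,
                                   experimental = 0.25)) {
  cts <- c(rescue_balancer, rescue_survivors, mutant_balancer,
           mutant_survivors)
  if (any(cts < 0) || any(cts != round(cts))) {
    stop("progeny counts must be non-negative integers")
  }
  if (rescue_balancer < 1 || mutant_balancer < 1) {
    stop("each arm needs at least one balancer-marked adult")
  }
  if (length(freqs) != 3 || abs(sum(freqs) - 1) > 1e-8) {
    stop("class frequencies must be three values summing to 1")
  }
  if (is.null(names(freqs))) {
    names(freqs) <- c("lethal", "balancer", "experimental")
  }
  structure(list(rescue = c(balancer = rescue_balancer,
                            survivors = rescue_survivors),
                 mutant = c(balancer = mutant_balancer,
                            survivors = mutant_survivors),
                 freqs = freqs),
            class = "cross_counts")
}

#' @export
print.cross_counts <- function(x, ...) {
  cat("cross_counts: rescue arm", x$rescue[["survivors"]], "survivors /",
      x$rescue[["balancer"]], "balancer adults; mutant arm",
      x$mutant[["survivors"]], "/", x$mutant[["balancer"]], "\n")
  invisible(x)
}

rdirichlet3 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * 3, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

sample_arm_survival <- function(arm, freqs, concentration, draws,
                                s_balancer) {
  f <- rdirichlet3(draws, concentration * freqs)
  p_bal <- f[, 2] * s_balancer
  b <- arm[["balancer"]]
  # total progeny from the balancer count, normal approximation to the
  # binomial: T-hat = B / p, SE = sqrt(B (1 - p)) / p
  total <- stats::rnorm(draws, mean = b / p_bal,
                        sd = sqrt(b * (1 - p_bal)) / p_bal)
  total <- pmax(total, b)
  n_class <- pmax(round(total * f[, 3]), arm[["survivors"]])
  stats::rbeta(draws, arm[["survivors"]] + 0.5,
               n_class - arm[["survivors"]] + 0.5)
}

#' Posterior of the rescue:mutant survival-probability ratio
#'
#' Conjugate Monte Carlo sampler for the ratio of survival probabilities
#' between the rescue and mutant genotype classes. Per draw: Mendelian
#' class frequencies are sampled from a Dirichlet prior concentrated near
#' the theoretical 1:2:1 values (concentration 500 puts the prior sd of the
#' 1/4 class near 2%); the unobserved total progeny of each arm is
#' estimated from its balancer-marked adult count through the normal
#' approximation to the binomial; the implied experimental-class size then
#' feeds a Jeffreys beta-binomial update of that arm's survival
#' probability; and the ratio rho = s_rescue / s_mutant is recorded.
#' The model is conjugate given the totals, so plain Monte Carlo over the
#' conjugate updates replaces general MCMC.
#'
#' @param cross A `cross_counts` object.
#' @param draws Number of posterior draws (>= 10^4; default 10^5).
#' @param concentration Dirichlet concentration on the class frequencies
#'   (default 500).
#' @param level Credible level for the equal-tailed interval (default
#'   0.95).
#' @param s_balancer Survival probability of the balancer-marked reference
#'   class (default 1: fully viable nonmutants).
#' @param seed Optional integer seed for reproducible draws.
#' @return A `rescue_posterior`: list with `draws` (s_rescue, s_mutant,
#'   rho vectors) and `summary` (posterior median of rho, equal-tailed
#'   interval, one-sided lower credible bound, medians of the survival
#'   probabilities).
#' @export
fit_rescue_model <- function(cross, draws = 1e5, concentration = 500,
                             level = 0.95, s_balancer = 1, seed = NULL) {
  stopifnot(inherits(cross, "cross_counts"))
  if (draws < 1e4) stop("draws must be at least 10^4")
  if (concentration <= 0) stop("concentration must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (s_balancer <= 0 || s_balancer > 1) stop("s_balancer must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  draws <- as.integer(draws)
  s_rescue <- sample_arm_survival(cross$rescue, cross$freqs, concentration,
                                  draws, s_balancer)
  s_mutant <- sample_arm_survival(cross$mutant, cross$freqs, concentration,
                                  draws, s_balancer)
  rho <- s_rescue / s_mutant
  qs <- stats::quantile(rho, c((1 - level) / 2, 0.5, 1 - (1 - level) / 2,
                               1 - level), names = FALSE)
  structure(list(
    draws = list(s_rescue = s_rescue, s_mutant = s_mutant, rho = rho),
    summary = list(
      rho_median = qs[2], rho_lower = qs[1], rho_upper = qs[3],
      rho_lower_bound = qs[4], level = level,
      s_rescue_median = stats::median(s_rescue),
      s_mutant_median = stats::median(s_mutant)
    ),
    config = list(draws = draws, concentration = concentration,
                  level = level, s_balancer = s_balancer, seed = seed)
  ), class = "rescue_posterior")
}

#' @export
print.rescue_posterior <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "rescue_posterior: rho median %.2f, %d%% CI [%.2f, %.2f], lower bound %.2f\n",
    s$rho_median, round(100 * s$level), s$rho_lower, s$rho_upper,
    s$rho_lower_bound))
  invisible(x)
}
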