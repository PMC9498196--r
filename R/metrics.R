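# Polarization metrics: extremity ratios, corner-cluster fractions,
# neutrality mass and the new-belief adoption ratio.

.get_concept <- function(pop, concept) {
  switch(concept,
         a1 = pop$a1, a2 = pop$a2, a3 = pop$a3,
         pooled = c(pop$a1, pop$a2),
         stop("`concept` must be one of 'a1', 'a2', 'a3', 'pooled'",
              call. = FALSE))
}

.check_eps <- function(eps) {
  if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) ||
      eps <= 0 || eps >= 1)
    stop("`eps` must be a single number in (0, 1)", call. = FALSE)
}

#' Fraction of extreme attitudes
#'
#' An attitude counts as extreme when it lies within `eps` of either pole,
#' i.e. `|a| >= 1 - eps` (boundary inclusive). With `eps = 0.01`, values in
#' \[0.99, 1\] or \[-1, -0.99\] are extreme.
#'
#' @param pop A [population()].
#' @param eps Extremity threshold in (0, 1).
#' @param concept `"a1"`, `"a2"`, `"a3"`, or `"pooled"` (a1 and a2
#'   together).
#' @return Fraction in \[0, 1\].
#' @export
extremity_ratio <- function(pop, eps, concept = "pooled") {
  stopifnot(inherits(pop, "population"))
  .check_eps(eps)
  a <- .get_concept(pop, concept)
  mean(abs(a) >= 1 - eps)
}

#' Fraction of near-neutral attitudes
#'
#' The share of attitudes with `|a| <= eps`, the mass near indifference.
#'
#' @inheritParams extremity_ratio
#' @return Fraction in \[0, 1\].
#' @export
neutral_fraction <- function(pop, eps, concept = "pooled") {
  stopifnot(inherits(pop, "population"))
  .check_eps(eps)
  a <- .get_concept(pop, concept)
  mean(abs(a) <= eps)
}

#' Corner-cluster fractions in the (a1, a2) plane
#'
#' For each of the four joint extremes (s1, s2) in \{-1, +1\}^2, the
#' fraction of agents with `|a1 - s1| <= eps` and `|a2 - s2| <= eps`. With
#' a contradictory link the dynamics piles agents onto the (+1, -1) and
#' (-1, +1) corners; with a supportive link onto (+1, +1) and (-1, -1).
#'
#' @inheritParams extremity_ratio
#' @return Named numeric vector `c(pp, pm, mp, mm)` where the first letter
#'   is the sign of a1 and the second of a2 (`p` = +1, `m` = -1). The four
#'   boxes are disjoint so the fractions sum to at most 1.
#' @export
corner_fractions <- function(pop, eps) {
  stopifnot(inherits(pop, "population"))
  .check_eps(eps)
  near <- function(a, s) abs(a - s) <= eps
  c(pp = mean(near(pop$a1, 1) & near(pop$a2, 1)),
    pm = mean(near(pop$a1, 1) & near(pop$a2, -1)),
    mp = mean(near(pop$a1, -1) & near(pop$a2, 1)),
    mm = mean(near(pop$a1, -1) & near(pop$a2, -1)))
}

#' Fraction of agents that adopted the new belief
#'
#' @param pop A [population()].
#' @return Fraction in \[0, 1\].
#' @export
adoption_ratio <- function(pop) {
  stopifnot(inherits(pop, "population"))
  mean(pop$adopted)
}

#' Metrics block for one population state
#'
#' Computes all polarization metrics at one instant, one row per epsilon.
#'
#' @param pop A [population()].
#' @param epsilons Numeric vector of thresholds in (0, 1).
#' @return A `data.frame` with columns `t`, `eps`, `extremity_a1`,
#'   `extremity_a2`, `corner_pp`, `corner_pm`, `corner_mp`, `corner_mm`,
#'   `neutral_a1`, `neutral_a2`, `adoption_ratio`.
#' @export
metrics_table <- function(pop, epsilons = c(0.01, 0.05, 0.1)) {
  stopifnot(inherits(pop, "population"))
  rows <- lapply(epsilons, function(eps) {
    cf <- corner_fractions(pop, eps)
    data.frame(t = pop$t, eps = eps,
               extremity_a1 = extremity_ratio(pop, eps, "a1"),
               extremity_a2 = extremity_ratio(pop, eps, "a2"),
               corner_pp = cf[["pp"]], corner_pm = cf[["pm"]],
               corner_mp = cf[["mp"]], corner_mm = cf[["mm"]],
               neutral_a1 = neutral_fraction(pop, eps, "a1"),
               neutral_a2 = neutral_fraction(pop, eps, "a2"),
               adoption_ratio = adoption_ratio(pop))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
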