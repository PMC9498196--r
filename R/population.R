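# Population container and initialization.

#' Construct a population
#'
#' A population is the ordered collection of agent states at one instant:
#' parallel vectors of attitudes towards concept 1 (`a1`), concept 2 (`a2`)
#' and the latent new belief (`a3`), an adoption flag per agent, and the
#' iteration index `t`.
#'
#' @param a1,a2,a3 Numeric vectors of equal length with values in \[-1, 1\].
#' @param adopted Logical vector of the same length.
#' @param t Iteration index (nonnegative integer).
#' @return An object of class `population`.
#' @export
population <- function(a1, a2, a3 = rep(0, length(a1)),
                       adopted = rep(FALSE, length(a1)), t = 0L) {
  n <- length(a1)
  if (length(a2) != n || length(a3) != n || length(adopted) != n)
    stop("`a1`, `a2`, `a3` and `adopted` must have equal length", call. = FALSE)
  .check_attitude(a1, "a1")
  .check_attitude(a2, "a2")
  .check_attitude(a3, "a3")
  if (!is.logical(adopted) || anyNA(adopted))
    stop("`adopted` must be logical without NA", call. = FALSE)
  structure(list(a1 = as.numeric(a1), a2 = as.numeric(a2),
                 a3 = as.numeric(a3), adopted = adopted,
                 t = as.integer(t)),
            class = "population")
}

#' Initialize a population with uniform attitudes
#'
#' All three attitudes of every agent are drawn independently and uniformly
#' from \[-1, 1\] (in the order: all `a1`, then all `a2`, then all `a3`),
#' so the initial population holds every stance from full condemnation to
#' full support with equal probability, averaging zero. `a3` is a latent
#' predisposition towards the not-yet-adopted new belief; it stays frozen
#' until adoption. Draws come from the current R random stream (seed it
#' with [set.seed()], or use [run_simulation()] which seeds from its
#' parameters).
#'
#' @param params A [model_params()] object.
#' @return A `population` of `params$n_agents` agents at `t = 0`.
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "model_params"))
  n <- params$n_agents
  population(a1 = stats::runif(n, -1, 1),
             a2 = stats::runif(n, -1, 1),
             a3 = stats::runif(n, -1, 1),
             adopted = rep(FALSE, n), t = 0L)
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d agents at t = %d (%d adopters)\n",
              length(x$a1), x$t, sum(x$adopted)))
  invisible(x)
}

#' @export
as.data.frame.population <- function(x, ...) {
  data.frame(agent_id = seq_along(x$a1), a1 = x$a1, a2 = x$a2, a3 = x$a3,
             adopted = x$adopted)
}
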