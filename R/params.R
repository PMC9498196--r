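# Run parameters and their validation.

#' Simulation parameters
#'
#' Bundles and validates everything a run needs. Defaults reproduce the
#' headline two-concept experiment: 100 agents exposed 50,000 times to news
#' with a contradictory link, attitude noise 0.01, fixed change scale
#' `rho = 1`.
#'
#' @param n_agents Population size N (positive integer).
#' @param n_steps Number of exposure events T (positive integer); one
#'   uniformly chosen agent is exposed per event.
#' @param k0 Sign of the news link between concepts 1 and 2: `+1` or `-1`.
#' @param k_nb Sign of the link between concept 1 and the new belief
#'   (used only when `new_belief = TRUE`): `+1` or `-1`.
#' @param za Magnitude of the attitude noise Z_A (nonnegative); each update
#'   adds `+za` or `-za` with equal probability.
#' @param rho_mode `"fixed"` uses `rho` for every update; `"uniform"`
#'   redraws rho ~ U(0, 1) independently at every attitude update.
#' @param rho Change scale in \[0, 1\] when `rho_mode = "fixed"`.
#' @param new_belief Enable the three-node mechanism: agents under
#'   dissonance may adopt a new belief linked to concept 1 by `k_nb`.
#' @param seed Nonnegative integer seed; together with the parameters it
#'   determines the run bit-exactly.
#' @param snapshot_every Record cadence in events; snapshots are always
#'   also taken at t = 0 and t = `n_steps`. Default: `n_steps %/% 100`
#'   (at least 1).
#' @param epsilons Extremity thresholds, each in (0, 1), used by the
#'   polarization metrics.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(n_agents = 50, n_steps = 1000, seed = 1)
#' @export
model_params <- function(n_agents = 100L,
                         n_steps = 50000L,
                         k0 = -1L,
                         k_nb = -1L,
                         za = 0.01,
                         rho_mode = c("fixed", "uniform"),
                         rho = 1.0,
                         new_belief = FALSE,
                         seed = 1L,
                         snapshot_every = NULL,
                         epsilons = c(0.01, 0.05, 0.1)) {
  rho_mode <- match.arg(rho_mode)
  .check_count(n_agents, "n_agents")
  .check_count(n_steps, "n_steps")
  .check_link(k0, "k0")
  .check_link(k_nb, "k_nb")
  if (!is.numeric(za) || length(za) != 1L || is.na(za) || za < 0)
    stop("`za` must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    stop("`rho` must be a single number in [0, 1]", call. = FALSE)
  if (!is.logical(new_belief) || length(new_belief) != 1L || is.na(new_belief))
    stop("`new_belief` must be TRUE or FALSE", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0 ||
      seed != trunc(seed))
    stop("`seed` must be a single nonnegative integer", call. = FALSE)
  if (is.null(snapshot_every))
    snapshot_every <- max(1L, as.integer(n_steps) %/% 100L)
  .check_count(snapshot_every, "snapshot_every")
  if (!is.numeric(epsilons) || length(epsilons) < 1L || anyNA(epsilons) ||
      any(epsilons <= 0 | epsilons >= 1))
    stop("`epsilons` must be a nonempty numeric vector with values in (0, 1)",
         call. = FALSE)
  structure(
    list(n_agents = as.integer(n_agents),
         n_steps = as.integer(n_steps),
         k0 = as.integer(k0),
         k_nb = as.integer(k_nb),
         za = as.numeric(za),
         rho_mode = rho_mode,
         rho = as.numeric(rho),
         new_belief = new_belief,
         seed = as.numeric(seed),
         snapshot_every = as.integer(snapshot_every),
         epsilons = as.numeric(epsilons)),
    class = "model_params")
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != trunc(x))
    stop("`", name, "` must be a single positive integer", call. = FALSE)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  N = %d agents, T = %d exposure events, seed = %s\n",
              x$n_agents, x$n_steps, format(x$seed)))
  cat(sprintf("  K0 = %+d%s, Z_A = %g, rho = %s\n",
              x$k0,
              if (x$new_belief) sprintf(", K_NB = %+d (new belief on)", x$k_nb)
              else "",
              x$za,
              if (x$rho_mode == "fixed") format(x$rho) else "U(0,1) per update"))
  cat(sprintf("  snapshots every %d events; epsilons = {%s}\n",
              x$snapshot_every, paste(x$epsilons, collapse = ", ")))
  invisible(x)
}
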