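# Reproducible stochastic event loop.
#
# Random draw order (one fixed stream, seeded once per run):
#   initialization: runif(n) for a1, runif(n) for a2, runif(n) for a3
#   per exposure event:
#     1. agent index            sample.int(n_agents, 1)
#     2. one uniform block      runif(m):
#          gate(a1), [rho(a1)], sign(a1), gate(a2), [rho(a2)], sign(a2),
#          [adoption coin]
#        rho uniforms only in rho_mode = "uniform"; the adoption coin only
#        with new_belief = TRUE (drawn every event to keep streams aligned).
#     3. adopters only          runif(4 or 6) for the new-belief edge:
#          gate(a1), [rho], sign(a1), gate(a3), [rho], sign(a3)
# A noise-sign uniform u maps to +Z_A when u < 0.5, else -Z_A. A gate
# uniform u opens its attitude when u < 1 - |a|.
#
# run_simulation() and repeated exposure_step() calls consume the stream
# identically, so the two are bit-equal given the same seed and start.

# gated update of the two endpoint attitudes of one edge; x, y scalars,
# u the uniform block (length 4, or 6 with per-update rho draws)
.edge_update <- function(x, y, k, rho, rho_unif, za, u) {
  cc <- x * y * k
  if (rho_unif) {
    gx <- u[1L]; rx <- u[2L]; sx <- u[3L]
    gy <- u[4L]; ry <- u[5L]; sy <- u[6L]
  } else {
    gx <- u[1L]; sx <- u[2L]; gy <- u[3L]; sy <- u[4L]
    rx <- rho; ry <- rho
  }
  nx <- if (gx < 1 - abs(x)) .upd(x, cc, rx, if (sx < 0.5) za else -za) else x
  ny <- if (gy < 1 - abs(y)) .upd(y, cc, ry, if (sy < 0.5) za else -za) else y
  c(nx, ny, cc)
}

# adoption decision plus gated update along the new-belief edge (scalars);
# returns c(a1, a3, adopted). u_nb may be NULL (drawn lazily, adopters only).
.nb_substep <- function(a1, a3, adopted, c_event, k_nb, rho, rho_unif, za,
                        u_adopt, u_nb) {
  if (!adopted && c_event < 0) {
    p <- a1 * a3 * k_nb
    if (p > 0 && u_adopt < p) adopted <- TRUE
  }
  if (adopted) {
    if (is.null(u_nb)) u_nb <- stats::runif(if (rho_unif) 6L else 4L)
    r <- .edge_update(a1, a3, k_nb, rho, rho_unif, za, u_nb)
    a1 <- r[1L]; a3 <- r[2L]
  }
  c(a1, a3, adopted)
}

# one full exposure event for one agent (scalars); returns
# c(a1, a2, a3, adopted). u/u_nb NULL -> drawn from the stream.
.apply_event <- function(a1, a2, a3, adopted, k0, k_nb, nb, rho, rho_unif, za,
                         u = NULL, u_nb = NULL) {
  m <- (if (rho_unif) 6L else 4L) + (if (nb) 1L else 0L)
  if (is.null(u)) u <- stats::runif(m)
  r <- .edge_update(a1, a2, k0, rho, rho_unif, za, u)
  if (nb) {
    s <- .nb_substep(r[1L], a3, adopted, r[3L], k_nb, rho, rho_unif, za,
                     u[m], u_nb)
    c(s[1L], r[2L], s[2L], s[3L])
  } else {
    c(r[1L], r[2L], a3, as.numeric(adopted))
  }
}

#' Expose one randomly chosen agent to the news
#'
#' Advances the population by one exposure event: an agent index is drawn
#' uniformly, the event coherence `c = a1 * a2 * k0` is computed from the
#' agent's pre-update attitudes, and each of the two attitudes is then,
#' independently and with probability `1 - |a|`, replaced by the clamped
#' update (both using the same pre-update `c`). With `new_belief = TRUE`
#' the new-belief sub-step then runs for the same agent: a non-adopter
#' under dissonance (`c < 0`) adopts with probability
#' `max(0, a1 * a3 * k_nb)`, and an adopter (including one who just
#' adopted) applies the same gated update along the new-belief edge to
#' `a1` and `a3`.
#'
#' @param pop A [population()].
#' @param params A [model_params()].
#' @param draws Optional injected randomness for testing symmetry and
#'   exact one-step distributions: a list with elements `idx` (agent
#'   index), `u` (the event's uniform block, see the draw-order comment in
#'   the source) and optionally `u_nb` (the new-belief edge block). When
#'   `NULL` all draws come from the current R random stream.
#' @return The updated `population`, with `t` incremented by 1.
#' @export
exposure_step <- function(pop, params, draws = NULL) {
  stopifnot(inherits(pop, "population"), inherits(params, "model_params"))
  n <- length(pop$a1)
  if (is.null(draws)) {
    i <- sample.int(n, 1L)
    u <- NULL; u_nb <- NULL
  } else {
    i <- draws$idx; u <- draws$u; u_nb <- draws$u_nb
  }
  st <- .apply_event(pop$a1[i], pop$a2[i], pop$a3[i], pop$adopted[i],
                     params$k0, params$k_nb, params$new_belief,
                     params$rho, params$rho_mode == "uniform", params$za,
                     u = u, u_nb = u_nb)
  pop$a1[i] <- st[1L]
  pop$a2[i] <- st[2L]
  pop$a3[i] <- st[3L]
  pop$adopted[i] <- st[4L] > 0
  pop$t <- pop$t + 1L
  pop
}

#' New-belief adoption and update sub-step for a single agent
#'
#' Applies the dissonance-relief mechanism to one agent state, given the
#' coherence `c_event` the triggering news produced: a non-adopter adopts
#' only under dissonance (`c_event < 0`), with probability
#' `max(0, a1 * a3 * k_nb)`; an adopter then re-evaluates `a1` and `a3`
#' along the new-belief edge with the usual gates and clamped updates.
#'
#' @param agent A list with elements `a1`, `a3`, `adopted` (scalars).
#' @param c_event Coherence of the triggering event, in \[-1, 1\].
#' @param params A [model_params()] with `new_belief = TRUE`.
#' @param draws Optional list with `u_adopt` (uniform for the adoption
#'   coin) and `u_nb` (edge uniform block); `NULL` draws from the stream.
#' @return The updated agent list.
#' @export
new_belief_substep <- function(agent, c_event, params, draws = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (!params$new_belief)
    stop("`params$new_belief` must be TRUE for the new-belief sub-step",
         call. = FALSE)
  u_adopt <- if (is.null(draws)) stats::runif(1) else draws$u_adopt
  u_nb <- if (is.null(draws)) NULL else draws$u_nb
  s <- .nb_substep(agent$a1, agent$a3, isTRUE(agent$adopted), c_event,
                   params$k_nb, params$rho, params$rho_mode == "uniform",
                   params$za, u_adopt, u_nb)
  agent$a1 <- s[1L]
  agent$a3 <- s[2L]
  agent$adopted <- s[3L] > 0
  agent
}

#' Run a full simulation
#'
#' Seeds the random stream from `params$seed`, draws the initial uniform
#' population and applies `params$n_steps` exposure events, recording a
#' full attitude snapshot and a polarization metrics block at t = 0, every
#' `params$snapshot_every` events, and at the final event. Identical
#' parameters and seed give a bit-identical result. The previous state of
#' R's random stream is restored on exit.
#'
#' @param params A [model_params()].
#' @return An object of class `trajectory`: a list with
#'   \describe{
#'     \item{times}{iteration indices of the snapshots (0 ... n_steps);}
#'     \item{snapshots}{one attitude `data.frame` per snapshot time
#'       (`agent_id`, `a1`, `a2`, `a3`, `adopted`);}
#'     \item{metrics}{long `data.frame` of metric rows, one per snapshot
#'       time and epsilon (see [metrics_table()]);}
#'     \item{final}{the final `population`;}
#'     \item{max_abs_attitude}{running maximum of |a| over every attitude
#'       of every agent after every update (clamping keeps it at most 1);}
#'     \item{exposure_counts}{how often each agent was selected;}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' p <- model_params(n_agents = 20, n_steps = 500, seed = 42)
#' tr <- run_simulation(p)
#' tr$metrics[tr$metrics$t == 500, ]
#' @export
run_simulation <- function(params) {
  stopifnot(inherits(params, "model_params"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  n <- params$n_agents
  T_ <- params$n_steps
  k0 <- params$k0; k_nb <- params$k_nb; nb <- params$new_belief
  rho <- params$rho; rho_unif <- params$rho_mode == "uniform"
  za <- params$za

  a1 <- stats::runif(n, -1, 1)
  a2 <- stats::runif(n, -1, 1)
  a3 <- stats::runif(n, -1, 1)
  adopted <- rep(FALSE, n)
  counts <- integer(n)
  max_abs <- max(abs(a1), abs(a2), abs(a3))

  record_at <- logical(T_)
  record_at[seq(params$snapshot_every, T_, by = params$snapshot_every)] <- TRUE
  record_at[T_] <- TRUE
  n_rec <- sum(record_at) + 1L

  times <- integer(n_rec)
  snapshots <- vector("list", n_rec)
  metric_blocks <- vector("list", n_rec)
  take <- function(slot, t_now) {
    pop <- structure(list(a1 = a1, a2 = a2, a3 = a3, adopted = adopted,
                          t = t_now), class = "population")
    times[slot] <<- t_now
    snapshots[[slot]] <<- as.data.frame(pop)
    metric_blocks[[slot]] <<- metrics_table(pop, params$epsilons)
  }
  take(1L, 0L)
  slot <- 1L

  for (t in seq_len(T_)) {
    i <- sample.int(n, 1L)
    counts[i] <- counts[i] + 1L
    st <- .apply_event(a1[i], a2[i], a3[i], adopted[i],
                       k0, k_nb, nb, rho, rho_unif, za)
    a1[i] <- st[1L]; a2[i] <- st[2L]; a3[i] <- st[3L]
    adopted[i] <- st[4L] > 0
    m <- max(abs(st[1L]), abs(st[2L]), abs(st[3L]))
    if (m > max_abs) max_abs <- m
    if (record_at[t]) {
      slot <- slot + 1L
      take(slot, t)
    }
  }

  structure(
    list(times = times,
         snapshots = snapshots,
         metrics = do.call(rbind, metric_blocks),
         final = structure(list(a1 = a1, a2 = a2, a3 = a3, adopted = adopted,
                                t = T_), class = "population"),
         max_abs_attitude = max_abs,
         exposure_counts = counts,
         params = params),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  p <- x$params
  cat(sprintf("<trajectory> N = %d, T = %d, K0 = %+d, seed = %s\n",
              p$n_agents, p$n_steps, p$k0, format(p$seed)))
  cat(sprintf("  %d snapshots (t = %d ... %d), max |a| observed = %g\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$max_abs_attitude))
  fin <- x$metrics[x$metrics$t == p$n_steps, ]
  cat("  final extremity ratios:",
      paste(sprintf("eps=%g: %.3f", fin$eps,
                    (fin$extremity_a1 + fin$extremity_a2) / 2),
            collapse = ", "), "\n")
  if (p$new_belief)
    cat(sprintf("  adoption ratio: %.3f\n", fin$adoption_ratio[1]))
  invisible(x)
}

#' Run replicate simulations
#'
#' Runs `n_replicates` independent simulations that differ only in seed;
#' replicate i uses `base seed + i - 1`, so the first replicate reproduces
#' a plain [run_simulation()] with the same parameters.
#'
#' @param params A [model_params()]; its `seed` is the base seed.
#' @param n_replicates Number of replicates (positive integer).
#' @return A list of `trajectory` objects.
#' @export
run_replicates <- function(params, n_replicates) {
  stopifnot(inherits(params, "model_params"))
  .check_count(n_replicates, "n_replicates")
  lapply(seq_len(n_replicates), function(i) {
    p <- params
    p$seed <- params$seed + i - 1
    run_simulation(p)
  })
}
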