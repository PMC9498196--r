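# Elementary update mathematics: signed coherence on a news-created edge,
# the hierarchical change-probability gate, the clamped attitude update and
# the new-belief adoption probability. All functions are pure and vectorised
# (arguments recycle as usual).

.sign0 <- function(a) ifelse(a < 0, -1, 1)

.clamp1 <- function(x) pmin(1, pmax(-1, x))

.check_attitude <- function(a, name) {
  if (!is.numeric(a) || anyNA(a) || any(abs(a) > 1))
    stop("`", name, "` must be numeric in [-1, 1]", call. = FALSE)
}

.check_link <- function(k, name = "k") {
  if (!is.numeric(k) || anyNA(k) || any(k != 1 & k != -1))
    stop("`", name, "` must be +1 or -1", call. = FALSE)
}

#' Coherence of two attitudes across a signed link
#'
#' The coherence an agent experiences when a piece of news connects two
#' concepts is the product of the two attitude values and the sign of the
#' connection, `a_first * a_second * k`. Positive values are reassurance
#' (the news fits the belief system), negative values are cognitive
#' dissonance. The product of values in \[-1, 1\] with a sign is itself
#' always in \[-1, 1\].
#'
#' @param a_first,a_second Attitude values in \[-1, 1\].
#' @param k Connection type, `+1` (supportive) or `-1` (contradictory).
#' @return Coherence value(s) in \[-1, 1\].
#' @examples
#' coherence(1, 1, -1)     # maximal dissonance
#' coherence(-0.5, 0.4, -1)
#' @export
coherence <- function(a_first, a_second, k) {
  .check_attitude(a_first, "a_first")
  .check_attitude(a_second, "a_second")
  .check_link(k)
  a_first * a_second * k
}

#' Probability that an attitude is open to change
#'
#' More extreme attitudes are harder to change (the hierarchical property of
#' belief systems): the probability that an attitude is re-evaluated on
#' exposure is `1 - |a|`. Fully extreme attitudes (|a| = 1) never change
#' through this gate; neutral attitudes always may.
#'
#' @param a Attitude value(s) in \[-1, 1\].
#' @return Probability value(s) in \[0, 1\].
#' @export
change_probability <- function(a) {
  .check_attitude(a, "a")
  1 - abs(a)
}

#' Re-evaluate an attitude under coherence pressure
#'
#' Applies the attitude update
#' `sign(a) * (|a| + rho * c) + za_draw`, clamped to \[-1, 1\]: reassurance
#' (`c > 0`) pushes the attitude further from zero, dissonance (`c < 0`)
#' pulls it towards zero (and, if the dissonance exceeds the current
#' commitment `|a|`, past it — the formula is applied literally, with no
#' floor at zero). `sign(0)` is taken as `+1` so the update is deterministic
#' everywhere. Values leaving \[-1, 1\] are set to the nearest endpoint.
#'
#' @param a Attitude value(s) in \[-1, 1\].
#' @param c Coherence value(s) in \[-1, 1\], from [coherence()].
#' @param rho Scale of the change, in \[0, 1\].
#' @param za_draw Realised signed noise (e.g. `+0.01` or `-0.01`).
#' @return Updated attitude value(s), clamped to \[-1, 1\].
#' @export
update_attitude <- function(a, c, rho, za_draw) {
  .check_attitude(a, "a")
  .check_attitude(c, "c")
  if (!is.numeric(rho) || anyNA(rho) || any(rho < 0 | rho > 1))
    stop("`rho` must be numeric in [0, 1]", call. = FALSE)
  if (!is.numeric(za_draw) || anyNA(za_draw))
    stop("`za_draw` must be numeric", call. = FALSE)
  .clamp1(.sign0(a) * (abs(a) + rho * c) + za_draw)
}

#' Probability of adopting a dissonance-relieving new belief
#'
#' An agent under cognitive dissonance may adopt a new belief connected to
#' concept 1 by a link of sign `k_nb`. Adoption happens with probability
#' proportional to the relief it provides: `max(0, a1 * a3 * k_nb)`. When
#' the new belief would itself create dissonance the probability is zero.
#'
#' @param a1 Attitude(s) towards concept 1, in \[-1, 1\].
#' @param a3 Attitude(s) towards the new belief, in \[-1, 1\].
#' @param k_nb Connection type of the new-belief link, `+1` or `-1`.
#' @return Adoption probability value(s) in \[0, 1\].
#' @export
adoption_probability <- function(a1, a3, k_nb) {
  .check_attitude(a1, "a1")
  .check_attitude(a3, "a3")
  .check_link(k_nb, "k_nb")
  pmax(0, a1 * a3 * k_nb)
}

# scalar fast path used by the event loop (inputs already validated by the
# parameter constructor; no recycling, no checks)
.upd <- function(a, cc, r, z) {
  v <- (if (a < 0) -1 else 1) * (abs(a) + r * cc) + z
  if (v > 1) 1 else if (v < -1) -1 else v
}
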