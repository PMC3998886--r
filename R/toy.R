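#' Hand-solvable toy systems with closed-form expectations
#'
#' Generates tiny models whose behaviour is known in closed form, for use
#' as independent oracles in tests.
#'
#' Families:
#' * `"one_compartment"` -- a single self-renewing pool; its positive
#'   steady state is `(2 a_max - 1) / k_a` with niche signal
#'   `1 / (2 a_max)`.
#' * `"zero_state"` -- the empty state of the one-compartment system: both
#'   signals equal 1 and all derivatives vanish.
#' * `"two_compartment_chain"` -- a stem pool feeding a dividing downstream
#'   pool with feedback gains so small the signals stay at 1 over the given
#'   counts, making the system linear; the expected trajectory is the
#'   explicit solution of the triangular 2x2 linear ODE.
#'
#' @param family One of the families above.
#' @param a_max,p_max Stem-compartment maximal rates.
#' @param k_a Self-renewal gain (one-compartment family).
#' @return A list with `params`, `state` (initial state vector), and
#'   `expected` -- a family-specific list of closed-form values/functions.
#' @export
#' @examples
#' fx <- make_toy_fixture("one_compartment")
#' fx$expected$steady_count
make_toy_fixture <- function(family = c("one_compartment", "zero_state",
                                        "two_compartment_chain"),
                             a_max = 0.7, p_max = 0.1, k_a = 1e-6) {
  family <- match.arg(family)
  if (family %in% c("one_compartment", "zero_state")) {
    lin <- lineage_params("normal", compartment_params(
      "stem", a_max = a_max, p_max = p_max, in_niche = TRUE))
    params <- model_params(list(lin),
                           feedback_params(k_p = 1e-6, k_a = k_a,
                                           niche_depth = 1L))
    if (family == "one_compartment") {
      return(list(
        params = params,
        state = system_state(params, (2 * a_max - 1) / k_a),
        expected = list(steady_count = (2 * a_max - 1) / k_a,
                        s_a_star = 1 / (2 * a_max))
      ))
    }
    return(list(params = params, state = system_state(params, 0),
                expected = list(signals = c(s_p = 1, s_a = 1),
                                dcdt = 0)))
  }

  # two_compartment_chain: gains ~0 so s_p = s_a = 1 (linear regime)
  a1 <- a_max; p1 <- p_max; a2 <- 0.4; p2 <- 0.3
  lin <- lineage_params("normal", dplyr::bind_rows(
    compartment_params("stem", a_max = a1, p_max = p1, in_niche = TRUE),
    compartment_params("progenitor", a_max = a2, p_max = p2)
  ))
  params <- model_params(list(lin),
                         feedback_params(k_p = 1e-300, k_a = 1e-300,
                                         niche_depth = 1L))
  l1 <- (2 * a1 - 1) * p1
  l2 <- (2 * a2 - 1) * p2
  b <- 2 * (1 - a1) * p1
  solution <- function(t, c0 = c(1, 0)) {
    c1 <- c0[1] * exp(l1 * t)
    c2 <- c0[2] * exp(l2 * t) +
      b * c0[1] * (exp(l1 * t) - exp(l2 * t)) / (l1 - l2)
    cbind(stem = c1, progenitor = c2)
  }
  list(params = params, state = system_state(params, c(1, 0)),
       expected = list(eigenvalues = c(l1, l2), coupling = b,
                       solution = solution))
}
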