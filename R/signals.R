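#' Evaluate the two feedback signals at a system state
#'
#' The proliferation signal responds to mature peripheral-blood cells,
#' `s_p = 1 / (1 + k_p * M)`; the self-renewal signal to primitive-cell
#' occupancy of the bone-marrow niche across both lineages,
#' `s_a = 1 / (1 + k_a * W)`. Both lie in `(0, 1]` and equal 1 exactly when
#' their driving pool is empty.
#'
#' @param state A state vector (see [system_state()]) or one-row data frame.
#' @param params An `mdsim_model`.
#' @return A one-row tibble with columns `s_p`, `s_a`.
#' @export
#' @examples
#' m <- get_preset("healthy_default")
#' compute_signals(system_state(m, 0), m)   # empty pools: both signals 1
compute_signals <- function(state, params) {
  y <- as_state_vector(state, params)
  lay <- state_layout(params)
  fb <- params$feedback
  M <- sum(y[lay$in_pb])
  W <- sum(y[lay$in_niche])
  tibble::tibble(s_p = 1 / (1 + fb$k_p * M), s_a = 1 / (1 + fb$k_a * W))
}

#' Realised per-compartment self-renewal and proliferation rates
#'
#' Scales every dividing compartment's maximal rates by the current signals:
#' `a_i = a_max_i * s_a`, `p_i = p_max_i * s_p`. Terminal compartments
#' report zero for both.
#'
#' @inheritParams compute_signals
#' @return [state_layout()] plus columns `a`, `p` (and `s_p`, `s_a`).
#' @export
effective_rates <- function(state, params) {
  y <- as_state_vector(state, params)
  sig <- compute_signals(y, params)
  state_layout(params) |>
    dplyr::mutate(
      s_p = sig$s_p, s_a = sig$s_a,
      a = ifelse(.data$divides, .data$a_max * sig$s_a, 0),
      p = ifelse(.data$divides, .data$p_max * sig$s_p, 0)
    )
}

# Compiled representation used by the ODE right-hand side: plain vectors,
# no tibble work inside the integrator loop.
compile_model <- function(params) {
  lay <- state_layout(params)
  fb <- params$feedback
  n <- nrow(lay)
  upstream <- rep(NA_integer_, n)          # index feeding compartment i
  for (lab in unique(lay$lineage)) {
    idx <- which(lay$lineage == lab)
    upstream[idx[-1]] <- idx[-length(idx)]
  }
  list(
    n = n, names = lay$state,
    a_max = lay$a_max, p_max = lay$p_max, d = lay$d,
    divides = lay$divides, in_niche = lay$in_niche, in_pb = lay$in_pb,
    upstream = upstream, k_p = fb$k_p, k_a = fb$k_a
  )
}

# Derivative on the compiled model; y may carry tiny negative solver noise,
# clamped to 0 for rate evaluation so signals stay in (0, 1].
rhs_compiled <- function(y, cm) {
  yc <- pmax(y, 0)
  s_p <- 1 / (1 + cm$k_p * sum(yc[cm$in_pb]))
  s_a <- 1 / (1 + cm$k_a * sum(yc[cm$in_niche]))
  a <- cm$a_max * s_a
  p <- cm$p_max * s_p
  self_flux <- ifelse(cm$divides, (2 * a - 1) * p * yc, 0)
  out_flux <- ifelse(cm$divides, 2 * (1 - a) * p * yc, 0)
  influx <- numeric(cm$n)
  has_up <- !is.na(cm$upstream)
  influx[has_up] <- out_flux[cm$upstream[has_up]]
  self_flux + influx - cm$d * yc
}

#' Right-hand side of the compartment ODE system
#'
#' Flux balance per compartment: the first dividing compartment of a lineage
#' obeys `dc/dt = (2a - 1) p c`; downstream dividing compartments add the
#' differentiation influx `2 (1 - a_up) p_up c_up` from their upstream
#' neighbour; terminal pools receive that influx and decay at their death
#' rate `d`. Death applies only where `d > 0` (mature cells and dysplastic
#' precursors in the shipped presets).
#'
#' @inheritParams compute_signals
#' @return A tibble: [state_layout()] plus column `dcdt` (cells/day).
#' @export
rhs <- function(state, params) {
  y <- as_state_vector(state, params)
  dplyr::mutate(state_layout(params),
                count = unname(y),
                dcdt = unname(rhs_compiled(y, compile_model(params))))
}
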