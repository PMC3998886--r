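#' Analytic steady state of healthy hematopoiesis
#'
#' Computes the positive equilibrium of the normal lineage with the MDS
#' clone absent. At the fixed point the stem compartment's realised
#' self-renewal is exactly 1/2 (each division replaces the dividing cell on
#' average), which pins the niche signal at `s_a* = 1 / (2 a_max_1)` and the
#' niche occupancy at `W* = (2 a_max_1 - 1) / k_a`. Downstream dividing
#' compartments follow from recursive flux balance (the proliferation signal
#' cancels between dividing stages), and the mature pool from the scalar
#' balance `d_m c_m = 2 (1 - a_last) p_max_last s_p(c_m) c_last`, solved by
#' root finding.
#'
#' @param params An `mdsim_model` containing a `normal` lineage.
#' @return A named state vector (MDS compartments at zero) with attributes
#'   `s_a_star`, `s_p_star`, `W_star` and `residual` (max `|dc/dt| / c`).
#' @export
#' @examples
#' ss <- healthy_steady_state(get_preset("healthy_default"))
#' effective_rates(ss, get_preset("healthy_default"))$a[1]  # 0.5
healthy_steady_state <- function(params) {
  validate_model(params)
  lin <- params$lineages[["normal"]]
  if (is.null(lin)) stop("model has no 'normal' lineage")
  cp <- lin$compartments
  fb <- params$feedback
  a1 <- cp$a_max[1]
  if (a1 <= 0.5)
    stop("no positive steady state: stem-cell a_max = ", a1, " must exceed 0.5")
  s_a <- 1 / (2 * a1)
  a_eff <- cp$a_max * s_a
  ndiv <- sum(cp$divides)
  if (ndiv >= 2 && any(a_eff[2:ndiv] >= 0.5))
    stop("no positive steady state: a downstream compartment's effective ",
         "self-renewal reaches 1/2 at the stem-cell fixed point")

  # ratios c_i / c_{i-1} between dividing compartments (s_p cancels)
  ratio <- rep(1, ndiv)
  for (i in seq_len(ndiv)[-1]) {
    ratio[i] <- 2 * (1 - a_eff[i - 1]) * cp$p_max[i - 1] /
      ((1 - 2 * a_eff[i]) * cp$p_max[i])
  }
  rel <- cumprod(ratio)                       # c_i / c_1
  W_star <- (2 * a1 - 1) / fb$k_a
  c1 <- W_star / sum(rel[seq_len(fb$niche_depth)])
  counts_div <- c1 * rel

  counts <- counts_div
  s_p <- 1
  if (nrow(cp) > ndiv) {                      # terminal mature pool
    term <- ndiv + 1L
    if (cp$d[term] <= 0)
      stop("terminal compartment needs d > 0 for a finite steady state")
    influx_max <- 2 * (1 - a_eff[ndiv]) * cp$p_max[ndiv] * counts_div[ndiv]
    k_p <- if (cp$in_pb[term]) fb$k_p else 0
    bal <- function(cm) cp$d[term] * cm * (1 + k_p * cm) - influx_max
    hi <- influx_max / cp$d[term]
    sol <- stats::uniroot(bal, c(0, hi), tol = 1e-12 * max(hi, 1))
    counts <- c(counts_div, sol$root)
    s_p <- 1 / (1 + k_p * sol$root)
  }

  state <- system_state(params)
  state[paste(lin$label, cp$name, sep = ".")] <- counts
  resid <- rhs_compiled(state, compile_model(params))
  structure(state,
            s_a_star = s_a, s_p_star = s_p, W_star = W_star,
            residual = max(abs(resid[state > 0]) / state[state > 0]))
}

#' Can the MDS clone take over? (analytic criterion)
#'
#' At the healthy fixed point the niche signal is `s_a* = 1 / (2 a_max_N)`,
#' so a seeded MDS stem cell grows at rate `(2 a_max_MDS s_a* - 1) p_MDS`,
#' which is positive if and only if `a_max_MDS > a_max_N` -- independent of
#' proliferation rates. Higher self-renewal of the disease-initiating cells,
#' not higher proliferation, decides takeover.
#'
#' @param params A two-lineage `mdsim_model`.
#' @return `TRUE` if the MDS stem compartment's maximal self-renewal strictly
#'   exceeds the normal one's.
#' @export
takeover_predicate <- function(params) {
  validate_model(params)
  if (length(params$lineages) < 2L || is.null(params$lineages[["mds"]]) ||
      is.null(params$lineages[["normal"]]))
    stop("takeover_predicate needs both a 'normal' and an 'mds' lineage")
  a_n <- params$lineages[["normal"]]$compartments$a_max[1]
  a_m <- params$lineages[["mds"]]$compartments$a_max[1]
  a_m > a_n
}
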