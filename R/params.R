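#' Define one maturation compartment
#'
#' A compartment is a pool of cells at one maturation stage of a lineage.
#' Dividing compartments self-renew (a fraction `a_max * s_a` of daughter
#' cells stays in the compartment) and differentiate into the next stage;
#' terminal compartments neither divide nor differentiate and can only die.
#'
#' @param name Compartment label, e.g. `"LT-HSC"` or `"dysplastic"`.
#' @param a_max Maximal self-renewal fraction in `[0, 1]` (dimensionless).
#'   Realised self-renewal is `a_max * s_a` where `s_a` is the niche signal.
#' @param p_max Maximal proliferation rate (divisions per cell per day).
#'   Realised rate is `p_max * s_p` where `s_p` is the proliferation signal.
#' @param d Death rate (1/day). Zero for dividing compartments in the
#'   baseline model; positive for the terminal pools.
#' @param divides Logical; `FALSE` for terminal pools (mature cells,
#'   dysplastic precursors), whose `a_max`/`p_max` are ignored.
#' @param in_niche Logical; does this pool occupy the bone-marrow niche and
#'   hence feed the self-renewal signal?
#' @param in_pb Logical; is this a mature peripheral-blood pool feeding the
#'   proliferation signal?
#'
#' @return A one-row tibble.
#' @export
#' @examples
#' compartment_params("LT-HSC", a_max = 0.7, p_max = 1 / 50, in_niche = TRUE)
compartment_params <- function(name, a_max = 0, p_max = 0, d = 0,
                               divides = TRUE, in_niche = FALSE,
                               in_pb = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  tibble::tibble(
    name = name, a_max = as.numeric(a_max), p_max = as.numeric(p_max),
    d = as.numeric(d), divides = isTRUE(divides),
    in_niche = isTRUE(in_niche), in_pb = isTRUE(in_pb)
  )
}

#' Define a cell lineage as an ordered chain of compartments
#'
#' @param label Either `"normal"` or `"mds"`.
#' @param compartments A tibble of compartments (rows ordered most primitive
#'   first), typically built by binding [compartment_params()] rows.
#'
#' @return A list of class `mdsim_lineage`.
#' @export
lineage_params <- function(label, compartments) {
  label <- match.arg(label, c("normal", "mds"))
  stopifnot(is.data.frame(compartments), nrow(compartments) >= 1L)
  structure(list(label = label, compartments = tibble::as_tibble(compartments)),
            class = "mdsim_lineage")
}

#' Feedback-signal parameters
#'
#' Both signals have the reciprocal-saturation form `s = 1 / (1 + k * x)`:
#' the proliferation signal `s_p` is down-regulated by the total mature
#' peripheral-blood cell count, the self-renewal signal `s_a` by the total
#' occupancy of the bone-marrow niche (the `niche_depth` most primitive
#' compartments of every lineage, malignant cells included).
#'
#' @param k_p Gain of the proliferation signal (1/cells).
#' @param k_a Gain of the self-renewal signal (1/cells).
#' @param niche_depth Number of most-primitive compartments per lineage that
#'   occupy the niche (default 3: LT-HSCs, ST-HSCs and MPPs).
#' @param apoptosis_visibility Duration (days) a dying cell remains countable
#'   as apoptotic; default 1 day (apoptosis takes about 24 h).
#'
#' @return A list of class `mdsim_feedback`.
#' @export
feedback_params <- function(k_p, k_a, niche_depth = 3L,
                            apoptosis_visibility = 1) {
  stopifnot(k_p > 0, k_a > 0, niche_depth >= 1L, apoptosis_visibility > 0)
  structure(list(k_p = as.numeric(k_p), k_a = as.numeric(k_a),
                 niche_depth = as.integer(niche_depth),
                 apoptosis_visibility = as.numeric(apoptosis_visibility)),
            class = "mdsim_feedback")
}

#' Assemble a full two-signal compartment model
#'
#' @param lineages List of one or two [lineage_params()] objects (a normal
#'   lineage, optionally plus an MDS lineage).
#' @param feedback A [feedback_params()] object.
#' @param variant `"baseline"` (dysplastic precursors are the terminal MDS
#'   pool) or `"mds_full_maturation"` (the MDS lineage matures fully into a
#'   short-lived mature pool).
#'
#' @return An object of class `mdsim_model`.
#' @export
model_params <- function(lineages, feedback,
                         variant = c("baseline", "mds_full_maturation")) {
  variant <- match.arg(variant)
  if (inherits(lineages, "mdsim_lineage")) lineages <- list(lineages)
  labels <- vapply(lineages, function(l) l$label, character(1))
  names(lineages) <- labels
  m <- structure(list(lineages = lineages, feedback = feedback,
                      variant = variant),
                 class = "mdsim_model")
  validate_model(m)
  m
}

#' Validate a model's parameter invariants
#'
#' Checks self-renewal fractions in `[0, 1]`, nonnegative rates, terminal
#' compartments last, positive feedback gains, and that the niche depth does
#' not exceed the number of dividing compartments of any lineage.
#'
#' @param m An `mdsim_model`.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "mdsim_model"))
  fb <- m$feedback
  if (!inherits(fb, "mdsim_feedback")) stop("feedback must be feedback_params()")
  if (!length(m$lineages) %in% 1:2) stop("a model has one or two lineages")
  if (anyDuplicated(names(m$lineages))) stop("duplicate lineage labels")
  for (lin in m$lineages) {
    cp <- lin$compartments
    if (any(cp$a_max < 0 | cp$a_max > 1)) stop("a_max must lie in [0, 1]")
    if (any(cp$p_max < 0)) stop("p_max must be nonnegative")
    if (any(cp$d < 0)) stop("death rates must be nonnegative")
    ndiv <- sum(cp$divides)
    if (ndiv < 1L) stop("each lineage needs at least one dividing compartment")
    if (any(cp$divides != c(rep(TRUE, ndiv), rep(FALSE, nrow(cp) - ndiv))))
      stop("terminal (non-dividing) compartments must come last")
    if (fb$niche_depth > ndiv)
      stop("niche_depth exceeds the number of dividing compartments")
    expect_niche <- seq_len(nrow(cp)) <= fb$niche_depth & cp$divides
    if (!identical(cp$in_niche, expect_niche))
      stop("exactly the first niche_depth dividing compartments must have in_niche = TRUE")
    if (any(cp$in_pb & cp$divides))
      stop("peripheral-blood pools must be terminal")
  }
  invisible(m)
}

#' Flat per-compartment layout of a model's state vector
#'
#' The global state vector concatenates lineages in their listed order,
#' each lineage most primitive first. Column `state` gives the canonical
#' `<lineage>.<compartment>` names used by [simulate_model()] trajectories.
#'
#' @param params An `mdsim_model`.
#' @return A tibble with one row per (lineage, compartment).
#' @export
state_layout <- function(params) {
  stopifnot(inherits(params, "mdsim_model"))
  purrr::map_dfr(params$lineages, function(lin) {
    dplyr::mutate(lin$compartments, lineage = lin$label, .before = 1)
  }) |>
    dplyr::mutate(index = dplyr::row_number(),
                  state = paste(.data$lineage, .data$name, sep = "."))
}

#' Build a state vector for a model
#'
#' @param params An `mdsim_model`.
#' @param counts Numeric cell counts, recycled if scalar; ordered as in
#'   [state_layout()]. May be a named vector using the layout's `state`
#'   names, in which case omitted compartments default to 0.
#' @return A named nonnegative numeric vector.
#' @export
system_state <- function(params, counts = 0) {
  lay <- state_layout(params)
  out <- stats::setNames(numeric(nrow(lay)), lay$state)
  if (!is.null(names(counts)) && any(nzchar(names(counts)))) {
    bad <- setdiff(names(counts), lay$state)
    if (length(bad)) stop("unknown compartments: ", paste(bad, collapse = ", "))
    out[names(counts)] <- counts
  } else {
    out[] <- counts
  }
  if (any(out < 0)) stop("cell counts must be nonnegative")
  out
}

# Coerce a state given as vector or one-row data frame to the layout order.
as_state_vector <- function(state, params) {
  lay <- state_layout(params)
  if (is.data.frame(state)) {
    if (nrow(state) != 1L) stop("state must be a single time point")
    state <- unlist(state[intersect(lay$state, names(state))])
  }
  if (length(state) != nrow(lay))
    stop("state length ", length(state), " does not match model layout (",
         nrow(lay), " compartments)")
  if (!is.null(names(state)) && !identical(names(state), lay$state)) {
    if (!setequal(names(state), lay$state))
      stop("state names do not match the model layout")
    state <- state[lay$state]
  }
  if (any(state < 0)) stop("cell counts must be nonnegative")
  stats::setNames(as.numeric(state), lay$state)
}
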