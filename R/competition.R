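#' Classify the long-run outcome of a competition scenario
#'
#' Labels a simulated scenario by its end-of-horizon state:
#' * `takeover` -- normal mature output collapsed (below `mature_collapse`
#'   of the healthy baseline) and the MDS clone dominates the marrow (share
#'   above `mds_dominance`);
#' * `no_takeover` -- the clone stayed at (or fell below) seed level while
#'   normal mature output is essentially intact (above `mature_intact`);
#' * `marginal` -- anything in between (e.g. equal stem-cell self-renewal,
#'   where the deterministic system has no leading-order drift).
#'
#' @param traj An `mdsim_trajectory` run to the classification horizon
#'   (100 years by default in [sweep_outcomes()]).
#' @param mature_collapse,mature_intact Fractions of the healthy baseline
#'   mature count bounding collapse (default 0.1) and intact output
#'   (default 0.9).
#' @param mds_dominance MDS bone-marrow share (fraction) above which the
#'   clone dominates (default 0.5).
#' @param seed_share MDS bone-marrow share at or below which the clone is
#'   considered still at seed level (default `1e-6`).
#' @return An object of class `mdsim_outcome`: list with `label`,
#'   `mature_fraction` (of baseline), `mds_bm_share` (percent), and
#'   `manifestation_years` (`NA` if never). Has [tidy()] and [glance()]
#'   methods.
#' @export
classify_outcome <- function(traj, mature_collapse = 0.1,
                             mature_intact = 0.9, mds_dominance = 0.5,
                             seed_share = 1e-6) {
  stopifnot(inherits(traj, "mdsim_trajectory"))
  smry <- trajectory_summary(traj)
  last <- smry[nrow(smry), ]
  if (is.na(last$mature_normal_rel))
    stop("cannot classify: healthy baseline unknown for this trajectory")
  share_frac <- last$mds_bm_share / 100
  share0 <- smry$mds_bm_share[1] / 100
  # a clone that neither grew nor declined (exact self-renewal tie) is
  # neutral to leading order and must not count as cleared
  declined <- is.na(share0) || share0 == 0 || share_frac < 0.5 * share0
  label <- if (last$mature_normal_rel < mature_collapse &&
               share_frac > mds_dominance) {
    "takeover"
  } else if (share_frac <= seed_share && declined &&
             last$mature_normal_rel >= mature_intact) {
    "no_takeover"
  } else {
    "marginal"
  }
  structure(list(label = label,
                 mature_fraction = unname(last$mature_normal_rel),
                 mds_bm_share = unname(last$mds_bm_share),
                 manifestation_years = attr(smry, "manifestation_years"),
                 horizon_years = unname(last$time_years)),
            class = "mdsim_outcome")
}

#' @export
print.mdsim_outcome <- function(x, ...) {
  cat("<mdsim_outcome> ", x$label, "\n",
      "  normal mature output: ", signif(100 * x$mature_fraction, 3),
      "% of healthy baseline\n",
      "  MDS share of bone marrow: ", signif(x$mds_bm_share, 3), "%\n",
      "  manifestation: ",
      if (is.na(x$manifestation_years)) "never"
      else paste0(signif(x$manifestation_years, 4), " years"),
      " (horizon ", x$horizon_years, " y)\n", sep = "")
  invisible(x)
}

#' Derive a variant MDS clone from a base model
#'
#' Replaces the MDS stem compartment's maximal self-renewal and rescales all
#' MDS proliferation rates; downstream MDS compartments' `a_max` are capped
#' at the new stem value so the self-renewal hierarchy stays monotone. This
#' is the per-cell transformation behind [sweep_outcomes()].
#'
#' @param base_params Two-lineage `mdsim_model`.
#' @param a_max_mds New MDS stem-cell maximal self-renewal (`NULL` keeps the
#'   base value).
#' @param p_scale Factor applied to every MDS compartment's `p_max`.
#' @return A validated `mdsim_model`.
#' @export
modify_mds_clone <- function(base_params, a_max_mds = NULL, p_scale = 1) {
  m <- base_params
  cp <- m$lineages[["mds"]]$compartments
  if (is.null(cp)) stop("base model has no 'mds' lineage")
  if (!is.null(a_max_mds)) {
    # keep downstream self-renewal below the stem compartment's
    cp$a_max[cp$divides] <- pmin(cp$a_max[cp$divides], a_max_mds)
    cp$a_max[1] <- a_max_mds
  }
  cp$p_max <- cp$p_max * p_scale
  m$lineages[["mds"]]$compartments <- cp
  validate_model(m)
  m
}

#' Sweep MDS clone properties and classify each outcome
#'
#' Runs one long-horizon competition simulation per grid cell, varying the
#' MDS stem-cell maximal self-renewal and a common scaling of all MDS
#' proliferation rates, and classifies each with [classify_outcome()].
#' Iteration is row-major in `a_max_mds` then `p_scale`, deterministically.
#'
#' @param base_params Two-lineage `mdsim_model` providing everything not
#'   varied by the grid.
#' @param a_max_mds Numeric vector of MDS stem-cell maximal self-renewal
#'   fractions.
#' @param p_scale Numeric vector of multiplicative factors applied to every
#'   MDS compartment's `p_max`.
#' @param horizon_years Classification horizon (default 100).
#' @param seed_cells Seeded MDS stem cells (default 1).
#' @param ... Passed to [classify_outcome()] (thresholds).
#' @return A tibble of class `mdsim_sweep`: one row per cell with
#'   `a_max_mds`, `p_scale`, `label`, `mature_fraction`, `mds_bm_share`,
#'   `manifestation_years`, and `error` (solver failures are recorded, not
#'   fatal).
#' @export
sweep_outcomes <- function(base_params, a_max_mds, p_scale = 1,
                           horizon_years = 100, seed_cells = 1, ...) {
  validate_model(base_params)
  grid <- tidyr::expand_grid(a_max_mds = a_max_mds, p_scale = p_scale)
  empty <- tibble::tibble(a_max_mds = numeric(), p_scale = numeric(),
                          label = character(), mature_fraction = numeric(),
                          mds_bm_share = numeric(),
                          manifestation_years = numeric(),
                          error = character())
  res <- dplyr::bind_rows(empty, purrr::pmap_dfr(grid, function(a_max_mds, p_scale) {
    row <- tibble::tibble(a_max_mds = a_max_mds, p_scale = p_scale,
                          label = NA_character_, mature_fraction = NA_real_,
                          mds_bm_share = NA_real_,
                          manifestation_years = NA_real_,
                          error = NA_character_)
    out <- tryCatch({
      m <- modify_mds_clone(base_params, a_max_mds, p_scale)
      traj <- simulate_model(m, seed_cells = seed_cells,
                             horizon_years = horizon_years,
                             output_interval_days = 90)
      classify_outcome(traj, ...)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      row$error <- conditionMessage(out)
    } else {
      row$label <- out$label
      row$mature_fraction <- out$mature_fraction
      row$mds_bm_share <- out$mds_bm_share
      row$manifestation_years <- out$manifestation_years
    }
    row
  }))
  class(res) <- c("mdsim_sweep", class(res))
  attr(res, "base_params") <- base_params
  res
}

#' Concordance between simulated outcomes and the analytic takeover criterion
#'
#' For every non-marginal grid cell, checks whether the simulated label
#' agrees with [takeover_predicate()] (takeover iff the MDS stem cell's
#' `a_max` exceeds the normal one's). Cells within `band` of equality are
#' excluded as analytically marginal.
#'
#' @param grid An `mdsim_sweep` result.
#' @param base_params The model the sweep was built from (defaults to the
#'   one stored on `grid`).
#' @param band Half-width of the excluded near-equality band on `a_max`
#'   (default 0.01).
#' @return A list with `concordance` (fraction agreeing; `NA` if no
#'   comparable cells), `n_compared`, and `discordant` (tibble of
#'   disagreeing cells).
#' @export
predicate_concordance <- function(grid, base_params = NULL, band = 0.01) {
  stopifnot(inherits(grid, "mdsim_sweep"))
  if (is.null(base_params)) base_params <- attr(grid, "base_params")
  a_n <- base_params$lineages[["normal"]]$compartments$a_max[1]
  g <- dplyr::filter(grid, is.na(.data$error),
                     !is.na(.data$label), .data$label != "marginal",
                     abs(.data$a_max_mds - a_n) > band)
  if (nrow(g) == 0L)
    return(list(concordance = NA_real_, n_compared = 0L,
                discordant = g))
  g <- dplyr::mutate(g,
                     predicted = ifelse(.data$a_max_mds > a_n,
                                        "takeover", "no_takeover"),
                     agree = .data$predicted == .data$label)
  list(concordance = mean(g$agree), n_compared = nrow(g),
       discordant = dplyr::filter(g, !.data$agree))
}
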