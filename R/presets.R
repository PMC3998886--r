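#' Read a model parameterization from YAML
#'
#' The YAML layout mirrors the model structure: a `feedback` block, a
#' `lineages` list with one `compartments` table per lineage, and an
#' optional `provenance` map recording, per parameter, whether its value is
#' printed in the source literature (`literature`), carried over from the predecessor
#' hematopoiesis model (`reference-model`), a calibrated choice
#' (`calibrated`), or a plain modelling assumption (`assumption`).
#'
#' @param path Path to a YAML file.
#' @return An `mdsim_model` (provenance map, if any, kept as an attribute).
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  fb <- doc$feedback
  feedback <- feedback_params(
    k_p = fb$k_p, k_a = fb$k_a,
    niche_depth = fb$niche_depth %||% 3L,
    apoptosis_visibility = fb$apoptosis_visibility %||% 1
  )
  lineages <- purrr::map(doc$lineages, function(lin) {
    cp <- purrr::map_dfr(lin$compartments, function(co) {
      compartment_params(
        name = co$name, a_max = co$a_max %||% 0, p_max = co$p_max %||% 0,
        d = co$d %||% 0, divides = co$divides %||% TRUE,
        in_niche = co$in_niche %||% FALSE, in_pb = co$in_pb %||% FALSE
      )
    })
    lineage_params(lin$label, cp)
  })
  m <- model_params(lineages, feedback, variant = doc$variant %||% "baseline")
  attr(m, "preset") <- doc$preset
  attr(m, "provenance") <- doc$provenance
  m
}

#' Write a model parameterization to YAML
#'
#' Inverse of [read_model_yaml()]; a read--write--read round trip
#' reproduces the model exactly.
#'
#' @param params An `mdsim_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(params, path) {
  validate_model(params)
  fb <- params$feedback
  doc <- list(
    preset = attr(params, "preset"),
    variant = params$variant,
    feedback = list(k_p = fb$k_p, k_a = fb$k_a,
                    niche_depth = fb$niche_depth,
                    apoptosis_visibility = fb$apoptosis_visibility),
    lineages = purrr::map(unname(params$lineages), function(lin) {
      list(label = lin$label,
           compartments = purrr::pmap(lin$compartments, function(...) {
             as.list(list(...))
           }))
    }),
    provenance = attr(params, "provenance")
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

preset_names <- c("healthy_default", "mds_baseline", "mds_full_maturation",
                  "toy_two_compartment")

#' List the shipped parameter presets
#'
#' @return Character vector of preset names usable with [get_preset()].
#' @export
list_presets <- function() preset_names

#' Load a shipped parameter preset
#'
#' Available presets:
#' * `healthy_default` -- the six-stage normal lineage alone.
#' * `mds_baseline` -- normal lineage plus a five-stage MDS clone whose
#'   terminal dysplastic precursors die in the marrow (mean lifespan 10 d);
#'   stem-cell contrasts: self-renewal up to 90% vs 70%, division at most
#'   once per 100 d vs once per 50 d.
#' * `mds_full_maturation` -- variant in which the MDS clone matures fully
#'   into a short-lived mature pool (half-life 16 h).
#' * `toy_two_compartment` -- a hand-solvable two-compartment system for
#'   analytic tests.
#'
#' @param name Preset name (see [list_presets()]).
#' @return A fresh `mdsim_model` (presets are immutable; each call returns
#'   an independent copy).
#' @export
#' @examples
#' get_preset("mds_baseline")
get_preset <- function(name) {
  if (!name %in% preset_names)
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names, collapse = ", "))
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "mdsim", mustWork = TRUE)
  read_model_yaml(path)
}

#' @export
print.mdsim_model <- function(x, ...) {
  cat("<mdsim_model> variant:", x$variant)
  if (!is.null(attr(x, "preset"))) cat("  (preset:", attr(x, "preset"), ")")
  cat("\n")
  for (lin in x$lineages) {
    cat("lineage:", lin$label, "\n")
    print(lin$compartments)
  }
  fb <- x$feedback
  cat("feedback: k_p =", format(fb$k_p), " k_a =", format(fb$k_a),
      " niche_depth =", fb$niche_depth,
      " apoptosis_visibility =", fb$apoptosis_visibility, "d\n")
  invisible(x)
}
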