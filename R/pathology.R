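# Stage II flatfoot ligament attenuation.
#
# Damage stages map to fixed stiffness-reduction fractions; the published
# attenuation scheme lists, per affected structure, the damage stage and the
# resulting attenuated ("flatfoot") stiffness. Baseline (pre-attenuation)
# stiffnesses are recovered by inverting the reduction fraction.

STAGE_FRACTION <- c("0" = 0, "I" = 1 / 8, "II" = 3 / 8, "IV" = 7 / 8)

# structure -> (damage stage, attenuated stiffness in N/mm)
FLATFOOT_SCHEME <- list(
  superomedial_spring          = list(stage = "IV", flatfoot_k = 39),
  inferomedial_spring          = list(stage = "II", flatfoot_k = 94),
  talocalcaneal_interosseus    = list(stage = "I",  flatfoot_k = 236),
  plantar_fascia               = list(stage = "I",  flatfoot_k = 175),
  plantar_metatarsocuneiform   = list(stage = "0",  flatfoot_k = 90),
  plantar_naviculocuneiform    = list(stage = "0",  flatfoot_k = 180),
  long_and_short_plantar       = list(stage = "0",  flatfoot_k = 240),
  deep_deltoid                 = list(stage = "0",  flatfoot_k = 200),
  anterior_superficial_deltoid = list(stage = "I",  flatfoot_k = 70),
  posterior_superficial_deltoid = list(stage = "0", flatfoot_k = 117)
)

#' Default flatfoot damage map
#'
#' Structure name to damage stage, exactly as in the published Stage II
#' attenuation scheme. Stages 0, I, II, IV remove 0, 1/8, 3/8, 7/8 of the
#' baseline stiffness respectively (there is no Stage III fraction, so the
#' stage set excludes it).
#'
#' @return named character vector of stages, class `pedmech_damage_map`.
#' @export
default_damage_map <- function() {
  out <- vapply(FLATFOOT_SCHEME, function(x) x$stage, "")
  structure(out, class = "pedmech_damage_map")
}

#' Baseline (pre-attenuation) stiffness of a structure
#'
#' Recovers the healthy stiffness from the published attenuated value:
#' `flatfoot_k / (1 - fraction)`. Stage 0 structures return the published
#' value unchanged.
#'
#' @param structure structure name (see [default_damage_map()] for the set).
#' @return stiffness, N/mm.
#' @export
baseline_stiffness <- function(structure) {
  entry <- FLATFOOT_SCHEME[[structure]]
  if (is.null(entry))
    stop("unknown structure '", structure,
         "'; known structures: ", paste(names(FLATFOOT_SCHEME), collapse = ", "))
  entry$flatfoot_k / (1 - STAGE_FRACTION[[entry$stage]])
}

#' Stiffness used for structures absent from the published table
#'
#' The mean of the baseline stiffnesses of the known structures, mirroring
#' the original model's use of averages of known structures where the
#' literature reports none.
#'
#' @return stiffness, N/mm.
#' @export
generic_stiffness <- function() {
  mean(vapply(names(FLATFOOT_SCHEME), baseline_stiffness, 0))
}

#' Apply the Stage II flatfoot attenuation to a band set
#'
#' Multiplies the stiffness of every band whose structure appears in the
#' damage map by `(1 - fraction(stage))`. Geometry, rest lengths and
#' unaffected bands are untouched. Re-application is rejected (bands carry a
#' provenance flag once attenuated).
#'
#' @param bands list of `pedmech_band` carrying baseline stiffnesses.
#' @param damage_map named character vector structure -> stage (default: the
#'   published scheme).
#' @return attenuated band list.
#' @export
apply_flatfoot <- function(bands, damage_map = default_damage_map()) {
  bad <- setdiff(unname(damage_map), names(STAGE_FRACTION))
  if (length(bad))
    stop("damage map contains unknown stage(s): ", paste(bad, collapse = ", "))
  lapply(bands, function(b) {
    if (!b$structure %in% names(damage_map)) return(b)
    if (isTRUE(b$attenuated))
      stop("band '", b$name, "' is already attenuated; ",
           "flatfoot damage cannot be applied twice")
    stage <- damage_map[[b$structure]]
    b$stiffness_k <- b$stiffness_k * (1 - STAGE_FRACTION[[stage]])
    b$damage_stage <- stage
    b$attenuated <- TRUE
    b
  })
}
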