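# Tension-only ligament band mechanics.
#
# A band is a linear spring that carries tension only: force k * max(0, L - L0)
# along its path. Paths may run through massless via-point beads that act as
# frictionless pulleys redirecting the band around bone; the bead radius is
# kept for mesh export only and does not enter the length computation.

#' Construct a ligament band
#'
#' @param name band identifier.
#' @param origin,insertion lists `list(bone =, p =)` with local (bone-frame)
#'   coordinates in mm.
#' @param via_beads list of `list(bone =, p =, radius =)` via points, ordered
#'   origin to insertion.
#' @param stiffness_k spring stiffness, N/mm (> 0).
#' @param rest_length_L0 slack length, mm (> 0), usually set by
#'   [calibrate_rest_lengths()].
#' @param damage_stage one of `"0"`, `"I"`, `"II"`, `"IV"`.
#' @param group structure array the band belongs to (e.g. `"long_plantar"`).
#' @param structure stiffness-table structure name (e.g.
#'   `"superomedial_spring"`, or `"generic"`).
#' @param index 1-based position of the band within its group, medial first.
#' @return object of class `pedmech_band`.
#' @export
ligament_band <- function(name, origin, insertion, via_beads = list(),
                          stiffness_k, rest_length_L0 = NA_real_,
                          damage_stage = "0", group = name, structure = name,
                          index = 1L) {
  if (!is.numeric(stiffness_k) || stiffness_k <= 0)
    stop("band '", name, "': stiffness_k must be > 0")
  if (!is.na(rest_length_L0) && rest_length_L0 <= 0)
    stop("band '", name, "': rest_length_L0 must be > 0")
  if (!damage_stage %in% c("0", "I", "II", "IV"))
    stop("band '", name, "': damage_stage must be one of 0, I, II, IV")
  structure(list(name = name, origin = origin, insertion = insertion,
                 via_beads = via_beads, stiffness_k = stiffness_k,
                 rest_length_L0 = rest_length_L0, damage_stage = damage_stage,
                 group = group, structure = structure, index = as.integer(index),
                 attenuated = FALSE),
            class = "pedmech_band")
}

# world positions of a band's path points (origin, beads..., insertion)
band_path_points <- function(band, poses, skeleton = NULL) {
  resolve <- function(bone, p_local) {
    if (!is.null(skeleton)) {
      if (is.null(skeleton$bones[[bone]]))
        stop("band references unknown bone '", bone, "'")
      x0 <- p_local + skeleton$bones[[bone]]$reference_pose$position
      grp <- skeleton$bones[[bone]]$fusion_group
    } else {
      x0 <- p_local
      grp <- bone
    }
    transform_point(x0, poses, grp)
  }
  pts <- list(resolve(band$origin$bone, band$origin$p))
  for (bd in band$via_beads) pts <- c(pts, list(resolve(bd$bone, bd$p)))
  pts <- c(pts, list(resolve(band$insertion$bone, band$insertion$p)))
  do.call(rbind, pts)
}

#' Path length of a band under a pose map
#'
#' Sum of straight segment lengths origin -> bead_1 -> ... -> insertion with
#' every point mapped to the world frame; always at least the straight-line
#' origin-insertion distance.
#'
#' @param band a `pedmech_band`.
#' @param poses pose map (`NULL` = neutral); see [neutral_poses()].
#' @param skeleton skeleton carrying the attachment frames. When `NULL`,
#'   local attachment coordinates are interpreted directly as fusion-group
#'   frame coordinates (convenient for small fixtures).
#' @return length in mm.
#' @export
path_length <- function(band, poses = NULL, skeleton = NULL) {
  pts <- band_path_points(band, poses, skeleton)
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

#' Tension carried by a band
#'
#' Tension-only linear spring law: `k * max(0, L - L0)`; strictly zero when
#' the path is at or below the rest length.
#'
#' @inheritParams path_length
#' @return tension in N.
#' @export
band_tension <- function(band, poses = NULL, skeleton = NULL) {
  if (is.na(band$rest_length_L0))
    stop("band '", band$name, "' has no rest length; calibrate first")
  L <- path_length(band, poses, skeleton)
  band$stiffness_k * max(0, L - band$rest_length_L0)
}

#' Engineering strain of a band relative to a resting length
#'
#' `(L - L_ref) / L_ref`; negative values mean the band is slack relative to
#' its resting state. Resting lengths come from the unloaded equilibrium of
#' the same scenario (see [solve_equilibrium()]).
#'
#' @inheritParams path_length
#' @param reference_lengths named numeric, resting length per band name (mm).
#' @return dimensionless strain.
#' @export
band_strain <- function(band, poses = NULL, reference_lengths,
                        skeleton = NULL) {
  Lr <- if (band$name %in% names(reference_lengths))
    reference_lengths[[band$name]] else NA_real_
  if (is.na(Lr))
    stop("no reference length for band '", band$name, "'")
  L <- path_length(band, poses, skeleton)
  (L - Lr) / Lr
}

#' In-situ strain table
#'
#' Maps structures to their reference-pose (in-situ) engineering strain.
#' Resolution order per band: band-level entry, then group-level, then the
#' global default. Strains must lie in [0, 0.10].
#'
#' @param default global default strain (dimensionless).
#' @param by_structure named numeric of structure-level overrides (e.g.
#'   `c(capsule = 0.02)`).
#' @param by_group named numeric of group-level overrides.
#' @param by_band named numeric of band-level overrides.
#' @return object of class `pedmech_insitu`.
#' @export
in_situ_strains <- function(default = 0, by_structure = numeric(),
                            by_group = numeric(), by_band = numeric()) {
  all <- c(default, by_structure, by_group, by_band)
  if (any(all < 0 | all > 0.10))
    stop("in-situ strains must lie in [0, 0.10]")
  structure(list(default = default, by_structure = by_structure,
                 by_group = by_group, by_band = by_band),
            class = "pedmech_insitu")
}

#' Default in-situ strain table
#'
#' Short capsular fibres carry a 0.5 percent resting pre-strain, keeping
#' every joint capsule snug around its neutral configuration; the long
#' named bands rest exactly at their neutral length so the unloaded
#' equilibrium stays at the generator's neutral pose. Published
#' per-structure values are not available, so these are configuration,
#' not inference.
#'
#' @return a [in_situ_strains()] table.
#' @export
default_in_situ <- function() {
  in_situ_strains(default = 0, by_structure = c(capsule = 0.005))
}

insitu_lookup <- function(table, band) {
  if (band$name %in% names(table$by_band)) return(table$by_band[[band$name]])
  if (band$group %in% names(table$by_group)) return(table$by_group[[band$group]])
  bs <- table$by_structure
  if (!is.null(bs) && band$structure %in% names(bs))
    return(bs[[band$structure]])
  table$default
}

#' Calibrate band rest lengths from in-situ strains
#'
#' Sets each band's rest length so that its strain at the generator's
#' neutral pose equals the prescribed in-situ strain:
#' `L0 = L_neutral / (1 + eps)`.
#'
#' @param bands list of `pedmech_band`.
#' @param skeleton skeleton providing the neutral reference pose.
#' @param in_situ a [in_situ_strains()] table.
#' @return the band list with `rest_length_L0` set.
#' @export
calibrate_rest_lengths <- function(bands, skeleton,
                                   in_situ = in_situ_strains()) {
  lapply(bands, function(b) {
    eps <- insitu_lookup(in_situ, b)
    if (eps <= -1) stop("in-situ strain must exceed -1 for band '", b$name, "'")
    Ln <- path_length(b, poses = NULL, skeleton = skeleton)
    b$rest_length_L0 <- Ln / (1 + eps)
    b
  })
}

#' Build the ligament band set of a skeleton
#'
#' Instantiates one tension-only band per attachment record, assigns
#' stiffnesses (structure-specific baseline values where known, otherwise
#' the average of the known structures), and calibrates rest lengths from
#' the in-situ strain table.
#'
#' @param skeleton a `pedmech_skeleton`.
#' @param in_situ an [in_situ_strains()] table.
#' @param stiffness_scale uniform multiplier on every stiffness (used by the
#'   robustness analyses; default 1).
#' @return list of calibrated `pedmech_band` objects.
#' @export
make_bands <- function(skeleton, in_situ = default_in_situ(),
                       stiffness_scale = 1) {
  stopifnot(stiffness_scale > 0)
  recs <- skeleton$attachments
  # a capsule restrains three motion families (distraction and the two
  # crossed shear senses) with three fibres each; every family carries the
  # field-average structure stiffness split across its three fibres. Other
  # structures without published values carry the field average directly.
  bands <- lapply(recs, function(r) {
    k <- if (identical(r$structure, "capsule"))
      generic_stiffness() / 3 *
        (if (is.null(r$k_scale)) 1 else r$k_scale)
    else if (identical(r$structure, "generic"))
      generic_stiffness()
    else baseline_stiffness(r$structure)
    ligament_band(r$name, r$origin, r$insertion, r$beads,
                  stiffness_k = k * stiffness_scale, group = r$group,
                  structure = r$structure, index = r$index)
  })
  calibrate_rest_lengths(bands, skeleton, in_situ)
}

#' Spring energy of a band
#'
#' `0.5 * k * max(0, L - L0)^2`: non-negative, zero iff the band is slack.
#'
#' @inheritParams path_length
#' @return energy in N mm.
#' @export
band_energy <- function(band, poses = NULL, skeleton = NULL) {
  L <- path_length(band, poses, skeleton)
  0.5 * band$stiffness_k * max(0, L - band$rest_length_L0)^2
}

#' Serialize a band list to a data.frame / CSV
#'
#' @param bands list of `pedmech_band`.
#' @param file optional path; when given the table is written as CSV.
#' @return data.frame (invisibly when `file` is given).
#' @export
bands_table <- function(bands, file = NULL) {
  df <- do.call(rbind, lapply(bands, function(b) {
    data.frame(name = b$name, group = b$group, structure = b$structure,
               index = b$index,
               origin_bone = b$origin$bone,
               ox = b$origin$p[1], oy = b$origin$p[2], oz = b$origin$p[3],
               insertion_bone = b$insertion$bone,
               ix = b$insertion$p[1], iy = b$insertion$p[2],
               iz = b$insertion$p[3],
               n_beads = length(b$via_beads),
               stiffness_k = b$stiffness_k, rest_length_L0 = b$rest_length_L0,
               damage_stage = b$damage_stage, stringsAsFactors = FALSE)
  }))
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
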