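# Radiographic measurement suite.
#
# Six joint angles taken from synthetic "radiographic views" (projections of
# landmark-defined axes), plus ligament strain tables, calcaneocuboid joint
# contact force, and plantar ground load distribution.
#
# View conventions (right foot; the lateral axis is mirrored for a left
# foot so all signed angles are handedness-invariant):
#   lateral view:  projection onto the sagittal plane (normal = lateral axis)
#   raised AP view: viewing direction elevated 70 deg from horizontal within
#                   the sagittal plane (a near-overhead oblique of the midfoot)
#   posterior view: projection onto the coronal plane (normal = anterior axis)

# unit axes of the measurement frame for a skeleton
measure_axes <- function(skeleton) {
  lat <- if (identical(skeleton$handedness, "left")) c(0, 0, -1) else c(0, 0, 1)
  list(anterior = c(1, 0, 0), superior = c(0, 1, 0), lateral = lat)
}

lm_w <- function(skeleton, bone, name, poses) {
  landmark_world(skeleton, bone, name, poses)
}

# sagittal-plane pitch (degrees) of a world direction: angle of its
# projection above the horizontal, positive when rising anteriorly
sagittal_pitch <- function(v, ax) {
  atan2(sum(v * ax$superior), sum(v * ax$anterior)) * 180 / pi
}

#' Lateral-view angles: talo-first-metatarsal, talocalcaneal, calcaneal pitch
#'
#' Axes are projected onto the sagittal plane. The talo-first-metatarsal
#' angle is signed: 0 when the talar and first-metatarsal axes are collinear,
#' negative when the construct apex points plantar (drooping medial arch).
#' Talocalcaneal is the unsigned angle between the talar and calcaneal long
#' axes; calcaneal pitch is the unsigned inclination of the calcaneal
#' inferior border above the ground plane.
#'
#' @param poses pose map from a converged equilibrium (or `NULL` for the
#'   neutral pose).
#' @param skeleton a `pedmech_skeleton`.
#' @return named numeric: `L_T1MT`, `L_TC`, `L_CP` (degrees).
#' @export
lateral_angles <- function(poses, skeleton) {
  ax <- measure_axes(skeleton)
  tal <- lm_w(skeleton, "talus", "talar_axis_ant", poses) -
    lm_w(skeleton, "talus", "talar_axis_post", poses)
  mt1 <- lm_w(skeleton, "ray1", "mt1_axis_dist", poses) -
    lm_w(skeleton, "ray1", "mt1_axis_prox", poses)
  calc <- lm_w(skeleton, "calcaneus", "calc_axis_ant", poses) -
    lm_w(skeleton, "calcaneus", "calc_axis_post", poses)
  inf <- lm_w(skeleton, "calcaneus", "calc_inf_ant", poses) -
    lm_w(skeleton, "calcaneus", "calc_inf_post", poses)
  p_tal <- sagittal_pitch(tal, ax)
  p_mt1 <- sagittal_pitch(mt1, ax)
  p_calc <- sagittal_pitch(calc, ax)
  c(L_T1MT = p_tal - p_mt1,
    L_TC = abs(p_calc - p_tal),
    L_CP = abs(sagittal_pitch(inf, ax)))
}

#' Raised-AP-view angles: talo-first-metatarsal and talonavicular coverage
#'
#' The viewing direction is raised 70 degrees from the horizontal within the
#' sagittal plane; axes are projected onto the plane normal to it. Both
#' angles are signed with positive = adduction (first metatarsal, or
#' navicular chord normal, deviated medially relative to the talar axis);
#' negative values signify forefoot abduction.
#'
#' @inheritParams lateral_angles
#' @return named numeric: `AP_T1MT`, `AP_TN` (degrees).
#' @export
ap_angles <- function(poses, skeleton) {
  ax <- measure_axes(skeleton)
  n <- cos(70 * pi / 180) * ax$anterior + sin(70 * pi / 180) * ax$superior
  tal <- lm_w(skeleton, "talus", "talar_axis_ant", poses) -
    lm_w(skeleton, "talus", "talar_axis_post", poses)
  mt1 <- lm_w(skeleton, "ray1", "mt1_axis_dist", poses) -
    lm_w(skeleton, "ray1", "mt1_axis_prox", poses)
  # positive rotation from the talar axis toward medial = adduction;
  # for a right foot medial is -Z and n is in the +X/+Y quadrant, so the
  # signed angle about +n from talar axis to MT1 axis is positive medially
  sgn <- if (identical(skeleton$handedness, "left")) -1 else 1
  ap_t1mt <- sgn * signed_angle_about(tal, mt1, n)
  chord <- lm_w(skeleton, "navicular", "nav_chord_lat", poses) -
    lm_w(skeleton, "navicular", "nav_chord_med", poses)
  # coverage: angle between the talar axis and the in-projection normal of
  # the navicular articular chord (zero when the chord faces the talar head
  # squarely); sign shares the adduction convention of AP_T1MT
  nrm <- n / sqrt(sum(n^2))
  pc <- chord - sum(chord * nrm) * nrm
  chord_normal <- crossprod3(nrm, pc)  # in-plane, rotated 90 deg from chord
  if (sum(chord_normal * ax$anterior) < 0) chord_normal <- -chord_normal
  ap_tn <- sgn * signed_angle_about(tal, chord_normal, n)
  c(AP_T1MT = ap_t1mt, AP_TN = ap_tn)
}

#' Posterior-view hindfoot varus/valgus angle
#'
#' The calcaneal bisection line (inferior to superior posterior midpoints)
#' is projected onto the coronal plane and measured against the ground
#' from the lateral aspect, i.e. the angle opening on the lateral side of
#' the heel, reported on the +90-degree-shifted scale: 90 is a vertical
#' heel. Eversion (hindfoot valgus) drops the medial border of the foot
#' and tips the bisection top medially, opening the lateral angle above
#' 90; inversion (varus) closes it below 90.
#'
#' @inheritParams lateral_angles
#' @return numeric, degrees (named `hindfoot`).
#' @export
hindfoot_angle <- function(poses, skeleton) {
  ax <- measure_axes(skeleton)
  v <- lm_w(skeleton, "calcaneus", "calc_bisect_sup", poses) -
    lm_w(skeleton, "calcaneus", "calc_bisect_inf", poses)
  lean <- atan2(-sum(v * ax$lateral), sum(v * ax$superior)) * 180 / pi
  c(hindfoot = 90 + lean)
}

#' All six radiographic angles
#' @inheritParams lateral_angles
#' @return named numeric of length 6: `L_T1MT`, `L_TC`, `L_CP`, `AP_T1MT`,
#'   `AP_TN`, `hindfoot` (degrees).
#' @export
angle_set <- function(poses, skeleton) {
  c(lateral_angles(poses, skeleton), ap_angles(poses, skeleton),
    hindfoot_angle(poses, skeleton))
}

#' Strain tables for the long plantar and plantar fascia arrays
#'
#' Engineering strain of each band relative to its unloaded-equilibrium
#' (resting) length, in percent, ordered medial to lateral.
#'
#' @param result converged `pedmech_equilibrium` result.
#' @param bands calibrated band list used in the simulation.
#' @param reference_lengths named per-band resting lengths (mm) from the same
#'   scenario's unloaded equilibrium.
#' @param skeleton the skeleton the bands attach to.
#' @return list with `long_plantar` (length 8) and `plantar_fascia`
#'   (length 5), percent strain.
#' @export
strain_tables <- function(result, bands, reference_lengths, skeleton = NULL) {
  nm <- vapply(bands, function(b) b$name, "")
  grab <- function(group, n) {
    idx <- which(vapply(bands, function(b) identical(b$group, group), TRUE))
    if (length(idx) != n)
      stop("expected ", n, " bands in group '", group, "', found ",
           length(idx))
    ord <- order(vapply(bands[idx], function(b) b$index, 0))
    idx <- idx[ord]
    out <- vapply(idx, function(i) {
      100 * band_strain(bands[[i]], result$poses, reference_lengths, skeleton)
    }, 0)
    names(out) <- nm[idx]
    out
  }
  list(long_plantar = grab("long_plantar", 8),
       plantar_fascia = grab("plantar_fascia", 5))
}

#' Full measurement report for one converged scenario
#'
#' @param result converged `pedmech_equilibrium`.
#' @param skeleton the skeleton the scenario ran on (post-surgery).
#' @param bands calibrated (and possibly attenuated) band list.
#' @param reference_lengths per-band resting lengths from the scenario's
#'   unloaded equilibrium.
#' @param scenario optional scenario configuration to attach.
#' @return object of class `pedmech_measures`: six angles, the two strain
#'   arrays, calcaneocuboid contact force (NA when that joint is fused),
#'   and the six plantar region loads.
#' @export
measure_all <- function(result, skeleton, bands, reference_lengths,
                        scenario = NULL) {
  if (!isTRUE(result$converged))
    stop("measure_all requires a converged equilibrium result")
  angles <- angle_set(result$poses, skeleton)
  strains <- strain_tables(result, bands, reference_lengths, skeleton)
  cc_fused <- skeleton$bones$cuboid$fusion_group ==
    skeleton$bones$calcaneus$fusion_group
  ccf <- if (cc_fused) NA_real_ else
    joint_contact_force(result, "calcaneus", "cuboid")
  loads <- ground_region_loads(result)
  structure(list(
    angles = angles,
    long_plantar_strains = strains$long_plantar,
    plantar_fascia_strains = strains$plantar_fascia,
    calcaneocuboid_force = ccf,
    plantar_loads = loads,
    scenario = scenario
  ), class = "pedmech_measures")
}

#' @export
print.pedmech_measures <- function(x, ...) {
  nm <- if (!is.null(x$scenario)) x$scenario$name else "scenario"
  cat("pedmech measures (", nm, ")\n", sep = "")
  cat("  angles (deg):",
      paste(sprintf("%s=%.1f", names(x$angles), x$angles), collapse = " "),
      "\n")
  cat("  long plantar strain (%):",
      paste(sprintf("%.1f", x$long_plantar_strains), collapse = " "), "\n")
  cat("  plantar fascia strain (%):",
      paste(sprintf("%.1f", x$plantar_fascia_strains), collapse = " "), "\n")
  cat("  calcaneocuboid force (N):",
      if (is.na(x$calcaneocuboid_force)) "n/a (fused)" else
        sprintf("%.0f", x$calcaneocuboid_force), "\n")
  cat("  plantar loads (N):",
      paste(sprintf("%s=%.0f", names(x$plantar_loads), x$plantar_loads),
            collapse = " "), "\n")
  invisible(x)
}
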