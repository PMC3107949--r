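# Virtual corrective osteotomies.
#
# Each procedure is a rigid transform of a landmark-defined bone fragment
# (or of the whole cuboid for the distraction arthrodesis): intra-fragment
# distances are preserved exactly, nothing outside the fragment moves, and
# ligament attachments riding on a fragment move with it - which is how the
# surgeries re-tension the plantar structures.

#' Osteotomy parameters
#'
#' @param mco_offset medial translation of the posterior calcaneal
#'   (Achilles tuberosity) fragment, mm.
#' @param evans_cut_offset distance of the Evans cut behind the
#'   calcaneocuboid articular surface, mm.
#' @param wedge_width opening width of the triangular wedge at its lateral
#'   base, mm.
#' @param wedge_depth medial-lateral depth of the wedge, mm; must exceed
#'   `wedge_width`.
#' @param ccda_resection articular surface shave per side for the
#'   calcaneocuboid distraction arthrodesis, mm.
#' @param ccda_trim trim of the exported wedge mesh to keep it out of the
#'   subtalar joint, mm (visualisation only; no mechanical effect).
#' @return object of class `pedmech_osteotomy_params`.
#' @export
osteotomy_params <- function(mco_offset = 10, evans_cut_offset = 10,
                             wedge_width = 10, wedge_depth = 25,
                             ccda_resection = 3, ccda_trim = 4) {
  stopifnot(mco_offset >= 0, evans_cut_offset > 0, wedge_width >= 0,
            wedge_depth > 0, ccda_resection >= 0, ccda_trim >= 0)
  if (wedge_width >= wedge_depth)
    stop("wedge_width must be smaller than wedge_depth")
  structure(list(mco_offset = mco_offset, evans_cut_offset = evans_cut_offset,
                 wedge_width = wedge_width, wedge_depth = wedge_depth,
                 ccda_resection = ccda_resection, ccda_trim = ccda_trim),
            class = "pedmech_osteotomy_params")
}

#' Hinge rotation angle that admits a triangular wedge
#'
#' Opening a cut about a hinge on its medial border until a wedge of the
#' given width and depth fits corresponds to a rotation of
#' `atan(width / depth)`.
#'
#' @param wedge_width,wedge_depth wedge dimensions, mm.
#' @return angle in degrees.
#' @export
wedge_hinge_angle <- function(wedge_width, wedge_depth) {
  atan2(wedge_width, wedge_depth) * 180 / pi
}

# ---- internal helpers -------------------------------------------------------

# apply world-space rigid map `tf` to every stored point of `bone` whose
# neutral world position satisfies `pred`
transform_bone_points <- function(skeleton, bone, pred, tf) {
  b <- skeleton$bones[[bone]]
  ctr <- b$reference_pose$position
  mov <- function(p_local) {
    w <- p_local + ctr
    if (pred(w)) tf(w) - ctr else p_local
  }
  b$landmarks <- t(apply(b$landmarks, 1, mov))
  if (!is.null(b$ground_contacts)) {
    for (i in seq_len(nrow(b$ground_contacts))) {
      p <- mov(c(b$ground_contacts$x[i], b$ground_contacts$y[i],
                 b$ground_contacts$z[i]))
      b$ground_contacts$x[i] <- p[1]
      b$ground_contacts$y[i] <- p[2]
      b$ground_contacts$z[i] <- p[3]
    }
  }
  skeleton$bones[[bone]] <- b
  skeleton$joints <- lapply(skeleton$joints, function(j) {
    if (j$bone_a == bone) j$a <- mov(j$a)
    if (j$bone_b == bone) j$b <- mov(j$b)
    j
  })
  skeleton$attachments <- lapply(skeleton$attachments, function(r) {
    if (r$origin$bone == bone) r$origin$p <- mov(r$origin$p)
    if (r$insertion$bone == bone) r$insertion$p <- mov(r$insertion$p)
    r$beads <- lapply(r$beads, function(bd) {
      if (bd$bone == bone) bd$p <- mov(bd$p)
      bd
    })
    r
  })
  skeleton
}

calc_axis_unit <- function(skeleton) {
  v <- landmark_world(skeleton, "calcaneus", "calc_axis_ant") -
    landmark_world(skeleton, "calcaneus", "calc_axis_post")
  v / sqrt(sum(v^2))
}

medial_unit <- function(skeleton) {
  if (identical(skeleton$handedness, "left")) c(0, 0, 1) else c(0, 0, -1)
}

# rotation of `angle_deg` about the vertical axis through `hinge`, sense
# chosen so points lateral of the hinge move anteriorly (internal rotation
# of the distal fragment, opening the cut laterally)
hinge_rotation <- function(skeleton, hinge, angle_deg) {
  sgn <- if (identical(skeleton$handedness, "left")) -1 else 1
  R <- rot_exp(c(0, sgn * angle_deg * pi / 180, 0))
  function(w) as.numeric(hinge + R %*% (w - hinge))
}

# ---- procedures -------------------------------------------------------------

#' Medializing calcaneal osteotomy (MCO)
#'
#' Cuts the calcaneus perpendicular to its long axis through the
#' `mco_cut_center` landmark, isolating the Achilles tuberosity, and
#' translates the posterior fragment medially by `mco_offset`, re-fixing it
#' to the calcaneal body (same rigid unit). The Achilles insertion and the
#' heel ground contact ride on the fragment, which is how the procedure
#' medialises the Achilles line of action and the heel support point.
#'
#' @param skeleton a `pedmech_skeleton` with an intact calcaneus.
#' @param params an [osteotomy_params()] set.
#' @return the modified skeleton.
#' @export
apply_mco <- function(skeleton, params = osteotomy_params()) {
  a <- calc_axis_unit(skeleton)
  ctr <- landmark_world(skeleton, "calcaneus", "mco_cut_center")
  pred <- function(w) sum((w - ctr) * a) < 0
  lm <- bone_landmarks_world(skeleton, "calcaneus")
  inside <- apply(lm, 1, pred)
  if (!any(inside))
    stop("MCO cut plane isolates no calcaneal landmarks")
  if (!inside["achilles_insertion"])
    stop("MCO cut plane fails to isolate the Achilles tuberosity")
  if (inside["cc_face_center"])
    stop("MCO cut plane must not isolate the calcaneocuboid articular surface")
  off <- params$mco_offset * medial_unit(skeleton)
  transform_bone_points(skeleton, "calcaneus", pred, function(w) w + off)
}

#' Evans lateral column lengthening osteotomy
#'
#' Detaches the anterior calcaneal fragment `evans_cut_offset` mm behind the
#' calcaneocuboid articular surface and rotates it internally about the
#' medial border of the cut by the angle that admits a
#' `wedge_width` x `wedge_depth` triangular wedge, opening the cut
#' laterally; the fragment is then re-fused to the calcaneal body.
#'
#' @inheritParams apply_mco
#' @return the modified skeleton.
#' @export
apply_evans <- function(skeleton, params = osteotomy_params()) {
  a <- calc_axis_unit(skeleton)
  face <- landmark_world(skeleton, "calcaneus", "cc_face_center")
  pc <- face - params$evans_cut_offset * a
  pred <- function(w) sum((w - pc) * a) > 0
  lm <- bone_landmarks_world(skeleton, "calcaneus")
  inside <- apply(lm, 1, pred)
  if (!any(inside) || !inside["cc_face_center"])
    stop("Evans cut plane misses the anterior calcaneus")
  if (params$wedge_width == 0) return(skeleton)
  hinge <- pc + (params$wedge_depth / 2) * medial_unit(skeleton)
  phi <- wedge_hinge_angle(params$wedge_width, params$wedge_depth)
  transform_bone_points(skeleton, "calcaneus", pred,
                        hinge_rotation(skeleton, hinge, phi))
}

#' Calcaneocuboid distraction arthrodesis (CCDA)
#'
#' Shaves `ccda_resection` mm off each calcaneocuboid articular surface,
#' rotates the entire cuboid internally about the medial border of the
#' joint by the wedge angle, and fuses the cuboid to the calcaneus (one
#' rigid unit). The fused joint's contact pairs no longer transmit
#' penalty load; its contact force is reported as not applicable.
#'
#' @inheritParams apply_mco
#' @return the modified skeleton.
#' @export
apply_ccda <- function(skeleton, params = osteotomy_params()) {
  if (skeleton$bones$cuboid$fusion_group ==
      skeleton$bones$calcaneus$fusion_group)
    stop("calcaneocuboid joint is already fused")
  cc <- skeleton$joints[vapply(skeleton$joints,
                               function(j) identical(j$joint, "calcaneocuboid"),
                               TRUE)]
  if (!length(cc)) stop("skeleton has no calcaneocuboid joint contacts")
  u <- colMeans(do.call(rbind, lapply(cc, function(j) j$b - j$a)))
  u <- u / sqrt(sum(u^2))
  if (params$ccda_resection > 0) {
    shave_a <- -params$ccda_resection * u
    shave_b <- params$ccda_resection * u
    ccpts_a <- do.call(rbind, lapply(cc, function(j)
      j$a + skeleton$bones$calcaneus$reference_pose$position))
    near_face_a <- function(w)
      any(sqrt(rowSums(sweep(ccpts_a, 2, w)^2)) < 1e-6) ||
      sqrt(sum((w - landmark_world(skeleton, "calcaneus", "cc_face_center"))^2)) < 1e-6
    skeleton <- transform_bone_points(skeleton, "calcaneus", near_face_a,
                                      function(w) w + shave_a)
    ccpts_b <- do.call(rbind, lapply(cc, function(j)
      j$b + skeleton$bones$cuboid$reference_pose$position))
    near_face_b <- function(w)
      any(sqrt(rowSums(sweep(ccpts_b, 2, w)^2)) < 1e-6) ||
      (("cc_face_center_cuboid" %in% rownames(skeleton$bones$cuboid$landmarks)) &&
       sqrt(sum((w - landmark_world(skeleton, "cuboid",
                                    "cc_face_center_cuboid"))^2)) < 1e-6)
    skeleton <- transform_bone_points(skeleton, "cuboid", near_face_b,
                                      function(w) w + shave_b)
  }
  if (params$wedge_width > 0) {
    face <- landmark_world(skeleton, "calcaneus", "cc_face_center")
    hinge <- face + (params$wedge_depth / 2) * medial_unit(skeleton)
    phi <- wedge_hinge_angle(params$wedge_width, params$wedge_depth)
    skeleton <- transform_bone_points(skeleton, "cuboid",
                                      function(w) TRUE,
                                      hinge_rotation(skeleton, hinge, phi))
  }
  skeleton$bones$cuboid$fusion_group <-
    skeleton$bones$calcaneus$fusion_group
  skeleton
}

#' Apply a set of procedures in canonical order
#'
#' The lateral column procedure (Evans or the distraction arthrodesis) is
#' applied first, then the medializing calcaneal osteotomy. Evans and CCDA
#' are mutually exclusive.
#'
#' @param skeleton a `pedmech_skeleton`.
#' @param procedures character subset of `c("MCO", "Evans", "CCDA")`.
#' @param params an [osteotomy_params()] set.
#' @return the modified skeleton.
#' @export
apply_procedures <- function(skeleton, procedures,
                             params = osteotomy_params()) {
  procedures <- as.character(procedures)
  bad <- setdiff(procedures, c("MCO", "Evans", "CCDA"))
  if (length(bad))
    stop("unknown procedure(s): ", paste(bad, collapse = ", "))
  if (all(c("Evans", "CCDA") %in% procedures))
    stop("Evans and CCDA are mutually exclusive lateral column procedures")
  if ("Evans" %in% procedures) skeleton <- apply_evans(skeleton, params)
  if ("CCDA" %in% procedures) skeleton <- apply_ccda(skeleton, params)
  if ("MCO" %in% procedures) skeleton <- apply_mco(skeleton, params)
  skeleton
}
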