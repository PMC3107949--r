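# Synthetic right-foot skeleton generator.
#
# The generator stands in for subject-specific (CT-derived) anatomy: bones are
# rigid bodies described by named landmarks plus sparse contact spheres, not
# surface meshes.  A deterministic template encodes a neutrally aligned foot
# with a medial arch; per-seed variation is confined to small landmark jitter.
#
# Coordinate frame (right foot): +X anterior (heel to toes), +Y superior,
# +Z lateral (medial = -Z); the ground plane is Y = 0; units mm.

BONE_UNITS <- c("tibfib", "talus", "calcaneus", "navicular", "cuboid",
                "cuneiforms", "ray1", "ray2", "ray3", "ray4", "ray5")

REQUIRED_LANDMARKS <- list(
  tibfib    = c("tibia_proximal", "gastroc_origin"),
  talus     = c("talar_axis_post", "talar_axis_ant"),
  calcaneus = c("calc_axis_post", "calc_axis_ant", "calc_inf_post",
                "calc_inf_ant", "calc_bisect_sup", "calc_bisect_inf",
                "achilles_insertion", "cc_face_center", "mco_cut_center"),
  navicular = c("nav_chord_med", "nav_chord_lat"),
  ray1      = c("mt1_axis_prox", "mt1_axis_dist")
)

#' Anatomy generator parameters
#'
#' Validated parameter set for [build_skeleton()]. All lengths in mm.
#'
#' @param foot_length heel-to-toe length, mm; allowed 200--300.
#' @param arch_height_fraction navicular height divided by foot length;
#'   allowed 0.15--0.35.
#' @param hindfoot_valgus_deg neutral coronal lean of the calcaneal bisection
#'   line, degrees lateral-at-top (physiologic slight valgus); allowed 0--6.
#' @param jitter_mm half-width of the uniform per-coordinate landmark jitter
#'   applied around the deterministic template; allowed 0--2.
#' @param handedness `"right"` or `"left"`.
#' @return a named list of class `pedmech_anatomy_params`.
#' @export
anatomy_params <- function(foot_length = 250,
                           arch_height_fraction = 0.18,
                           hindfoot_valgus_deg = 3,
                           jitter_mm = 0.5,
                           handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
      stop(sprintf("anatomy parameter '%s' = %s outside allowed range [%s, %s]",
                   nm, format(x), lo, hi), call. = FALSE)
    as.numeric(x)
  }
  structure(list(
    foot_length = chk(foot_length, 200, 300, "foot_length"),
    arch_height_fraction = chk(arch_height_fraction, 0.15, 0.35,
                               "arch_height_fraction"),
    hindfoot_valgus_deg = chk(hindfoot_valgus_deg, 0, 6, "hindfoot_valgus_deg"),
    jitter_mm = chk(jitter_mm, 0, 2, "jitter_mm"),
    handedness = handedness
  ), class = "pedmech_anatomy_params")
}

# The canonical template: landmark and attachment coordinates for a 250 mm
# right foot with arch fraction 0.18.  Returns plain world-coordinate tables;
# build_skeleton() scales, jitters, re-seats contacts, and packs bones.
foot_template <- function(valgus_deg = 3) {
  # physiologic hindfoot valgus (eversion) tips the bisection top medially
  zb <- 1 - 30 * tan(valgus_deg * pi / 180)
  lm <- list(
    tibfib = rbind(
      tibia_proximal = c(60, 400, 2),
      gastroc_origin = c(40, 380, 5),
      med_malleolus  = c(58, 64, -22),
      lat_malleolus  = c(60, 56, 26)),
    talus = rbind(
      talar_axis_post = c(50, 64, 8),
      talar_axis_ant  = c(90, 46, -7),
      talar_head      = c(90, 46, -7)),
    calcaneus = rbind(
      calc_axis_post     = c(10, 30, 2),
      calc_axis_ant      = c(76, 48, 6),
      calc_inf_post      = c(14, 18, 2),
      calc_inf_ant       = c(72, 34, 8),
      calc_bisect_inf    = c(18, 10, 1),
      calc_bisect_sup    = c(12, 40, zb),
      achilles_insertion = c(8, 42, 5),
      sustentaculum      = c(70, 44, -10),
      cc_face_center     = c(84, 33, 10),
      mco_cut_center     = c(30, 30, 2)),
    navicular = rbind(
      nav_center    = c(101, 45, -9),
      nav_chord_med = c(99, 45, -19),
      nav_chord_lat = c(103, 45, 1)),
    cuboid = rbind(
      cuboid_center         = c(112, 24, 12),
      cc_face_center_cuboid = c(88, 33, 11)),
    cuneiforms = rbind(
      cun_center = c(122, 40, -6)),
    ray1 = rbind(
      mt1_axis_prox = c(132, 38, -14),
      mt1_axis_dist = c(185, 16, -30),
      mt1_head      = c(185, 16, -30),
      toe1          = c(230, 8, -32)),
    ray2 = rbind(mt2_base = c(134, 36, -4), mt2_head = c(191, 15, -12),
                 toe2 = c(235, 8, -12)),
    ray3 = rbind(mt3_base = c(132, 34, 4), mt3_head = c(187, 14, 0),
                 toe3 = c(230, 8, 2)),
    ray4 = rbind(mt4_base = c(128, 28, 11), mt4_head = c(179, 13, 11),
                 toe4 = c(222, 8, 13)),
    ray5 = rbind(mt5_base = c(122, 25, 17), mt5_head = c(170, 13, 21),
                 toe5 = c(212, 8, 23)))

  # ground contact spheres: bone, x, z, radius, region (y is seated to r).
  # The heel is a single sphere: the rounded calcaneal tuberosity rolls in
  # the coronal plane, so hindfoot varus/valgus stays ligament-governed
  ground <- data.frame(
    bone   = c("calcaneus", "ray1", "ray2", "ray3", "ray4", "ray5"),
    name   = c("heel", "mt1_head_c", "mt2_head_c", "mt3_head_c",
               "mt4_head_c", "mt5_head_c"),
    x      = c(22, 185, 191, 187, 179, 170),
    z      = c(0, -30, -12, 0, 11, 21),
    radius = c(15, 12, 10, 10, 10, 10),
    region = c("calcaneus", "ray1", "ray2", "ray3", "ray4", "ray5"),
    stringsAsFactors = FALSE)

  # joint contact facets: each joint is a small patch of sphere pairs (the
  # pairs are re-placed after jitter so every pair touches exactly in the
  # neutral pose); multi-point patches let compression carry joint torque
  # the way broad articular facets do
  joints <- list(
    # the ankle load line passes anterior to the subtalar posterior facet,
    # so standing load torques the talar head plantarward onto the
    # navicular and the spring hammock (the medial column load path)
    list(name = "tibiotalar", bone_a = "talus", bone_b = "tibfib",
         a = list(c(64, 66, -8), c(64, 66, 10), c(78, 66, -8), c(78, 66, 10)),
         dir = c(0, 1, 0), ra = 5, rb = 5, socket_k = 800),
    # the subtalar joint articulates about the oblique hindfoot axis
    # (posterolateral-plantar to anteromedial-dorsal); two socket points
    # along that axis make the joint an oblique hinge, which couples
    # hindfoot eversion to forefoot abduction the way the facet geometry
    # does
    list(name = "subtalar", bone_a = "calcaneus", bone_b = "talus",
         a = list(c(46, 46, 10), c(46, 46, 0), c(62, 46, -6)),
         dir = c(0, 1, 0), ra = 5, rb = 5, socket_k = 800,
         socket_pts = list(c(34, 26, 6), c(66, 50, -8))),
    # the talonavicular joint has no bony socket: the talar head rests in
    # the acetabulum pedis whose floor is the spring ligament hammock.
    # Its bony facet points push the navicular only anteriorly, dorsally
    # or laterally; inferior-medial support is ligamentous, which is what
    # lets the head sag and deviate when the spring complex attenuates
    # facet normals push the navicular anteriorly, dorsally or laterally
    # only: the head's medial-plantar restraint is purely ligamentous
    # the dorsal talonavicular capsule is thin, so this joint gets only
    # the axial capsule fibres; its shear restraint is the spring hammock
    # and the deltoid, which is what flatfoot attenuation degrades
    # the fourth, plantar-facing facet point is the inferior rim of the
    # acetabulum pedis: talar head depression presses the medial column
    # plantarward through it
    list(name = "talonavicular", bone_a = "talus", bone_b = "navicular",
         a = list(c(86, 47, -9), c(85, 43, -13), c(87, 44, -3),
                  c(87, 42, -9)),
         dirs = list(c(0.94, 0.34, 0), c(0.99, 0, 0.05),
                     c(0.99, 0.05, 0.12), c(0.84, -0.55, 0)),
         dir = c(0.92, -0.25, -0.3), ra = 6, rb = 5,
         socket = FALSE, clearance = 0, capsule = "axial"),
    list(name = "calcaneocuboid", bone_a = "calcaneus", bone_b = "cuboid",
         a = list(c(82, 36, 8), c(82, 26, 8), c(82, 30, 14)),
         dir = c(1, 0, 0.05), ra = 5, rb = 5, socket_k = 800),
    list(name = "naviculocuneiform", bone_a = "navicular",
         bone_b = "cuneiforms",
         a = list(c(108, 46, -8), c(108, 40, -12), c(108, 40, 0)),
         dir = c(1, -0.1, 0), ra = 5, rb = 5, socket_k = 2000,
         capsule_scale = 3),
    list(name = "cuneocuboid", bone_a = "cuneiforms", bone_b = "cuboid",
         a = list(c(118, 32, 2)), dir = c(0, -0.4, 1), ra = 5, rb = 5,
         socket_k = 2000, capsule_scale = 3),
    list(name = "tmt1", bone_a = "cuneiforms", bone_b = "ray1",
         a = list(c(124, 42, -13), c(124, 34, -13)),
         dir = c(1, -0.1, -0.1), ra = 4, rb = 4, socket_k = 2000,
         capsule_scale = 3),
    list(name = "tmt2", bone_a = "cuneiforms", bone_b = "ray2",
         a = list(c(126, 40, -4), c(126, 33, -4)),
         dir = c(1, -0.1, 0), ra = 4, rb = 4, socket_k = 2000,
         capsule_scale = 3),
    list(name = "tmt3", bone_a = "cuneiforms", bone_b = "ray3",
         a = list(c(124, 38, 4), c(124, 31, 4)),
         dir = c(1, -0.1, 0), ra = 4, rb = 4, socket_k = 2000,
         capsule_scale = 3),
    list(name = "cuboid_ray4", bone_a = "cuboid", bone_b = "ray4",
         a = list(c(120, 31, 11), c(120, 24, 11)),
         dir = c(1, 0.05, 0), ra = 4, rb = 4, socket_k = 2000,
         capsule_scale = 3),
    list(name = "cuboid_ray5", bone_a = "cuboid", bone_b = "ray5",
         a = list(c(114, 28, 16), c(114, 21, 16)),
         dir = c(1, 0.05, 0.1), ra = 4, rb = 4, socket_k = 2000,
         capsule_scale = 3))

  # named ligament band attachments (origin -> [beads] -> insertion)
  att <- list()
  add <- function(name, group, structure, index, ob, op, ib, ip, beads = list()) {
    att[[length(att) + 1]] <<- list(
      name = name, group = group, structure = structure, index = index,
      origin = list(bone = ob, p = op), insertion = list(bone = ib, p = ip),
      beads = beads)
  }
  # the spring (calcaneonavicular) ligament portions form the hammock the
  # talar head rests on: each band runs from the sustentaculum to the
  # navicular through a bead on the plantar-medial talar head, so talar
  # head depression and medial deviation load these bands directly
  add("spring_superomedial", "spring", "superomedial_spring", 1,
      "calcaneus", c(70, 44, -10), "navicular", c(98, 44, -14),
      beads = list(list(bone = "talus", p = c(86, 38, -19), radius = 3)))
  add("spring_inferomedial", "spring", "inferomedial_spring", 1,
      "calcaneus", c(73, 41, -6), "navicular", c(100, 41, -9),
      beads = list(list(bone = "talus", p = c(87, 37, -15), radius = 3)))
  add("talocalcaneal_interosseous", "interosseous", "talocalcaneal_interosseus",
      1, "talus", c(62, 54, 0), "calcaneus", c(62, 44, 0))
  add("deltoid_deep", "deltoid", "deep_deltoid", 1,
      "tibfib", c(58, 62, -20), "talus", c(64, 54, -10))
  add("deltoid_superficial_anterior", "deltoid", "anterior_superficial_deltoid",
      1, "tibfib", c(60, 64, -20), "navicular", c(98, 45, -14))
  add("deltoid_superficial_posterior", "deltoid", "posterior_superficial_deltoid",
      1, "tibfib", c(56, 60, -20), "calcaneus", c(68, 44, -10))

  # plantar fascia: 5 bands, medial -> lateral, calcaneal origin, windlass
  # bead under each metatarsal head, insertion at the toe base
  pf_rays <- c("ray1", "ray2", "ray3", "ray4", "ray5")
  pf_origin_z <- c(-6, -3, 0, 3, 6)
  heads <- rbind(c(185, 7, -30), c(191, 7, -12), c(187, 7, 0),
                 c(179, 7, 11), c(170, 7, 21))
  toes <- rbind(c(207, 8, -31), c(213, 8, -12), c(209, 8, 1),
                c(201, 8, 12), c(192, 8, 22))
  for (i in 1:5) {
    add(sprintf("plantar_fascia_%d", i), "plantar_fascia", "plantar_fascia", i,
        "calcaneus", c(20, 10, pf_origin_z[i]), pf_rays[i], toes[i, ],
        beads = list(list(bone = pf_rays[i], p = heads[i, ], radius = 3)))
  }

  # long plantar ligament: 8 bands medial -> lateral from the plantar
  # calcaneus to the metatarsal bases; lateral bands wrap the cuboid ridge
  lp_origin_z <- c(-6, -2, 2, 5, 8, 11, 14, 17)
  lp_ray <- c("ray1", "ray2", "ray2", "ray3", "ray3", "ray4", "ray4", "ray5")
  lp_ins <- rbind(c(132, 30, -14), c(134, 28, -6), c(134, 28, -2),
                  c(132, 26, 2), c(132, 26, 6), c(128, 22, 9),
                  c(128, 22, 13), c(122, 20, 17))
  for (i in 1:8) {
    beads <- if (i >= 4)
      list(list(bone = "cuboid", p = c(110, 14, lp_origin_z[i] + 2), radius = 3))
    else list()
    add(sprintf("long_plantar_%d", i), "long_plantar", "long_and_short_plantar",
        i, "calcaneus", c(50, 16, lp_origin_z[i]), lp_ray[i], lp_ins[i, ],
        beads = beads)
  }
  add("short_plantar", "short_plantar", "long_and_short_plantar", 1,
      "calcaneus", c(68, 18, 10), "cuboid", c(100, 18, 12))

  for (i in 1:3) {
    add(sprintf("plantar_metatarsocuneiform_%d", i), "plantar_metatarsocuneiform",
        "plantar_metatarsocuneiform", i, "cuneiforms",
        c(120, 32, c(-10, -2, 4)[i]), sprintf("ray%d", i),
        rbind(c(132, 30, -14), c(134, 28, -4), c(132, 26, 4))[i, ])
  }
  add("plantar_naviculocuneiform", "plantar_naviculocuneiform",
      "plantar_naviculocuneiform", 1, "navicular", c(102, 38, -6),
      "cuneiforms", c(118, 32, -6))

  # transverse forefoot ties: deep transverse metatarsal ligaments between
  # adjacent metatarsal heads and interosseous ligaments between adjacent
  # metatarsal bases; they bind the five rays into a forefoot unit
  head_pl <- rbind(c(185, 13, -30), c(191, 12, -12), c(187, 11, 0),
                   c(179, 10, 11), c(170, 10, 21))
  base_pl <- rbind(c(134, 34, -14), c(136, 32, -4), c(134, 30, 4),
                   c(130, 25, 11), c(124, 22, 17))
  for (i in 1:4) {
    add(sprintf("transverse_metatarsal_%d", i), "transverse_metatarsal",
        "generic", i, sprintf("ray%d", i), head_pl[i, ],
        sprintf("ray%d", i + 1), head_pl[i + 1, ])
    add(sprintf("intermetatarsal_base_%d", i), "intermetatarsal_base",
        "generic", i, sprintf("ray%d", i), base_pl[i, ],
        sprintf("ray%d", i + 1), base_pl[i + 1, ])
  }
  add("cuboideonavicular", "cuboideonavicular", "generic", 1,
      "navicular", c(106, 40, 0), "cuboid", c(112, 30, 8))

  list(landmarks = lm, ground = ground, joints = joints, attachments = att)
}

#' Generate a synthetic foot skeleton
#'
#' Builds a parametric, neutrally aligned foot skeleton: eleven rigid bone
#' units (tibia+fibula merged; each ray's phalanges merged into its
#' metatarsal), named landmarks for the six radiographic angle measures,
#' ground and joint contact spheres, and the ligament attachment map.
#' All randomness is a small uniform landmark jitter controlled by `seed`;
#' the same `(params, seed)` always yields a bit-identical skeleton.
#'
#' @param params [anatomy_params()] set.
#' @param seed integer generation seed.
#' @return object of class `pedmech_skeleton`.
#' @export
build_skeleton <- function(params = anatomy_params(), seed = 0) {
  if (!inherits(params, "pedmech_anatomy_params"))
    params <- do.call(anatomy_params, as.list(params))
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  seed <- as.integer(seed)

  tpl <- foot_template(params$hindfoot_valgus_deg)
  s <- params$foot_length / 250
  a <- params$arch_height_fraction / 0.18

  # scale: x,z with foot length; arch-bearing y values with arch fraction
  arch_bones <- c("talus", "navicular", "cuboid", "cuneiforms")
  scale_pt <- function(p, bone) {
    y <- p[2]
    if (bone %in% arch_bones) y <- y * a
    if (bone %in% paste0("ray", 1:5) && p[1] < 140) y <- y * a  # ray bases
    if (bone == "calcaneus" && p[1] > 40) y <- y * a            # anterior calc
    c(p[1] * s, y, p[3] * s)
  }

  # deterministic jitter stream (isolated from the caller's RNG state)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  jit <- function(p) p + stats::runif(3, -params$jitter_mm, params$jitter_mm)

  lmw <- lapply(names(tpl$landmarks), function(b) {
    m <- tpl$landmarks[[b]]
    out <- t(apply(m, 1, function(p) jit(scale_pt(p, b))))
    rownames(out) <- rownames(m)
    out
  })
  names(lmw) <- names(tpl$landmarks)

  g <- tpl$ground
  g$x <- g$x * s
  g$z <- g$z * s
  gj <- matrix(stats::runif(2 * nrow(g), -params$jitter_mm, params$jitter_mm),
               ncol = 2)
  g$x <- g$x + gj[, 1]
  g$z <- g$z + gj[, 2]
  g$y <- g$radius  # seat every ground sphere exactly on the plane

  # each joint becomes one "socket" pair at the patch centre - the
  # congruent articular surfaces and the short deep binding ligaments of
  # the tarsus, modeled as a smooth ball joint (vector penalty on the
  # relative displacement of the shared articulation centre) - plus
  # unilateral (compression-only) facet-edge pairs that let compression
  # carry joint torque about that centre
  joints <- list()
  for (j in tpl$joints) {
    u <- j$dir / sqrt(sum(j$dir^2))
    udirs <- if (!is.null(j$dirs))
      lapply(j$dirs, function(d) d / sqrt(sum(d^2)))
    else rep(list(u), length(j$a))
    apts <- lapply(j$a, function(p) jit(scale_pt(p, j$bone_a)))
    if (!identical(j$socket, FALSE)) {
      spts <- if (!is.null(j$socket_pts)) {
        lapply(j$socket_pts, function(p) jit(scale_pt(p, j$bone_a)))
      } else {
        list(colMeans(do.call(rbind, apts)) + (j$ra + j$rb) / 2 * u)
      }
      for (si in seq_along(spts)) {
        joints[[length(joints) + 1]] <- list(
          name = if (length(spts) > 1)
            sprintf("%s_socket_%d", j$name, si)
          else sprintf("%s_socket", j$name),
          joint = j$name,
          bone_a = j$bone_a, a = spts[[si]], ra = 0,
          bone_b = j$bone_b, b = spts[[si]], rb = 0,
          dir = u, bilateral = TRUE,
          socket_k = if (is.null(j$socket_k)) 500 else j$socket_k)
      }
    }
    if (length(apts) > 1) {
      # clearance: the cartilage-covered facet periphery engages only near
      # the end of physiologic rotation, so ligaments govern the mid-range
      # and the edges act as articular stops; socketless joints articulate
      # on their facet points directly (zero clearance)
      clr <- if (is.null(j$clearance)) 1 else j$clearance
      clrs <- if (is.null(j$clearances)) rep(clr, length(apts)) else
        j$clearances
      for (k in seq_along(apts)) {
        joints[[length(joints) + 1]] <- list(
          name = sprintf("%s_%d", j$name, k), joint = j$name,
          bone_a = j$bone_a, a = apts[[k]], ra = j$ra,
          bone_b = j$bone_b,
          b = apts[[k]] + (j$ra + j$rb + clrs[k]) * udirs[[k]], rb = j$rb,
          dir = udirs[[k]], bilateral = FALSE)
      }
    }
  }

  atts <- lapply(tpl$attachments, function(r) {
    r$origin$p <- jit(scale_pt(r$origin$p, r$origin$bone))
    r$insertion$p <- jit(scale_pt(r$insertion$p, r$insertion$bone))
    r$beads <- lapply(r$beads, function(bd) {
      bd$p <- jit(scale_pt(bd$p, bd$bone))
      bd
    })
    r
  })

  # generic per-joint capsular stabilizer bands. Tension-only fibres only
  # restrain motions that stretch them at first order, so each joint gets a
  # capsule of nine fibres: three axial fibres around the contact patch
  # (separation and tilt) and two counter-wound sets of three oblique
  # fibres (shear and axial rotation, either sense) - the crossed-fibre
  # architecture of real joint capsules. They carry the field-average
  # stiffness (see pathology module).
  for (jn in unique(vapply(joints, function(j) j$joint, ""))) {
    prs <- joints[vapply(joints, function(j) identical(j$joint, jn), TRUE)]
    mid <- colMeans(do.call(rbind, lapply(prs, function(j) (j$a + j$b) / 2)))
    u <- prs[[1]]$dir
    t1 <- crossprod3(u, c(0, 0, 1))
    if (sqrt(sum(t1^2)) < 0.3) t1 <- crossprod3(u, c(1, 0, 0))
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- crossprod3(u, t1)
    jtpl <- tpl$joints[[which(vapply(tpl$joints, function(x)
      identical(x$name, jn), TRUE))]]
    style <- jtpl$capsule
    cscale <- if (is.null(jtpl$capsule_scale)) 1 else jtpl$capsule_scale
    tang <- function(ang) 10 * (cos(ang) * t1 + sin(ang) * t2)
    idx <- 0
    addcap <- function(pa, pb) {
      idx <<- idx + 1
      atts[[length(atts) + 1]] <<- list(
        name = sprintf("capsule_%s_%d", jn, idx),
        group = sprintf("capsule_%s", jn), structure = "capsule",
        index = idx, k_scale = cscale,
        origin = list(bone = prs[[1]]$bone_a, p = pa),
        insertion = list(bone = prs[[1]]$bone_b, p = pb),
        beads = list())
    }
    for (k in 0:2) {
      a0 <- 2 * pi * k / 3 + pi / 6
      a1 <- 2 * pi * (k + 1) / 3 + pi / 6
      addcap(mid + tang(a0) - 6 * u, mid + tang(a0) + 6 * u)   # axial
      if (!identical(style, "axial")) {
        addcap(mid + tang(a0) - 4 * u, mid + tang(a1) + 4 * u) # wound +
        addcap(mid + tang(a1) - 4 * u, mid + tang(a0) + 4 * u) # wound -
      }
    }
  }

  # handedness: mirror the medial-lateral axis
  if (params$handedness == "left") {
    flipz <- function(p) p * c(1, 1, -1)
    lmw <- lapply(lmw, function(m) {
      m[, 3] <- -m[, 3]
      m
    })
    g$z <- -g$z
    joints <- lapply(joints, function(j) {
      j$a <- flipz(j$a); j$b <- flipz(j$b); j
    })
    atts <- lapply(atts, function(r) {
      r$origin$p <- flipz(r$origin$p)
      r$insertion$p <- flipz(r$insertion$p)
      r$beads <- lapply(r$beads, function(bd) { bd$p <- flipz(bd$p); bd })
      r
    })
  }

  # pack bones: local frames at per-bone centroids, identity orientation
  bones <- list()
  for (b in BONE_UNITS) {
    pts <- lmw[[b]]
    gb <- g[g$bone == b, , drop = FALSE]
    allpts <- rbind(pts, as.matrix(gb[, c("x", "y", "z")]))
    ctr <- colMeans(allpts)
    bones[[b]] <- structure(list(
      name = b, fusion_group = b,
      reference_pose = pose(position = ctr),
      landmarks = sweep(pts, 2, ctr),
      ground_contacts = if (nrow(gb)) data.frame(
        name = gb$name,
        x = gb$x - ctr[1], y = gb$y - ctr[2], z = gb$z - ctr[3],
        radius = gb$radius, region = gb$region, stringsAsFactors = FALSE)
      else NULL
    ), class = "pedmech_bone")
  }
  to_local <- function(bone, p) p - bones[[bone]]$reference_pose$position
  joints <- lapply(joints, function(j) {
    j$a <- to_local(j$bone_a, j$a)
    j$b <- to_local(j$bone_b, j$b)
    j
  })
  atts <- lapply(atts, function(r) {
    r$origin$p <- to_local(r$origin$bone, r$origin$p)
    r$insertion$p <- to_local(r$insertion$bone, r$insertion$p)
    r$beads <- lapply(r$beads, function(bd) {
      bd$p <- to_local(bd$bone, bd$p)
      bd
    })
    r
  })

  skel <- structure(list(
    bones = bones, joints = joints, attachments = atts,
    ground_height = 0, handedness = params$handedness,
    generation_seed = seed, params = params
  ), class = "pedmech_skeleton")
  validate_skeleton(skel)
  skel
}

#' Validate skeleton invariants
#'
#' Checks bone-unit completeness, landmark name uniqueness, positive contact
#' radii, presence of all landmarks the measurement suite needs, and that no
#' ground contact sphere penetrates the ground by more than 0.1 mm in the
#' neutral pose.
#'
#' @param skeleton a `pedmech_skeleton`.
#' @return the skeleton, invisibly; errors describe the violated invariant.
#' @export
validate_skeleton <- function(skeleton) {
  stopifnot(inherits(skeleton, "pedmech_skeleton"))
  missing_units <- setdiff(BONE_UNITS, names(skeleton$bones))
  if (length(missing_units))
    stop("skeleton missing bone units: ", paste(missing_units, collapse = ", "))
  for (b in skeleton$bones) {
    if (anyDuplicated(rownames(b$landmarks)))
      stop("duplicate landmark names on bone ", b$name)
    if (!is.null(b$ground_contacts) && any(b$ground_contacts$radius <= 0))
      stop("non-positive contact radius on bone ", b$name)
  }
  for (b in names(REQUIRED_LANDMARKS)) {
    miss <- setdiff(REQUIRED_LANDMARKS[[b]],
                    rownames(skeleton$bones[[b]]$landmarks))
    if (length(miss))
      stop("bone ", b, " missing required landmark(s): ",
           paste(miss, collapse = ", "))
  }
  for (b in skeleton$bones) {
    gc <- b$ground_contacts
    if (is.null(gc)) next
    yw <- gc$y + b$reference_pose$position[2]
    pen <- gc$radius - (yw - skeleton$ground_height)
    if (any(pen > 0.1))
      stop("ground contact penetrates the ground in the neutral pose on bone ",
           b$name)
  }
  invisible(skeleton)
}

#' Neutral world coordinates of a bone's landmarks
#' @param skeleton a `pedmech_skeleton`.
#' @param bone bone unit name.
#' @return matrix of world coordinates (neutral pose).
#' @export
bone_landmarks_world <- function(skeleton, bone) {
  b <- skeleton$bones[[bone]]
  if (is.null(b)) stop("unknown bone unit: ", bone)
  pose_apply(b$reference_pose, b$landmarks)
}

#' World position of one landmark under a pose map
#'
#' @param skeleton a `pedmech_skeleton`.
#' @param bone bone unit name.
#' @param name landmark name.
#' @param poses pose map as returned by the equilibrium solver (per fusion
#'   group: rotation, translation, origin); `NULL` means the neutral pose.
#' @return numeric length-3 world position, mm.
#' @export
landmark_world <- function(skeleton, bone, name, poses = NULL) {
  b <- skeleton$bones[[bone]]
  if (is.null(b)) stop("unknown bone unit: ", bone)
  if (!name %in% rownames(b$landmarks))
    stop("bone ", bone, " has no landmark '", name, "'")
  x0 <- b$landmarks[name, ] + b$reference_pose$position
  transform_point(x0, poses, b$fusion_group)
}

# apply the pose map of one fusion group to a neutral world point
transform_point <- function(x0, poses, group) {
  if (is.null(poses)) return(x0)
  pg <- poses[[group]]
  if (is.null(pg)) stop("pose map missing fusion group '", group, "'")
  as.numeric(pg$origin + pg$t + pg$R %*% (x0 - pg$origin))
}

#' Neutral (identity) pose map for a skeleton
#' @param skeleton a `pedmech_skeleton`.
#' @return named list per fusion group with identity rotation, zero
#'   translation, and the group frame origin.
#' @export
neutral_poses <- function(skeleton) {
  groups <- unique(vapply(skeleton$bones, function(b) b$fusion_group, ""))
  out <- lapply(groups, function(g) {
    pts <- do.call(rbind, lapply(skeleton$bones, function(b) {
      if (b$fusion_group == g)
        pose_apply(b$reference_pose, b$landmarks)
      else NULL
    }))
    list(R = diag(3), t = c(0, 0, 0), origin = colMeans(pts))
  })
  names(out) <- groups
  out
}

#' Ligament attachment table
#'
#' Returns the attachment records of every ligament band in the skeleton:
#' the mandatory named structures (spring ligament portions, talocalcaneal
#' interosseous, 5-band plantar fascia, 8-band long plantar, short plantar,
#' plantar metatarsocuneiform and naviculocuneiform, the three deltoid
#' portions) plus the generic per-joint capsular stabilizers that bound the
#' equilibrium.
#'
#' @param skeleton a `pedmech_skeleton`.
#' @return data.frame with one row per band (name, group, structure, index,
#'   origin/insertion bone and local coordinates, bead count) and the full
#'   records in attribute `"records"`.
#' @export
attachment_map <- function(skeleton) {
  stopifnot(inherits(skeleton, "pedmech_skeleton"))
  recs <- skeleton$attachments
  for (r in recs) {
    for (side in c("origin", "insertion")) {
      if (is.null(skeleton$bones[[r[[side]]$bone]]))
        stop("band '", r$name, "' references missing bone ", r[[side]]$bone)
    }
  }
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(name = r$name, group = r$group, structure = r$structure,
               index = as.integer(r$index),
               origin_bone = r$origin$bone,
               ox = r$origin$p[1], oy = r$origin$p[2], oz = r$origin$p[3],
               insertion_bone = r$insertion$bone,
               ix = r$insertion$p[1], iy = r$insertion$p[2],
               iz = r$insertion$p[3],
               n_beads = length(r$beads), stringsAsFactors = FALSE)
  }))
  attr(df, "records") <- recs
  df
}

#' @export
print.pedmech_skeleton <- function(x, ...) {
  cat("pedmech skeleton:", length(x$bones), "bone units,",
      length(x$attachments), "ligament bands,",
      length(x$joints), "joint contacts\n")
  cat("  handedness:", x$handedness,
      " seed:", x$generation_seed,
      " foot length:", x$params$foot_length, "mm\n")
  invisible(x)
}
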