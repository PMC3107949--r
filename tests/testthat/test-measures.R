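# Radiographic angle oracles on constructed landmark sets, strain table
# shape/order, and report assembly.

# a skeleton whose measurement landmarks are overwritten with constructed
# world coordinates (local frame == world frame at centroid offset)
constructed_skeleton <- function(edits) {
  sk <- fixture_skeleton()
  for (bone in names(edits)) {
    b <- sk$bones[[bone]]
    for (nm in rownames(edits[[bone]])) {
      b$landmarks[nm, ] <- edits[[bone]][nm, ] - b$reference_pose$position
    }
    sk$bones[[bone]] <- b
  }
  sk
}

test_that("lateral-view angles recover constructed in-plane angles", {
  # calcaneal inferior border at 20 deg pitch -> L_CP = 20
  sk <- constructed_skeleton(list(
    calcaneus = rbind(calc_inf_post = c(0, 30, 5),
                      calc_inf_ant = c(0, 30, 5) +
                        50 * c(cos(20 * pi / 180), sin(20 * pi / 180), 0))))
  expect_equal(unname(lateral_angles(NULL, sk)["L_CP"]), 20,
               tolerance = 1e-6)

  # collinear talar and first-metatarsal axes -> L_T1MT = 0
  sk2 <- constructed_skeleton(list(
    talus = rbind(talar_axis_post = c(50, 60, 0),
                  talar_axis_ant = c(90, 50, 0)),
    ray1 = rbind(mt1_axis_prox = c(120, 42.5, 0),
                 mt1_axis_dist = c(160, 32.5, 0))))
  expect_equal(unname(lateral_angles(NULL, sk2)["L_T1MT"]), 0,
               tolerance = 1e-6)

  # talar axis pitched 40 deg below the calcaneal axis -> L_TC = 40
  sk3 <- constructed_skeleton(list(
    talus = rbind(talar_axis_post = c(50, 60, 0),
                  talar_axis_ant = c(50, 60, 0) +
                    40 * c(cos(-20 * pi / 180), sin(-20 * pi / 180), 0)),
    calcaneus = rbind(calc_axis_post = c(10, 30, 0),
                      calc_axis_ant = c(10, 30, 0) +
                        60 * c(cos(20 * pi / 180), sin(20 * pi / 180), 0))))
  expect_equal(unname(lateral_angles(NULL, sk3)["L_TC"]), 40,
               tolerance = 1e-6)

  # plantar apex (talus steeper than metatarsal) -> L_T1MT < 0
  sk4 <- constructed_skeleton(list(
    talus = rbind(talar_axis_post = c(50, 60, 0),
                  talar_axis_ant = c(90, 40, 0)),
    ray1 = rbind(mt1_axis_prox = c(120, 40, 0),
                 mt1_axis_dist = c(160, 35, 0))))
  expect_lt(unname(lateral_angles(NULL, sk4)["L_T1MT"]), 0)
})

test_that("raised-AP angles recover constructed in-projection rotations", {
  n <- cos(70 * pi / 180) * c(1, 0, 0) + sin(70 * pi / 180) * c(0, 1, 0)
  n <- n / sqrt(sum(n^2))
  tal <- c(40, -15, -10)
  base <- c(50, 60, 0)

  # identical axes -> AP_T1MT = 0
  sk <- constructed_skeleton(list(
    talus = rbind(talar_axis_post = base, talar_axis_ant = base + tal),
    ray1 = rbind(mt1_axis_prox = c(120, 40, 0),
                 mt1_axis_dist = c(120, 40, 0) + tal)))
  expect_equal(unname(ap_angles(NULL, sk)["AP_T1MT"]), 0, tolerance = 1e-6)

  # a pure in-projection rotation of 7.2 deg toward medial -> +7.2
  rot_about <- function(v, axis, ang) {
    as.numeric(rot_exp(axis / sqrt(sum(axis^2)) * ang * pi / 180) %*% v)
  }
  mt1_adducted <- rot_about(tal, n, 7.2)   # +n rotation moves the tip medial
  sk5 <- constructed_skeleton(list(
    talus = rbind(talar_axis_post = base, talar_axis_ant = base + tal),
    ray1 = rbind(mt1_axis_prox = c(120, 40, 0),
                 mt1_axis_dist = c(120, 40, 0) + mt1_adducted)))
  a4 <- unname(ap_angles(NULL, sk5)["AP_T1MT"])
  expect_equal(abs(a4), 7.2, tolerance = 1e-6)
  expect_gt(a4, 0)  # medial deviation of the metatarsal = adduction = positive

  # navicular chord perpendicular to the talar axis -> AP_TN = 0
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  chord <- cross3(n, tal)                # in-plane, perpendicular to tal
  chord <- chord / sqrt(sum(chord^2)) * 20
  sk6 <- constructed_skeleton(list(
    talus = rbind(talar_axis_post = base, talar_axis_ant = base + tal),
    navicular = rbind(nav_chord_med = c(100, 45, -10),
                      nav_chord_lat = c(100, 45, -10) + chord)))
  expect_equal(unname(ap_angles(NULL, sk6)["AP_TN"]), 0, tolerance = 1e-6)
})

test_that("hindfoot angle follows the lateral-aspect convention", {
  # vertical bisection -> 90
  sk <- constructed_skeleton(list(
    calcaneus = rbind(calc_bisect_inf = c(18, 10, 0),
                      calc_bisect_sup = c(18, 40, 0))))
  expect_equal(unname(hindfoot_angle(NULL, sk)), 90, tolerance = 1e-6)

  # top tipped 3.4 deg medially (eversion / valgus) -> 93.4
  skv <- constructed_skeleton(list(
    calcaneus = rbind(calc_bisect_inf = c(18, 10, 0),
                      calc_bisect_sup = c(18, 10, 0) +
                        30 * c(0, cos(3.4 * pi / 180),
                               -sin(3.4 * pi / 180)))))
  expect_equal(unname(hindfoot_angle(NULL, skv)), 93.4, tolerance = 1e-6)

  # top tipped 2.3 deg laterally (inversion / varus) -> 87.7
  skr <- constructed_skeleton(list(
    calcaneus = rbind(calc_bisect_inf = c(18, 10, 0),
                      calc_bisect_sup = c(18, 10, 0) +
                        30 * c(0, cos(2.3 * pi / 180),
                               sin(2.3 * pi / 180)))))
  expect_equal(unname(hindfoot_angle(NULL, skr)), 87.7, tolerance = 1e-6)
})

test_that("all six angles are invariant under a global translation", {
  sk <- fixture_skeleton()
  poses <- neutral_poses(sk)
  shifted <- lapply(poses, function(p) { p$t <- c(14, 0, -8); p })
  expect_equal(angle_set(shifted, sk), angle_set(NULL, sk), tolerance = 1e-9)
})

test_that("strain tables have the published shape and ordering", {
  sk <- fixture_skeleton()
  bands <- make_bands(sk, in_situ_strains(0))
  ref <- vapply(bands, function(b) path_length(b, NULL, sk), 0)
  names(ref) <- vapply(bands, function(b) b$name, "")
  fake <- list(poses = NULL, converged = TRUE)
  st <- strain_tables(fake, bands, ref, sk)
  expect_length(st$long_plantar, 8)
  expect_length(st$plantar_fascia, 5)
  expect_identical(names(st$long_plantar)[1], "long_plantar_1")
  expect_identical(names(st$long_plantar)[8], "long_plantar_8")
  # medial -> lateral ordering of the attachments (right foot: z increasing)
  oz <- vapply(bands[match(names(st$long_plantar),
                           vapply(bands, function(b) b$name, ""))],
               function(b) b$origin$p[3], 0)
  expect_true(all(diff(oz) > 0))
  # loaded pose == resting pose -> all zeros
  expect_equal(unname(st$long_plantar), rep(0, 8), tolerance = 1e-9)
  expect_equal(unname(st$plantar_fascia), rep(0, 5), tolerance = 1e-9)
})

test_that("measurement report serializes losslessly", {
  m <- structure(list(
    angles = c(L_T1MT = 0.5123456789012, L_TC = 39.4, L_CP = 16.6,
               AP_T1MT = 7.2, AP_TN = -7.0, hindfoot = 93.4),
    long_plantar_strains = setNames(seq(1.0, 1.7, by = 0.1),
                                    paste0("long_plantar_", 1:8)),
    plantar_fascia_strains = setNames(c(3.9, 2.1, 2.7, 2.7, 3.2),
                                      paste0("plantar_fascia_", 1:5)),
    calcaneocuboid_force = 123.456789,
    plantar_loads = c(ray1 = 116, ray2 = 8, ray3 = 40, ray4 = 24,
                      ray5 = 61, calcaneus = 428),
    scenario = list(name = "normal")), class = "pedmech_measures")
  f <- tempfile(fileext = ".json")
  measures_to_json(m, f)
  back <- measures_from_json(f)
  expect_identical(back$angles, m$angles)
  expect_identical(back$long_plantar_strains, m$long_plantar_strains)
  expect_identical(back$calcaneocuboid_force, m$calcaneocuboid_force)
  expect_identical(back$plantar_loads, m$plantar_loads)
})
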