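# Virtual osteotomies: rigid-motion exactness, wedge trigonometry,
# composition rules.

all_landmarks_world <- function(sk) {
  do.call(rbind, lapply(names(sk$bones), function(b) {
    m <- bone_landmarks_world(sk, b)
    rownames(m) <- paste(b, rownames(m), sep = ".")
    m
  }))
}

test_that("wedge hinge angle follows arctan(width / depth)", {
  expect_equal(wedge_hinge_angle(10, 25), atan2(10, 25) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(wedge_hinge_angle(10, 25), 21.80141, tolerance = 1e-5)
  expect_equal(wedge_hinge_angle(0, 25), 0)
})

test_that("MCO translates the tuberosity fragment medially, rigidly", {
  sk <- fixture_skeleton()
  lm0 <- all_landmarks_world(sk)

  ident <- apply_mco(sk, osteotomy_params(mco_offset = 0))
  expect_equal(all_landmarks_world(ident), lm0, tolerance = 1e-12)

  post <- apply_mco(sk, osteotomy_params(mco_offset = 10))
  lm1 <- all_landmarks_world(post)
  # the Achilles insertion moves exactly 10 mm medially (right foot: -z)
  expect_equal(unname(lm1["calcaneus.achilles_insertion", 3] -
                        lm0["calcaneus.achilles_insertion", 3]), -10)
  expect_equal(lm1["calcaneus.achilles_insertion", 1:2],
               lm0["calcaneus.achilles_insertion", 1:2])
  # fragment internal distances are preserved to 1e-9
  frag <- c("calcaneus.achilles_insertion", "calcaneus.calc_bisect_sup",
            "calcaneus.calc_bisect_inf")
  d0 <- dist(lm0[frag, ]); d1 <- dist(lm1[frag, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  # nothing outside the calcaneus moves; the articular surface stays
  others <- setdiff(rownames(lm0), rownames(lm0)[startsWith(rownames(lm0),
                                                            "calcaneus")])
  expect_equal(lm1[others, ], lm0[others, ], tolerance = 1e-12)
  expect_equal(lm1["calcaneus.cc_face_center", ],
               lm0["calcaneus.cc_face_center", ], tolerance = 1e-12)
})

test_that("two 5 mm MCO translations equal one 10 mm translation", {
  sk <- fixture_skeleton()
  twice <- apply_mco(apply_mco(sk, osteotomy_params(mco_offset = 5)),
                     osteotomy_params(mco_offset = 5))
  once <- apply_mco(sk, osteotomy_params(mco_offset = 10))
  expect_equal(all_landmarks_world(twice), all_landmarks_world(once),
               tolerance = 1e-9)
})

test_that("Evans rotates the anterior fragment about the medial hinge", {
  sk <- fixture_skeleton()
  lm0 <- all_landmarks_world(sk)
  ident <- apply_evans(sk, osteotomy_params(wedge_width = 0))
  expect_equal(all_landmarks_world(ident), lm0, tolerance = 1e-12)

  post <- apply_evans(sk)
  lm1 <- all_landmarks_world(post)
  # the articular face moves, the posterior body does not
  expect_gt(sqrt(sum((lm1["calcaneus.cc_face_center", ] -
                        lm0["calcaneus.cc_face_center", ])^2)), 1)
  expect_equal(lm1["calcaneus.achilles_insertion", ],
               lm0["calcaneus.achilles_insertion", ], tolerance = 1e-12)
  # the rotation advances the lateral side of the cut (internal rotation)
  expect_gt(lm1["calcaneus.cc_face_center", 1] -
              lm0["calcaneus.cc_face_center", 1], 0)
})

test_that("osteotomy fragments move rigidly and attachments ride along", {
  sk <- fixture_skeleton()
  post <- apply_evans(sk)
  # capsule attachments at the calcaneocuboid joint sit on the fragment:
  # identical local offsets relative to the rotated articular face
  rec0 <- sk$attachments[[which(vapply(sk$attachments, function(r)
    r$name == "capsule_calcaneocuboid_1", TRUE))]]
  rec1 <- post$attachments[[which(vapply(post$attachments, function(r)
    r$name == "capsule_calcaneocuboid_1", TRUE))]]
  face0 <- sk$bones$calcaneus$landmarks["cc_face_center", ]
  face1 <- post$bones$calcaneus$landmarks["cc_face_center", ]
  expect_equal(sqrt(sum((rec1$origin$p - face1)^2)),
               sqrt(sum((rec0$origin$p - face0)^2)), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(rec1$origin$p, rec0$origin$p)))
})

test_that("CCDA shaves, rotates and fuses the cuboid", {
  sk <- fixture_skeleton()
  dof0 <- attr(degrees_of_freedom(sk), "total")
  expect_identical(dof0, 61L)

  fuse_only <- apply_ccda(sk, osteotomy_params(wedge_width = 0.01,
                                               ccda_resection = 0))
  expect_identical(fuse_only$bones$cuboid$fusion_group, "calcaneus")
  expect_identical(attr(degrees_of_freedom(fuse_only), "total"), 55L)

  post <- apply_ccda(sk)
  expect_identical(post$bones$cuboid$fusion_group, "calcaneus")
  # the articular shave moves only the joint-face landmark; away from it
  # the cuboid moved as one rigid body
  keep <- setdiff(rownames(sk$bones$cuboid$landmarks),
                  "cc_face_center_cuboid")
  lm0 <- bone_landmarks_world(sk, "cuboid")[keep, , drop = FALSE]
  lm1 <- bone_landmarks_world(post, "cuboid")[keep, , drop = FALSE]
  expect_equal(as.numeric(dist(lm1)), as.numeric(dist(lm0)),
               tolerance = 1e-9)
  face0 <- bone_landmarks_world(sk, "cuboid")["cc_face_center_cuboid", ]
  face1 <- bone_landmarks_world(post, "cuboid")["cc_face_center_cuboid", ]
  expect_gt(sqrt(sum((face1 - face0)^2)), 1)  # shaved and rotated
  expect_error(apply_ccda(post), "already fused")
})

test_that("procedure sets validate and compose in canonical order", {
  sk <- fixture_skeleton()
  expect_equal(all_landmarks_world(apply_procedures(sk, character())),
               all_landmarks_world(sk), tolerance = 1e-12)
  expect_error(apply_procedures(sk, c("Evans", "CCDA")), "exclusive")
  expect_error(apply_procedures(sk, "FDL"), "unknown")

  both <- apply_procedures(sk, c("Evans", "MCO"))
  lm0 <- all_landmarks_world(sk)
  lm1 <- all_landmarks_world(both)
  # MCO post-condition holds
  expect_equal(unname(lm1["calcaneus.achilles_insertion", 3] -
                        lm0["calcaneus.achilles_insertion", 3]), -10)
  # Evans post-condition holds simultaneously
  expect_gt(lm1["calcaneus.cc_face_center", 1] -
              lm0["calcaneus.cc_face_center", 1], 0)
})

test_that("handedness mirrors the surgical directions", {
  skL <- build_skeleton(anatomy_params(handedness = "left"), seed = 0)
  lm0 <- bone_landmarks_world(skL, "calcaneus")
  post <- apply_mco(skL)
  lm1 <- bone_landmarks_world(post, "calcaneus")
  # medial for a left foot is +z
  expect_equal(unname(lm1["achilles_insertion", 3] -
                        lm0["achilles_insertion", 3]), 10)
})
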