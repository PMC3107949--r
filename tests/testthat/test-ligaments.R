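# Tension-only band mechanics: path geometry, spring law, calibration.

test_that("path length sums straight segments through via points", {
  b <- plain_band(c(0, 0, 0), c(3, 4, 0))
  expect_equal(path_length(b), 5)

  collinear <- plain_band(c(0, 0, 0), c(10, 0, 0),
    beads = list(list(bone = "a", p = c(4, 0, 0), radius = 2)))
  expect_equal(path_length(collinear), 10)

  corner <- plain_band(c(0, 0, 0), c(10, 10, 0),
    beads = list(list(bone = "a", p = c(10, 0, 0), radius = 2)))
  expect_equal(path_length(corner), 20)

  straight <- sqrt(200)
  expect_gte(path_length(corner), straight)
})

test_that("tension-only spring law: k * max(0, L - L0)", {
  b <- plain_band(c(0, 0, 0), c(21, 0, 0), k = 39, L0 = 20)
  expect_equal(band_tension(b), 39)
  b2 <- plain_band(c(0, 0, 0), c(20, 0, 0), k = 39, L0 = 20)
  expect_equal(band_tension(b2), 0)
  b3 <- plain_band(c(0, 0, 0), c(49, 0, 0), k = 240, L0 = 50)
  expect_equal(band_tension(b3), 0)
})

test_that("engineering strain is relative to the resting length", {
  ref <- c(b = 100)
  expect_equal(band_strain(plain_band(c(0, 0, 0), c(100, 0, 0)), NULL, ref), 0)
  expect_equal(band_strain(plain_band(c(0, 0, 0), c(102.8, 0, 0)), NULL, ref),
               0.028)
  expect_equal(band_strain(plain_band(c(0, 0, 0), c(99, 0, 0)), NULL, ref),
               -0.01)
  expect_error(band_strain(plain_band(c(0, 0, 0), c(1, 0, 0)), NULL,
                           c(other = 1)), "reference length")
})

test_that("rest-length calibration inverts the in-situ strain", {
  sk <- fixture_skeleton()
  b <- plain_band(c(0, 0, 0), c(51, 0, 0))
  cal <- calibrate_rest_lengths(list(b), NULL, in_situ_strains(0.02))[[1]]
  expect_equal(cal$rest_length_L0, 50)
  cal0 <- calibrate_rest_lengths(list(b), NULL, in_situ_strains(0))[[1]]
  expect_equal(cal0$rest_length_L0, 51)

  # round trip on the full band set: neutral strain equals the table entry
  bands <- make_bands(sk, in_situ_strains(0.02))
  for (bd in bands[seq(1, length(bands), by = 7)]) {
    Ln <- path_length(bd, NULL, sk)
    expect_equal((Ln - bd$rest_length_L0) / bd$rest_length_L0, 0.02,
                 tolerance = 1e-9)
  }
})

test_that("spring energy gradient matches the analytic tension", {
  k <- 150; L0 <- 30
  for (L in c(30.5, 33, 40)) {
    b <- plain_band(c(0, 0, 0), c(L, 0, 0), k = k, L0 = L0)
    h <- 1e-6
    bp <- plain_band(c(0, 0, 0), c(L + h, 0, 0), k = k, L0 = L0)
    bm <- plain_band(c(0, 0, 0), c(L - h, 0, 0), k = k, L0 = L0)
    num <- (band_energy(bp) - band_energy(bm)) / (2 * h)
    expect_equal(num, band_tension(b), tolerance = 1e-6 * max(1, num))
  }
})

test_that("energy is non-negative and zero iff slack", {
  slack <- plain_band(c(0, 0, 0), c(10, 0, 0), k = 50, L0 = 12)
  taut <- plain_band(c(0, 0, 0), c(10, 0, 0), k = 50, L0 = 8)
  expect_identical(band_energy(slack), 0)
  expect_gt(band_energy(taut), 0)
})

test_that("bead path length is invariant under joint rigid motion", {
  sk <- fixture_skeleton()
  bands <- make_bands(sk, in_situ_strains(0))
  wrapped <- bands[vapply(bands, function(b) length(b$via_beads) > 0, TRUE)]
  b <- wrapped[[1]]
  R <- rot_exp(c(0.3, -0.2, 0.5))
  tr <- c(12, -4, 7)
  poses <- neutral_poses(sk)
  for (g in names(poses)) {
    poses[[g]]$R <- R
    poses[[g]]$t <- tr + (diag(3) - R) %*% (poses[[g]]$origin - c(0, 0, 0))
    poses[[g]]$t <- as.numeric(tr)
    poses[[g]]$origin <- poses[[g]]$origin  # rotation about each origin differs;
  }
  # apply ONE common world transform: x -> R x + tr, expressed per group
  for (g in names(poses)) {
    o <- poses[[g]]$origin
    poses[[g]]$R <- R
    poses[[g]]$t <- as.numeric(R %*% o + tr - o)
  }
  expect_equal(path_length(b, poses, sk), path_length(b, NULL, sk),
               tolerance = 1e-9)
})

test_that("in-situ strain tables validate and resolve by specificity", {
  expect_error(in_situ_strains(0.5), "0.10")
  tab <- in_situ_strains(0.01, by_structure = c(capsule = 0.02),
                         by_group = c(long_plantar = 0.03),
                         by_band = c(long_plantar_2 = 0.04))
  sk <- fixture_skeleton()
  bands <- make_bands(sk, tab)
  nm <- vapply(bands, function(b) b$name, "")
  get_eps <- function(b) {
    Ln <- path_length(b, NULL, sk)
    (Ln - b$rest_length_L0) / b$rest_length_L0
  }
  expect_equal(get_eps(bands[[match("long_plantar_2", nm)]]), 0.04,
               tolerance = 1e-9)
  expect_equal(get_eps(bands[[match("long_plantar_1", nm)]]), 0.03,
               tolerance = 1e-9)
  expect_equal(get_eps(bands[[match("capsule_tibiotalar_1", nm)]]), 0.02,
               tolerance = 1e-9)
  expect_equal(get_eps(bands[[match("spring_superomedial", nm)]]), 0.01,
               tolerance = 1e-9)
})
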