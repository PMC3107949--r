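# Energy formulation, analytic gradients, contact laws, and equilibrium
# solves on small cases.

test_that("degrees of freedom follow the stated layout", {
  sk <- fixture_skeleton()
  dof <- degrees_of_freedom(sk)
  expect_identical(attr(dof, "total"), 61L)  # 1 (tibia) + 10 x 6
  expect_identical(dof$n_coords[dof$group == "tibfib"], 1L)
  expect_identical(sum(dof$group != "tibfib"), 10L)
  fused <- apply_ccda(sk)
  expect_identical(attr(degrees_of_freedom(fused), "total"), 55L)
})

test_that("the ground penalty is linear in penetration at exponent 1", {
  sys <- toy_contact_system(radius = 10,
                            options = solver_options(penalty_stiffness = 2000,
                                                     tangential_stiffness = 0))
  q <- numeric(6)
  expect_equal(as.numeric(total_potential(q, sys, 0)), 0)
  for (delta in c(0.1, 0.5, 1.2)) {
    q[2] <- -delta  # push the body down
    v <- total_potential(q, sys, 0)
    expect_equal(as.numeric(v), 0.5 * 2000 * delta^2, tolerance = 1e-9)
    # vertical gradient equals minus the penalty force
    expect_equal(attr(v, "gradient")[2], -2000 * delta, tolerance = 1e-9)
  }
  # separation costs nothing
  q[2] <- 2
  expect_equal(as.numeric(total_potential(q, sys, 0)), 0)
})

test_that("the tangential anchor resists footprint shear", {
  sys <- toy_contact_system(options = solver_options(tangential_stiffness = 50))
  q <- numeric(6); q[1] <- 0.8; q[3] <- -0.4
  v <- total_potential(q, sys, 0)
  expect_equal(as.numeric(v), 0.5 * 50 * (0.8^2 + 0.4^2), tolerance = 1e-9)
  expect_equal(attr(v, "gradient")[1], 50 * 0.8, tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  sk <- fixture_skeleton()
  bands <- make_bands(sk, in_situ_strains(0))
  sys <- build_system(sk, bands)
  nq <- attr(degrees_of_freedom(sk), "total")
  set.seed(11)
  for (case in 1:3) {
    q <- rnorm(nq, 0, c(1, 4, 8)[case])
    v <- total_potential(q, sys, load_fraction = 0.7)
    g <- attr(v, "gradient")
    h <- 1e-5
    idx <- sample.int(nq, 12)  # spot-check a random coordinate subset
    for (j in idx) {
      e <- numeric(nq); e[j] <- h
      num <- (as.numeric(total_potential(q + e, sys, 0.7)) -
                as.numeric(total_potential(q - e, sys, 0.7))) / (2 * h)
      expect_equal(g[j], num, tolerance = 1e-5 * max(1, abs(num)))
    }
  }
})

test_that("zero-load equilibrium is the calibrated neutral pose", {
  sk <- fixture_skeleton()
  bands <- make_bands(sk, in_situ_strains(0))
  res <- solve_equilibrium(sk, bands, load_case(0, 0))
  expect_true(res$converged)
  # strains equal the (zero) in-situ strains
  for (b in bands[seq(1, length(bands), by = 9)]) {
    L <- path_length(b, res$poses, sk)
    expect_equal((L - b$rest_length_L0) / b$rest_length_L0, 0,
                 tolerance = 1e-6)
  }
  # no contact force anywhere
  expect_equal(sum(abs(res$ground_forces$fy)), 0, tolerance = 1e-6)
  expect_true(all(res$band_tensions < 1e-4))
})

test_that("joint contact force is the resultant over declared pairs", {
  fake <- structure(list(
    converged = TRUE,
    joint_forces = data.frame(
      name = c("cc_1", "cc_2", "tn_1"),
      bone_a = c("calcaneus", "calcaneus", "talus"),
      bone_b = c("cuboid", "cuboid", "navicular"),
      bilateral = FALSE,
      fx = c(0, 0, 5), fy = c(30, 30, 0), fz = c(40, -40, 0),
      magnitude = c(50, 50, 5), stringsAsFactors = FALSE)),
    class = "pedmech_equilibrium")
  expect_equal(joint_contact_force(fake, "calcaneus", "cuboid"), 60)
  expect_equal(joint_contact_force(fake, "cuboid", "calcaneus"), 60)
  expect_equal(joint_contact_force(fake, "talus", "navicular"), 5)
  expect_error(joint_contact_force(fake, "talus", "cuboid"),
               "no declared joint contacts")
  fake$converged <- FALSE
  expect_error(joint_contact_force(fake, "calcaneus", "cuboid"), "converged")
})

test_that("region loads sum vertical components and partition the total", {
  fake <- structure(list(
    converged = TRUE,
    ground_forces = data.frame(
      region = c("calcaneus", "ray1", "ray1"),
      fx = c(1, 0, 2), fy = c(428, 60, 56), fz = c(0, 3, 0),
      stringsAsFactors = FALSE)),
    class = "pedmech_equilibrium")
  out <- ground_region_loads(fake)
  expect_equal(unname(out["calcaneus"]), 428)
  expect_equal(unname(out["ray1"]), 116)
  expect_equal(unname(out["ray3"]), 0)
  expect_equal(sum(out), sum(fake$ground_forces$fy))
})

test_that("doubling stiffness and halving load shrinks displacements", {
  sk <- fixture_skeleton()
  soft <- make_bands(sk, in_situ_strains(0), stiffness_scale = 1)
  stiff <- make_bands(sk, in_situ_strains(0), stiffness_scale = 2)
  opts <- solver_options(ramp_steps = 3, tolerance = 1)
  r1 <- solve_equilibrium(sk, soft, load_case(300, 150), opts)
  r2 <- solve_equilibrium(sk, stiff, load_case(150, 75), opts)
  expect_true(r1$converged && r2$converged)
  d1 <- max(vapply(r1$poses, function(p) sqrt(sum(p$t^2)), 0))
  d2 <- max(vapply(r2$poses, function(p) sqrt(sum(p$t^2)), 0))
  expect_lt(d2, d1)
})

test_that("the solver is deterministic for identical inputs", {
  sk <- fixture_skeleton()
  bands <- make_bands(sk)
  opts <- solver_options(ramp_steps = 2, max_restarts = 2, tolerance = 2)
  r1 <- solve_equilibrium(sk, bands, load_case(200, 100), opts)
  r2 <- solve_equilibrium(sk, bands, load_case(200, 100), opts)
  expect_identical(r1$poses, r2$poses)
  expect_identical(r1$band_tensions, r2$band_tensions)
  expect_identical(r1$energy_trace, r2$energy_trace)
})

test_that("non-finite states are rejected with a hard failure", {
  sk <- fixture_skeleton()
  bands <- make_bands(sk)
  sys <- build_system(sk, bands)
  expect_error(total_potential(c(NaN, numeric(60)), sys), "non-finite")
})
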