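# Serialization round trips, configuration loading, manifest, CLI plumbing.

test_that("skeleton JSON round-trips bit-exactly", {
  sk <- fixture_skeleton()
  f <- tempfile(fileext = ".json")
  skeleton_to_json(sk, f)
  back <- skeleton_from_json(f)
  expect_equal(back$bones$talus$landmarks, sk$bones$talus$landmarks,
               tolerance = 0)
  expect_identical(back$handedness, sk$handedness)
  expect_identical(back$generation_seed, sk$generation_seed)
  expect_equal(length(back$attachments), length(sk$attachments))
  i <- 5
  expect_identical(back$attachments[[i]]$name, sk$attachments[[i]]$name)
  expect_equal(back$attachments[[i]]$origin$p, sk$attachments[[i]]$origin$p,
               tolerance = 0)
  # identical measurement results from the round-tripped skeleton
  expect_equal(angle_set(NULL, back), angle_set(NULL, sk), tolerance = 0)
})

test_that("YAML configs expand and validate", {
  f <- tempfile(fileext = ".yaml")
  write_default_config(f, seed = 3)
  cfg <- read_config(f)
  expect_length(cfg, 7)
  expect_identical(cfg$normal$seed, 3)

  f2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(scenarios = list(
    list(name = "bad", condition = "normal", procedures = list("MCO")))), f2)
  expect_error(read_config(f2), "flatfoot")

  f3 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(scenarios = list(
    list(name = "one", condition = "flatfoot", procedures = list("Evans"),
         seed = 1, surgery = list(wedge_width = 8),
         solver = list(ramp_steps = 4)))), f3)
  cfg3 <- read_config(f3)
  expect_identical(cfg3$one$osteotomy$wedge_width, 8)
  expect_identical(cfg3$one$solver$ramp_steps, 4L)
})

test_that("mesh export writes parseable STL and PLY", {
  sk <- fixture_skeleton()
  d <- file.path(tempdir(), "mesh-test")
  files <- export_skeleton_meshes(sk, d)
  stl <- file.path(d, "calcaneus.stl")
  expect_true(file.exists(stl))
  con <- file(stl, "rb")
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  close(con)
  expect_gt(ntri, 0)
  expect_identical(file.size(stl), 84 + 50 * as.numeric(ntri))
  ply <- readLines(file.path(d, "talus.ply"))
  expect_identical(ply[1], "ply")
  nv <- as.integer(sub("element vertex ", "", ply[3]))
  expect_identical(length(ply), 7L + nv)
  unlink(d, recursive = TRUE)
})

test_that("the CLI generates deterministic skeleton files", {
  d1 <- file.path(tempdir(), "cli-a"); d2 <- file.path(tempdir(), "cli-b")
  expect_identical(pedmech_cli(c("generate", "--seed", "4", "--out", d1)), 0L)
  pedmech_cli(c("generate", "--seed", "4", "--out", d2))
  s1 <- unname(tools::md5sum(file.path(d1, "skeleton.json")))
  s2 <- unname(tools::md5sum(file.path(d2, "skeleton.json")))
  expect_identical(s1, s2)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  m <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  expect_true("skeleton.json" %in% names(m$files))
  expect_error(pedmech_cli(c("generate", "--seed", "0", "--out",
                             tempdir(), "--foot-length", "900")),
               "foot_length")
  expect_error(pedmech_cli(c("frobnicate")), "unknown command")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("compare rebuilds a table from report files", {
  d <- file.path(tempdir(), "cli-reports")
  dir.create(d, showWarnings = FALSE)
  mk <- function(nm) structure(list(
    angles = c(L_T1MT = 1, L_TC = 40, L_CP = 16, AP_T1MT = 7, AP_TN = -7,
               hindfoot = 93),
    long_plantar_strains = setNames(rep(1, 8), paste0("long_plantar_", 1:8)),
    plantar_fascia_strains = setNames(rep(2, 5),
                                      paste0("plantar_fascia_", 1:5)),
    calcaneocuboid_force = 500,
    plantar_loads = c(ray1 = 100, ray2 = 10, ray3 = 40, ray4 = 25,
                      ray5 = 60, calcaneus = 430),
    scenario = list(name = nm)), class = "pedmech_measures")
  measures_to_json(mk("normal"), file.path(d, "normal_measures.json"))
  measures_to_json(mk("flatfoot"), file.path(d, "flatfoot_measures.json"))
  pedmech_cli(c("compare", "--results", d))
  expect_true(file.exists(file.path(d, "comparison.csv")))
  tab <- utils::read.csv(file.path(d, "comparison.csv"), row.names = 1,
                         check.names = FALSE)
  expect_identical(ncol(tab), 2L)
  unlink(d, recursive = TRUE)
})
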