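# Shared fixtures: cached skeletons and a minimal hand-built mechanical
# system for direct energy/gradient checks.

.fixture_env <- new.env(parent = emptyenv())

fixture_skeleton <- function(seed = 0, ...) {
  key <- paste0("sk_", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_skeleton(anatomy_params(...), seed = seed)
  .fixture_env[[key]]
}

fixture_bands <- function(seed = 0, in_situ = in_situ_strains(0)) {
  make_bands(fixture_skeleton(seed), in_situ)
}

# a one-body system with a single ground contact sphere (radius r, centre
# height r at rest) and no bands: exposes the contact penalty law directly
toy_contact_system <- function(radius = 10,
                               options = solver_options()) {
  P0 <- rbind(c(0, radius, 0),   # ground contact sphere centre
              c(0, 50, 0))       # load application point (unused, 0 N)
  structure(list(
    groups = "body", dof = structure(
      data.frame(group = "body", n_coords = 6L, offset = 0L,
                 stringsAsFactors = FALSE), total = 6L),
    origins = list(c(0, radius, 0)), gpt = list(1:2),
    P0 = P0, Pg = c(1L, 1L),
    seg_ia = integer(), seg_ib = integer(), seg_band = integer(),
    band_k = numeric(), band_L0 = numeric(), band_names = character(),
    ach_i = 2L, ach_j = 2L, tib_i = 2L,
    gc_idx = 1L, gc_r = radius, gc_region = "calcaneus",
    gc_anchor = matrix(c(0, 0), 1, 2),
    jc_ia = integer(), jc_ib = integer(), jc_rsum = numeric(),
    jc_name = character(), jc_bones = list(), jc_bilateral = logical(),
    jc_k = numeric(), rom = list(),
    loads = load_case(0, 0), options = options, ground_height = 0
  ), class = "pedmech_system")
}

# build a band between explicit fusion-group frame coordinates (no skeleton)
plain_band <- function(origin_p, insertion_p, beads = list(),
                       k = 100, L0 = NA_real_, name = "b") {
  ligament_band(name,
                origin = list(bone = "a", p = origin_p),
                insertion = list(bone = "b", p = insertion_p),
                via_beads = beads, stiffness_k = k, rest_length_L0 = L0)
}
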