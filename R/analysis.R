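# Scenario orchestration and cross-configuration comparisons.
#
# A scenario fully determines one simulation: condition (normal or
# flatfoot), procedure set, anatomy parameters + seed, load case, osteotomy
# parameters and solver options. The default suite is the seven standard
# configurations: normal, flatfoot, and flatfoot treated with MCO, Evans,
# CCDA, Evans+MCO, CCDA+MCO.

#' Scenario configuration
#'
#' @param name scenario label.
#' @param condition `"normal"` or `"flatfoot"`.
#' @param procedures character subset of `c("MCO", "Evans", "CCDA")`;
#'   non-empty sets require `condition = "flatfoot"` (osteotomies are
#'   simulated on the flatfoot model).
#' @param seed anatomy generation seed.
#' @param anatomy an [anatomy_params()] set.
#' @param loads a [load_case()].
#' @param osteotomy an [osteotomy_params()] set.
#' @param solver a [solver_options()] set.
#' @param in_situ an [in_situ_strains()] table.
#' @param stiffness_scale uniform multiplier on all ligament stiffnesses
#'   (robustness analyses).
#' @return object of class `pedmech_scenario`.
#' @export
scenario_config <- function(name, condition = c("normal", "flatfoot"),
                            procedures = character(), seed = 0,
                            anatomy = anatomy_params(), loads = load_case(),
                            osteotomy = osteotomy_params(),
                            solver = solver_options(),
                            in_situ = default_in_situ(),
                            stiffness_scale = 1) {
  condition <- match.arg(condition)
  procedures <- as.character(procedures)
  bad <- setdiff(procedures, c("MCO", "Evans", "CCDA"))
  if (length(bad))
    stop("unknown procedure(s): ", paste(bad, collapse = ", "))
  if (length(procedures) && condition != "flatfoot")
    stop("osteotomies are applied to the flatfoot model; ",
         "set condition = 'flatfoot'")
  if (all(c("Evans", "CCDA") %in% procedures))
    stop("Evans and CCDA are mutually exclusive")
  structure(list(name = name, condition = condition, procedures = procedures,
                 seed = seed, anatomy = anatomy, loads = loads,
                 osteotomy = osteotomy, solver = solver, in_situ = in_situ,
                 stiffness_scale = stiffness_scale),
            class = "pedmech_scenario")
}

#' The seven standard scenario configurations
#'
#' @param seed shared anatomy seed.
#' @param ... further arguments passed to every [scenario_config()] call
#'   (anatomy, solver, stiffness_scale, ...).
#' @return named list of `pedmech_scenario`.
#' @export
default_suite <- function(seed = 0, ...) {
  cfg <- list(
    scenario_config("normal", "normal", character(), seed, ...),
    scenario_config("flatfoot", "flatfoot", character(), seed, ...),
    scenario_config("MCO", "flatfoot", "MCO", seed, ...),
    scenario_config("Evans", "flatfoot", "Evans", seed, ...),
    scenario_config("CCDA", "flatfoot", "CCDA", seed, ...),
    scenario_config("Evans and MCO", "flatfoot", c("Evans", "MCO"), seed, ...),
    scenario_config("CCDA and MCO", "flatfoot", c("CCDA", "MCO"), seed, ...))
  names(cfg) <- vapply(cfg, function(x) x$name, "")
  cfg
}

# update band attachment geometry from a (post-surgery) skeleton while
# keeping stiffness, rest length and damage stage
rebind_bands <- function(bands, skeleton) {
  recs <- skeleton$attachments
  rn <- vapply(recs, function(r) r$name, "")
  lapply(bands, function(b) {
    i <- match(b$name, rn)
    if (is.na(i)) stop("post-operative skeleton lost band '", b$name, "'")
    b$origin <- recs[[i]]$origin
    b$insertion <- recs[[i]]$insertion
    b$via_beads <- recs[[i]]$beads
    b
  })
}

#' Run one scenario
#'
#' Builds the intact anatomy, calibrates the ligament set on the intact
#' neutral pose, applies the flatfoot attenuation and the virtual
#' procedures as configured, solves the unloaded equilibrium (the resting
#' state that anchors strain measurements), solves the loaded equilibrium,
#' and measures.
#'
#' @param config a [scenario_config()].
#' @return list with elements `config`, `skeleton` (post-operative),
#'   `bands`, `unloaded`, `result`, `reference_lengths`, and `measures`
#'   (`NULL` with a warning if the loaded solve fails to converge).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "pedmech_scenario"))
  sk0 <- build_skeleton(config$anatomy, config$seed)
  bands <- make_bands(sk0, config$in_situ, config$stiffness_scale)
  if (config$condition == "flatfoot") bands <- apply_flatfoot(bands)
  # resting-state solves carry a 1 percent seating load so the unloaded
  # foot stays seated on the plate (a free-floating rigid pose would make
  # the resting footprint, and hence the strain reference, ill-defined)
  seat <- load_case(0.01 * config$loads$axial_load,
                    0.01 * config$loads$achilles_load)
  if (length(config$procedures)) {
    # osteotomy continuation: grow the fragment displacement in steps and
    # track the unloaded equilibrium with warm starts, so the surgical
    # pre-stress relaxes along the physical path instead of jumping into a
    # distant energy basin
    op <- config$osteotomy
    unloaded <- NULL
    nstep <- config$solver$continuation_steps
    for (tfrac in seq_len(nstep) / nstep) {
      op_t <- osteotomy_params(
        mco_offset = op$mco_offset * tfrac,
        evans_cut_offset = op$evans_cut_offset,
        wedge_width = op$wedge_width * tfrac,
        wedge_depth = op$wedge_depth,
        ccda_resection = op$ccda_resection * tfrac,
        ccda_trim = op$ccda_trim)
      sk <- apply_procedures(sk0, config$procedures, op_t)
      bands_t <- rebind_bands(bands, sk)
      unloaded <- solve_equilibrium(sk, bands_t, seat, config$solver,
                                    init_poses = unloaded$poses,
                                    anchors = unloaded$ground_footprint,
                                    ramp = is.null(unloaded$poses))
    }
    # the resting footprint is a fixed point: re-seat until the contacts
    # stop sliding against their own anchors
    for (i in 1:4) {
      prev <- unloaded$ground_footprint
      unloaded <- solve_equilibrium(sk, bands_t, seat, config$solver,
                                    init_poses = unloaded$poses,
                                    anchors = prev, ramp = FALSE)
      if (max(abs(unloaded$ground_footprint - prev)) < 0.1) break
    }
    bands <- bands_t
  } else {
    sk <- sk0
    unloaded <- solve_equilibrium(sk, bands, seat, config$solver)
  }
  ref_len <- vapply(bands, function(b)
    path_length(b, unloaded$poses, sk), 0)
  names(ref_len) <- vapply(bands, function(b) b$name, "")

  # the loaded solve anchors the footprint where the unloaded
  # (post-operative resting) equilibrium seated the foot
  result <- solve_equilibrium(sk, bands, config$loads, config$solver,
                              init_poses = unloaded$poses,
                              anchors = unloaded$ground_footprint)
  meas <- NULL
  if (result$converged) {
    meas <- measure_all(result, sk, bands, ref_len, config)
  } else {
    warning("scenario '", config$name, "' did not converge (|grad| = ",
            format(result$gradient_norm), " N)")
  }
  list(config = config, skeleton = sk, bands = bands, unloaded = unloaded,
       result = result, reference_lengths = ref_len, measures = meas)
}

#' Run a scenario suite and assemble the comparison table
#'
#' @param configs list of [scenario_config()] sharing one anatomy seed.
#' @return object of class `pedmech_suite`: per-scenario runs, the measure
#'   comparison table, and a convergence flag per scenario.
#' @export
run_suite <- function(configs) {
  if (!length(configs)) stop("empty scenario list")
  seeds <- vapply(configs, function(c) c$seed, 0)
  if (length(unique(seeds)) != 1)
    stop("all scenarios in a suite must share one anatomy seed")
  runs <- lapply(configs, run_scenario)
  names(runs) <- vapply(configs, function(c) c$name, "")
  structure(list(
    runs = runs,
    table = comparison_table(lapply(runs, `[[`, "measures")),
    converged = vapply(runs, function(r) isTRUE(r$result$converged), TRUE)
  ), class = "pedmech_suite")
}

#' Measurement comparison table
#'
#' One column per scenario, rows for the six angles, the thirteen strain
#' bands, the calcaneocuboid force, and the six plantar loads.
#'
#' @param reports named list of `pedmech_measures` (NULL entries allowed
#'   for unconverged scenarios; their column is NA).
#' @return data.frame.
#' @export
comparison_table <- function(reports) {
  rows <- c(paste0("angle_", c("L_T1MT", "L_TC", "L_CP", "AP_T1MT", "AP_TN",
                               "hindfoot")),
            paste0("strain_long_plantar_", 1:8),
            paste0("strain_plantar_fascia_", 1:5),
            "calcaneocuboid_force",
            paste0("load_", c("ray1", "ray2", "ray3", "ray4", "ray5",
                              "calcaneus")))
  cols <- lapply(reports, function(m) {
    if (is.null(m)) return(rep(NA_real_, length(rows)))
    c(unname(m$angles), unname(m$long_plantar_strains),
      unname(m$plantar_fascia_strains), m$calcaneocuboid_force,
      unname(m$plantar_loads))
  })
  out <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  names(out) <- names(reports)
  rownames(out) <- rows
  out
}

#' @export
print.pedmech_suite <- function(x, ...) {
  cat("pedmech suite:", length(x$runs), "scenarios;",
      sum(x$converged), "converged\n")
  print(round(x$table, 1))
  invisible(x)
}

# ---- comparison arithmetic --------------------------------------------------

#' Angle difference
#'
#' `a - b` reported to 0.1 degree; positive values are improvements toward
#' normal when `a` is the later (treated) state and `b` the earlier one.
#'
#' @param a,b angles in degrees.
#' @return difference in degrees, one decimal.
#' @export
angle_delta <- function(a, b) round(a - b, 1)

#' Percent change relative to a reference value
#'
#' `(new - reference) / reference * 100`, rounded to the nearest integer
#' percent (sign retained). A zero or negative reference is rejected: a
#' 0 -> positive transition has no defined percent change.
#'
#' @param reference,new values on a common positive scale.
#' @return integer percent.
#' @export
percent_change <- function(reference, new) {
  if (!is.numeric(reference) || reference <= 0)
    stop("percent_change requires a positive reference value")
  round((new - reference) / reference * 100)
}

#' Value as a percent of a reference
#'
#' `new / reference * 100`, nearest integer.
#'
#' @inheritParams percent_change
#' @return integer percent.
#' @export
percent_of_reference <- function(reference, new) {
  if (!is.numeric(reference) || reference <= 0)
    stop("percent_of_reference requires a positive reference value")
  round(new / reference * 100)
}

#' Published reference tables
#'
#' The measurement tables of the cadaver-based simulation study this model
#' family reproduces, shipped as packaged CSV fixtures: the flatfoot
#' stiffness-attenuation scheme, and the joint angles, soft-tissue strains
#' and plantar loads of its seven configurations. Checksums guard against
#' transcription drift.
#'
#' @return named list of data.frames: `stiffness`, `angles`, `strains`,
#'   `plantar_loads`.
#' @export
reference_tables <- function() {
  dir <- system.file("extdata", package = "pedmech")
  if (dir == "") dir <- "inst/extdata"  # source-tree fallback
  files <- c(stiffness = "reference_stiffness.csv",
             angles = "reference_angles.csv",
             strains = "reference_strains.csv",
             plantar_loads = "reference_plantar_loads.csv")
  sums <- c(stiffness = "6a06f42a16a110b1e77c0d74528c1e1e", angles = "ddc34db8c5a73d6d19ecdd72aacc01f2",
            strains = "6f16bf15446ef1baa0e7b9729068e2f0", plantar_loads = "8cbf302b25f805c6daa3179d4da7da37")
  out <- lapply(names(files), function(nm) {
    path <- file.path(dir, files[[nm]])
    if (!file.exists(path)) stop("missing reference table: ", files[[nm]])
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, sums[[nm]]))
      stop("reference table ", files[[nm]], " failed its checksum")
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  })
  names(out) <- names(files)
  out
}
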