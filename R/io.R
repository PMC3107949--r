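# Serialization and file interfaces.
#
# JSON for skeletons, equilibrium results and measurement reports (floats at
# full precision for lossless round trips), CSV for human-readable tables,
# YAML for scenario configuration, binary STL / ASCII PLY for visualisation
# meshes, and a run manifest with checksums for reproducibility audits.

#' Serialize a skeleton to JSON
#'
#' Bones carry their landmarks and contact spheres in local frames together
#' with a reference pose (position + unit quaternion, order w,x,y,z); joint
#' contact pairs and ligament attachment records are stored alongside.
#'
#' @param skeleton a `pedmech_skeleton`.
#' @param file optional path; when given the JSON is written there.
#' @return the JSON string, invisibly when `file` is given.
#' @export
skeleton_to_json <- function(skeleton, file = NULL) {
  bones <- lapply(skeleton$bones, function(b) {
    list(name = b$name, fusion_group = b$fusion_group,
         pose = list(position = b$reference_pose$position,
                     quaternion = rot_to_quat(b$reference_pose$rotation)),
         landmarks = lapply(seq_len(nrow(b$landmarks)), function(i)
           list(name = rownames(b$landmarks)[i],
                p = as.numeric(b$landmarks[i, ]))),
         ground_contacts = if (is.null(b$ground_contacts)) list() else
           lapply(seq_len(nrow(b$ground_contacts)), function(i)
             list(name = b$ground_contacts$name[i],
                  p = c(b$ground_contacts$x[i], b$ground_contacts$y[i],
                        b$ground_contacts$z[i]),
                  radius = b$ground_contacts$radius[i],
                  region = b$ground_contacts$region[i])))
  })
  obj <- list(
    format = "pedmech-skeleton", version = 1L,
    handedness = skeleton$handedness,
    generation_seed = skeleton$generation_seed,
    ground_height = skeleton$ground_height,
    params = unclass(skeleton$params),
    bones = unname(bones),
    joints = lapply(skeleton$joints, function(j)
      list(name = j$name, joint = j$joint, bone_a = j$bone_a,
           a = as.numeric(j$a), ra = j$ra, bone_b = j$bone_b,
           b = as.numeric(j$b), rb = j$rb, dir = as.numeric(j$dir),
           bilateral = isTRUE(j$bilateral),
           socket_k = if (is.null(j$socket_k)) NULL else j$socket_k)),
    attachments = lapply(skeleton$attachments, function(r)
      list(name = r$name, group = r$group, structure = r$structure,
           index = r$index,
           k_scale = if (is.null(r$k_scale)) 1 else r$k_scale,
           origin = list(bone = r$origin$bone, p = as.numeric(r$origin$p)),
           insertion = list(bone = r$insertion$bone,
                            p = as.numeric(r$insertion$p)),
           beads = lapply(r$beads, function(bd)
             list(bone = bd$bone, p = as.numeric(bd$p),
                  radius = bd$radius)))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Read a skeleton back from its JSON serialization
#'
#' @param file path to a JSON file written by [skeleton_to_json()].
#' @return a `pedmech_skeleton`.
#' @export
skeleton_from_json <- function(file) {
  o <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (!identical(o$format, "pedmech-skeleton"))
    stop("not a pedmech skeleton file: ", file)
  bones <- lapply(o$bones, function(b) {
    lm <- do.call(rbind, lapply(b$landmarks, function(l) as.numeric(l$p)))
    rownames(lm) <- vapply(b$landmarks, function(l) l$name, "")
    gc <- NULL
    if (length(b$ground_contacts)) {
      gc <- do.call(rbind, lapply(b$ground_contacts, function(g)
        data.frame(name = g$name, x = g$p[[1]], y = g$p[[2]], z = g$p[[3]],
                   radius = g$radius, region = g$region,
                   stringsAsFactors = FALSE)))
    }
    structure(list(
      name = b$name, fusion_group = b$fusion_group,
      reference_pose = pose(as.numeric(b$pose$position),
                            quat_to_rot(as.numeric(b$pose$quaternion))),
      landmarks = lm, ground_contacts = gc), class = "pedmech_bone")
  })
  names(bones) <- vapply(o$bones, function(b) b$name, "")
  joints <- lapply(o$joints, function(j)
    list(name = j$name, joint = j$joint, bone_a = j$bone_a,
         a = as.numeric(j$a), ra = j$ra, bone_b = j$bone_b,
         b = as.numeric(j$b), rb = j$rb, dir = as.numeric(j$dir),
         bilateral = isTRUE(j$bilateral), socket_k = j$socket_k))
  atts <- lapply(o$attachments, function(r)
    list(name = r$name, group = r$group, structure = r$structure,
         index = as.integer(r$index), k_scale = r$k_scale,
         origin = list(bone = r$origin$bone, p = as.numeric(r$origin$p)),
         insertion = list(bone = r$insertion$bone,
                          p = as.numeric(r$insertion$p)),
         beads = lapply(r$beads, function(bd)
           list(bone = bd$bone, p = as.numeric(bd$p), radius = bd$radius))))
  skel <- structure(list(
    bones = bones, joints = joints, attachments = atts,
    ground_height = o$ground_height, handedness = o$handedness,
    generation_seed = o$generation_seed,
    params = do.call(anatomy_params, o$params)
  ), class = "pedmech_skeleton")
  validate_skeleton(skel)
  skel
}

#' Serialize an equilibrium result to JSON
#'
#' @param result a `pedmech_equilibrium`.
#' @param file optional output path.
#' @return JSON string, invisibly when `file` is given.
#' @export
result_to_json <- function(result, file = NULL) {
  obj <- list(
    format = "pedmech-equilibrium", version = 1L,
    converged = result$converged, gradient_norm = result$gradient_norm,
    iterations = result$iterations, energy = result$energy,
    energy_trace = result$energy_trace,
    load_case = unclass(result$load_case),
    poses = lapply(result$poses, function(p)
      list(origin = as.numeric(p$origin), translation = as.numeric(p$t),
           quaternion = rot_to_quat(p$R))),
    band_tensions = as.list(result$band_tensions),
    ground_forces = result$ground_forces,
    joint_forces = result$joint_forces)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                         null = "null", dataframe = "rows")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Serialize a measurement report to JSON
#'
#' @param measures a `pedmech_measures`.
#' @param file optional output path.
#' @return JSON string, invisibly when `file` is given.
#' @export
measures_to_json <- function(measures, file = NULL) {
  obj <- list(
    format = "pedmech-measures", version = 1L,
    scenario = if (!is.null(measures$scenario)) measures$scenario$name else NULL,
    angles = as.list(measures$angles),
    long_plantar_strains = as.list(measures$long_plantar_strains),
    plantar_fascia_strains = as.list(measures$plantar_fascia_strains),
    calcaneocuboid_force = measures$calcaneocuboid_force,
    plantar_loads = as.list(measures$plantar_loads))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Read a measurement report from JSON
#' @param file path written by [measures_to_json()].
#' @return a `pedmech_measures` (without the scenario configuration).
#' @export
measures_from_json <- function(file) {
  o <- jsonlite::fromJSON(file)
  if (!identical(o$format, "pedmech-measures"))
    stop("not a pedmech measures file: ", file)
  num <- function(x) {
    out <- unlist(x)
    storage.mode(out) <- "double"
    out
  }
  structure(list(
    angles = num(o$angles),
    long_plantar_strains = num(o$long_plantar_strains),
    plantar_fascia_strains = num(o$plantar_fascia_strains),
    calcaneocuboid_force = if (is.null(o$calcaneocuboid_force)) NA_real_
      else as.numeric(o$calcaneocuboid_force),
    plantar_loads = num(o$plantar_loads),
    scenario = list(name = o$scenario)
  ), class = "pedmech_measures")
}

#' Write a comparison table as CSV (display-rounded) and JSON (full precision)
#'
#' @param table data.frame from [comparison_table()].
#' @param path_csv,path_json output paths (either may be NULL).
#' @return invisibly, the table.
#' @export
write_comparison <- function(table, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    disp <- round(table, 1)
    utils::write.csv(disp, path_csv, row.names = TRUE)
  }
  if (!is.null(path_json)) {
    obj <- list(format = "pedmech-comparison", version = 1L,
                rows = rownames(table), columns = names(table),
                values = unname(as.list(table)))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                null = "null"), path_json)
  }
  invisible(table)
}

# ---- scenario configuration (YAML) -----------------------------------------

#' Read scenario configurations from a YAML file
#'
#' The file holds either `suite: {seed: N}` (expanded to the seven standard
#' configurations) or a `scenarios:` list, each entry with fields `name`,
#' `condition`, `procedures`, `seed`, and optional `anatomy:`, `loads:`,
#' `surgery:`, `solver:` blocks. Values are validated by the respective
#' constructors.
#'
#' @param file YAML path.
#' @return named list of `pedmech_scenario`.
#' @export
read_config <- function(file) {
  y <- yaml::read_yaml(file)
  build_one <- function(s) {
    scenario_config(
      name = if (is.null(s$name)) stop("scenario without a name") else s$name,
      condition = if (is.null(s$condition)) "normal" else s$condition,
      procedures = if (is.null(s$procedures)) character() else
        unlist(s$procedures),
      seed = if (is.null(s$seed)) 0 else s$seed,
      anatomy = if (is.null(s$anatomy)) anatomy_params() else
        do.call(anatomy_params, s$anatomy),
      loads = if (is.null(s$loads)) load_case() else
        do.call(load_case, s$loads),
      osteotomy = if (is.null(s$surgery)) osteotomy_params() else
        do.call(osteotomy_params, s$surgery),
      solver = if (is.null(s$solver)) solver_options() else
        do.call(solver_options, s$solver))
  }
  if (!is.null(y$suite)) {
    seed <- if (is.null(y$suite$seed)) 0 else y$suite$seed
    solver <- if (is.null(y$suite$solver)) solver_options() else
      do.call(solver_options, y$suite$solver)
    return(default_suite(seed = seed, solver = solver))
  }
  if (is.null(y$scenarios)) stop("config must contain 'suite:' or 'scenarios:'")
  cfg <- lapply(y$scenarios, build_one)
  names(cfg) <- vapply(cfg, function(x) x$name, "")
  cfg
}

#' Write the default suite configuration as YAML
#' @param file output path.
#' @param seed anatomy seed.
#' @return invisibly, the path.
#' @export
write_default_config <- function(file, seed = 0) {
  yaml::write_yaml(list(suite = list(seed = seed)), file)
  invisible(file)
}

# ---- run manifest -----------------------------------------------------------

#' Write a run manifest
#'
#' Records the software version, the anatomy seed, per-scenario convergence
#' diagnostics and an md5 checksum for every output file, sufficient to
#' audit a re-run for bit identity.
#'
#' @param dir directory holding the run outputs.
#' @param suite a `pedmech_suite` (optional; adds convergence diagnostics).
#' @param config_file optional path of the configuration that produced the
#'   run (checksummed).
#' @return invisibly, the manifest path.
#' @export
write_manifest <- function(dir, suite = NULL, config_file = NULL) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  sums <- as.list(tools::md5sum(file.path(dir, files)))
  names(sums) <- files
  obj <- list(
    format = "pedmech-manifest", version = 1L,
    package_version = as.character(utils::packageVersion("pedmech")),
    config_checksum = if (!is.null(config_file))
      unname(tools::md5sum(config_file)) else NULL,
    scenarios = if (!is.null(suite)) lapply(names(suite$runs), function(nm) {
      r <- suite$runs[[nm]]
      list(name = nm, seed = r$config$seed,
           converged = r$result$converged,
           gradient_norm = r$result$gradient_norm,
           iterations = r$result$iterations)
    }) else NULL,
    files = sums)
  path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

# ---- mesh export ------------------------------------------------------------

# unit icosahedron subdivided once (80 faces), cached
icosphere <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    t <- (1 + sqrt(5)) / 2
    v <- rbind(
      c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
      c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
      c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
    v <- v / sqrt(rowSums(v^2))
    f <- rbind(
      c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
      c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
      c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
      c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
    # one subdivision
    nv <- v
    nf <- NULL
    midpoint <- function(a, b) {
      m <- (nv[a, ] + nv[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- rbind(nv, m)
      nrow(nv)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                  c(ab, bc, ca))
    }
    cache <<- list(v = nv, f = nf)
    cache
  }
})

write_stl_binary <- function(tris, file) {
  # tris: n x 9 matrix, one triangle per row (v1, v2, v3)
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(tris)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(tris))) {
    p1 <- tris[i, 1:3]; p2 <- tris[i, 4:6]; p3 <- tris[i, 7:9]
    n <- crossprod3(p2 - p1, p3 - p1)
    nl <- sqrt(sum(n^2))
    if (nl > 0) n <- n / nl
    writeBin(as.numeric(c(n, p1, p2, p3)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(file)
}

write_ply_points <- function(pts, file) {
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(pts)),
           "property float x", "property float y", "property float z",
           "end_header")
  body <- apply(pts, 1, function(p) paste(format(p, trim = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Export visualisation meshes of a skeleton
#'
#' Bones are landmark frames plus contact spheres, not surface models, so
#' the export is for visualisation only: each bone's contact spheres are
#' triangulated (binary STL) and its landmark cloud written as ASCII PLY,
#' all in the world frame, units mm.
#'
#' @param skeleton a `pedmech_skeleton`.
#' @param dir output directory (created if needed).
#' @param format `"stl"`, `"ply"` or both.
#' @return invisibly, the vector of files written.
#' @export
export_skeleton_meshes <- function(skeleton, dir,
                                   format = c("stl", "ply")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ico <- icosphere()
  written <- character()
  for (b in skeleton$bones) {
    ctr <- b$reference_pose$position
    if ("stl" %in% format) {
      spheres <- list()
      gc <- b$ground_contacts
      if (!is.null(gc)) {
        for (i in seq_len(nrow(gc)))
          spheres[[length(spheres) + 1]] <-
            list(c(gc$x[i], gc$y[i], gc$z[i]) + ctr, gc$radius[i])
      }
      for (j in skeleton$joints) {
        if (j$bone_a == b$name && j$ra > 0)
          spheres[[length(spheres) + 1]] <- list(j$a + ctr, j$ra)
        if (j$bone_b == b$name && j$rb > 0)
          spheres[[length(spheres) + 1]] <- list(j$b + ctr, j$rb)
      }
      if (length(spheres)) {
        tris <- do.call(rbind, lapply(spheres, function(s) {
          v <- sweep(ico$v * s[[2]], 2, s[[1]], "+")
          t(apply(ico$f, 1, function(fc) c(t(v[fc, ]))))
        }))
        f <- file.path(dir, paste0(b$name, ".stl"))
        write_stl_binary(tris, f)
        written <- c(written, f)
      }
    }
    if ("ply" %in% format) {
      pts <- sweep(b$landmarks, 2, ctr, "+")
      f <- file.path(dir, paste0(b$name, ".ply"))
      write_ply_points(pts, f)
      written <- c(written, f)
    }
  }
  invisible(written)
}
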