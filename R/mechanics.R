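# Quasi-static equilibrium by penalized energy minimisation.
#
# The skeleton's fusion groups are rigid bodies. Generalized coordinates:
# the tibia unit contributes a single vertical translation (the proximal
# tibia is restrained to superior-inferior motion); every other group
# contributes 3 translations + 3 rotation coordinates. Rotations are
# axis-angle increments composed onto a per-group reference rotation that is
# re-centred after every accepted solver step, so no chart singularity is
# approached. Rotation coordinates are scaled by a characteristic length so
# the full gradient is in force units (N) and the convergence tolerance is a
# force.
#
# Total potential = tension-only spring energies
#                 + unilateral ground/joint penalty energies
#                 + tangential ground regularisation (quasi-static no-slip)
#                 - work of the applied loads (tibial axial force, and the
#                   Achilles modeled as a constant-tension cable between its
#                   calcaneal insertion and the proximal gastrocnemius site).

ROT_SCALE <- 50  # mm; rotation coordinate = angle (rad) * ROT_SCALE

#' Mid-stance load case
#'
#' @param axial_load downward force on the proximal tibia, N (default 690,
#'   an average body weight).
#' @param achilles_load Achilles tendon tension, N (default 345, half body
#'   weight), acting along the line from the calcaneal insertion to the
#'   proximal gastrocnemius/soleus landmark.
#' @return object of class `pedmech_load_case`.
#' @export
load_case <- function(axial_load = 690, achilles_load = 345) {
  stopifnot(axial_load >= 0, achilles_load >= 0)
  structure(list(axial_load = axial_load, achilles_load = achilles_load),
            class = "pedmech_load_case")
}

#' Solver options
#'
#' @param tolerance convergence tolerance on the gradient norm, N.
#' @param ramp_steps number of equal load increments (continuation with warm
#'   starts; slack/taut ligament switching makes direct full-load solves
#'   unreliable).
#' @param max_restarts L-BFGS restarts allowed per ramp step.
#' @param maxit iteration cap per L-BFGS call.
#' @param penalty_stiffness contact penalty stiffness, N/mm.
#' @param penalty_exponent contact penalty exponent (1 = linear force law).
#' @param tangential_stiffness ground shear stiffness, N/mm, anchored at
#'   each contact's neutral footprint. It models the shear compliance of
#'   the plantar soft tissue between bone and ground; a compliant default
#'   keeps the heel/forefoot load split governed by the moment balance of
#'   the applied loads rather than by footprint shear.
#' @param socket_stiffness penalty stiffness of the joint socket pairs
#'   (congruent articular surfaces with cartilage compliance plus the deep
#'   binding ligaments), N/mm.
#' @param continuation_steps number of increments used to grow an
#'   osteotomy displacement during the resting-state continuation (see
#'   [run_scenario()]).
#' @param rom_limit_deg relative joint rotation beyond which the bony
#'   range-of-motion stop engages (facet-edge impingement), degrees.
#' @param rom_stiffness quadratic stop stiffness beyond the limit,
#'   N mm / rad^2.
#' @return object of class `pedmech_solver_options`.
#' @export
solver_options <- function(tolerance = 0.5, ramp_steps = 10,
                           max_restarts = 6, maxit = 2000,
                           penalty_stiffness = 2000, penalty_exponent = 1,
                           tangential_stiffness = 5,
                           socket_stiffness = 500,
                           continuation_steps = 4,
                           rom_limit_deg = 10, rom_stiffness = 5e5) {
  stopifnot(tolerance > 0, ramp_steps >= 1, penalty_stiffness > 0,
            penalty_exponent >= 1, tangential_stiffness >= 0,
            socket_stiffness > 0, continuation_steps >= 1,
            rom_limit_deg > 0, rom_stiffness >= 0)
  structure(list(tolerance = tolerance, ramp_steps = as.integer(ramp_steps),
                 max_restarts = as.integer(max_restarts),
                 maxit = as.integer(maxit),
                 penalty_stiffness = penalty_stiffness,
                 penalty_exponent = penalty_exponent,
                 tangential_stiffness = tangential_stiffness,
                 socket_stiffness = socket_stiffness,
                 continuation_steps = as.integer(continuation_steps),
                 rom_limit_deg = rom_limit_deg,
                 rom_stiffness = rom_stiffness),
            class = "pedmech_solver_options")
}

#' Generalized-coordinate layout of a skeleton
#'
#' The tibia unit contributes one coordinate (vertical translation); every
#' other fusion group contributes six (three translations, three rotations).
#' Bones fused by surgery share one pose and therefore one coordinate block.
#'
#' @param skeleton a `pedmech_skeleton`.
#' @return data.frame with columns `group`, `n_coords`, `offset` (0-based)
#'   and attribute `"total"`.
#' @export
degrees_of_freedom <- function(skeleton) {
  groups <- unique(vapply(skeleton$bones, function(b) b$fusion_group, ""))
  n <- ifelse(groups == "tibfib", 1L, 6L)
  off <- cumsum(c(0L, n[-length(n)]))
  out <- data.frame(group = groups, n_coords = n, offset = off,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(n)
  out
}

#' Assemble the mechanical system of a scenario
#'
#' Flattens skeleton, bands, contacts and loads into indexed arrays for fast
#' energy/gradient evaluation.
#'
#' @param skeleton a `pedmech_skeleton` (post-surgery if applicable).
#' @param bands calibrated band list.
#' @param loads a [load_case()].
#' @param options a [solver_options()].
#' @return object of class `pedmech_system`.
#' @export
build_system <- function(skeleton, bands, loads = load_case(),
                         options = solver_options()) {
  dof <- degrees_of_freedom(skeleton)
  groups <- dof$group
  gid <- function(bone) match(skeleton$bones[[bone]]$fusion_group, groups)

  P <- list(); Pg <- integer()
  addpt <- function(bone, p_local) {
    x0 <- p_local + skeleton$bones[[bone]]$reference_pose$position
    P[[length(P) + 1]] <<- x0
    Pg[length(P)] <<- gid(bone)
    length(P)
  }

  seg_ia <- integer(); seg_ib <- integer(); seg_band <- integer()
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    if (is.na(b$rest_length_L0))
      stop("band '", b$name, "' is uncalibrated")
    idx <- c(addpt(b$origin$bone, b$origin$p))
    for (bd in b$via_beads) idx <- c(idx, addpt(bd$bone, bd$p))
    idx <- c(idx, addpt(b$insertion$bone, b$insertion$p))
    seg_ia <- c(seg_ia, idx[-length(idx)])
    seg_ib <- c(seg_ib, idx[-1])
    seg_band <- c(seg_band, rep(bi, length(idx) - 1))
  }
  band_k <- vapply(bands, function(b) b$stiffness_k, 0)
  band_L0 <- vapply(bands, function(b) b$rest_length_L0, 0)
  band_names <- vapply(bands, function(b) b$name, "")

  ach_i <- addpt("calcaneus",
                 skeleton$bones$calcaneus$landmarks["achilles_insertion", ])
  ach_j <- addpt("tibfib", skeleton$bones$tibfib$landmarks["gastroc_origin", ])
  tib_i <- addpt("tibfib", skeleton$bones$tibfib$landmarks["tibia_proximal", ])

  gc_idx <- integer(); gc_r <- numeric(); gc_region <- character()
  for (b in skeleton$bones) {
    gc <- b$ground_contacts
    if (is.null(gc)) next
    for (i in seq_len(nrow(gc))) {
      gc_idx <- c(gc_idx, addpt(b$name, c(gc$x[i], gc$y[i], gc$z[i])))
      gc_r <- c(gc_r, gc$radius[i])
      gc_region <- c(gc_region, gc$region[i])
    }
  }

  jc_ia <- integer(); jc_ib <- integer(); jc_rsum <- numeric()
  jc_name <- character(); jc_bones <- list(); jc_bilateral <- logical()
  jc_k0 <- numeric()
  for (j in skeleton$joints) {
    # joints internal to one fusion group (e.g. an arthrodesis) carry load
    # through the fusion itself and are dropped from the contact set
    if (gid(j$bone_a) == gid(j$bone_b)) next
    jc_ia <- c(jc_ia, addpt(j$bone_a, j$a))
    jc_ib <- c(jc_ib, addpt(j$bone_b, j$b))
    jc_rsum <- c(jc_rsum, j$ra + j$rb)
    jc_name <- c(jc_name, j$name)
    jc_bilateral <- c(jc_bilateral, isTRUE(j$bilateral))
    jc_k0 <- c(jc_k0, if (is.null(j$socket_k)) NA_real_ else j$socket_k)
    jc_bones[[length(jc_bones) + 1]] <-
      c(skeleton$bones[[j$bone_a]]$fusion_group,
        skeleton$bones[[j$bone_b]]$fusion_group)
  }

  P0 <- do.call(rbind, P)
  origins <- lapply(seq_along(groups), function(g)
    colMeans(P0[Pg == g, , drop = FALSE]))
  gpt <- lapply(seq_along(groups), function(g) which(Pg == g))

  # one range-of-motion stop per articulated joint (group pair)
  rom <- list()
  seen <- character()
  for (j in skeleton$joints) {
    if (gid(j$bone_a) == gid(j$bone_b) || j$joint %in% seen) next
    seen <- c(seen, j$joint)
    rom[[length(rom) + 1]] <- list(joint = j$joint,
                                   ga = gid(j$bone_a), gb = gid(j$bone_b))
  }

  structure(list(
    skeleton = skeleton, groups = groups, dof = dof, origins = origins,
    gpt = gpt, P0 = P0, Pg = Pg,
    seg_ia = seg_ia, seg_ib = seg_ib, seg_band = seg_band,
    band_k = band_k, band_L0 = band_L0, band_names = band_names,
    ach_i = ach_i, ach_j = ach_j, tib_i = tib_i,
    gc_idx = gc_idx, gc_r = gc_r, gc_region = gc_region,
    gc_anchor = P0[gc_idx, c(1, 3), drop = FALSE],
    jc_ia = jc_ia, jc_ib = jc_ib, jc_rsum = jc_rsum, jc_name = jc_name,
    jc_bones = jc_bones, jc_bilateral = jc_bilateral,
    jc_k = ifelse(jc_bilateral,
                  ifelse(is.na(jc_k0), options$socket_stiffness,
                         jc_k0 * options$socket_stiffness / 500),
                  options$penalty_stiffness),
    rom = rom,
    loads = loads, options = options,
    ground_height = skeleton$ground_height
  ), class = "pedmech_system")
}

# split the coordinate vector into per-group translation / rotation parts
state_unpack <- function(sys, q) {
  lapply(seq_along(sys$groups), function(g) {
    off <- sys$dof$offset[g]
    if (sys$groups[g] == "tibfib") {
      list(t = c(0, q[off + 1], 0), th = c(0, 0, 0))
    } else {
      list(t = q[off + (1:3)], th = q[off + (4:6)] / ROT_SCALE)
    }
  })
}

# world positions of all system points given state parts and reference
# rotations; returns list(Pw, Rg)
state_points <- function(sys, parts, Rref) {
  Pw <- sys$P0
  Rg <- vector("list", length(sys$groups))
  for (g in seq_along(sys$groups)) {
    R <- Rref[[g]] %*% rot_exp(parts[[g]]$th)
    Rg[[g]] <- R
    idx <- sys$gpt[[g]]
    o <- sys$origins[[g]]
    Pw[idx, ] <- sweep(sweep(sys$P0[idx, , drop = FALSE], 2, o) %*% t(R),
                       2, o + parts[[g]]$t, "+")
  }
  list(Pw = Pw, Rg = Rg)
}

#' Total potential energy and its analytic gradient
#'
#' Evaluates the system potential at a generalized-coordinate vector:
#' spring, contact-penalty, tangential-regularisation and load-work terms.
#' The gradient (attribute `"gradient"`) is analytic and is validated
#' against central finite differences in the test suite.
#'
#' @param q generalized coordinates (see [degrees_of_freedom()]); rotation
#'   coordinates are angle * 50 mm so every gradient entry is in N.
#' @param system a `pedmech_system`.
#' @param load_fraction continuation fraction in `[0, 1]` applied to both
#'   loads.
#' @param Rref optional list of per-group reference rotations (default
#'   identity; the solver re-centres onto these).
#' @return energy in N mm with attribute `"gradient"`.
#' @export
total_potential <- function(q, system, load_fraction = 1, Rref = NULL) {
  sys <- system
  if (!all(is.finite(q))) stop("non-finite generalized coordinates")
  if (is.null(Rref)) Rref <- rep(list(diag(3)), length(sys$groups))
  parts <- state_unpack(sys, q)
  sp <- state_points(sys, parts, Rref)
  Pw <- sp$Pw
  opt <- sys$options
  G <- matrix(0, nrow(Pw), 3)  # dE/d(point)
  E <- 0

  # tension-only springs
  d <- Pw[sys$seg_ib, , drop = FALSE] - Pw[sys$seg_ia, , drop = FALSE]
  slen <- sqrt(rowSums(d * d))
  L <- as.numeric(rowsum(slen, sys$seg_band))
  ext <- pmax(0, L - sys$band_L0)
  E <- E + 0.5 * sum(sys$band_k * ext^2)
  Tens <- sys$band_k * ext
  Ts <- Tens[sys$seg_band]
  u <- d / pmax(slen, 1e-12)
  fu <- u * Ts
  acc <- rowsum(rbind(-fu, fu), c(sys$seg_ia, sys$seg_ib))
  idx <- as.integer(rownames(acc))
  G[idx, ] <- G[idx, ] + acc

  # Achilles: constant-tension cable (potential = tension x length)
  A <- load_fraction * sys$loads$achilles_load
  if (A > 0) {
    dv <- Pw[sys$ach_j, ] - Pw[sys$ach_i, ]
    dl <- sqrt(sum(dv * dv))
    E <- E + A * dl
    uv <- dv / dl
    G[sys$ach_i, ] <- G[sys$ach_i, ] - A * uv
    G[sys$ach_j, ] <- G[sys$ach_j, ] + A * uv
  }

  # axial load: downward force on the proximal tibia
  E <- E + load_fraction * sys$loads$axial_load * Pw[sys$tib_i, 2]
  G[sys$tib_i, 2] <- G[sys$tib_i, 2] + load_fraction * sys$loads$axial_load

  # ground contacts: unilateral normal penalty + anchored tangential spring
  e <- opt$penalty_exponent
  kp <- opt$penalty_stiffness
  kt <- opt$tangential_stiffness
  gcp <- Pw[sys$gc_idx, , drop = FALSE]
  pen <- pmax(0, sys$gc_r - (gcp[, 2] - sys$ground_height))
  E <- E + sum(kp / (e + 1) * pen^(e + 1))
  gy <- -kp * pen^e
  G[sys$gc_idx, 2] <- G[sys$gc_idx, 2] + gy
  tx <- gcp[, 1] - sys$gc_anchor[, 1]
  tz <- gcp[, 3] - sys$gc_anchor[, 2]
  E <- E + 0.5 * kt * sum(tx^2 + tz^2)
  G[sys$gc_idx, 1] <- G[sys$gc_idx, 1] + kt * tx
  G[sys$gc_idx, 3] <- G[sys$gc_idx, 3] + kt * tz

  # joint contacts: facet-edge pairs are unilateral (compression only);
  # socket pairs are bilateral (facet congruence plus the deep binding
  # ligaments, lumped as a symmetric penalty on the centre distance)
  if (length(sys$jc_ia)) {
    dj <- Pw[sys$jc_ib, , drop = FALSE] - Pw[sys$jc_ia, , drop = FALSE]
    dist <- sqrt(rowSums(dj * dj))
    delta <- sys$jc_rsum - dist
    penj <- ifelse(sys$jc_bilateral, delta, pmax(0, delta))
    kj <- sys$jc_k
    E <- E + sum(kj / (e + 1) * abs(penj)^(e + 1))
    fmag <- kj * sign(penj) * abs(penj)^e  # + repulsive, - attractive
    uj <- dj / pmax(dist, 1e-12)
    act <- which(penj != 0)
    if (length(act)) {
      fj <- uj[act, , drop = FALSE] * fmag[act]
      accj <- rowsum(rbind(fj, -fj), c(sys$jc_ia[act], sys$jc_ib[act]))
      idxj <- as.integer(rownames(accj))
      G[idxj, ] <- G[idxj, ] + accj
    }
  }

  # range-of-motion stops: smooth quadratic penalty on the relative joint
  # rotation angle beyond the impingement limit
  rom_grad <- vector("list", length(sys$groups))
  alpha0 <- opt$rom_limit_deg * pi / 180
  if (opt$rom_stiffness > 0) {
    for (r in sys$rom) {
      Ra <- sp$Rg[[r$ga]]
      Rb <- sp$Rg[[r$gb]]
      Rrel <- crossprod(Ra, Rb)
      ca <- (sum(diag(Rrel)) - 1) / 2
      alpha <- acos(min(1, max(-1, ca)))
      if (alpha <= alpha0) next
      w <- c(Rrel[3, 2] - Rrel[2, 3], Rrel[1, 3] - Rrel[3, 1],
             Rrel[2, 1] - Rrel[1, 2])
      wn <- sqrt(sum(w^2))
      if (wn < 1e-12) next
      w <- w / wn
      E <- E + 0.5 * opt$rom_stiffness * (alpha - alpha0)^2
      dE <- opt$rom_stiffness * (alpha - alpha0)
      add_rg <- function(g, v) {
        if (is.null(rom_grad[[g]])) rom_grad[[g]] <<- v else
          rom_grad[[g]] <<- rom_grad[[g]] + v
      }
      add_rg(r$gb, dE * w)
      add_rg(r$ga, -dE * w)
    }
  }

  # map point gradients to generalized coordinates
  grad <- numeric(length(q))
  for (g in seq_along(sys$groups)) {
    idx <- sys$gpt[[g]]
    Gg <- G[idx, , drop = FALSE]
    off <- sys$dof$offset[g]
    if (sys$groups[g] == "tibfib") {
      grad[off + 1] <- sum(Gg[, 2])
    } else {
      grad[off + (1:3)] <- colSums(Gg)
      R <- sp$Rg[[g]]
      pl <- sweep(sys$P0[idx, , drop = FALSE], 2, sys$origins[[g]])
      RtG <- Gg %*% R  # rows: R^T g_p
      m <- c(sum(pl[, 2] * RtG[, 3] - pl[, 3] * RtG[, 2]),
             sum(pl[, 3] * RtG[, 1] - pl[, 1] * RtG[, 3]),
             sum(pl[, 1] * RtG[, 2] - pl[, 2] * RtG[, 1]))
      if (!is.null(rom_grad[[g]])) m <- m + rom_grad[[g]]
      grad[off + (4:6)] <-
        as.numeric(crossprod(rot_right_jacobian(parts[[g]]$th), m)) / ROT_SCALE
    }
  }
  structure(E, gradient = grad,
            band_tensions = stats::setNames(Tens, sys$band_names))
}

#' Solve the quasi-static equilibrium of a scenario
#'
#' Minimises the total potential by L-BFGS with analytic gradients, ramping
#' the loads in equal increments and warm-starting each increment from the
#' previous solution. After each accepted step the per-group rotation chart
#' is re-centred. The result is deterministic for identical inputs.
#'
#' @param skeleton a `pedmech_skeleton` (post-surgery where applicable).
#' @param bands calibrated band list.
#' @param loads a [load_case()]; use `load_case(0, 0)` for the unloaded
#'   (resting) equilibrium that anchors strain measurements.
#' @param options a [solver_options()].
#' @param init_poses optional pose map to warm-start from (e.g. the
#'   unloaded equilibrium of the same scenario, or a nearby osteotomy
#'   continuation step).
#' @param anchors optional n x 2 matrix of (x, z) tangential ground-spring
#'   anchor positions, one row per ground contact, typically the contact
#'   footprint of the scenario's unloaded equilibrium (the foot is seated
#'   on the ground in its post-operative resting posture before loading).
#' @param ramp apply the load-continuation schedule (default). Disable for
#'   warm-started re-solves near an equilibrium, where a single full-load
#'   minimisation converges directly.
#' @return object of class `pedmech_equilibrium`: pose map, band tensions,
#'   contact forces, gradient norm, convergence flag, iteration count and
#'   the energy trace of the final load stage.
#' @export
solve_equilibrium <- function(skeleton, bands, loads = load_case(),
                              options = solver_options(),
                              init_poses = NULL, anchors = NULL,
                              ramp = TRUE) {
  sys <- build_system(skeleton, bands, loads, options)
  if (!is.null(anchors)) {
    stopifnot(nrow(anchors) == length(sys$gc_idx), ncol(anchors) == 2)
    sys$gc_anchor <- as.matrix(anchors)
  }
  nq <- attr(sys$dof, "total")
  q <- numeric(nq)
  Rref <- rep(list(diag(3)), length(sys$groups))
  if (!is.null(init_poses)) {
    for (g in seq_along(sys$groups)) {
      pg <- init_poses[[sys$groups[g]]]
      if (is.null(pg)) next
      if (sys$groups[g] == "tibfib") {
        q[sys$dof$offset[g] + 1] <- pg$t[2]
      } else {
        Rref[[g]] <- pg$R
        # re-express the translation about this system's group origin
        o_old <- pg$origin
        o_new <- sys$origins[[g]]
        q[sys$dof$offset[g] + (1:3)] <-
          pg$t + (o_old - o_new) - as.numeric(pg$R %*% (o_old - o_new))
      }
    }
  }
  iters <- 0L
  trace <- numeric()

  fracs <- if (!ramp || (loads$axial_load == 0 && loads$achilles_load == 0)) 1
  else seq_len(options$ramp_steps) / options$ramp_steps

  recentre <- function(q) {
    parts <- state_unpack(sys, q)
    for (g in seq_along(sys$groups)) {
      if (sys$groups[g] == "tibfib") next
      Rref[[g]] <<- Rref[[g]] %*% rot_exp(parts[[g]]$th)
      q[sys$dof$offset[g] + (4:6)] <- 0
    }
    q
  }

  gnorm <- Inf
  for (f in fracs) {
    last <- new.env(parent = emptyenv())
    ev <- function(qq) {
      if (!all(is.finite(qq)))
        stop("solver produced non-finite state at evaluation ", iters)
      if (!is.null(last$q) && identical(qq, last$q)) return(last$val)
      val <- total_potential(qq, sys, load_fraction = f, Rref = Rref)
      iters <<- iters + 1L
      last$q <- qq
      last$val <- val
      val
    }
    fn <- function(qq) as.numeric(ev(qq))
    gr <- function(qq) attr(ev(qq), "gradient")

    final_stage <- f == fracs[length(fracs)]
    stage_trace <- numeric()
    restarts <- if (final_stage) options$max_restarts else 2L
    for (r in seq_len(restarts)) {
      res <- stats::optim(q, fn, gr, method = "L-BFGS-B",
                          control = list(
                            maxit = options$maxit,
                            factr = if (final_stage) 10 else 1e4,
                            pgtol = 0, lmm = 12))
      q <- recentre(res$par)
      val <- total_potential(q, sys, load_fraction = f, Rref = Rref)
      iters <- iters + 1L
      stage_trace <- c(stage_trace, as.numeric(val))
      gnorm <- sqrt(sum(attr(val, "gradient")^2))
      if (gnorm <= options$tolerance * (if (final_stage) 1 else 10)) break
    }
    trace <- stage_trace
  }

  final <- total_potential(q, sys, load_fraction = fracs[length(fracs)],
                           Rref = Rref)
  parts <- state_unpack(sys, q)
  sp <- state_points(sys, parts, Rref)
  poses <- lapply(seq_along(sys$groups), function(g)
    list(R = sp$Rg[[g]], t = parts[[g]]$t, origin = sys$origins[[g]]))
  names(poses) <- sys$groups

  opt <- sys$options
  gcp <- sp$Pw[sys$gc_idx, , drop = FALSE]
  pen <- pmax(0, sys$gc_r - (gcp[, 2] - sys$ground_height))
  fn_y <- opt$penalty_stiffness * pen^opt$penalty_exponent
  ft_x <- -opt$tangential_stiffness * (gcp[, 1] - sys$gc_anchor[, 1])
  ft_z <- -opt$tangential_stiffness * (gcp[, 3] - sys$gc_anchor[, 2])
  ground <- data.frame(region = sys$gc_region,
                       fx = ft_x, fy = fn_y, fz = ft_z,
                       stringsAsFactors = FALSE)

  joint <- NULL
  if (length(sys$jc_ia)) {
    dj <- sp$Pw[sys$jc_ib, , drop = FALSE] - sp$Pw[sys$jc_ia, , drop = FALSE]
    dist <- sqrt(rowSums(dj * dj))
    delta <- sys$jc_rsum - dist
    # facet-edge pairs push only (compression); the socket transmits the
    # full vector force of the congruent articulation
    penj <- ifelse(sys$jc_bilateral, delta, pmax(0, delta))
    kj <- sys$jc_k
    fmag <- kj * sign(penj) * abs(penj)^opt$penalty_exponent
    uj <- dj / pmax(dist, 1e-12)
    joint <- data.frame(name = sys$jc_name,
                        bone_a = vapply(sys$jc_bones, `[`, "", 1),
                        bone_b = vapply(sys$jc_bones, `[`, "", 2),
                        bilateral = sys$jc_bilateral,
                        fx = fmag * uj[, 1], fy = fmag * uj[, 2],
                        fz = fmag * uj[, 3], magnitude = fmag,
                        stringsAsFactors = FALSE)
  }

  structure(list(
    poses = poses, band_tensions = attr(final, "band_tensions"),
    ground_footprint = gcp[, c(1, 3), drop = FALSE],
    ground_forces = ground, joint_forces = joint,
    energy = as.numeric(final), gradient_norm = gnorm,
    converged = gnorm <= options$tolerance, iterations = iters,
    energy_trace = trace, load_case = loads, options = opt
  ), class = "pedmech_equilibrium")
}

#' @export
print.pedmech_equilibrium <- function(x, ...) {
  cat("pedmech equilibrium:",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(|grad| = %.3g N, %d evaluations)\n", x$gradient_norm,
              x$iterations))
  invisible(x)
}

#' Plantar load per ground region
#'
#' Sums the vertical components of the ground contact forces per region
#' (rays 1-5 and the calcaneus).
#'
#' @param result a converged `pedmech_equilibrium`.
#' @return named numeric, N; regions with no active contact report 0.
#' @export
ground_region_loads <- function(result) {
  if (!isTRUE(result$converged))
    stop("ground_region_loads requires a converged result")
  regions <- c("ray1", "ray2", "ray3", "ray4", "ray5", "calcaneus")
  out <- stats::setNames(numeric(length(regions)), regions)
  agg <- tapply(result$ground_forces$fy, result$ground_forces$region, sum)
  out[names(agg)] <- agg
  out
}

#' Resultant joint contact force between two bones
#'
#' Magnitude of the vector sum of the penalty contact forces transmitted
#' across all declared contact pairs of the named bone pair.
#'
#' @param result a converged `pedmech_equilibrium`.
#' @param bone_a,bone_b bone unit names.
#' @return force magnitude, N.
#' @export
joint_contact_force <- function(result, bone_a, bone_b) {
  if (!isTRUE(result$converged))
    stop("joint_contact_force requires a converged result")
  jf <- result$joint_forces
  sel <- !is.null(jf) &
    ((jf$bone_a == bone_a & jf$bone_b == bone_b) |
       (jf$bone_a == bone_b & jf$bone_b == bone_a))
  if (is.null(jf) || !any(sel))
    stop("no declared joint contacts between ", bone_a, " and ", bone_b)
  f <- colSums(jf[sel, c("fx", "fy", "fz"), drop = FALSE])
  sqrt(sum(f^2))
}
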