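# Quasi-static total-Lagrangian solver: Newton iteration with load stepping
# and automatic bisection, linear tetrahedra, nodal-patch (average nodal
# pressure) projection of the Mooney-Rivlin volumetric term against
# volumetric locking, and follower pressure on the endovascular surface.

comp_index <- c(x = 1L, y = 2L, z = 3L)

#' Load case definition
#'
#' At most one of `bending` and `end_pulse` may be active; couplings with
#' intravascular pressure are handled by [couplePrestress()].
#'
#' @param pulse_pressure intravascular pulse pressure in mmHg (>= 0).
#' @param bending midspan transverse displacement d_Vessel (um) prescribed on
#'   the node ring nearest z = L/2 (x direction), with both ends fixed.
#' @param end_pulse for dynamics: `list(amplitude, rise, direction, profile)`
#'   - a displacement pulse (um, us, `"x"|"y"|"z"`, `"halfcos"` or
#'   `"linear"`) applied at one longitudinal end.
#' @param pulse_set node set receiving the end pulse (default `"end_A"`).
#' @param fixed named list: surface-set name -> components to fix, e.g.
#'   `list(end_A = "xyz", end_B = "xyz")` (the default: fixtures at both
#'   longitudinal ends).
#' @param extra_prescribed optional `data.frame(node, comp, value)` of
#'   additional prescribed displacement components (comp in `"x","y","z"`).
#' @param follower if `TRUE` (default) the pressure tracks the deformed
#'   surface normals.
#' @return object of class `load_case`.
#' @export
loadCase <- function(pulse_pressure = 0, bending = 0, end_pulse = NULL,
                     pulse_set = "end_A",
                     fixed = list(end_A = "xyz", end_B = "xyz"),
                     extra_prescribed = NULL, follower = TRUE) {
  if (pulse_pressure < 0) stop("pulse_pressure must be >= 0")
  if (bending != 0 && !is.null(end_pulse))
    stop("at most one of bending and end_pulse may be active per run")
  if (!is.null(end_pulse)) {
    end_pulse <- utils::modifyList(
      list(amplitude = 1, rise = 1, direction = "z", profile = "halfcos"),
      end_pulse)
  }
  structure(list(pulse_pressure = pulse_pressure, bending = bending,
                 end_pulse = end_pulse, pulse_set = pulse_set, fixed = fixed,
                 extra_prescribed = extra_prescribed, follower = follower),
            class = "load_case")
}

# encode per-element material arrays for the kernels
encode_materials <- function(mesh, materials, active) {
  regs <- unique(mesh$region[active])
  missing <- setdiff(regs, names(materials))
  if (length(missing) > 0)
    stop("no material assigned to region(s): ", paste(missing, collapse = ", "))
  M <- sum(active)
  mtype <- integer(M); mpar <- matrix(0, M, 7); proj <- logical(M)
  reg_active <- mesh$region[active]
  for (r in regs) {
    m <- materials[[r]]
    sel <- reg_active == r
    if (inherits(m, "mooney_rivlin5")) {
      mtype[sel] <- 0L
      mpar[sel, ] <- matrix(c(m$C10, m$C01, m$C20, m$C11, m$C02, m$D1,
                              m$density), sum(sel), 7, byrow = TRUE)
      proj[sel] <- TRUE
    } else if (inherits(m, "linear_elastic")) {
      mtype[sel] <- 1L
      mpar[sel, ] <- matrix(c(m$E, m$nu, m$density, 0, 0, 0, m$density),
                            sum(sel), 7, byrow = TRUE)
      mpar[sel, 7] <- m$density
    } else {
      stop("region '", r, "' has an ignored/unsupported material; ",
           "exclude it from `regions`")
    }
  }
  list(mtype = mtype, mpar = mpar, proj = proj)
}

default_static_regions <- function(mesh) {
  setdiff(unique(mesh$region), "blood")
}

# constraint table: data.frame(dof, value) at full load scale
build_constraints <- function(mesh, load, d_full) {
  dof <- integer(0); val <- numeric(0)
  for (nm in names(load$fixed)) {
    nodes <- mesh$node_sets[[nm]]
    if (is.null(nodes)) stop("unknown node set in fixed: ", nm)
    comps <- comp_index[strsplit(load$fixed[[nm]], "")[[1]]]
    for (cc in comps) {
      dof <- c(dof, 3L * (nodes - 1L) + cc)
      val <- c(val, rep(0, length(nodes)))
    }
  }
  if (!is.null(load$extra_prescribed)) {
    ep <- load$extra_prescribed
    dof <- c(dof, 3L * (as.integer(ep$node) - 1L) + comp_index[ep$comp])
    val <- c(val, as.numeric(ep$value))
  }
  if (load$bending != 0) {
    ring <- midspan_ring(mesh)
    dof <- c(dof, 3L * (ring - 1L) + 1L) # x component
    val <- c(val, rep(d_full, length(ring)))
  }
  keep <- !duplicated(dof)
  data.frame(dof = dof[keep], value = val[keep])
}

midspan_ring <- function(mesh) {
  z <- mesh$nodes[, 3]
  zs <- sort(unique(round(z, 9)))
  zm <- zs[which.min(abs(zs - mesh$length / 2))]
  which(abs(z - zm) < 1e-8 * mesh$length)
}

#' Follower pressure nodal forces
#'
#' Consistent nodal forces of a uniform pressure applied on an oriented
#' facet set (traction `-p n` with `n` the outward surface normal, so a
#' lumen pressure inflates the wall). In follower mode the normals and
#' areas are evaluated on the deformed configuration.
#'
#' @param mesh a `vessel_mesh`.
#' @param surface facet set name (default `"inner_lumen"`) or an F x 3
#'   facet matrix.
#' @param p pressure in MPa.
#' @param u optional N x 3 displacement field (deformed configuration).
#' @return N x 3 nodal force matrix.
#' @export
applyPressureLoad <- function(mesh, surface = "inner_lumen", p, u = NULL) {
  fac <- if (is.character(surface)) mesh$surface_sets[[surface]] else surface
  if (is.null(fac) || nrow(fac) == 0) stop("empty pressure surface set")
  Xc <- mesh$nodes
  if (!is.null(u)) Xc <- Xc + u
  a <- triangle_areas(Xc, fac)
  if (any(a <= 0)) stop("zero-area facet in pressure surface")
  fem_pressure_force(Xc, fac, p)
}

#' Quasi-static nonlinear solve
#'
#' Total-Lagrangian Newton iteration with load stepping (default 10 equal
#' increments, automatic bisection on divergence). Pressure is applied as a
#' follower load on `inner_lumen`; bending as a prescribed transverse
#' displacement on the midspan node ring with both ends fixed.
#'
#' @param mesh a `vessel_mesh`.
#' @param materials named list mapping region tags to `material_model`s
#'   (default from [materialFromTable()] given the vessel class).
#' @param load a [loadCase()].
#' @param regions regions to include; default: all except `blood` (blood is
#'   mass-only and contributes nothing statically).
#' @param tol relative residual tolerance.
#' @param max_iter Newton iterations per load step.
#' @param n_steps load increments.
#' @param max_bisect maximum step bisections before giving up.
#' @param verbose print residual trace.
#' @return a `field_state`: full-length displacement field, per-element
#'   Cauchy stress and von Mises (MPa; `NA` for inactive elements),
#'   residual norm, convergence flag.
#' @export
solveStatic <- function(mesh, materials = NULL, load = loadCase(),
                        regions = NULL, tol = 1e-6, max_iter = 30,
                        n_steps = 10, max_bisect = 8, verbose = FALSE) {
  if (is.null(materials)) materials <- defaultMaterials(mesh)
  if (is.null(regions)) regions <- default_static_regions(mesh)
  active <- mesh$region %in% regions
  if (!any(active)) stop("no active elements for regions: ",
                         paste(regions, collapse = ", "))
  tets <- mesh$tets[active, , drop = FALSE]
  enc <- encode_materials(mesh, materials, active)
  pre <- fem_precompute(mesh$nodes, tets)
  N <- nrow(mesh$nodes)
  active_nodes <- sort(unique(as.vector(tets)))
  inactive_dofs <- setdiff(seq_len(3 * N),
                           as.vector(outer(3 * (active_nodes - 1L), 1:3, "+")))

  p_full <- mmHgToMPa(load$pulse_pressure)
  d_full <- load$bending
  cons <- build_constraints(mesh, load, d_full)
  cons <- cons[!(cons$dof %in% inactive_dofs), , drop = FALSE]
  fixed_dofs <- c(cons$dof, inactive_dofs)
  free <- setdiff(as.vector(outer(3 * (active_nodes - 1L), 1:3, "+")), cons$dof)

  u <- numeric(3 * N)
  fac <- mesh$surface_sets$inner_lumen

  residual <- function(u) {
    Xc <- mesh$nodes + matrix(u, N, 3, byrow = TRUE)
    fr <- fem_force(Xc, mesh$nodes, tets, pre$G, pre$V0, enc$mtype, enc$mpar,
                    enc$proj, FALSE)
    if (!fr$ok) stop("inverted element during load stepping (element ",
                     fr$bad, ")", call. = FALSE)
    list(fint = as.vector(t(fr$force)), Xc = Xc)
  }
  external <- function(lam, Xc) {
    f <- numeric(3 * N)
    if (p_full > 0) {
      Xp <- if (load$follower) Xc else mesh$nodes
      fp <- fem_pressure_force(Xp, fac, lam * p_full)
      f <- as.vector(t(fp))
    }
    f
  }

  idx <- matrix(0L, nrow(tets), 12)
  for (a in 1:4) for (cc in 1:3)
    idx[, 3L * (a - 1L) + cc] <- 3L * (tets[, a] - 1L) + cc

  newton <- function(u, lam) {
    set_cons <- function(u) { u[cons$dof] <- lam * cons$value; u }
    u <- set_cons(u)
    res_norm <- Inf
    for (it in seq_len(max_iter)) {
      r <- residual(u)
      fext <- external(lam, r$Xc)
      rhs <- fext - r$fint
      res_norm <- sqrt(sum(rhs[free]^2))
      # scale by the full internal-force norm (includes reactions), so
      # displacement-driven cases keep a meaningful reference at equilibrium
      ref <- max(sqrt(sum(fext[free]^2)), sqrt(sum(r$fint^2)), 1e-12)
      if (verbose) message(sprintf("  lam=%.4f it=%d |r|=%.3e ref=%.3e",
                                   lam, it, res_norm, ref))
      if (res_norm <= tol * ref || res_norm < 1e-14)
        return(list(u = u, converged = TRUE, iterations = it,
                    residual = res_norm))
      Xc <- r$Xc
      Kloc <- fem_tangent(Xc, mesh$nodes, tets, pre$G, pre$V0, enc$mtype, enc$mpar)
      ii <- idx[, rep(1:12, times = 12), drop = FALSE]
      jj <- idx[, rep(1:12, each = 12), drop = FALSE]
      K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                                x = as.vector(Kloc), dims = c(3 * N, 3 * N))
      if (any(enc$proj)) {
        vp <- fem_vol_projection(Xc, mesh$nodes, tets, pre$G, pre$V0, enc$proj, enc$mpar)
        gi <- rep(as.vector(tets), times = 12)
        gj <- as.vector(idx[, rep(1:12, each = 4)])
        gx <- as.vector(vp$dv[, rep(1:12, each = 4)]) / 4
        keep <- gx != 0
        Gv <- Matrix::sparseMatrix(i = gi[keep], j = gj[keep], x = gx[keep],
                                   dims = c(N, 3 * N))
        w <- ifelse(vp$V0a > 0, 2 * vp$WDa / pmax(vp$V0a, 1e-300)^2, 0)
        K <- K + Matrix::t(Gv) %*% Matrix::Diagonal(x = w) %*% Gv
      }
      Kff <- K[free, free, drop = FALSE]
      # the assembled tangent is symmetric (hyperelastic + projection);
      # sparse Cholesky with an LU fallback for indefinite intermediates
      du <- tryCatch({
        ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                               perm = TRUE)
        as.vector(Matrix::solve(ch, rhs[free]))
      }, error = function(e)
        tryCatch(as.vector(Matrix::solve(Kff, rhs[free])),
                 error = function(e2) NULL))
      if (is.null(du) || any(!is.finite(du)))
        return(list(u = u, converged = FALSE, iterations = it,
                    residual = res_norm))
      u[free] <- u[free] + du
    }
    list(u = u, converged = FALSE, iterations = max_iter, residual = res_norm)
  }

  lam_done <- 0; lam_target <- 0
  n_bis <- 0
  total_it <- 0
  last <- NULL
  while (lam_done < 1 - 1e-12) {
    step_size <- min(1 / n_steps / 2^n_bis, 1 - lam_done)
    lam_target <- lam_done + step_size
    ans <- tryCatch(newton(u, lam_target), error = function(e) e)
    failed <- inherits(ans, "error") || !ans$converged
    if (failed) {
      n_bis <- n_bis + 1
      if (n_bis > max_bisect) {
        lastres <- if (inherits(ans, "error")) conditionMessage(ans)
                   else sprintf("last residual %.3e", ans$residual)
        stop("static solve failed to converge at load factor ",
             signif(lam_target, 4), " after ", max_bisect,
             " bisections (", lastres, ")")
      }
    } else {
      u <- ans$u
      lam_done <- lam_target
      total_it <- total_it + ans$iterations
      last <- ans
      n_bis <- max(0, n_bis - 1)
    }
  }

  Xc <- mesh$nodes + matrix(u, N, 3, byrow = TRUE)
  fr <- fem_force(Xc, mesh$nodes, tets, pre$G, pre$V0, enc$mtype, enc$mpar,
                  enc$proj, TRUE)
  Mfull <- nrow(mesh$tets)
  vm <- rep(NA_real_, Mfull); vm[active] <- fr$vm
  stress <- matrix(NA_real_, Mfull, 6)
  stress[active, ] <- fr$stress
  colnames(stress) <- c("sxx", "syy", "szz", "sxy", "syz", "sxz")
  structure(list(u = matrix(u, N, 3, byrow = TRUE),
                 stress = stress, vm = vm, active = active,
                 residual_norm = last$residual, converged = TRUE,
                 iterations = total_it, load = load, regions = regions,
                 strain_energy = fr$SE),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("field_state: converged=%s, %d Newton iterations, |r|=%.3e\n",
              x$converged, x$iterations, x$residual_norm))
  cat(sprintf("  max |u| = %.4g um, max von Mises = %.4g kPa\n",
              max(abs(x$u)), 1000 * max(x$vm, na.rm = TRUE)))
  invisible(x)
}

#' Default materials for a vessel mesh
#'
#' Maps the mesh regions to the tissue defaults: wall of an artery or
#' arteriole to the Mooney-Rivlin fit, blood and marrow to their
#' linear-elastic defaults.
#'
#' @param mesh a `vessel_mesh`.
#' @return named list of `material_model`s keyed by region.
#' @export
defaultMaterials <- function(mesh) {
  regs <- unique(mesh$region)
  out <- list()
  for (r in regs) {
    out[[r]] <- switch(r,
      wall = materialFromTable(paste0(mesh$spec$vessel_class, "_wall")),
      blood = materialFromTable("blood"),
      marrow = materialFromTable("marrow"),
      stop("unknown region: ", r))
  }
  out
}
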