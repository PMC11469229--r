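# Explicit central-difference dynamics: CFL time step, vibratory end-stretch
# pulse, and coupling with a statically pre-pressurized configuration.

#' Stable explicit time step (CFL)
#'
#' `dt = safety * min_e(h_e / c_e)` over active elements, with `h_e` the
#' minimum tetrahedron altitude (3V/A_max) and `c_e` the dilatational wave
#' speed `sqrt((kappa + 4 mu/3)/rho)` of the element material.
#'
#' @param mesh a `vessel_mesh`.
#' @param materials named list of `material_model`s per region.
#' @param regions regions to include (default: all with a real material).
#' @param safety safety factor, default 0.5.
#' @return time step in us.
#' @export
stableTimestep <- function(mesh, materials = NULL, regions = NULL,
                           safety = 0.5) {
  if (is.null(materials)) materials <- defaultMaterials(mesh)
  if (is.null(regions)) regions <- names(materials)
  active <- mesh$region %in% regions
  tets <- mesh$tets[active, , drop = FALSE]
  v <- tetVolumes(mesh$nodes, tets)
  amax <- pmax(
    triangle_areas(mesh$nodes, tets[, c(2, 3, 4), drop = FALSE]),
    triangle_areas(mesh$nodes, tets[, c(1, 3, 4), drop = FALSE]),
    triangle_areas(mesh$nodes, tets[, c(1, 2, 4), drop = FALSE]),
    triangle_areas(mesh$nodes, tets[, c(1, 2, 3), drop = FALSE]))
  h <- 3 * v / amax
  dt <- Inf
  for (r in unique(mesh$region[active])) {
    m <- smallStrainModuli(materials[[r]])
    if (m$density <= 0) stop("zero density in region '", r, "'")
    cdil <- sqrt((m$kappa + 4 * m$mu / 3) / m$density)
    if (cdil <= 0) next
    dt <- min(dt, min(h[mesh$region[active] == r]) / cdil)
  }
  if (!is.finite(dt)) stop("no finite wave speed in any active region")
  safety * dt
}

#' Explicit dynamic run
#'
#' Lumped-mass central-difference integration of a vessel mesh under a
#' prescribed displacement pulse at one longitudinal end (smooth half-cosine
#' ramp from 0 to the amplitude over the rise time, then held), optionally
#' with a held follower pressure. An energy ledger (external work, kinetic,
#' strain) is maintained; the run aborts with a diagnostic on numerical
#' instability or NaN fields.
#'
#' @param mesh a `vessel_mesh`.
#' @param materials named list of `material_model`s per region.
#' @param load a [loadCase()]; its `end_pulse` defines the pulse and its
#'   `pulse_pressure` (mmHg) a held follower pressure. Fixtures come from
#'   `load$fixed` (pass `fixed = list()` for unconstrained far structures).
#' @param duration total time (us), default 20.
#' @param output_times snapshot times (us), default `c(1, 2, 5, 10, 20)`.
#' @param dt time step (us); defaults to [stableTimestep()].
#' @param regions regions to include (default: all).
#' @param u0,v0 optional initial nodal displacement / velocity (N x 3).
#' @param damping mass-proportional Rayleigh damping coefficient (1/us),
#'   default 0 (undamped).
#' @param safety CFL safety factor when `dt` is derived.
#' @param ledger_stride record the energy ledger every this many steps.
#' @return a `dynamic_series`: snapshot times, displacement fields, element
#'   von Mises fields (MPa, `NA` for inactive elements), and the energy
#'   ledger.
#' @export
runExplicit <- function(mesh, materials = NULL, load = loadCase(fixed = list()),
                        duration = 20, output_times = c(1, 2, 5, 10, 20),
                        dt = NULL, regions = NULL, u0 = NULL, v0 = NULL,
                        damping = 0, safety = 0.5, ledger_stride = NULL) {
  if (is.null(materials)) materials <- defaultMaterials(mesh)
  if (is.null(regions)) regions <- intersect(unique(mesh$region),
                                             names(materials))
  active <- mesh$region %in% regions
  tets <- mesh$tets[active, , drop = FALSE]
  enc <- encode_materials(mesh, materials, active)
  pre <- fem_precompute(mesh$nodes, tets)
  N <- nrow(mesh$nodes)
  if (is.null(dt)) dt <- stableTimestep(mesh, materials, regions, safety)
  nsteps <- as.integer(ceiling(duration / dt))
  output_times <- sort(unique(output_times))
  out_steps <- pmin(as.integer(round(output_times / dt)), nsteps)
  out_steps <- sort(unique(out_steps))

  # lumped mass
  mass <- numeric(N)
  mv <- rep(enc$mpar[, 7] * pre$V0 / 4, 4)
  ms <- rowsum(mv, as.vector(tets))
  mass[as.integer(rownames(ms))] <- ms[, 1]
  active_nodes <- which(mass > 0)

  # constrained dofs: configured fixtures + all dofs of inactive nodes
  fixed_dofs <- integer(0)
  for (nm in names(load$fixed)) {
    nodes <- mesh$node_sets[[nm]]
    if (is.null(nodes)) stop("unknown node set in fixed: ", nm)
    comps <- comp_index[strsplit(load$fixed[[nm]], "")[[1]]]
    fixed_dofs <- c(fixed_dofs, as.vector(outer(3L * (nodes - 1L), comps, "+")))
  }
  inactive <- setdiff(seq_len(N), active_nodes)
  fixed_dofs <- unique(c(fixed_dofs,
                         as.vector(outer(3L * (inactive - 1L), 1:3, "+"))))
  mass[inactive] <- 1 # never used (fixed), avoid division by zero

  pulse <- load$end_pulse
  if (is.null(pulse)) {
    presc_nodes <- integer(0); pdir <- 2L; amp <- 0; rise <- 1; prof <- 0L
  } else {
    presc_nodes <- intersect(mesh$node_sets[[load$pulse_set]], active_nodes)
    pdir <- comp_index[[pulse$direction]] - 1L
    amp <- pulse$amplitude; rise <- pulse$rise
    prof <- if (identical(pulse$profile, "linear")) 1L else 0L
  }
  p <- mmHgToMPa(load$pulse_pressure)
  fac <- if (p > 0) mesh$surface_sets$inner_lumen else
    matrix(0L, 0, 3)
  if (is.null(u0)) u0 <- matrix(0, N, 3)
  if (is.null(v0)) v0 <- matrix(0, N, 3)
  if (is.null(ledger_stride)) ledger_stride <- max(1L, nsteps %/% 4000L)

  res <- explicit_run(mesh$nodes, tets, pre$G, pre$V0, enc$mtype, enc$mpar,
                      enc$proj, mass, dt, nsteps,
                      as.integer(fixed_dofs - 1L),
                      as.integer(presc_nodes), pdir, amp, rise, prof,
                      fac, p, u0, v0, out_steps, damping,
                      as.integer(ledger_stride))
  if (res$status == 1L)
    stop("explicit run aborted: kinetic energy exceeds 10x external work ",
         "(numerical instability); reduce dt")
  if (res$status == 2L) stop("explicit run aborted: non-finite field detected")
  if (res$status == 3L) stop("explicit run aborted: inverted element ",
                             res$bad)
  Mfull <- nrow(mesh$tets)
  vm <- lapply(seq_len(res$n_out), function(i) {
    out <- rep(NA_real_, Mfull); out[active] <- res$vm[[i]]; out
  })
  led <- as.data.frame(res$ledger[seq_len(res$n_ledger), , drop = FALSE])
  names(led) <- c("t", "W_ext", "KE", "SE")
  structure(list(times = res$times[seq_len(res$n_out)],
                 U = res$U[seq_len(res$n_out)], vm = vm,
                 ledger = led, dt = dt, nsteps = nsteps,
                 active = active, load = load, regions = regions),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("dynamic_series: %d snapshots over %g us (dt = %.4g us, %d steps)\n",
              length(x$times), max(x$times), x$dt, x$nsteps))
  cat(sprintf("  energy drift: %.3g%%\n", 100 * energyDrift(x)))
  invisible(x)
}

#' Relative energy-balance drift of a dynamic series
#'
#' `max_t |W_ext - (KE + SE)| / max(max|W_ext|, max SE)` over the ledger.
#'
#' @param series a `dynamic_series`.
#' @return relative drift (dimensionless).
#' @export
energyDrift <- function(series) {
  led <- series$ledger
  num <- max(abs(led$W_ext - (led$KE + led$SE)))
  den <- max(max(abs(led$W_ext)), max(led$SE), 1e-300)
  num / den
}

#' Explicit run from a pre-pressurized static state
#'
#' Solves the static follower-pressure inflation at `pp` mmHg (on the full
#' mesh, blood included, so the static and dynamic formulations match
#' exactly), then integrates the end-stretch pulse dynamically from the
#' stressed configuration with the pressure held throughout. With `pp = 0`
#' the path is identical to [runExplicit()] from a cold start.
#'
#' @param mesh a `vessel_mesh`.
#' @param materials named list of `material_model`s per region.
#' @param pp pulse pressure in mmHg.
#' @param then a [loadCase()] with the `end_pulse` to apply (its fixtures
#'   are used for the dynamic phase; the static phase fixes both ends).
#' @param duration,output_times,dt,damping,... passed to [runExplicit()].
#' @return a `dynamic_series`.
#' @export
couplePrestress <- function(mesh, materials = NULL, pp, then,
                            duration = 20, output_times = c(1, 2, 5, 10, 20),
                            dt = NULL, damping = 0, ...) {
  if (is.null(materials)) materials <- defaultMaterials(mesh)
  dyn_load <- loadCase(pulse_pressure = pp, end_pulse = then$end_pulse,
                       pulse_set = then$pulse_set, fixed = then$fixed,
                       follower = TRUE)
  if (pp == 0)
    return(runExplicit(mesh, materials, dyn_load, duration = duration,
                       output_times = output_times, dt = dt,
                       damping = damping, ...))
  static_load <- loadCase(pulse_pressure = pp,
                          fixed = list(end_A = "xyz", end_B = "xyz"))
  st <- solveStatic(mesh, materials, static_load,
                    regions = unique(mesh$region))
  runExplicit(mesh, materials, dyn_load, duration = duration,
              output_times = output_times, dt = dt, u0 = st$u,
              damping = damping, ...)
}
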