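# Surface stress statistics: unwrapped (z, arc) grid sampling of von Mises
# stress, area-weighted histograms with Gaussian fits, threshold area
# fractions, and stress-front tracking / propagation velocity.
#
# All stresses are reported in kPa at this interface (internal MPa x 1000).

facet_owners <- function(mesh, surface) {
  fac <- mesh$surface_sets[[surface]]
  if (is.null(fac)) stop("unknown surface set: ", surface)
  own <- attr(fac, "owner")
  if (is.null(own)) stop("surface set has no owner map")
  list(fac = fac, owner = own)
}

#' Sample a surface field on an unwrapped grid
#'
#' Area-averages per-element von Mises values of the facets of a
#' (topologically cylindrical) surface set into cells of the unwrapped
#' (axial z, circumferential arc s) plane; the default cell is
#' 10 um x 10 um.
#'
#' @param state a `field_state`, a `dynamic_series` snapshot index paired
#'   via [summarize()], or a numeric vector of per-element values (MPa).
#' @param mesh the `vessel_mesh`.
#' @param surface facet set to sample (default `"outer_wall"`).
#' @param cell grid cell size in um.
#' @return a `surface_stress_sample`: matrices `value` (kPa) and `area`
#'   (um^2) of dimension n_z x n_s, plus grid metadata.
#' @export
gridSample <- function(state, mesh, surface = "outer_wall", cell = 10) {
  values <- if (inherits(state, "field_state")) state$vm else state
  fo <- facet_owners(mesh, surface)
  fac <- fo$fac
  v_f <- values[fo$owner]
  if (anyNA(v_f)) stop("surface facets owned by inactive elements")
  cen <- (mesh$nodes[fac[, 1], , drop = FALSE] +
          mesh$nodes[fac[, 2], , drop = FALSE] +
          mesh$nodes[fac[, 3], , drop = FALSE]) / 3
  a_f <- triangle_areas(mesh$nodes, fac)
  r_f <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  Rbar <- mean(r_f)
  if (stats::sd(r_f) > 0.5 * Rbar)
    stop("surface is not cylindrical enough to unwrap; ",
         "use facet-level statistics instead")
  L <- mesh$length
  nz <- ceiling(L / cell)
  ns <- ceiling(2 * pi * Rbar / cell)
  iz <- pmin(pmax(floor(cen[, 3] / cell) + 1L, 1L), nz)
  th <- atan2(cen[, 2], cen[, 1]) %% (2 * pi)
  is <- pmin(floor(th * Rbar / cell) + 1L, ns)
  idx <- (is - 1L) * nz + iz
  area <- matrix(0, nz, ns)
  wsum <- matrix(0, nz, ns)
  asum <- rowsum(a_f, idx)
  vsum <- rowsum(a_f * v_f, idx)
  ids <- as.integer(rownames(asum))
  area[ids] <- asum[, 1]
  wsum[ids] <- vsum[, 1]
  value <- ifelse(area > 0, wsum / pmax(area, 1e-300), NA_real_) * 1000 # kPa
  structure(list(value = value, area = area, cell = cell, length = L,
                 radius = Rbar, surface = surface),
            class = "surface_stress_sample")
}

#' @export
print.surface_stress_sample <- function(x, ...) {
  cat(sprintf("surface_stress_sample: %d x %d cells of %g um, surface '%s'\n",
              nrow(x$value), ncol(x$value), x$cell, x$surface))
  cat(sprintf("  sigma_S range %.3g - %.3g kPa over %.4g um^2\n",
              min(x$value, na.rm = TRUE), max(x$value, na.rm = TRUE),
              sum(x$area)))
  invisible(x)
}

#' Gaussian fit of the surface stress distribution
#'
#' Least-squares Gaussian fitted to the area-weighted histogram of the cell
#' values (default 1 kPa bins); the fitted mean is reported as the
#' distribution mode.
#'
#' @param sample a `surface_stress_sample` (or numeric vector of kPa values,
#'   equally weighted).
#' @param bin_width histogram bin width in kPa (default 1). Narrow
#'   distributions are re-binned automatically so the histogram spans at
#'   least 12 bins.
#' @param threshold threshold for the reported area fraction (kPa).
#' @return a `stress_summary`: histogram (edges, area-weighted frequencies
#'   summing to 1), `gaussian_fit` (mu, sigma, amplitude, r_squared,
#'   converged, poor_fit flag), `fraction_above_threshold`, `sigma_smax`.
#' @export
fitGaussian <- function(sample, bin_width = 1, threshold = 10) {
  if (inherits(sample, "surface_stress_sample")) {
    ok <- !is.na(sample$value)
    v <- sample$value[ok]; w <- sample$area[ok]
  } else {
    v <- as.numeric(sample); w <- rep(1, length(v))
  }
  if (length(v) < 10) stop("need at least 10 cells to fit a distribution")
  rng <- max(v) - min(v)
  if (rng < 1e-12)
    stop("degenerate distribution: zero spread across cells")
  # narrow distributions get proportionally finer bins so the fit is posed
  bin_width <- min(bin_width, rng / 12)
  w <- w / sum(w)
  edges <- seq(floor(min(v) / bin_width) * bin_width,
               max(v) + bin_width, by = bin_width)
  bin <- pmin(findInterval(v, edges), length(edges) - 1L)
  freq <- numeric(length(edges) - 1L)
  fs <- rowsum(w, bin)
  freq[as.integer(rownames(fs))] <- fs[, 1]
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  mu0 <- sum(w * v); sd0 <- sqrt(max(sum(w * (v - mu0)^2), 1e-12))
  df <- data.frame(x = centers, y = freq)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                      start = list(A = max(freq), mu = mu0, s = sd0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # a fitted mode outside the data range means the fit degenerated
  if (!is.null(fit)) {
    mu_hat <- stats::coef(fit)[["mu"]]
    if (mu_hat < min(v) - bin_width || mu_hat > max(v) + bin_width) fit <- NULL
  }
  if (is.null(fit)) {
    warning("Gaussian fit did not converge; reporting the empirical mode")
    gf <- list(mu = centers[which.max(freq)], sigma = sd0, amplitude = max(freq),
               r_squared = NA_real_, converged = FALSE, poor_fit = TRUE)
  } else {
    cf <- stats::coef(fit)
    pred <- cf[["A"]] * exp(-(centers - cf[["mu"]])^2 / (2 * cf[["s"]]^2))
    ssr <- sum((freq - pred)^2); sst <- sum((freq - mean(freq))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
    gf <- list(mu = cf[["mu"]], sigma = abs(cf[["s"]]), amplitude = cf[["A"]],
               r_squared = r2, converged = TRUE,
               poor_fit = is.na(r2) || r2 < 0.8)
  }
  frac <- sum(w[v >= threshold])
  structure(list(histogram = list(edges = edges, freq = freq),
                 gaussian_fit = gf,
                 fraction_above_threshold = frac, threshold = threshold,
                 sigma_smax = max(v)),
            class = "stress_summary")
}

#' @export
print.stress_summary <- function(x, ...) {
  gf <- x$gaussian_fit
  cat(sprintf("stress_summary: mode %.3g kPa (sigma %.3g), sigma_Smax %.3g kPa\n",
              gf$mu, gf$sigma, x$sigma_smax))
  cat(sprintf("  fraction of area >= %g kPa: %.4f%s\n", x$threshold,
              x$fraction_above_threshold,
              if (isTRUE(gf$poor_fit)) "  [poor Gaussian fit]" else ""))
  invisible(x)
}

#' Area fraction above a stress threshold
#'
#' @param sample a `surface_stress_sample`.
#' @param threshold stress threshold in kPa (default 10).
#' @param weight `"area"` (default) or `"count"`.
#' @return fraction in `[0, 1]` of surface area (or cell count) with
#'   `sigma_S >= threshold`.
#' @export
fractionAbove <- function(sample, threshold = 10, weight = c("area", "count")) {
  weight <- match.arg(weight)
  ok <- !is.na(sample$value)
  v <- sample$value[ok]
  w <- if (weight == "area") sample$area[ok] else rep(1, sum(ok))
  sum(w[v >= threshold]) / sum(w)
}

#' Track the propagating stress front of a dynamic series
#'
#' Per snapshot, the front position is the axial coordinate of the global
#' maximum of outer-surface von Mises stress; facets within `tie_tol` of the
#' maximum count as ties, resolved to the position farthest from the loaded
#' end. The mean velocity is (last - first position)/(elapsed time);
#' per-interval velocities are also reported.
#'
#' @param series a `dynamic_series`.
#' @param mesh the `vessel_mesh`.
#' @param surface facet set (default `"outer_wall"`; for sinusoids the
#'   blood/marrow interface `"inner_lumen"`).
#' @param tie_tol relative tie tolerance on the maximum (default 0.02).
#' @param loaded_end `"A"` (z = 0) or `"B"`.
#' @return a `front_trace`: times, front positions (um), per-snapshot peak
#'   `sigma_smax` (kPa), mean velocity `v_s` (um/us) and per-interval
#'   velocities.
#' @export
trackFront <- function(series, mesh, surface = NULL, tie_tol = 0.02,
                       loaded_end = "A") {
  if (length(series$times) < 2) stop("need at least 2 snapshots")
  if (is.null(surface))
    surface <- if ("outer_wall" %in% names(mesh$surface_sets)) "outer_wall"
               else "inner_lumen" # sinusoid: the vessel surface itself
  fo <- facet_owners(mesh, surface)
  cen_z <- (mesh$nodes[fo$fac[, 1], 3] + mesh$nodes[fo$fac[, 2], 3] +
            mesh$nodes[fo$fac[, 3], 3]) / 3
  nt <- length(series$times)
  pos <- numeric(nt); peak <- numeric(nt)
  for (i in seq_len(nt)) {
    v <- series$vm[[i]][fo$owner] * 1000 # kPa
    mx <- max(v)
    peak[i] <- mx
    if (mx <= 1e-12) { pos[i] <- NA_real_; next }
    cand <- cen_z[v >= (1 - tie_tol) * mx]
    pos[i] <- if (loaded_end == "A") max(cand) else min(cand)
  }
  if (all(is.na(pos))) stop("undefined front: all-zero stress fields")
  ok <- which(!is.na(pos))
  i0 <- ok[1]; i1 <- ok[length(ok)]
  elapsed <- series$times[i1] - series$times[i0]
  v_s <- if (elapsed > 0) abs(pos[i1] - pos[i0]) / elapsed else 0
  dv <- diff(pos[ok]) / diff(series$times[ok])
  structure(list(times = series$times, positions = pos, sigma_smax = peak,
                 v_s = v_s, interval_velocities = dv, surface = surface),
            class = "front_trace")
}

#' @export
print.front_trace <- function(x, ...) {
  cat(sprintf("front_trace on '%s': v_S = %.3g um/us\n", x$surface, x$v_s))
  cat(sprintf("  positions %s um at t = %s us\n",
              paste(signif(x$positions, 3), collapse = ", "),
              paste(signif(x$times, 3), collapse = ", ")))
  invisible(x)
}

#' Bundle the surface-stress statistics of a solution
#'
#' For a static `field_state`: grid sample, Gaussian-fitted histogram,
#' threshold fraction and `sigma_smax`. For a `dynamic_series`:
#' additionally the front trace and the peak stress over time;
#' `sigma_smax` is the maximum over surface and time.
#'
#' @param x a `field_state` or `dynamic_series`.
#' @param mesh the `vessel_mesh`.
#' @param surface facet set; default `outer_wall` (`inner_lumen` for
#'   sinusoids).
#' @param cell sampling cell size (um).
#' @param bin_width histogram bin (kPa).
#' @param threshold area-fraction threshold (kPa).
#' @return a list report with elements `sample`, `summary` (`stress_summary`
#'   or NULL for a uniform field), `sigma_smax` (kPa), and for dynamics
#'   `front` (a `front_trace`) and `sigma_smax_t`.
#' @export
summarize <- function(x, mesh, surface = NULL, cell = 10, bin_width = 1,
                      threshold = 10) {
  if (is.null(surface))
    surface <- if ("outer_wall" %in% names(mesh$surface_sets)) "outer_wall"
               else "inner_lumen" # sinusoid: the vessel surface itself
  if (inherits(x, "field_state")) {
    sam <- gridSample(x, mesh, surface, cell)
    vals <- sam$value[!is.na(sam$value)]
    uniform <- (max(vals) - min(vals)) < 1e-12
    summ <- if (uniform) NULL else fitGaussian(sam, bin_width, threshold)
    list(kind = "static", sample = sam, summary = summ,
         uniform_field = uniform,
         sigma_smax = max(vals),
         fraction_above = fractionAbove(sam, threshold))
  } else if (inherits(x, "dynamic_series")) {
    front <- tryCatch(trackFront(x, mesh, surface),
                      error = function(e) NULL)
    last <- gridSample(x$vm[[length(x$vm)]], mesh, surface, cell)
    peak_t <- if (!is.null(front)) front$sigma_smax else
      vapply(x$vm, function(v) 1000 * max(v[facet_owners(mesh, surface)$owner]), 0)
    vals <- last$value[!is.na(last$value)]
    uniform <- length(vals) == 0 || (max(vals) - min(vals)) < 1e-12
    list(kind = "dynamic", sample = last,
         summary = if (uniform) NULL else fitGaussian(last, bin_width, threshold),
         uniform_field = uniform,
         sigma_smax = max(peak_t),
         sigma_smax_t = peak_t, front = front,
         v_s = if (!is.null(front)) front$v_s else NA_real_)
  } else stop("summarize expects a field_state or dynamic_series")
}
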