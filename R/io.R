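# File formats and orchestration: STL read/write (ASCII + binary) with
# vertex deduplication and small-hole bridging, VTU export of solution
# fields, YAML run configuration with unit suffixes, and the one-stop
# pipeline driver.

#' Read a triangulated surface from STL
#'
#' Handles ASCII and binary STL. Vertices are deduplicated to a 1e-6 um
#' tolerance; boundary loops whose maximum chord is at most `bridge_gap` are
#' closed by fan triangulation (small-hole bridging); a manifold check is
#' reported via attributes.
#'
#' @param path STL file.
#' @param bridge_gap maximum hole chord to bridge (um), default 4.2; set to
#'   0 to disable.
#' @param tol vertex deduplication tolerance (um).
#' @return a `surface_mesh` with attributes `n_bridged` and `manifold`.
#' @export
readSTL <- function(path, bridge_gap = 4.2, tol = 1e-6) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("STL format error: file too short (size ", sz, ")")
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  head_txt <- suppressWarnings(rawToChar(head[head != as.raw(0)]))
  if (!validUTF8(head_txt)) head_txt <- ""
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("STL format error: vertex count ", length(vl),
           " is not a multiple of 3")
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    if (anyNA(nums)) stop("STL format error: unparsable vertex line")
    verts <- nums
  } else {
    if (sz < 84) stop("STL format error at byte ", sz, ": truncated header")
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (sz != 84 + 50 * nt)
      stop("STL format error at byte ", sz, ": expected ", 84 + 50 * nt,
           " bytes for ", nt, " triangles")
    body <- readBin(con, "raw", n = 50 * nt)
    base <- 50 * (seq_len(nt) - 1L)
    verts <- matrix(0, 3 * nt, 3)
    for (vtx in 1:3) for (k in 1:3) {
      off <- 12L + 12L * (vtx - 1L) + 4L * (k - 1L)
      bytes <- body[rep(base + off, each = 4L) + rep(1:4, nt)]
      verts[3L * (seq_len(nt) - 1L) + vtx, k] <-
        readBin(bytes, "numeric", size = 4, n = nt, endian = "little")
    }
  }
  key <- paste(round(verts[, 1] / tol), round(verts[, 2] / tol),
               round(verts[, 3] / tol))
  uid <- match(key, unique(key))
  first <- !duplicated(uid)
  v <- verts[first, , drop = FALSE]
  tr <- matrix(uid, ncol = 3, byrow = TRUE)
  degen <- tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]
  tr <- tr[!degen, , drop = FALSE]
  surf <- surfaceMesh(v, tr, label = sub("\\.stl$", "", basename(path),
                                         ignore.case = TRUE))
  nb <- 0L
  if (bridge_gap > 0) {
    br <- bridge_holes(surf, bridge_gap)
    surf <- br$surface; nb <- br$n_bridged
  }
  edges <- rbind(surf$triangles[, 1:2], surf$triangles[, 2:3],
                 surf$triangles[, c(3, 1)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(ek)
  manifold <- all(cnt <= 2)
  if (!manifold)
    warning("non-manifold surface: ", sum(cnt > 2), " edges shared by >2 triangles")
  attr(surf, "n_bridged") <- nb
  attr(surf, "manifold") <- manifold && all(cnt == 2)
  surf
}

# close small boundary loops (max chord <= gap) by centroid fan
bridge_holes <- function(surf, gap) {
  tr <- surf$triangles
  edges <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(ek)
  bnd <- edges[cnt[ek] == 1, , drop = FALSE]
  if (nrow(bnd) == 0) return(list(surface = surf, n_bridged = 0L))
  # follow loops
  nxt <- split(bnd[, 2], bnd[, 1])
  visited <- rep(FALSE, nrow(bnd))
  loops <- list()
  bkey <- paste(bnd[, 1], bnd[, 2])
  for (i in seq_len(nrow(bnd))) {
    if (visited[i]) next
    loop <- bnd[i, 1]; cur <- bnd[i, 2]
    visited[i] <- TRUE
    steps <- 0
    while (cur != loop[1] && steps < nrow(bnd) + 1) {
      loop <- c(loop, cur)
      cand <- nxt[[as.character(cur)]]
      if (is.null(cand)) break
      cur2 <- cand[1]
      visited[bkey == paste(cur, cur2)] <- TRUE
      cur <- cur2
      steps <- steps + 1
    }
    if (cur == loop[1] && length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  v <- surf$vertices; newtr <- list(); nb <- 0L
  for (loop in loops) {
    pts <- v[loop, , drop = FALSE]
    chord <- max(stats::dist(pts))
    if (chord > gap) next
    cen <- colMeans(pts)
    v <- rbind(v, cen)
    ci <- nrow(v)
    k <- length(loop)
    newtr[[length(newtr) + 1]] <-
      cbind(ci, loop, loop[c(2:k, 1)])
    nb <- nb + 1L
  }
  if (nb == 0L) return(list(surface = surf, n_bridged = 0L))
  out <- surfaceMesh(v, rbind(surf$triangles, do.call(rbind, newtr)),
                     label = surf$label, clean = FALSE)
  list(surface = out, n_bridged = nb)
}

#' Write a surface to STL
#'
#' @param surface a `surface_mesh`.
#' @param path output file.
#' @param binary write binary STL (default `FALSE` = ASCII).
#' @export
writeSTL <- function(surface, path, binary = FALSE) {
  v <- surface$vertices; tr <- surface$triangles
  n <- triangle_normals(v, tr)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste0("binary STL ", surface$label)))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(c(n[i, ], v[tr[i, 1], ], v[tr[i, 2], ], v[tr[i, 3], ])),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    lines <- character(0)
    out <- file(path, "w")
    on.exit(close(out))
    writeLines(paste0("solid ", surface$label), out)
    for (i in seq_len(nrow(tr))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           v[tr[i, ], 1], v[tr[i, ], 2], v[tr[i, ], 3]),
                   "    endloop", "  endfacet"), out)
    }
    writeLines(paste0("endsolid ", surface$label), out)
  }
  invisible(path)
}

vtu_array <- function(name, x, ncomp = 1, type = "Float64") {
  vals <- if (type == "Float64") sprintf("%.17g", x) else sprintf("%d", x)
  paste0('        <DataArray type="', type, '" Name="', name,
         '" NumberOfComponents="', ncomp, '" format="ascii">\n          ',
         paste(vals, collapse = " "), "\n        </DataArray>")
}

#' Export solution fields as VTU
#'
#' Writes one VTK unstructured-grid (.vtu, XML ascii) file per snapshot with
#' nodal displacement and per-element von Mises stress, plus an index file
#' listing snapshot times for a series.
#'
#' @param state a `field_state` or `dynamic_series`.
#' @param mesh the `vessel_mesh`.
#' @param path output path; for a series used as a prefix
#'   (`<path>_t<k>.vtu` plus `<path>_index.csv`).
#' @return invisibly, the files written.
#' @export
writeFields <- function(state, mesh, path) {
  write_one <- function(u, vm, file) {
    N <- nrow(mesh$nodes); M <- nrow(mesh$tets)
    vm_out <- ifelse(is.na(vm), 0, vm) * 1000 # kPa
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0"?>',
      '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
      "  <UnstructuredGrid>",
      sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', N, M),
      "      <Points>",
      vtu_array("Points", as.vector(t(mesh$nodes)), 3),
      "      </Points>",
      "      <Cells>",
      vtu_array("connectivity", as.vector(t(mesh$tets)) - 1L, 1, "Int32"),
      vtu_array("offsets", 4L * seq_len(M), 1, "Int32"),
      vtu_array("types", rep(10L, M), 1, "UInt8"),
      "      </Cells>",
      "      <PointData>",
      vtu_array("displacement", as.vector(t(u)), 3),
      "      </PointData>",
      "      <CellData>",
      vtu_array("von_mises_kPa", vm_out, 1),
      "      </CellData>",
      "    </Piece>",
      "  </UnstructuredGrid>",
      "</VTKFile>"), con)
    file
  }
  if (inherits(state, "field_state")) {
    f <- write_one(state$u, state$vm,
                   if (grepl("\\.vtu$", path)) path else paste0(path, ".vtu"))
    return(invisible(f))
  }
  if (!inherits(state, "dynamic_series")) stop("unsupported state")
  files <- character(0)
  for (i in seq_along(state$times)) {
    f <- sprintf("%s_t%03d.vtu", path, i)
    write_one(state$U[[i]], state$vm[[i]], f)
    files <- c(files, f)
  }
  idx <- sprintf("%s_index.csv", path)
  utils::write.csv(data.frame(snapshot = seq_along(state$times),
                              time_us = state$times, file = basename(files)),
                   idx, row.names = FALSE)
  invisible(c(files, idx))
}

#' Read back a VTU file written by [writeFields()]
#'
#' Minimal reader for the package's own VTU output (requires the `xml2`
#' package).
#'
#' @param path .vtu file.
#' @return list with `points`, `connectivity` (1-based), `displacement`,
#'   `von_mises_kPa`.
#' @export
readVTU <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("readVTU requires the xml2 package")
  doc <- xml2::read_xml(path)
  arr <- function(name) {
    nd <- xml2::xml_find_first(doc, sprintf(".//DataArray[@Name='%s']", name))
    as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
  }
  pts <- matrix(arr("Points"), ncol = 3, byrow = TRUE)
  conn <- matrix(as.integer(arr("connectivity")), ncol = 4, byrow = TRUE) + 1L
  list(points = pts, connectivity = conn,
       displacement = matrix(arr("displacement"), ncol = 3, byrow = TRUE),
       von_mises_kPa = arr("von_mises_kPa"))
}

# ---- run configuration ------------------------------------------------------

parse_quantity <- function(x, expect = NULL) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^\\s*([-0-9.eE+]+)\\s*([A-Za-z]*)\\s*$", x))[[1]]
  if (length(m) < 2 || is.na(suppressWarnings(as.numeric(m[2]))))
    stop("cannot parse quantity: ", x)
  val <- as.numeric(m[2]); unit <- m[3]
  if (!is.null(expect) && nzchar(unit) && unit != expect)
    stop("expected unit '", expect, "' but got '", unit, "' in: ", x)
  val
}

#' Run configuration
#'
#' A serializable description of one pipeline run. Quantities may carry
#' unit suffixes when read from YAML (`pulse_pressure: 50 mmHg`,
#' `length: 200 um`).
#'
#' @param vessel_class vessel type.
#' @param mode `"static"`, `"dynamic"` or `"couple"`.
#' @param pulse_pressure mmHg.
#' @param bending_strain dimensionless bone bending strain (converted to a
#'   midspan displacement via [midspanDisplacement()]).
#' @param characteristic_edge target mesh edge (um).
#' @param wiggle centerline irregularity amplitude (um).
#' @param duration,output_times dynamics timing (us).
#' @param seed integer seed.
#' @param outdir output directory (`NULL` = no files written).
#' @param geometry named list of overrides passed to [vesselSpec()].
#' @param materials named list of material overrides, e.g.
#'   `list(wall = list(C10 = 0.2))`.
#' @return object of class `run_config`.
#' @export
runConfig <- function(vessel_class = "artery", mode = "static",
                      pulse_pressure = 0, bending_strain = 0,
                      characteristic_edge = 3, wiggle = 0,
                      duration = 20, output_times = c(1, 2, 5, 10, 20),
                      seed = 1L, outdir = NULL, geometry = list(),
                      materials = list()) {
  if (!mode %in% c("static", "dynamic", "couple"))
    stop("config error: mode must be static, dynamic or couple")
  if (!vessel_class %in% c("artery", "arteriole", "sinusoid"))
    stop("config error: unknown vessel_class '", vessel_class, "'")
  structure(list(vessel_class = vessel_class, mode = mode,
                 pulse_pressure = parse_quantity(pulse_pressure, "mmHg"),
                 bending_strain = parse_quantity(bending_strain),
                 characteristic_edge = parse_quantity(characteristic_edge, "um"),
                 wiggle = parse_quantity(wiggle, "um"),
                 duration = parse_quantity(duration, "us"),
                 output_times = vapply(output_times, parse_quantity, 0, expect = "us"),
                 seed = as.integer(seed), outdir = outdir,
                 geometry = geometry, materials = materials),
            class = "run_config")
}

#' @rdname runConfig
#' @param path YAML file.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

#' @rdname runConfig
#' @param config a `run_config`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' One-stop pipeline run
#'
#' Geometry -> materials -> solve (static / dynamic / coupled) ->
#' post-process -> optional VTU/CSV/JSON files. Deterministic for a fixed
#' config (the seed controls the centerline irregularity).
#'
#' @param config a [runConfig()].
#' @return report list with the summary statistics (fields in kPa / um/us)
#'   and, when `outdir` is set, the files written.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(runConfig, config)
  geo <- config$geometry
  geo$vessel_class <- config$vessel_class
  geo$characteristic_edge <- config$characteristic_edge
  geo$centerline_wiggle_amplitude <- config$wiggle
  geo$seed <- config$seed
  spec <- do.call(vesselSpec, geo)
  mesh <- if (config$vessel_class == "sinusoid") makeSinusoidDomain(spec)
          else makeTubeMesh(spec)
  materials <- defaultMaterials(mesh)
  for (r in names(config$materials)) {
    ov <- config$materials[[r]]
    materials[[r]] <- do.call(
      if (!is.null(ov$E)) linear_elastic else mooney_rivlin5, ov)
  }
  d_mid <- if (config$bending_strain > 0)
    midspanDisplacement(config$bending_strain, mesh$length) else 0

  if (config$mode == "static") {
    load <- loadCase(pulse_pressure = config$pulse_pressure, bending = d_mid)
    state <- solveStatic(mesh, materials, load)
    rep_ <- summarize(state, mesh)
  } else if (config$mode == "dynamic") {
    load <- loadCase(pulse_pressure = 0,
                     end_pulse = list(amplitude = 1, rise = 1, direction = "z"),
                     fixed = if (config$vessel_class == "sinusoid")
                       list(marrow_outer = "xyz") else list())
    state <- runExplicit(mesh, materials, load, duration = config$duration,
                         output_times = config$output_times)
    rep_ <- summarize(state, mesh)
  } else {
    then <- loadCase(end_pulse = list(amplitude = 1, rise = 1, direction = "z"),
                     fixed = if (config$vessel_class == "sinusoid")
                       list(marrow_outer = "xyz", end_B = "xyz")
                     else list(end_A = "xy", end_B = "xyz"))
    state <- couplePrestress(mesh, materials, config$pulse_pressure, then,
                             duration = config$duration,
                             output_times = config$output_times)
    rep_ <- summarize(state, mesh)
  }

  report <- list(
    config = unclass(config),
    n_nodes = nrow(mesh$nodes), n_tets = nrow(mesh$tets),
    sigma_smax_kPa = rep_$sigma_smax,
    fraction_above_10kPa = if (rep_$kind == "static") rep_$fraction_above
                           else fractionAbove(rep_$sample),
    gaussian_mode_kPa = if (!is.null(rep_$summary)) rep_$summary$gaussian_fit$mu
                        else NA_real_,
    uniform_field = rep_$uniform_field,
    v_s_um_per_us = if (rep_$kind == "dynamic") rep_$v_s else NA_real_)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    writeFields(state, mesh, file.path(config$outdir, "fields"))
    if (!is.null(rep_$summary))
      utils::write.csv(
        data.frame(bin_lower = rep_$summary$histogram$edges[-length(rep_$summary$histogram$edges)],
                   frequency = rep_$summary$histogram$freq),
        file.path(config$outdir, "histogram.csv"), row.names = FALSE)
    if (rep_$kind == "dynamic" && !is.null(rep_$front))
      utils::write.csv(
        data.frame(time_us = rep_$front$times, position_um = rep_$front$positions,
                   sigma_smax_kPa = rep_$front$sigma_smax),
        file.path(config$outdir, "front_trace.csv"), row.names = FALSE)
    jsonlite::write_json(report[-1], file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    report$files <- list.files(config$outdir)
  }
  report
}
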