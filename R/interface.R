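# Run configuration (YAML), output writers (CSV trajectories, legacy-ASCII
# VTK structured grids, JSON summaries).

run_config_schema <- list(
  device = c("preset", "particles", "tilt_deg", "drive_voltage"),
  numerics = c("mode", "tol", "streaming", "streaming_grid"),
  output = c("directory"),
  seed = NULL)

run_config_defaults <- list(
  device = list(preset = "validation", particles = "beads",
                tilt_deg = NULL, drive_voltage = NULL),
  numerics = list(mode = "overdamped", tol = 1e-6, streaming = TRUE,
                  streaming_grid = c(64L, 24L, 8L)),
  output = list(directory = "sawstream-out"),
  seed = 1L)

#' Load a run configuration
#'
#' YAML configuration with sections `device`, `numerics`, `output` and a
#' top-level `seed`. Unknown keys are a hard error (they are listed);
#' missing keys take documented defaults, and the provenance of every
#' applied default is recorded in the returned object's
#' `"default_provenance"` attribute. Units are SI throughout; keys that
#' carry units say so in their names where ambiguity is possible.
#'
#' @param path YAML file path.
#' @return named list of class `run_config` with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown_top <- setdiff(names(raw), names(run_config_schema))
  if (length(unknown_top))
    stopf("unknown config key(s): %s (allowed: %s)",
          paste(unknown_top, collapse = ", "),
          paste(names(run_config_schema), collapse = ", "))
  for (sec in names(run_config_schema)) {
    keys <- run_config_schema[[sec]]
    if (is.null(keys) || is.null(raw[[sec]])) next
    unknown <- setdiff(names(raw[[sec]]), keys)
    if (length(unknown))
      stopf("unknown config key(s) in '%s': %s (allowed: %s)", sec,
            paste(unknown, collapse = ", "), paste(keys, collapse = ", "))
  }
  prov <- character()
  cfg <- run_config_defaults
  for (sec in c("device", "numerics", "output")) {
    for (k in names(cfg[[sec]])) {
      if (!is.null(raw[[sec]]) && k %in% names(raw[[sec]])) {
        cfg[[sec]][k] <- raw[[sec]][k]
      } else {
        prov <- c(prov, sprintf("%s.%s = %s (default)", sec, k,
                                paste(format(cfg[[sec]][[k]]),
                                      collapse = " ")))
      }
    }
  }
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  else prov <- c(prov, sprintf("seed = %d (default)", cfg$seed))
  structure(cfg, class = "run_config", default_provenance = prov)
}

#' Serialize a run configuration back to YAML
#'
#' Round-trips with [load_config()]: loading the dump yields an identical
#' resolved configuration.
#'
#' @param cfg `run_config`. @param path output file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  x <- unclass(cfg)
  attr(x, "default_provenance") <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write simulation outputs
#'
#' Writes tidy trajectory CSVs (`time, particle, x, y, z, vx, vy, vz` and
#' the per-step force decomposition), VTK structured-grid snapshots of any
#' supplied fields (real and imaginary parts as separate arrays) and a
#' JSON summary holding the separation metrics, amplitude, validity
#' report, package version and seed. Fails before any computation if the
#' directory cannot be created.
#'
#' @param results list as returned by [run_device()] (or at least
#'   `trajectories` and `outlet`), plus optional `fields` (named list of
#'   `first_order_field`) and `streaming` (named list of
#'   `second_order_field`).
#' @param config `run_config` (its seed is recorded in every header).
#' @param extra named list merged into the JSON summary (e.g. contrast
#'   factors).
#' @return character vector of the files written.
#' @export
write_outputs <- function(results, config, extra = list()) {
  dir <- config$output$directory
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", dir)
  seed <- config$seed
  written <- character()
  # trajectories
  if (!is.null(results$trajectories)) {
    rows <- list()
    for (si in seq_along(results$trajectories)) {
      trs <- results$trajectories[[si]]
      for (pi in seq_along(trs)) {
        tr <- as.data.frame(trs[[pi]])
        tr$stage <- si
        tr$particle <- attr(trs[[pi]], "particle")$label
        rows[[length(rows) + 1]] <- tr
      }
    }
    df <- do.call(rbind, rows)
    f <- file.path(dir, "trajectories.csv")
    con <- file(f, "w")
    writeLines(sprintf("# sawstream trajectories; seed = %d", seed), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    written <- c(written, f)
  }
  # fields
  for (nm in names(results$streaming %||% list())) {
    f <- file.path(dir, paste0("streaming_", nm, ".vtk"))
    write_vtk_structured(f, results$streaming[[nm]], seed = seed)
    written <- c(written, f)
  }
  for (nm in names(results$fields %||% list())) {
    f <- file.path(dir, paste0("field_", nm, ".vtk"))
    write_vtk_field(f, results$fields[[nm]], seed = seed)
    written <- c(written, f)
  }
  # summary
  summ <- c(list(
    package = "sawstream",
    version = as.character(utils::packageVersion("sawstream")),
    seed = seed,
    delta_m = results$outlet$delta %||% NA,
    outlet = results$outlet$positions %||% NULL,
    stages = lapply(results$stages %||% list(), function(s)
      list(kind = s$kind, p_a = s$p_a, flow = s$flow))),
    extra)
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  written <- c(written, f)
  written
}

#' Write a second-order field as a legacy-ASCII VTK structured grid
#'
#' @param path output file. @param sof `second_order_field`.
#' @param seed recorded in the VTK header line.
#' @return `path`, invisibly.
#' @export
write_vtk_structured <- function(path, sof, seed = NA) {
  nx <- sof$grid[1]; ny <- sof$grid[2]; nz <- sof$grid[3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("sawstream streaming field; seed = %s", seed),
               "ASCII", "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
               sprintf("X_COORDINATES %d double", nx),
               paste(format(sof$x, digits = 12), collapse = " "),
               sprintf("Y_COORDINATES %d double", ny),
               paste(format(sof$y, digits = 12), collapse = " "),
               sprintf("Z_COORDINATES %d double", nz),
               paste(format(sof$z, digits = 12), collapse = " "),
               sprintf("POINT_DATA %d", nx * ny * nz),
               "VECTORS v2 double"), con)
  # VTK wants x fastest; arrays are [x, y, z] so aperm to x-fastest order
  vecs <- cbind(as.vector(sof$u), as.vector(sof$v), as.vector(sof$w))
  writeLines(apply(vecs, 1, function(r)
    paste(format(r, digits = 9), collapse = " ")), con)
  writeLines(c("SCALARS p2 double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(sof$p), digits = 9), con)
  invisible(path)
}

#' Write a first-order field snapshot as VTK (real and imaginary parts)
#'
#' Samples the analytic field on a regular grid over the footprint at a
#' fixed height and writes pressure real/imaginary parts as separate
#' scalar arrays.
#'
#' @param path output file. @param f `first_order_field`.
#' @param n grid points per axis. @param z sampling height, m.
#' @param seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(path, f, n = 64, z = 20e-6, seed = NA) {
  g <- f$geometry
  xs <- seq(0, g$L, length.out = n)
  ys <- seq(0, g$w, length.out = n)
  xq <- rep(xs, times = n); yq <- rep(ys, each = n)
  p <- f$pressure(xq, yq, z)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("sawstream first-order field; seed = %s", seed),
               "ASCII", "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", n, n, 1L),
               sprintf("X_COORDINATES %d double", n),
               paste(format(xs, digits = 12), collapse = " "),
               sprintf("Y_COORDINATES %d double", n),
               paste(format(ys, digits = 12), collapse = " "),
               "Z_COORDINATES 1 double",
               format(z, digits = 12),
               sprintf("POINT_DATA %d", n * n),
               "SCALARS p1_re double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(Re(p), digits = 9), con)
  writeLines(c("SCALARS p1_im double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(Im(p), digits = 9), con)
  invisible(path)
}

#' Minimal VTK rectilinear-grid reader (structural round-trip check)
#'
#' Parses files written by [write_vtk_structured()] / [write_vtk_field()]
#' back into coordinate vectors and named data arrays; used to verify the
#' files are structurally valid.
#'
#' @param path VTK file.
#' @return list with `dims`, `x`, `y`, `z`, `data` (named list).
#' @export
read_vtk_rectilinear <- function(path) {
  ln <- readLines(path)
  stopifnot(grepl("^# vtk DataFile", ln[1]),
            any(grepl("DATASET RECTILINEAR_GRID", ln)))
  dims <- as.integer(strsplit(sub("DIMENSIONS ", "",
                                  grep("^DIMENSIONS", ln, value = TRUE)),
                              " ")[[1]])
  getcoord <- function(axis) {
    i <- grep(sprintf("^%s_COORDINATES", axis), ln)
    as.numeric(strsplit(trimws(ln[i + 1]), "\\s+")[[1]])
  }
  npts <- prod(dims)
  data <- list()
  i <- grep("^POINT_DATA", ln) + 1
  while (i <= length(ln)) {
    header <- ln[i]
    if (grepl("^VECTORS", header)) {
      nm <- strsplit(header, " ")[[1]][2]
      vals <- do.call(rbind, lapply(ln[(i + 1):(i + npts)], function(s)
        as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
      data[[nm]] <- vals
      i <- i + npts + 1
    } else if (grepl("^SCALARS", header)) {
      nm <- strsplit(header, " ")[[1]][2]
      vals <- as.numeric(ln[(i + 2):(i + 1 + npts)])
      data[[nm]] <- vals
      i <- i + npts + 2
    } else i <- i + 1
  }
  list(dims = dims, x = getcoord("X"), y = getcoord("Y"),
       z = getcoord("Z"), data = data)
}
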