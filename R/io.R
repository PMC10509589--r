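# Field I/O: legacy-ASCII VTK unstructured-grid snapshots plus a JSON series
# index, CSV waveforms, and a CSV bundle for wall shear series. All files
# store SI units; doubles are written with 17 significant digits so round
# trips are exact at double precision.

fmt_num <- function(x) sprintf("%.17g", x)

write_vtk_snapshot <- function(file, mesh, vectors = NULL, scalars = NULL,
                               vec_name = "velocity", sc_name = "value") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "haemopost snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(apply(mesh$nodes, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(apply(mesh$tets - 1L, 1L, function(r)
    paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  if (!is.null(vectors)) {
    writeLines(sprintf("VECTORS %s double", vec_name), con)
    writeLines(apply(vectors, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
  }
  if (!is.null(scalars)) {
    writeLines(sprintf("SCALARS %s double 1", sc_name), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(fmt_num(scalars), con)
  }
  invisible(file)
}

read_vtk_snapshot <- function(file) {
  toks <- scan(file, what = character(), quiet = TRUE, comment.char = "#")
  eat <- function(i, kw) {
    if (toupper(toks[i]) != kw)
      stop_hp("malformed VTK file %s: expected %s", file, kw, class = "format_error")
    i + 1L
  }
  i <- which(toupper(toks) == "DATASET")[1]
  if (is.na(i) || toupper(toks[i + 1L]) != "UNSTRUCTURED_GRID")
    stop_hp("%s is not an unstructured grid", file, class = "format_error")
  i <- which(toupper(toks) == "POINTS")[1]
  n <- as.integer(toks[i + 1L])
  pts <- matrix(as.numeric(toks[(i + 3L):(i + 2L + 3L * n)]), n, 3L, byrow = TRUE)
  i <- which(toupper(toks) == "CELLS")[1]
  m <- as.integer(toks[i + 1L]); sz <- as.integer(toks[i + 2L])
  cell_tok <- as.integer(toks[(i + 3L):(i + 2L + sz)])
  if (sz != 5L * m || any(cell_tok[seq(1L, sz, by = 5L)] != 4L))
    stop_hp("%s contains non-tetrahedral cells", file,
            class = "unsupported_mesh_error")
  tets <- matrix(cell_tok, m, 5L, byrow = TRUE)[, 2:5, drop = FALSE] + 1L
  i <- which(toupper(toks) == "CELL_TYPES")[1]
  types <- as.integer(toks[(i + 2L):(i + 1L + m)])
  if (any(types != 10L))
    stop_hp("%s contains non-tetrahedral cell types", file,
            class = "unsupported_mesh_error")
  out <- list(nodes = pts, tets = tets)
  iv <- which(toupper(toks) == "VECTORS")
  if (length(iv)) {
    iv <- iv[1]
    out$vectors <- matrix(as.numeric(toks[(iv + 3L):(iv + 2L + 3L * n)]),
                          n, 3L, byrow = TRUE)
  }
  is_ <- which(toupper(toks) == "SCALARS")
  if (length(is_)) {
    is_ <- is_[1] + 6L  # SCALARS name type 1 LOOKUP_TABLE default
    out$scalars <- as.numeric(toks[is_:(is_ + n - 1L)])
  }
  out
}

#' Write a velocity field as a VTK time series
#'
#' One legacy-ASCII VTK file per snapshot plus a `series.json` index holding
#' the snapshot times and cycle period.
#'
#' @param field an `hd_velocity_field`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_field <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("snapshot_%04d.vtk", seq_along(field$values))
  for (k in seq_along(field$values))
    write_vtk_snapshot(file.path(dir, files[k]), field$mesh, field$values[[k]])
  idx <- list(kind = "velocity", units = "SI", period = field$grid$period,
              times = field$grid$times, files = files)
  jsonlite::write_json(idx, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a wall shear series as a CSV bundle
#'
#' @param tau an `hd_wall_shear_field`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_wall_shear <- function(tau, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("tau_%04d.csv", seq_along(tau$tau))
  for (k in seq_along(tau$tau)) {
    df <- data.frame(node_id = tau$wall_node_ids,
                     tx = fmt_num(tau$tau[[k]][, 1]),
                     ty = fmt_num(tau$tau[[k]][, 2]),
                     tz = fmt_num(tau$tau[[k]][, 3]))
    utils::write.csv(df, file.path(dir, files[k]), row.names = FALSE,
                     quote = FALSE)
  }
  idx <- list(kind = "wall_shear", units = "SI", period = tau$grid$period,
              times = tau$grid$times, files = files)
  jsonlite::write_json(idx, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a field series from disk
#'
#' Reads the layouts written by [write_field()] / [write_wall_shear()] (or a
#' scalar nodal map as a single CSV with columns `node_id,value`). Velocity
#' series are returned as `hd_velocity_field`, wall shear series as
#' `hd_wall_shear_field`.
#'
#' @param path series directory (velocity / wall shear) or CSV file (scalar).
#' @param kind `"velocity"`, `"wall_shear"` or `"scalar"`.
#' @return the typed field object.
#' @export
load_field <- function(path, kind = c("velocity", "wall_shear", "scalar")) {
  kind <- match.arg(kind)
  if (kind == "scalar") {
    df <- utils::read.csv(path)
    return(stats::setNames(df$value, df$node_id))
  }
  idx_path <- file.path(path, "series.json")
  if (!file.exists(idx_path))
    stop_hp("missing series.json in %s (no time metadata)", path,
            class = "format_error")
  idx <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  if (is.null(idx$times) || is.null(idx$period))
    stop_hp("series.json lacks time metadata", class = "format_error")
  if (length(idx$times) < 2L)
    stop_hp("series has %d snapshot(s); at least 2 are required",
            length(idx$times), class = "time_grid_error")
  grid <- check_uniform_times(idx$times, idx$period)
  if (!identical(idx$kind, kind))
    stop_hp("series kind is %s, requested %s", idx$kind, kind,
            class = "format_error")
  if (kind == "velocity") {
    snaps <- lapply(file.path(path, idx$files), read_vtk_snapshot)
    mesh <- hd_mesh(snaps[[1]]$nodes, snaps[[1]]$tets)
    velocity_field(mesh, grid, lapply(snaps, `[[`, "vectors"))
  } else {
    tau <- lapply(file.path(path, idx$files), function(f) {
      df <- utils::read.csv(f)
      cbind(df$tx, df$ty, df$tz)
    })
    ids <- utils::read.csv(file.path(path, idx$files[1]))$node_id
    wall_shear_field(ids, grid, tau)
  }
}

#' Read or write a waveform CSV
#'
#' Waveforms are stored as two-column CSV files (`time_s`, `value`).
#'
#' @param path CSV path.
#' @return data.frame with columns `time_s`, `value`.
#' @export
read_waveform <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop_hp("waveform CSV needs columns time_s,value", class = "format_error")
  df
}

#' @rdname read_waveform
#' @param time_s,value waveform samples.
#' @export
write_waveform <- function(path, time_s, value) {
  utils::write.csv(data.frame(time_s = fmt_num(time_s), value = fmt_num(value)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
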