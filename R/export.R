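#' Export cell-centred fields as a legacy VTK structured-points file
#'
#' ASCII legacy VTK, readable by ParaView. Vector velocity is written if the
#' state components are supplied (face values averaged to centres).
#'
#' @param file output path (`.vtk`).
#' @param grid a `cartesian_grid`.
#' @param fields named list of numeric arrays with dims `grid$n` (scalars)
#'   or `c(grid$n, 3)` (vectors).
#' @export
write_vtk_structured <- function(file, grid, fields) {
  n <- grid$n
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aortaflow fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %g %g %g", grid$origin[1] + grid$h[1] / 2,
                       grid$origin[2] + grid$h[2] / 2,
                       grid$origin[3] + grid$h[3] / 2),
               sprintf("SPACING %g %g %g", grid$h[1], grid$h[2], grid$h[3]),
               sprintf("POINT_DATA %d", prod(n))), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (length(dim(f)) == 4) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      m <- cbind(as.numeric(f[, , , 1]), as.numeric(f[, , , 2]),
                 as.numeric(f[, , , 3]))
      writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(f), digits = 9), con)
    }
  }
  invisible(file)
}

#' Export wall samples as legacy VTK polydata
#'
#' Points with outward normals and one scalar array (WSS or pressure).
#'
#' @param file output path.
#' @param surface a surface field as returned by [wall_traction()] /
#'   [wss_magnitude()] / [wall_pressure()], or any list with `points`,
#'   `normals`, `values`.
#' @param name scalar array name.
#' @export
write_vtk_polydata <- function(file, surface, name = "value") {
  p <- surface$points
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aortaflow surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(p))), con)
  writeLines(paste(p[, 1], p[, 2], p[, 3]), con)
  writeLines(sprintf("POINT_DATA %d", nrow(p)), con)
  v <- surface$values
  if (is.matrix(v)) {
    writeLines(sprintf("VECTORS %s double", name), con)
    writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  } else {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(v), digits = 9), con)
  }
  writeLines(sprintf("NORMALS normals double"), con)
  writeLines(paste(surface$normals[, 1], surface$normals[, 2],
                   surface$normals[, 3]), con)
  invisible(file)
}

#' Triangulate the zero level set
#'
#' Marching-tetrahedra triangulation of `phi = 0` over the dual lattice of
#' cell centres.
#'
#' @param geom a `levelset_geometry`.
#' @return Numeric matrix with 9 columns (three xyz vertices per triangle).
#' @export
surface_triangulation <- function(geom) {
  marching_tet_cpp(as.numeric(geom$phi), geom$grid$n, geom$grid$h,
                   geom$grid$origin)
}

#' Total area of a surface triangulation
#'
#' @param tri triangle matrix from [surface_triangulation()].
#' @return Area (m^2).
#' @export
surface_area <- function(tri) {
  e1 <- tri[, 4:6] - tri[, 1:3]
  e2 <- tri[, 7:9] - tri[, 1:3]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Write the wall surface as a binary STL file
#'
#' @param geom a `levelset_geometry`.
#' @param file output `.stl` path.
#' @export
write_stl <- function(geom, file) {
  tri <- surface_triangulation(geom)
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
  for (r in seq_len(nrow(tri))) {
    e1 <- tri[r, 4:6] - tri[r, 1:3]
    e2 <- tri[r, 7:9] - tri[r, 1:3]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    mg <- sqrt(sum(nrm^2))
    if (mg > 0) nrm <- nrm / mg
    writeBin(as.numeric(c(nrm, tri[r, ])), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(file)
}
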