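#' Write a field snapshot as a legacy VTK structured-points file
#'
#' ASCII legacy VTK with cell-centered scalars `r` (phase fraction), `p`
#' (pressure) and the cell-centered velocity vector; readable by ParaView
#' and VisIt.
#'
#' @param snapshot one element of a run's `snapshots` list
#' @param geometry `pc_geometry`
#' @param path output file path (.vtk)
#' @return `path`, invisibly
#' @export
write_snapshot_vtk <- function(snapshot, geometry, path) {
  r <- snapshot$r
  nx <- nrow(r); ny <- ncol(r)
  dx <- geometry$W1 / nx; dy <- geometry$H_total / ny
  uc <- cell_centered_u(snapshot$u)
  vc <- cell_centered_v(snapshot$v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("pcslosh snapshot t=%.6g", snapshot$t),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", dx / 2, dy / 2),
               sprintf("SPACING %g %g 1", dx, dy),
               sprintf("POINT_DATA %d", nx * ny)), con)
  wf <- function(name, M) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", as.vector(M)), con)
  }
  wf("phase_fraction", r)
  wf("pressure", snapshot$p)
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.9g %.9g 0", as.vector(uc), as.vector(vc)), con)
  invisible(path)
}
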