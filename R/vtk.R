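#' Write cell fields to a legacy-ASCII VTK file
#'
#' Writes the structured grid and any number of cell-centered fields as a
#' legacy VTK `STRUCTURED_POINTS` dataset with `CELL_DATA`, readable by
#' standard visualization tools (ParaView, VisIt). Plain text.
#'
#' @param mesh a `thermo_mesh`.
#' @param fields named list of per-cell numeric vectors.
#' @param path output file path (conventionally `.vtk`).
#' @return the path, invisibly.
#' @export
write_vtk <- function(mesh, fields, path) {
  stopifnot(inherits(mesh, "thermo_mesh"), is.list(fields),
            length(names(fields)) == length(fields))
  dims <- c(mesh$cells, rep(1L, 3 - mesh$dim)) + c(rep(1L, mesh$dim),
                                                   rep(0L, 3 - mesh$dim))
  sp <- c(mesh$h, rep(1, 3 - mesh$dim))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "thermoembo cell fields",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.10g %.10g %.10g", sp[1], sp[2], sp[3]),
               sprintf("CELL_DATA %d", mesh$ncell)), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    stopifnot(length(v) == mesh$ncell)
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default",
                 paste(sprintf("%.10g", v), collapse = "\n")), con)
  }
  invisible(path)
}

#' Write all checkpoints of a run as VTK files
#'
#' One file per checkpoint (`checkpoint_0000.vtk`, ...) holding temperature,
#' bolus saturation and blood pressure, plus the per-step ledger as CSV.
#'
#' @param sim a [run_simulation()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_checkpoints <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(sim$checkpoints)) {
    cp <- sim$checkpoints[[k]]
    write_vtk(sim$config$mesh,
              list(temperature = cp$u, s_bolus = cp$s_bolus,
                   p_blood = cp$p_blood),
              file.path(dir, sprintf("checkpoint_%04d.vtk", k - 1)))
  }
  write.csv(sim$ledger, file.path(dir, "ledger.csv"), row.names = FALSE)
  invisible(dir)
}
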