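# Result serialization: flat TSV trace tables, JSON metric summaries, and
# ASCII VTK rectilinear-grid exports of the mesh classification and field
# snapshots.  All physical quantities carry their units in column names.

#' Write probe traces as TSV
#'
#' One row per sample: `time_ms`, then `v_mV`, `ue_mV`, `ui_mV` (and
#' `ina_uA_cm2` when recorded) per probe.
#'
#' @param result an `emi_result`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_traces_tsv <- function(result, path) {
  np <- ncol(result$v)
  tab <- data.frame(time_ms = result$time)
  lbl <- function(stub) sprintf("%s_p%d", stub, seq_len(np))
  vcols <- as.data.frame(result$v); names(vcols) <- lbl("v_mV")
  ecols <- as.data.frame(result$ue); names(ecols) <- lbl("ue_mV")
  icols <- as.data.frame(result$ui); names(icols) <- lbl("ui_mV")
  tab <- cbind(tab, vcols, ecols, icols)
  if (!is.null(result$ina)) {
    ncols <- as.data.frame(result$ina); names(ncols) <- lbl("ina_uA_cm2")
    tab <- cbind(tab, ncols)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a metric table as TSV and JSON
#'
#' @param metrics a data.frame of metrics (one row per condition).
#' @param path_base output path without extension; writes `.tsv` and
#'   `.json`.
#' @param run_id identifier stored in the JSON summary.
#' @return The two paths, invisibly.
#' @export
write_metrics <- function(metrics, path_base, run_id = "run") {
  tsv <- paste0(path_base, ".tsv")
  jsn <- paste0(path_base, ".json")
  utils::write.table(metrics, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(run = run_id, metrics = metrics), jsn,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, jsn))
}

#' Export the mesh (and optionally a snapshot) as VTK rectilinear grid
#'
#' Writes a legacy-format ASCII VTK file with the integer node class array
#' (0 extracellular, 1 Dirichlet, 2 Neumann, 3 intracellular, 4 membrane,
#' 5 disc), the cell index, and optionally the potential field of a
#' snapshot (u_e on extracellular nodes, u_i on intracellular ones, the
#' intracellular trace on interfaces).  Coordinates are written in um.
#'
#' @param mesh an `emi_mesh`.
#' @param path output `.vtk` file.
#' @param snapshot optional snapshot from `emi_result$snapshots`.
#' @param system the `emi_system` (required with `snapshot` to map the
#'   unknown layout onto nodes).
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, path, snapshot = NULL, system = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- mesh$nx * mesh$ny * mesh$nz
  cat("# vtk DataFile Version 3.0\n", file = con)
  cat("EMI strand mesh\nASCII\nDATASET RECTILINEAR_GRID\n", file = con)
  cat(sprintf("DIMENSIONS %d %d %d\n", mesh$nx, mesh$ny, mesh$nz),
      file = con)
  wr <- function(tag, v) {
    cat(sprintf("%s %d double\n", tag, length(v)), file = con)
    cat(format(v / 1e-4, digits = 10), fill = 72, file = con)
  }
  wr("X_COORDINATES", mesh$xs)
  wr("Y_COORDINATES", mesh$ys)
  wr("Z_COORDINATES", mesh$zs)
  cat(sprintf("POINT_DATA %d\n", n), file = con)
  cat("SCALARS node_class int 1\nLOOKUP_TABLE default\n", file = con)
  cat(mesh$cls, fill = 72, file = con)
  cat("SCALARS cell_index int 1\nLOOKUP_TABLE default\n", file = con)
  cat(mesh$c1, fill = 72, file = con)
  if (!is.null(snapshot)) {
    if (is.null(system)) stop("snapshot export needs the emi_system")
    lay <- system$lay
    u <- numeric(n)
    sel_e <- lay$ue > 0 & lay$ui == 0
    u[sel_e] <- snapshot$u[lay$ue[sel_e]]
    sel_i <- lay$ui > 0
    u[sel_i] <- snapshot$u[lay$ui[sel_i]]
    dn <- mesh$disc$node
    if (length(dn)) u[dn] <- snapshot$u[lay$dL[dn]]
    cat("SCALARS potential_mV double 1\nLOOKUP_TABLE default\n",
        file = con)
    cat(format(u, digits = 8), fill = 72, file = con)
  }
  invisible(path)
}
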