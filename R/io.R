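#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Elements are written as 6-node triangles (type 9) with the material
#' code as physical tag; boundary edges as 3-node lines (type 8) with the
#' marker as physical tag.
#'
#' @param mesh a \code{breast_mesh}.
#' @param path output file.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.9g %.9g 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  nel <- nrow(mesh$tri); nbe <- nrow(mesh$belem)
  writeLines(c("$EndNodes", "$Elements", as.character(nel + nbe)), con)
  if (nbe > 0)
    writeLines(sprintf("%d 8 2 %d %d %d %d %d", seq_len(nbe),
                       mesh$belem[, "marker"], mesh$belem[, "marker"],
                       mesh$belem[, "n1"], mesh$belem[, "n2"],
                       mesh$belem[, "mid"]), con)
  ## MSH type-9 node order: corners then mids (12, 23, 31), as stored
  writeLines(sprintf("%d 9 2 %d %d %d %d %d %d %d %d", nbe + seq_len(nel),
                     mesh$material, mesh$material,
                     mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3],
                     mesh$tri[, 4], mesh$tri[, 5], mesh$tri[, 6]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a mesh written by [write_mesh_msh()]
#' @param path MSH 2.2 ASCII file.
#' @return list with \code{nodes}, \code{tri}, \code{material},
#'   \code{belem} (as in a \code{breast_mesh}; the cell-status grid is not
#'   stored in the format).
#' @export
read_mesh_msh <- function(path) {
  lines <- readLines(path)
  ni <- which(lines == "$Nodes")
  nn <- as.integer(lines[ni + 1L])
  nd <- do.call(rbind, strsplit(lines[(ni + 2L):(ni + 1L + nn)], " "))
  nodes <- cbind(as.numeric(nd[, 2]), as.numeric(nd[, 3]))
  ei <- which(lines == "$Elements")
  ne <- as.integer(lines[ei + 1L])
  el <- strsplit(lines[(ei + 2L):(ei + 1L + ne)], " ")
  tri <- list(); mat <- integer(0); be <- list()
  for (e in el) {
    v <- as.integer(e)
    if (v[2] == 9L) {
      tri[[length(tri) + 1L]] <- v[6:11]
      mat <- c(mat, v[4])
    } else if (v[2] == 8L) {
      be[[length(be) + 1L]] <- c(v[6], v[7], v[8], v[4])
    }
  }
  belem <- do.call(rbind, be)
  if (!is.null(belem)) colnames(belem) <- c("n1", "n2", "mid", "marker")
  list(nodes = nodes, tri = do.call(rbind, tri), material = mat,
       belem = belem)
}

#' Write a mesh (optionally with solution fields) as legacy ASCII VTK
#'
#' Quadratic triangles (VTK cell type 22).  Point displacements and cell
#' fields of a solved state are attached when given.
#'
#' @param mesh a \code{breast_mesh}.
#' @param path output file.
#' @param state optional \code{mechanical_state} providing displacements
#'   and per-element J, W and normalised stress.
#' @export
write_mesh_vtk <- function(mesh, path, state = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); nel <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0", "breast mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(paste("CELLS", nel, nel * 7L), con)
  writeLines(sprintf("6 %d %d %d %d %d %d",
                     mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L, mesh$tri[, 4] - 1L,
                     mesh$tri[, 5] - 1L, mesh$tri[, 6] - 1L), con)
  writeLines(paste("CELL_TYPES", nel), con)
  writeLines(rep("22", nel), con)
  writeLines(paste("CELL_DATA", nel), con)
  writeLines(c("SCALARS material int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$material), con)
  if (!is.null(state)) {
    writeLines(c("SCALARS J double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", state$J), con)
    writeLines(c("SCALARS W double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", state$W), con)
    writeLines(c("SCALARS Ehat double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", normalized_stress(state)), con)
    writeLines(paste("POINT_DATA", n), con)
    writeLines("VECTORS displacement double", con)
    um <- matrix(state$u, ncol = 2, byrow = TRUE)
    writeLines(sprintf("%.9g %.9g 0", um[, 1], um[, 2]), con)
  }
  invisible(path)
}

#' Write a healing trajectory time series as CSV
#'
#' Columns: week, wound area (mm^2), major and minor wound axes (mm) and
#' the clinical phase label.
#'
#' @param traj a \code{healing_trajectory} from [coupling_loop()].
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  rows <- lapply(traj$records, function(r) {
    dims <- if (is.null(r$wound_polygon))
      c(major = 0, minor = 0) else cavity_dimensions(r$wound_polygon)
    data.frame(week = r$week, wound_area_mm2 = r$wound_area,
               wound_major_mm = dims[["major"]],
               wound_minor_mm = dims[["minor"]],
               phase = phase_of_week(r$week))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a lattice healing state as CSV
#'
#' Columns: axial coordinates q, r; occupancy; growth-factor
#' concentration; active-layer membership.
#'
#' @param state a \code{healing_state}.
#' @param path output file.
#' @export
write_lattice_csv <- function(state, path) {
  df <- data.frame(q = state$lattice$axial[, 1], r = state$lattice$axial[, 2],
                   occupied = as.integer(state$occupied),
                   c = state$c, active = as.integer(state$active))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
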