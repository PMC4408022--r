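## Element material codes.  1..3 follow the tissue label codes; scar and
## inflamed tissue only exist on meshes.
MATERIAL_LEVELS <- c(fat = 1L, glandular = 2L, skin = 3L,
                     scar = 5L, inflamed = 6L)

## Boundary-edge markers.
EDGE_MARKERS <- c(skin_surface = 1L, chest_wall = 2L, cavity_wall = 3L)

#' Specification of the virtual-lumpectomy cavity
#'
#' @param center cavity-bed centre (x, y) in mm.
#' @param bed_axes full major and minor axes of the cavity bed (mm).
#' @param margin negative surgical margin added radially to each semi-axis
#'   (mm), so the effective semi-axes are \code{bed_axes/2 + margin}.
#' @param orientation major-axis direction (radians from x axis).
#' @return a \code{cavity_spec}.
#' @export
cavity_spec <- function(center, bed_axes = c(12, 9), margin = 5,
                        orientation = pi / 2) {
  stopifnot(length(center) == 2, all(bed_axes > 0), margin >= 0)
  structure(list(center = center, bed_axes = bed_axes, margin = margin,
                 orientation = orientation),
            class = "cavity_spec")
}

#' Build a quadratic triangular mesh from a tissue label map
#'
#' Pixels are aggregated into square cells of side at most
#' \code{target_size}; each retained cell is split into two quadratic
#' (6-node) triangles carrying the cell's majority tissue material.
#' Boundary edges are marked \code{skin_surface}, \code{chest_wall}
#' (clamped in the mechanics) or \code{cavity_wall}.
#'
#' @param map a \code{tissue_label_map}.
#' @param target_size upper bound on the element edge length (mm).
#' @return a \code{breast_mesh}: nodes (mm), \code{tri} (6-column
#'   connectivity: corners then edge midpoints), per-element
#'   \code{material}, boundary edge table, the cell-status grid the mesh
#'   was built from, cell size \code{h} and \code{origin}.
#' @export
build_mesh <- function(map, target_size = 2) {
  stopifnot(inherits(map, "tissue_label_map"), target_size > 0)
  p <- map$pixel_pitch
  k <- max(1L, floor(target_size / p + 1e-9))
  lab <- map$labels
  ncy <- nrow(lab) %/% k; ncx <- ncol(lab) %/% k
  if (ncy < 1 || ncx < 1) stop("label map empty at this target size")
  lab <- lab[seq_len(ncy * k), seq_len(ncx * k), drop = FALSE]
  ## per-cell label counts
  cell_of_px <- (((col(lab) - 1L) %/% k) * ncy + ((row(lab) - 1L) %/% k)) + 1L
  status <- matrix(0L, ncy, ncx)
  counts <- sapply(TISSUE_LEVELS, function(v)
    tabulate(cell_of_px[lab == v], nbins = ncy * ncx))
  fg <- counts[, "fat"] + counts[, "glandular"] + counts[, "skin"]
  tot <- k * k
  is_chest <- counts[, "chest"] > tot / 2
  is_fg <- !is_chest & fg >= tot / 2
  mat2 <- counts[, c("fat", "glandular")]
  best <- max.col(mat2, ties.method = "first")
  status[] <- 0L
  status[is_chest] <- -1L
  status[is_fg] <- c(MATERIAL_LEVELS[["fat"]],
                     MATERIAL_LEVELS[["glandular"]])[best[is_fg]]
  ## the 1 mm skin film is thinner than the elements: any boundary cell
  ## with a substantial skin-pixel share becomes a skin element, so the
  ## skin band is resolved at one element width
  is_skin <- is_fg & counts[, "skin"] >= pmax(1, tot / 4)
  status[is_skin] <- MATERIAL_LEVELS[["skin"]]
  status <- keep_largest_component(status)
  if (!any(status > 0L)) stop("empty foreground: nothing to mesh")
  mesh_from_cells(status, h = k * p, origin = map$origin, map = map)
}

## Drop meshed cells not in the largest 4-connected positive component.
keep_largest_component <- function(status) {
  mask <- status > 0L
  if (!any(mask)) return(status)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nr <- nrow(lab); nc <- ncol(lab)
    nb <- pmax(rbind(lab[1, , drop = FALSE] * 0L, lab[-nr, , drop = FALSE]),
               rbind(lab[-1, , drop = FALSE], lab[nr, , drop = FALSE] * 0L),
               cbind(lab[, 1, drop = FALSE] * 0L, lab[, -nc, drop = FALSE]),
               cbind(lab[, -1, drop = FALSE], lab[, nc, drop = FALSE] * 0L))
    new_lab <- pmax(lab, nb * (lab > 0L))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  tab <- table(lab[lab > 0L])
  main <- as.integer(names(tab)[which.max(tab)])
  status[mask & lab != main] <- 0L
  status
}

## Core constructor: cell-status grid -> conforming P2 mesh.
## status codes: 0 outside, -1 chest (not meshed), -2 cavity, >0 material.
mesh_from_cells <- function(status, h, origin, map = NULL) {
  ncy <- nrow(status); ncx <- ncol(status)
  meshed <- which(status > 0L, arr.ind = TRUE)
  nel_cells <- nrow(meshed)
  r <- meshed[, 1]; c <- meshed[, 2]

  corner <- matrix(0L, ncy + 1L, ncx + 1L)
  hmid <- matrix(0L, ncy + 1L, ncx)     # horizontal edge mids at y-levels
  vmid <- matrix(0L, ncy, ncx + 1L)     # vertical edge mids
  dmid <- matrix(0L, ncy, ncx)          # diagonal mids

  mark <- function(m, idx) { m[idx] <- 1L; m }
  corner <- mark(corner, cbind(r, c));     corner <- mark(corner, cbind(r, c + 1L))
  corner <- mark(corner, cbind(r + 1L, c)); corner <- mark(corner, cbind(r + 1L, c + 1L))
  hmid <- mark(hmid, cbind(r, c)); hmid <- mark(hmid, cbind(r + 1L, c))
  vmid <- mark(vmid, cbind(r, c)); vmid <- mark(vmid, cbind(r, c + 1L))
  dmid <- mark(dmid, cbind(r, c))

  ids <- cumsum(c(corner, hmid, vmid, dmid))
  n_corner <- length(corner); n_h <- length(hmid); n_v <- length(vmid)
  corner[corner > 0L] <- ids[which(corner > 0L)]
  hmid[hmid > 0L] <- ids[n_corner + which(hmid > 0L)]
  vmid[vmid > 0L] <- ids[n_corner + n_h + which(vmid > 0L)]
  dmid[dmid > 0L] <- ids[n_corner + n_h + n_v + which(dmid > 0L)]
  nnode <- ids[length(ids)]

  nodes <- matrix(0, nnode, 2)
  ic <- which(corner > 0L, arr.ind = TRUE)
  nodes[corner[ic], ] <- cbind(origin[1] + (ic[, 2] - 1) * h,
                               origin[2] + (ic[, 1] - 1) * h)
  ih <- which(hmid > 0L, arr.ind = TRUE)
  nodes[hmid[ih], ] <- cbind(origin[1] + (ih[, 2] - 0.5) * h,
                             origin[2] + (ih[, 1] - 1) * h)
  iv <- which(vmid > 0L, arr.ind = TRUE)
  nodes[vmid[iv], ] <- cbind(origin[1] + (iv[, 2] - 1) * h,
                             origin[2] + (iv[, 1] - 0.5) * h)
  id <- which(dmid > 0L, arr.ind = TRUE)
  nodes[dmid[id], ] <- cbind(origin[1] + (id[, 2] - 0.5) * h,
                             origin[2] + (id[, 1] - 0.5) * h)

  bl <- corner[cbind(r, c)]; br <- corner[cbind(r, c + 1L)]
  tr <- corner[cbind(r + 1L, c + 1L)]; tl <- corner[cbind(r + 1L, c)]
  hb <- hmid[cbind(r, c)]; ht <- hmid[cbind(r + 1L, c)]
  vl <- vmid[cbind(r, c)]; vr <- vmid[cbind(r, c + 1L)]
  dg <- dmid[cbind(r, c)]
  triA <- cbind(bl, br, tr, hb, vr, dg)
  triB <- cbind(bl, tr, tl, dg, ht, vl)
  tri <- matrix(0L, 2L * nel_cells, 6L)
  tri[seq(1L, 2L * nel_cells, by = 2L), ] <- triA
  tri[seq(2L, 2L * nel_cells, by = 2L), ] <- triB
  material <- rep(status[meshed], each = 2L)
  cell_of_element <- rep(seq_len(nel_cells), each = 2L)

  ## boundary edges, tissue on the left of the direction of travel
  stat_at <- function(rr, cc) {
    out <- rep(0L, length(rr))
    ok <- rr >= 1L & rr <= ncy & cc >= 1L & cc <= ncx
    out[ok] <- status[cbind(rr[ok], cc[ok])]
    out
  }
  marker_for <- function(nb) {
    m <- rep(EDGE_MARKERS[["skin_surface"]], length(nb))
    m[nb == -1L] <- EDGE_MARKERS[["chest_wall"]]
    m[nb == -2L] <- EDGE_MARKERS[["cavity_wall"]]
    m
  }
  edges <- list()
  nb <- stat_at(r, c - 1L); s <- nb <= 0L
  edges[[1]] <- cbind(tl[s], bl[s], vl[s], marker_for(nb[s]))      # left, down
  nb <- stat_at(r, c + 1L); s <- nb <= 0L
  edges[[2]] <- cbind(br[s], tr[s], vr[s], marker_for(nb[s]))      # right, up
  nb <- stat_at(r - 1L, c); s <- nb <= 0L
  edges[[3]] <- cbind(bl[s], br[s], hb[s], marker_for(nb[s]))      # bottom
  nb <- stat_at(r + 1L, c); s <- nb <= 0L
  edges[[4]] <- cbind(tr[s], tl[s], ht[s], marker_for(nb[s]))      # top
  belem <- do.call(rbind, edges)
  colnames(belem) <- c("n1", "n2", "mid", "marker")

  structure(list(nodes = nodes, tri = tri, material = material,
                 belem = belem, status = status, h = h, origin = origin,
                 cell_of_element = cell_of_element, map = map),
            class = "breast_mesh")
}

#' Total meshed area
#' @param mesh a \code{breast_mesh}.
#' @param u optional displacement vector (2 per node) giving deformed area.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh, u = NULL) {
  xy <- mesh$nodes
  if (!is.null(u)) xy <- xy + matrix(u, ncol = 2, byrow = TRUE)
  sum(element_areas(xy, mesh$tri))
}

element_areas <- function(nodes, tri) {
  p1 <- nodes[tri[, 1], , drop = FALSE]
  p2 <- nodes[tri[, 2], , drop = FALSE]
  p3 <- nodes[tri[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
     (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])) / 2
}

#' Minimum interior angle over all elements (degrees)
#' @param mesh a \code{breast_mesh}.
#' @return smallest corner angle in degrees.
#' @export
mesh_min_angle <- function(mesh) {
  xy <- mesh$nodes; tri <- mesh$tri
  ang <- function(a, b, c) {
    v1 <- xy[b, , drop = FALSE] - xy[a, , drop = FALSE]
    v2 <- xy[c, , drop = FALSE] - xy[a, , drop = FALSE]
    num <- v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]
    den <- sqrt(rowSums(v1^2) * rowSums(v2^2))
    acos(pmin(pmax(num / den, -1), 1)) * 180 / pi
  }
  min(ang(tri[, 1], tri[, 2], tri[, 3]),
      ang(tri[, 2], tri[, 3], tri[, 1]),
      ang(tri[, 3], tri[, 1], tri[, 2]))
}

## Cells whose centre falls inside the effective cavity ellipse.
cells_in_ellipse <- function(status, h, origin, cavity) {
  ncy <- nrow(status); ncx <- ncol(status)
  cx <- origin[1] + (rep(seq_len(ncx), each = ncy) - 0.5) * h
  cy <- origin[2] + (rep(seq_len(ncy), times = ncx) - 0.5) * h
  a <- cavity$bed_axes[1] / 2 + cavity$margin
  b <- cavity$bed_axes[2] / 2 + cavity$margin
  co <- cos(cavity$orientation); si <- sin(cavity$orientation)
  dx <- cx - cavity$center[1]; dy <- cy - cavity$center[2]
  xr <- co * dx + si * dy; yr <- -si * dx + co * dy
  matrix((xr / a)^2 + (yr / b)^2 < 1, ncy, ncx)
}

#' Cut the virtual-lumpectomy cavity out of a mesh
#'
#' Removes elements whose cell centre lies inside the effective cavity
#' ellipse (bed semi-axes plus radial margin) and marks the newly exposed
#' boundary as \code{cavity_wall}.
#'
#' @param mesh a \code{breast_mesh} without a cavity.
#' @param cavity a [cavity_spec()].
#' @return a new \code{breast_mesh} with the cavity removed.
#' @export
apply_virtual_lumpectomy <- function(mesh, cavity) {
  stopifnot(inherits(mesh, "breast_mesh"), inherits(cavity, "cavity_spec"))
  status <- mesh$status
  inside <- cells_in_ellipse(status, mesh$h, mesh$origin, cavity)
  if (!any(inside & status > 0L)) stop("cavity ellipse covers no tissue")
  if (any(status[inside] == MATERIAL_LEVELS[["skin"]]) ||
      any(status[inside] <= 0L))
    stop("cavity ellipse breaches the skin or chest wall")
  ## also refuse contact: any cavity cell touching skin/outside/chest
  tch <- touches(inside & status > 0L,
                 status == 0L | status == -1L |
                   status == MATERIAL_LEVELS[["skin"]])
  if (tch) stop("cavity ellipse touches the skin or chest wall")
  status[inside & status > 0L] <- -2L
  out <- mesh_from_cells(status, mesh$h, mesh$origin, map = mesh$map)
  out$cavity <- cavity
  out
}

## TRUE when any TRUE cell of a is 4-adjacent to a TRUE cell of b.
touches <- function(a, b) {
  any(a & dilate4(b))
}

#' Rebuild the mesh after a healing update
#'
#' Cells inside the wound polyline stay open; former cavity cells outside
#' it become scar.  With an empty polyline the wound is closed and the
#' whole former cavity becomes scar.
#'
#' @param mesh a \code{breast_mesh} with a cavity.
#' @param wound closed polyline (mm) of the current wound boundary, or
#'   \code{NULL} for a closed wound.
#' @return a new \code{breast_mesh}.
#' @export
remesh_from_wound <- function(mesh, wound) {
  stopifnot(inherits(mesh, "breast_mesh"))
  status <- mesh$status
  cav <- status == -2L
  if (!any(cav)) stop("mesh has no cavity to update")
  if (!is.null(wound) && nrow(wound) >= 3) {
    idx <- which(cav, arr.ind = TRUE)
    cx <- mesh$origin[1] + (idx[, 2] - 0.5) * mesh$h
    cy <- mesh$origin[2] + (idx[, 1] - 0.5) * mesh$h
    keep_open <- points_in_polygon(cx, cy, wound)
  } else {
    keep_open <- rep(FALSE, sum(cav))
  }
  newstat <- status
  newstat[cav] <- ifelse(keep_open, -2L, MATERIAL_LEVELS[["scar"]])
  out <- mesh_from_cells(newstat, mesh$h, mesh$origin, map = mesh$map)
  out$cavity <- mesh$cavity
  out
}

#' Area of the open cavity hole
#' @param mesh a \code{breast_mesh}.
#' @return hole area in mm^2 (0 when no cavity).
#' @export
cavity_area <- function(mesh) {
  sum(mesh$status == -2L) * mesh$h^2
}

#' Closed polyline of the cavity wall (reference configuration)
#' @param mesh a \code{breast_mesh} with an open cavity.
#' @param u optional displacement vector for the deformed wall.
#' @return vertex matrix (mm), or \code{NULL} when the cavity is closed.
#' @export
cavity_wall_contour <- function(mesh, u = NULL) {
  cav <- mesh$status == -2L
  if (!any(cav)) return(NULL)
  if (is.null(u)) {
    loops <- trace_mask_loops(cav, mesh$h, mesh$origin)
    areas <- vapply(loops, polygon_area, numeric(1))
    poly <- loops[[which.max(abs(areas))]]
    if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    return(simplify_collinear(poly))
  }
  ## deformed: chain the cavity_wall boundary edges
  be <- mesh$belem[mesh$belem[, "marker"] == EDGE_MARKERS[["cavity_wall"]], ,
                   drop = FALSE]
  if (nrow(be) == 0) return(NULL)
  ord <- chain_boundary(be)
  xy <- mesh$nodes + matrix(u, ncol = 2, byrow = TRUE)
  xy[ord, , drop = FALSE]
}

## Chain boundary P2 edges (n1 -> mid -> n2) into an ordered vertex loop.
chain_boundary <- function(be) {
  nxt <- be[, "n2"]; names(nxt) <- be[, "n1"]
  mid <- be[, "mid"]; names(mid) <- be[, "n1"]
  start <- be[1, "n1"]
  ord <- integer(0)
  cur <- start
  for (i in seq_len(nrow(be))) {
    ord <- c(ord, cur, mid[[as.character(cur)]])
    cur <- nxt[[as.character(cur)]]
    if (cur == start) break
  }
  ord
}

#' Outer boundary contour of the breast mesh
#'
#' The ordered loop of outer boundary vertices (skin surface plus chest
#' wall), optionally deformed by a displacement field.  This is the
#' contour the calibration objective rasterises.
#'
#' @param mesh a \code{breast_mesh}.
#' @param u optional displacement vector (2 entries per node, mm).
#' @return closed vertex matrix (mm), counter-clockwise.
#' @export
mesh_skin_contour <- function(mesh, u = NULL) {
  be <- mesh$belem[mesh$belem[, "marker"] != EDGE_MARKERS[["cavity_wall"]], ,
                   drop = FALSE]
  ord <- chain_boundary(be)
  xy <- mesh$nodes
  if (!is.null(u)) xy <- xy + matrix(u, ncol = 2, byrow = TRUE)
  poly <- xy[ord, , drop = FALSE]
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  poly
}

#' Mark an inflamed ring of tissue around the cavity
#'
#' Elements whose cell centre lies within \code{width} of the cavity wall
#' (and are not skin) are relabelled \code{inflamed}; the mechanics then
#' assigns them the inflammation modulus.
#'
#' @param mesh a \code{breast_mesh} with a cavity.
#' @param width ring width in mm.
#' @return the mesh with updated element materials.
#' @export
mark_inflamed_ring <- function(mesh, width = 5) {
  cav <- mesh$status == -2L
  if (!any(cav) || width <= 0) return(mesh)
  ndil <- max(1L, as.integer(round(width / mesh$h)))
  ring <- cav
  for (i in seq_len(ndil)) ring <- dilate4(ring)
  ring <- ring & !cav
  meshed <- which(mesh$status > 0L, arr.ind = TRUE)
  in_ring <- ring[meshed] &
    mesh$status[meshed] != MATERIAL_LEVELS[["skin"]]
  el_ring <- in_ring[mesh$cell_of_element]
  mesh$material[el_ring] <- MATERIAL_LEVELS[["inflamed"]]
  mesh
}

#' @export
print.breast_mesh <- function(x, ...) {
  cat("breast_mesh:", nrow(x$nodes), "nodes,", nrow(x$tri),
      "P2 triangles, h =", format(x$h, digits = 4), "mm\n")
  cat("  materials:", paste(names(MATERIAL_LEVELS)[match(sort(unique(x$material)),
                                                         MATERIAL_LEVELS)],
                            collapse = ", "), "\n")
  cat("  cavity area:", format(cavity_area(x), digits = 5), "mm^2\n")
  invisible(x)
}
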