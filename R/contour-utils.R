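#' @useDynLib bctshape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Signed area of a closed polygon
#'
#' Shoelace formula. Vertices are rows of a two-column matrix; the closing
#' edge from the last vertex back to the first is implied.
#'
#' @param poly numeric matrix with columns x, y (mm).
#' @return Signed area (mm^2); positive for counter-clockwise orientation.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Centroid of a closed polygon (area-weighted)
#' @param poly numeric matrix with columns x, y.
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  cross <- x[j] * y - x * y[j]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(poly[, 1:2, drop = FALSE]))
  cx <- sum((x[j] + x) * cross) / (6 * a)
  cy <- sum((y[j] + y) * cross) / (6 * a)
  c(cx, cy)
}

#' Second-order area moments of a closed polygon about its centroid
#' @param poly vertex matrix (x, y).
#' @return 2x2 covariance matrix of the uniform distribution over the
#'   polygon interior.
#' @export
polygon_covariance <- function(poly) {
  ctr <- polygon_centroid(poly)
  x <- poly[, 1] - ctr[1]; y <- poly[, 2] - ctr[2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  cross <- x[j] * y - x * y[j]
  a <- sum(cross) / 2
  ixx <- sum(cross * (y[j]^2 + y[j] * y + y^2)) / 12
  iyy <- sum(cross * (x[j]^2 + x[j] * x + x^2)) / 12
  ixy <- sum(cross * (x[j] * y[j] * 2 + x[j] * y + x * y[j] + 2 * x * y)) / 24
  matrix(c(iyy, ixy, ixy, ixx), 2, 2) / a
}

#' Test points for inclusion in a closed polygon
#'
#' Vectorised even-odd ray casting.
#'
#' @param px,py point coordinates.
#' @param poly vertex matrix (x, y), closing edge implied.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py))
    if (any(crosses)) {
      xin <- (x[j] - x[i]) * (py[crosses] - y[i]) / (y[j] - y[i]) + x[i]
      inside[crosses] <- xor(inside[crosses], px[crosses] < xin)
    }
    j <- i
  }
  inside
}

## Trace the boundary of a binary mask along pixel edges, so that the traced
## polygon area equals exactly (pixel count) * pitch^2.  Returns loops as a
## list of vertex matrices in physical mm; interior lies to the left of the
## traversal direction (outer loop CCW, holes CW).
trace_mask_loops <- function(mask, pitch, origin = c(0, 0)) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  fg <- which(pad, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("empty mask: nothing to trace")
  r <- fg[, 1]; c <- fg[, 2]
  W <- nc + 3L
  vid <- function(x, y) x + W * y          # corner id; x in 0..nc+2, y likewise
  ## mask rows index y, cols index x: cell (r,c) covers x in [c-1,c], y in [r-1,r]
  ## (in padded pixel units; unpad by subtracting 1 later)
  at <- function(rr, cc) pad[cbind(rr, cc)]
  starts <- integer(0); ends <- integer(0)
  ## left neighbour empty: edge (c-1, r) -> (c-1, r-1)
  s <- !at(r, c - 1L)
  starts <- c(starts, vid(c[s] - 1L, r[s]));      ends <- c(ends, vid(c[s] - 1L, r[s] - 1L))
  ## right neighbour empty: (c, r-1) -> (c, r)
  s <- !at(r, c + 1L)
  starts <- c(starts, vid(c[s], r[s] - 1L));      ends <- c(ends, vid(c[s], r[s]))
  ## bottom neighbour empty: (c-1, r-1) -> (c, r-1)
  s <- !at(r - 1L, c)
  starts <- c(starts, vid(c[s] - 1L, r[s] - 1L)); ends <- c(ends, vid(c[s], r[s] - 1L))
  ## top neighbour empty: (c, r) -> (c-1, r)
  s <- !at(r + 1L, c)
  starts <- c(starts, vid(c[s], r[s]));           ends <- c(ends, vid(c[s] - 1L, r[s]))
  loops <- chain_edges(starts, ends, W)
  lapply(loops, function(v) {
    x <- (v %% W) - 1L; y <- (v %/% W) - 1L
    cbind(x = origin[1] + x * pitch, y = origin[2] + y * pitch)
  })
}

## Chain directed edges into closed loops.  At degree-2 corners (two outgoing
## edges from one vertex) prefer the left turn relative to the incoming
## direction, which keeps checkerboard touch points separated.
chain_edges <- function(starts, ends, W) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  first <- match(unique(starts), starts)
  lookup_start <- starts[first]
  used <- rep(FALSE, length(starts))
  cnt <- tabulate(match(starts, lookup_start))
  loops <- list()
  dirvec <- function(a, b) c((b %% W) - (a %% W), (b %/% W) - (a %/% W))
  for (seed in seq_along(starts)) {
    if (used[seed]) next
    loop <- integer(0)
    cur <- seed
    repeat {
      used[cur] <- TRUE
      loop <- c(loop, starts[cur])
      nxt_v <- ends[cur]
      k <- match(nxt_v, lookup_start)
      if (is.na(k)) break  # should not happen on valid masks
      i0 <- first[k]; ncand <- cnt[k]
      cand <- i0:(i0 + ncand - 1L)
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      if (length(cand) > 1L) {
        ind <- dirvec(starts[cur], ends[cur])
        turn <- vapply(cand, function(e) {
          outd <- dirvec(starts[e], ends[e])
          ind[1] * outd[2] - ind[2] * outd[1]  # z of cross product; left > 0
        }, numeric(1))
        cand <- cand[which.max(turn)]
      }
      cur <- cand[1]
      if (cur == seed) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

## Collapse runs of collinear vertices in a closed polyline.
simplify_collinear <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(poly)
  prv <- rbind(poly[n, ], poly[-n, , drop = FALSE])
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, ])
  v1 <- poly - prv; v2 <- nxt - poly
  keep <- abs(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]) > 1e-9
  if (!any(keep)) keep[1] <- TRUE
  poly[keep, , drop = FALSE]
}

#' Write a contour to CSV
#'
#' One vertex per row with columns \code{x_mm}, \code{y_mm}; the closing
#' edge is implied.
#' @param contour vertex matrix.
#' @param path output file.
#' @export
write_contour_csv <- function(contour, path) {
  df <- data.frame(x_mm = contour[, 1], y_mm = contour[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a contour written by [write_contour_csv()]
#' @param path CSV file with columns x_mm, y_mm.
#' @return vertex matrix.
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, c("x_mm", "y_mm")])
}

#' Write an 8-bit grayscale image as ASCII PGM (P2)
#' @param img numeric matrix (rows = y, columns = x), values 0..255.
#' @param path output file.
#' @export
write_pgm <- function(img, path) {
  img <- round(pmin(pmax(img, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  ## PGM stores top row first; our row 1 is y = 0 (bottom)
  write(t(img[nrow(img):1, , drop = FALSE]), con, ncolumns = 16L)
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#' @param path PGM file.
#' @return numeric matrix with row 1 at the bottom (y = 0).
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  stopifnot(toks[1] == "P2")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  m[h:1, , drop = FALSE]
}

## Derive a reproducible child seed from a master seed; keeps results
## below 2^31 so they remain valid R integers.
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 48271 + 11 * stream) %% 2147483647)
}
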