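#' @importFrom stats median optimize coef lm pf setNames runif rnorm aggregate
#' @importFrom utils head tail
NULL

# ---- point-set validation ----------------------------------------------------

as_centers <- function(centers) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L)
    stop("`centers` must be an n x 2 matrix of (x, y) coordinates")
  storage.mode(centers) <- "double"
  if (!all(is.finite(centers)))
    stop("all coordinates must be finite")
  if (anyDuplicated(paste(centers[, 1], centers[, 2], sep = "\r")))
    stop("duplicate points in `centers`")
  centers
}

check_noncollinear <- function(centers) {
  if (nrow(centers) < 3L) stop("need at least 3 points")
  p0 <- centers[1L, ]
  v <- sweep(centers[-1L, , drop = FALSE], 2L, p0)
  cr <- v[1L, 1L] * v[, 2L] - v[1L, 2L] * v[, 1L]
  scale <- max(abs(v)) + 1
  if (all(abs(cr) <= 1e-12 * scale^2))
    stop("all points are collinear; plane tessellation undefined")
  invisible(TRUE)
}

# Characteristic spacing of a point set (used to scale perturbations and
# tolerances): square root of bounding-box area per point.
spacing_estimate <- function(centers) {
  n <- nrow(centers)
  dx <- diff(range(centers[, 1]))
  dy <- diff(range(centers[, 2]))
  s <- sqrt(max(dx * dy, dx^2, dy^2, 1) / n)
  if (!is.finite(s) || s <= 0) s <- 1
  s
}

# Deterministic symbolic perturbation: breaks the exact cocircularity that is
# everywhere present in perfect triangular lattices, so the triangulation has
# a fixed, reproducible tie-break.  Low-discrepancy offsets of magnitude
# ~1e-6 of the lattice spacing; the near-zero Voronoi edges this creates are
# removed again by `edge_tol` merging before walls are counted.
perturb_centers <- function(centers, magnitude = 1e-6) {
  n <- nrow(centers)
  eps <- magnitude * spacing_estimate(centers)
  i <- seq_len(n)
  px <- ((i * 0.7548776662466927) %% 1) - 0.5
  py <- ((i * 0.5698402909980532) %% 1) - 0.5
  centers + eps * cbind(px, py)
}

# ---- convex hull helpers -----------------------------------------------------

# TRUE for query points strictly inside the convex hull of `centers`
# (margin `tol`, an absolute distance).
in_hull <- function(qx, qy, centers, tol) {
  h <- grDevices::chull(centers)
  hx <- centers[h, 1]; hy <- centers[h, 2]
  k <- length(h)
  inside <- rep(TRUE, length(qx))
  # chull returns vertices clockwise; orient so interior is on the left
  area2 <- sum(hx * hy[c(2:k, 1)] - hx[c(2:k, 1)] * hy)
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }
  for (e in seq_len(k)) {
    e2 <- if (e == k) 1L else e + 1L
    ex <- hx[e2] - hx[e]; ey <- hy[e2] - hy[e]
    elen <- sqrt(ex^2 + ey^2)
    d <- (ex * (qy - hy[e]) - ey * (qx - hx[e])) / elen
    inside <- inside & (d > tol)
  }
  inside
}

# ---- circumcircle ------------------------------------------------------------

#' Strict circumcircle interiority test
#'
#' Tests whether a query point lies strictly inside the circle through three
#' non-collinear points.  This is the empty-circumcircle condition underlying
#' the Delaunay triangulation of comb cell centres: a triangle belongs to the
#' triangulation only if its circumscribing circle contains no other centre.
#'
#' The convention is strict interiority: a point exactly on the circle (within
#' `tol` times the circumradius) is *not* inside.  This matches the defect
#' model, where a mismatch of exactly half a reproductive cell width does not
#' yet force a dislocation.
#'
#' @param a,b,c numeric length-2 vectors, the triangle vertices (non-collinear).
#' @param q numeric length-2 vector, the query point.
#' @param tol relative tolerance, scaled by the circumradius.
#' @return `TRUE` iff `q` is strictly inside the circumcircle of `a`, `b`, `c`.
#' @examples
#' a <- c(0, 0); b <- c(1, 0); c <- c(0.5, sqrt(3) / 2)
#' circumcircle_contains(a, b, c, c(0.5, 0.3))   # centroid region: TRUE
#' circumcircle_contains(a, b, c, c(5, 5))       # far outside: FALSE
#' @export
circumcircle_contains <- function(a, b, c, q, tol = 1e-9) {
  cc <- circumcenter(a[1], a[2], b[1], b[2], c[1], c[2])
  if (!all(is.finite(cc))) stop("triangle vertices are collinear")
  r <- sqrt((a[1] - cc[1])^2 + (a[2] - cc[2])^2)
  d <- sqrt((q[1] - cc[1])^2 + (q[2] - cc[2])^2)
  d < r * (1 - tol)
}

# Vectorised circumcenter of triangles (ax, ay, bx, by, cx, cy); returns
# cbind(x, y), NaN rows for collinear triples.
circumcenter <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  cbind(ux, uy)
}

# ---- Voronoi cells -----------------------------------------------------------

#' Voronoi cell reconstruction from comb cell centres
#'
#' Decomposes the plane into one polygonal cell per centre, the dual
#' representation of a comb: observed cell walls are well approximated by the
#' Voronoi partition of the cell centres.  Wall counts are taken from the
#' Voronoi diagram after merging near-zero edges, so that the exact
#' cocircularity of near-regular lattices does not inflate the count, and
#' cells whose polygon is unbounded or touches the convex hull of the point
#' set are flagged non-interior and excluded from downstream statistics.
#'
#' @param centers n x 2 matrix of cell-centre coordinates, in worker-cell-width
#'   units.
#' @param edge_tol Voronoi edges shorter than `edge_tol` times the median
#'   Voronoi edge length are merged into a single vertex before walls are
#'   counted.  Default 0.01.
#' @return A data frame of class `"voronoi_cells"` with one row per centre:
#'   `cell_id` (0-based), `x`, `y`, `n_walls`, `area` (worker-width^2 units;
#'   `NA` for non-interior cells), `is_interior`.  Attributes: `polygons`
#'   (list of vertex-ring matrices, `NULL` where unbounded), `adjacency`
#'   (data frame `i`, `j`, 1-based point indices, `wall_length`, `retained`),
#'   `edge_tol`.
#' @seealso [delaunay_graph()] for the dual neighbour graph.
#' @examples
#' p <- hex_patch(6, 6, spacing = 1)
#' vc <- voronoi_cells(p)
#' table(vc$n_walls[vc$is_interior])  # all interior cells are hexagons
#' @export
voronoi_cells <- function(centers, edge_tol = 0.01) {
  centers <- as_centers(centers)
  n <- nrow(centers)
  if (n < 4L) stop("need at least 4 points for cell reconstruction")
  check_noncollinear(centers)

  pert <- perturb_centers(centers)
  sp <- spacing_estimate(centers)
  rw <- c(range(pert[, 1]) + c(-2, 2) * sp, range(pert[, 2]) + c(-2, 2) * sp)
  dd <- deldir::deldir(pert[, 1], pert[, 2], rw = rw, suppressMsge = TRUE)

  seg <- dd$dirsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  tol_len <- edge_tol * stats::median(len[len > 0])
  retained <- len >= tol_len

  # interior cells: no incident Voronoi edge clipped by the window, and all
  # incident Voronoi vertices strictly inside the convex hull of the centres
  vtol <- 1e-9 * sp
  v_in1 <- in_hull(seg$x1, seg$y1, pert, vtol)
  v_in2 <- in_hull(seg$x2, seg$y2, pert, vtol)
  seg_bad <- seg$bp1 | seg$bp2 | !v_in1 | !v_in2
  interior <- rep(TRUE, n)
  interior[unique(c(seg$ind1[seg_bad], seg$ind2[seg_bad]))] <- FALSE

  # wall counts: retained Voronoi edges incident to each cell
  inc <- c(seg$ind1[retained], seg$ind2[retained])
  n_walls <- tabulate(inc, nbins = n)

  areas <- dd$summary$dir.area
  areas[!interior] <- NA_real_

  polygons <- voronoi_polygons(dd, n, tol_len, interior)

  out <- data.frame(
    cell_id = seq_len(n) - 1L,
    x = centers[, 1], y = centers[, 2],
    n_walls = n_walls, area = areas, is_interior = interior
  )
  class(out) <- c("voronoi_cells", "data.frame")
  attr(out, "polygons") <- polygons
  attr(out, "adjacency") <- data.frame(
    i = seg$ind1, j = seg$ind2, wall_length = len, retained = retained
  )
  attr(out, "edge_tol") <- edge_tol
  out
}

# Ordered vertex rings per cell from a deldir tessellation; vertices closer
# than tol_len are collapsed.  NULL for cells flagged non-interior.
voronoi_polygons <- function(dd, n, tol_len, interior) {
  seg <- dd$dirsgs
  polys <- vector("list", n)
  idx1 <- split(seq_len(nrow(seg)), factor(seg$ind1, levels = seq_len(n)))
  idx2 <- split(seq_len(nrow(seg)), factor(seg$ind2, levels = seq_len(n)))
  px <- dd$summary$x; py <- dd$summary$y
  for (i in which(interior)) {
    rows <- c(idx1[[i]], idx2[[i]])
    vx <- c(seg$x1[rows], seg$x2[rows])
    vy <- c(seg$y1[rows], seg$y2[rows])
    ord <- order(atan2(vy - py[i], vx - px[i]))
    vx <- vx[ord]; vy <- vy[ord]
    keep <- !duplicated(round(cbind(vx, vy) / (tol_len / 4)))
    vx <- vx[keep]; vy <- vy[keep]
    # collapse ring vertices closer than tol_len (cyclic)
    k <- length(vx)
    if (k > 3L) {
      d <- sqrt((vx - vx[c(2:k, 1)])^2 + (vy - vy[c(2:k, 1)])^2)
      drop <- d < tol_len
      if (any(drop)) { vx <- vx[!drop]; vy <- vy[!drop] }
    }
    polys[[i]] <- cbind(x = vx, y = vy)
  }
  polys
}

# shoelace area of an ordered ring
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  k <- length(x)
  abs(sum(x * y[c(2:k, 1)] - x[c(2:k, 1)] * y)) / 2
}

# ---- Delaunay graph ----------------------------------------------------------

#' Delaunay neighbour graph of comb cell centres
#'
#' The neighbour graph of cell centres is the Delaunay triangulation, dual to
#' the Voronoi partition of [voronoi_cells()]: two cells are adjacent exactly
#' when their polygons share a wall.  Degenerate cocircular configurations
#' (ubiquitous in perfect lattices) are resolved by the same deterministic
#' perturbation used for the Voronoi construction, so the tie-break is fixed
#' and reproducible.
#'
#' @inheritParams voronoi_cells
#' @param triangles if `TRUE`, also enumerate the triangles of the
#'   triangulation (slower; used mainly for verification).
#' @return A list of class `"delaunay_graph"`: `edges` (data frame `i`, `j`
#'   1-based indices, `wall_length` of the dual Voronoi edge, `retained` -
#'   whether the dual edge survives `edge_tol` merging), `triangles`
#'   (m x 3 integer matrix or `NULL`), `n`.
#' @examples
#' p <- hex_patch(4, 4, spacing = 1)
#' g <- delaunay_graph(p)
#' nrow(g$edges)
#' @export
delaunay_graph <- function(centers, edge_tol = 0.01, triangles = FALSE) {
  centers <- as_centers(centers)
  check_noncollinear(centers)
  n <- nrow(centers)
  pert <- perturb_centers(centers)
  sp <- spacing_estimate(centers)
  rw <- c(range(pert[, 1]) + c(-2, 2) * sp, range(pert[, 2]) + c(-2, 2) * sp)
  dd <- deldir::deldir(pert[, 1], pert[, 2], rw = rw, suppressMsge = TRUE)
  seg <- dd$dirsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  tol_len <- edge_tol * stats::median(len[len > 0])
  edges <- data.frame(
    i = pmin(seg$ind1, seg$ind2), j = pmax(seg$ind1, seg$ind2),
    wall_length = len, retained = len >= tol_len
  )
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  tri <- if (triangles) delaunay_triangles(edges, pert) else NULL
  structure(list(edges = edges, triangles = tri, n = n),
            class = "delaunay_graph")
}

# Enumerate triangulation faces as 3-cliques of the edge graph, excluding
# separating triangles (a clique with a common neighbour inside it is not a
# face of a planar triangulation).
delaunay_triangles <- function(edges, centers) {
  n <- nrow(centers)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    common <- intersect(adj[[i]], adj[[j]])
    for (k in common[common > j]) {
      others <- setdiff(intersect(common, adj[[k]]), c(i, j, k))
      sep <- FALSE
      for (m in others) {
        if (point_in_triangle(centers[m, ], centers[i, ], centers[j, ],
                              centers[k, ])) { sep <- TRUE; break }
      }
      if (!sep) out[[length(out) + 1L]] <- c(i, j, k)
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), ncol = 3))
  do.call(rbind, out)
}

point_in_triangle <- function(p, a, b, c) {
  s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
  s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
  (s1 >= 0 && s2 >= 0 && s3 >= 0) || (s1 <= 0 && s2 <= 0 && s3 <= 0)
}
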