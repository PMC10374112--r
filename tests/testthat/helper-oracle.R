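# Independent brute-force Voronoi construction by half-plane intersection.
# Used as the oracle for the deldir-based pipeline: the cell of point i is
# the intersection of the half-planes bounded by the perpendicular bisectors
# towards every other point, clipped to a large box.

clip_halfplane <- function(poly, p, q) {
  # keep the side of the p|q bisector containing p
  m <- (p + q) / 2
  nrm <- p - q  # points towards p
  k <- nrow(poly)
  inside <- (poly[, 1] - m[1]) * nrm[1] + (poly[, 2] - m[2]) * nrm[2] >= 0
  out <- list()
  for (e in seq_len(k)) {
    e2 <- if (e == k) 1L else e + 1L
    a <- poly[e, ]; b <- poly[e2, ]
    if (inside[e]) out[[length(out) + 1L]] <- a
    if (inside[e] != inside[e2]) {
      da <- (a[1] - m[1]) * nrm[1] + (a[2] - m[2]) * nrm[2]
      db <- (b[1] - m[1]) * nrm[1] + (b[2] - m[2]) * nrm[2]
      t <- da / (da - db)
      out[[length(out) + 1L]] <- a + t * (b - a)
    }
  }
  if (length(out) < 3L) return(NULL)
  do.call(rbind, out)
}

oracle_cell <- function(centers, i, box = 50) {
  p <- centers[i, ]
  poly <- rbind(p + c(-box, -box), p + c(box, -box),
                p + c(box, box), p + c(-box, box))
  neighbors <- integer(0)
  ord <- order((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
  for (j in ord) {
    if (j == i) next
    poly <- clip_halfplane(poly, p, centers[j, ])
    if (is.null(poly)) stop("degenerate oracle cell")
  }
  poly
}

# wall count of cell i: number of polygon edges at least tol_len long
oracle_wall_count <- function(centers, i, tol_frac = 0.01) {
  poly <- oracle_cell(centers, i)
  k <- nrow(poly)
  len <- sqrt(rowSums((poly - poly[c(2:k, 1), , drop = FALSE])^2))
  sum(len >= tol_frac * stats::median(len[len > 1e-12]))
}

oracle_cell_area <- function(centers, i) {
  poly <- oracle_cell(centers, i)
  k <- nrow(poly)
  abs(sum(poly[, 1] * poly[c(2:k, 1), 2] - poly[c(2:k, 1), 1] * poly[, 2])) / 2
}

# grid of exact-hundredth scale ratios used by the closure checks
alpha_grid <- function(from = 1.05, to = 2, by = 0.05) round(seq(from, to, by = by), 2)

# dislocation pairs whose 5-sided member sits on the generated line window
pairs_on_window <- function(cb, det = detect_57_pairs(cb)) {
  w <- cb$metadata$window
  sum(det$pairs$five_x >= w[1] & det$pairs$five_x < w[2])
}
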