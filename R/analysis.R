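# ---- per-comb measurement pipeline -------------------------------------------

#' Analyse a comb: polygons, wall counts, areas, neighbour graph
#'
#' Runs the Voronoi reconstruction on a comb's cell centres and assembles the
#' per-cell table used by all downstream measurements.  Only interior cells
#' (polygon bounded and away from the convex hull of the point set) enter any
#' statistic.
#'
#' @param x a [comb()].
#' @param edge_tol passed to [voronoi_cells()].
#' @return An object of class `"comb_analysis"`: `cells` (data frame with
#'   `cell_id`, `x`, `y`, `label`, `n_walls`, `area`, `is_interior`),
#'   `adjacency` (retained Delaunay/Voronoi dual edges), `comb`, `edge_tol`.
#' @export
analyze_comb <- function(x, edge_tol = 0.01) {
  stopifnot(inherits(x, "comb"))
  vc <- voronoi_cells(x$centers, edge_tol)
  cells <- data.frame(
    cell_id = vc$cell_id, x = vc$x, y = vc$y, label = x$labels,
    n_walls = vc$n_walls, area = vc$area, is_interior = vc$is_interior,
    stringsAsFactors = FALSE
  )
  structure(list(comb = x, cells = cells,
                 adjacency = attr(vc, "adjacency"),
                 polygons = attr(vc, "polygons"),
                 edge_tol = edge_tol),
            class = "comb_analysis")
}

#' @export
print.comb_analysis <- function(x, ...) {
  cl <- x$cells[x$cells$is_interior, ]
  cat("<comb_analysis> ", nrow(x$cells), " cells (", nrow(cl),
      " interior)\n", sep = "")
  cat("  interior wall counts: ")
  print(table(cl$n_walls))
  invisible(x)
}

as_analysis <- function(x, edge_tol = 0.01) {
  if (inherits(x, "comb_analysis")) x else analyze_comb(x, edge_tol)
}

# Reference (worker, reproductive) median areas from hexagonal interior
# cells, excluding the rows bordering the transition: cells in the boundary
# row are systematically deformed towards the other patch's pitch (worker
# cells enlarged, reproductive cells compressed), so the reference medians
# come from the regular far-field of each patch.  Falls back to all cells of
# a class when the far-field filter would empty it or no line can be fit.
class_median_areas <- function(a) {
  cl <- a$cells
  use <- cl$is_interior & cl$n_walls == 6L & !is.na(cl$area)
  med_of <- function(sel, far) {
    if (any(sel & far)) stats::median(cl$area[sel & far])
    else if (any(sel)) stats::median(cl$area[sel]) else NA_real_
  }
  w <- use & cl$label == "worker"
  r <- use & cl$label == "reproductive"
  far_w <- far_r <- rep(TRUE, nrow(cl))
  line <- tryCatch(fit_transition_line(a), error = function(e) NULL)
  if (!is.null(line)) {
    d <- signed_distances(cl, line)
    mw0 <- med_of(w, TRUE); mr0 <- med_of(r, TRUE)
    alpha0 <- if (!is.na(mw0) && !is.na(mr0) && mw0 > 0)
      sqrt(max(mr0 / mw0, 1)) else 1
    far_w <- d < -0.9 * ROW_PITCH
    far_r <- d > 0.9 * ROW_PITCH * alpha0
  }
  c(worker = med_of(w, far_w), reproductive = med_of(r, far_r))
}

# median worker area; prefers hexagonal far-field worker cells
worker_median_area <- function(a) {
  m <- class_median_areas(a)[["worker"]]
  if (is.na(m)) stop("no interior worker-labelled cells")
  m
}

#' Normalised cell areas
#'
#' Expresses every cell area relative to the median worker cell area:
#' `normalized = area / median(worker area) - 1`, so the worker median maps
#' to 0 and a cell 2.70 times the worker median maps to 1.70 (the dimorphism
#' scale).
#'
#' @param x a [comb()] or [analyze_comb()] result.
#' @param edge_tol used if `x` still needs analysing.
#' @return numeric vector aligned with the cell table (`NA` for non-interior
#'   cells).
#' @export
normalized_areas <- function(x, edge_tol = 0.01) {
  a <- as_analysis(x, edge_tol)
  med <- worker_median_area(a)
  a$cells$area / med - 1
}

#' Dimorphism score of a comb
#'
#' `D = median(reproductive cell area) / median(worker cell area) - 1`,
#' computed over hexagonal interior cells only (non-hexagonal cells are
#' systematically deformed and would bias the medians).
#'
#' @inheritParams normalized_areas
#' @return `D`, or `NA` when either label class is absent among hexagonal
#'   interior cells.
#' @export
dimorphism_score <- function(x, edge_tol = 0.01) {
  a <- as_analysis(x, edge_tol)
  m <- class_median_areas(a)
  if (anyNA(m)) return(NA_real_)
  m[["reproductive"]] / m[["worker"]] - 1
}

# ---- transition line ---------------------------------------------------------

#' Fit the transition line between worker and reproductive patches
#'
#' Total-least-squares line through the midpoints of label-discordant
#' neighbour pairs (a worker cell adjacent to a reproductive or
#' transition-layer cell): the first principal component of the midpoints
#' gives the direction, their centroid the point.  Symmetric in the two
#' classes and rotation-equivariant.
#'
#' @inheritParams normalized_areas
#' @return list with `point` (centroid), `direction` (unit vector), `normal`
#'   (unit vector oriented towards the reproductive side), `n_pairs`.
#' @export
fit_transition_line <- function(x, edge_tol = 0.01) {
  a <- as_analysis(x, edge_tol)
  cl <- a$cells
  adj <- a$adjacency[a$adjacency$retained, ]
  li <- cl$label[adj$i]; lj <- cl$label[adj$j]
  upstream <- function(l) l == "worker"
  downstream <- function(l) l == "reproductive" | grepl("^transition_", l)
  disc <- (upstream(li) & downstream(lj)) | (downstream(li) & upstream(lj))
  if (sum(disc) < 2L) stop("fewer than 2 worker/reproductive boundary pairs")
  mx <- (cl$x[adj$i[disc]] + cl$x[adj$j[disc]]) / 2
  my <- (cl$y[adj$i[disc]] + cl$y[adj$j[disc]]) / 2
  ctr <- c(mean(mx), mean(my))
  cov <- stats::cov(cbind(mx, my))
  ev <- eigen(cov, symmetric = TRUE)
  dir <- ev$vectors[, 1]
  nrm <- c(-dir[2], dir[1])
  # orient the normal towards the reproductive side
  rep_ctr <- c(mean(cl$x[downstream(cl$label)]), mean(cl$y[downstream(cl$label)]))
  wrk_ctr <- c(mean(cl$x[upstream(cl$label)]), mean(cl$y[upstream(cl$label)]))
  if (sum((rep_ctr - wrk_ctr) * nrm) < 0) nrm <- -nrm
  list(point = ctr, direction = dir / sqrt(sum(dir^2)), normal = nrm,
       n_pairs = sum(disc),
       lateral_extent = diff(range((mx - ctr[1]) * dir[1] +
                                   (my - ctr[2]) * dir[2])))
}

# signed perpendicular distance of every cell centre from the line
# (positive on the reproductive side)
signed_distances <- function(cells, line) {
  (cells$x - line$point[1]) * line$normal[1] +
    (cells$y - line$point[2]) * line$normal[2]
}

# ---- 4-parameter transition fit ----------------------------------------------

# profile least squares: given the ramp value r in [0, 1] per cell, the
# plateau areas (A_w, A_r) are linear; solve the 2 x 2 normal equations.
ramp_rss <- function(d, y, ow, width) {
  r <- if (width <= 0) as.numeric(d > ow) else pmin(pmax((d - ow) / width, 0), 1)
  f0 <- 1 - r
  s00 <- sum(f0 * f0); s01 <- sum(f0 * r); s11 <- sum(r * r)
  t0 <- sum(f0 * y); t1 <- sum(r * y)
  det <- s00 * s11 - s01 * s01
  if (abs(det) < 1e-12) {
    aw <- ar <- sum(y) / length(y)
  } else {
    aw <- (t0 * s11 - t1 * s01) / det
    ar <- (t1 * s00 - t0 * s01) / det
  }
  res <- y - (aw * f0 + ar * r)
  list(rss = sum(res^2), A_worker = aw, A_rep = ar)
}

#' Fit the four-parameter transition-profile model
#'
#' Fits cell area versus signed distance from the transition line with a
#' plateau-ramp-plateau model: cells further than `O_worker` on the worker
#' side have area `A_worker`, cells further than `O_rep` on the reproductive
#' side have area `A_rep`, and areas between the two offsets are linearly
#' interpolated.  Only hexagonal interior cells enter the least-squares loss
#' (non-hexagonal cells are deformed by construction).  Among
#' equal-residual fits the narrowest ramp is preferred (a vanishing
#' micro-penalty on the ramp width breaks the degeneracy of noiseless
#' one-step data).
#'
#' @param x a [comb()] or [analyze_comb()] result; alternatively supply
#'   `distances` and `areas` directly.
#' @param line optional transition line from [fit_transition_line()]
#'   (computed if missing).
#' @param distances,areas optional numeric vectors to fit directly (bypassing
#'   the comb geometry), e.g. for simulation studies of the fit itself.
#' @param edge_tol used if `x` still needs analysing.
#' @return list of class `"transition_fit"`: `A_worker`, `A_rep`, `O_worker`,
#'   `O_rep`, `rss`, `depth` (`O_rep - O_worker`, worker widths), `L_obs`
#'   (lateral extent of the transition boundary, worker widths; `NA` when
#'   fitting raw vectors), `hex_fraction_in_transition`, `n_cells`, `line`.
#' @export
fit_transition <- function(x = NULL, line = NULL, distances = NULL,
                           areas = NULL, edge_tol = 0.01) {
  hexfrac <- NA_real_
  L_obs <- NA_real_
  if (is.null(distances)) {
    a <- as_analysis(x, edge_tol)
    if (is.null(line)) line <- fit_transition_line(a)
    cl <- a$cells
    d_all <- signed_distances(cl, line)
    use <- cl$is_interior & cl$n_walls == 6L & !is.na(cl$area)
    distances <- d_all[use]
    areas <- cl$area[use]
    L_obs <- line$lateral_extent
  } else {
    a <- NULL
    stopifnot(length(distances) == length(areas))
  }
  if (length(distances) < 5L)
    stop("fewer hexagonal cells than model parameters")

  y <- areas; d <- distances
  dr <- range(d); span <- diff(dr)
  eps_w <- 1e-7 * (stats::sd(y) + 1e-12)  # narrow-ramp tie-break

  obj <- function(par) {
    ow <- par[1]; width <- max(par[2], 0)
    ramp_rss(d, y, ow, width)$rss + eps_w * width
  }
  # coarse grid, then simplex refinement
  ows <- seq(dr[1], dr[2], length.out = 25)
  wds <- seq(0, span, length.out = 25)
  grid <- expand.grid(ow = ows, w = wds)
  vals <- vapply(seq_len(nrow(grid)),
                 function(i) obj(c(grid$ow[i], grid$w[i])), numeric(1))
  best <- grid[which.min(vals), ]
  op <- stats::optim(c(best$ow, best$w), obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12))
  ow <- op$par[1]; width <- max(op$par[2], 0)
  fit <- ramp_rss(d, y, ow, width)

  if (!is.null(a)) {
    cl <- a$cells
    d_all <- signed_distances(cl, line)
    inside <- cl$is_interior & d_all > ow & d_all < ow + width
    hexfrac <- if (any(inside)) mean(cl$n_walls[inside] == 6L) else 1
  }
  structure(list(A_worker = fit$A_worker, A_rep = fit$A_rep,
                 O_worker = ow, O_rep = ow + width,
                 rss = fit$rss, depth = width, L_obs = L_obs,
                 hex_fraction_in_transition = hexfrac,
                 n_cells = length(d), line = line),
            class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat("4-parameter transition fit\n")
  cat(sprintf("  A_worker = %.4f, A_rep = %.4f (worker-width^2)\n",
              x$A_worker, x$A_rep))
  cat(sprintf("  O_worker = %.4f, O_rep = %.4f (depth %.4f worker widths)\n",
              x$O_worker, x$O_rep, x$depth))
  cat(sprintf("  rss = %.6g over %d hexagonal cells\n", x$rss, x$n_cells))
  if (!is.na(x$L_obs))
    cat(sprintf("  lateral transition length L_obs = %.2f\n", x$L_obs))
  if (!is.na(x$hex_fraction_in_transition))
    cat(sprintf("  hexagonal fraction in transition region = %.2f\n",
                x$hex_fraction_in_transition))
  invisible(x)
}

#' Estimate the number of observed transition layers
#'
#' Fills the fitted transition depth (`O_rep - O_worker`, perpendicular to
#' the line) with optimally stepped layers: each layer increases the linear
#' scale by `alpha_L = L/(L-1)` (the largest defect-free step for the
#' observed lateral line length `L`), so layer `t` occupies a row pitch of
#' `sqrt(3)/2 * (alpha_L^(t-1) + alpha_L^t)/2` worker widths.  The last,
#' partially filled layer is counted fractionally.  When the transition
#' region contains fewer than 50% hexagonal cells the estimate is forced to
#' zero: such regions are dominated by the deformed neighbours of 5-7 pairs,
#' not by deliberate intermediate-sized cells.
#'
#' @param fit a [fit_transition()] result.
#' @param alpha linear scale ratio of the comb; default
#'   `sqrt(A_rep / A_worker)` from the fit.
#' @param L lateral transition length; default `fit$L_obs`.
#' @return `T_obs` (fractional, >= 0).
#' @export
observed_layers <- function(fit, alpha = NULL, L = NULL) {
  if (is.null(alpha)) {
    if (fit$A_worker <= 0) return(0)
    alpha <- sqrt(max(fit$A_rep, 0) / fit$A_worker)
  }
  if (!is.finite(alpha) || alpha <= 1) return(0)
  if (is.null(L)) L <- fit$L_obs
  if (!is.finite(L) || L <= 1) return(0)
  hf <- fit$hex_fraction_in_transition
  if (!is.na(hf) && hf < 0.5) return(0)
  depth <- fit$depth
  if (depth <= 0) return(0)
  aL <- max_defect_free(L)
  t <- 0L; acc <- 0
  repeat {
    p <- ROW_PITCH * (aL^t + aL^(t + 1)) / 2
    if (acc + p > depth) return(t + (depth - acc) / p)
    acc <- acc + p
    t <- t + 1L
    if (t > 1000L) return(t)  # degenerate: absurdly deep region
  }
}

# ---- 5-7 pair detection ------------------------------------------------------

#' Detect and orient 5-7 defect pairs
#'
#' A 5-7 pair is a 5-walled and a 7-walled interior cell whose polygons share
#' a wall.  Each cell joins at most one pair; candidates are matched
#' greedily by increasing centre-to-centre distance (ties broken by cell id).
#' A pair is `oriented_correctly` when the 5-sided cell precedes the 7-sided
#' cell along the growth direction, the configuration in which the truncated
#' pentagon is built first and its new wall seeds the heptagon.
#'
#' @inheritParams normalized_areas
#' @return list of class `"pair_detection"`: `pairs` (data frame `five_id`,
#'   `seven_id`, 0-based, `five_label`, `seven_label`, `distance`,
#'   `oriented_correctly` - `NA` without a growth direction), and `summary`
#'   (named counts of 4/5/7/8-walled interior cells, `n_pairs`,
#'   `fraction_paired` among 5- and 7-sided cells, `n_interior`,
#'   `n_nonhex`).
#' @export
detect_57_pairs <- function(x, edge_tol = 0.01) {
  a <- as_analysis(x, edge_tol)
  cl <- a$cells
  adj <- a$adjacency[a$adjacency$retained, ]
  wi <- cl$n_walls[adj$i]; wj <- cl$n_walls[adj$j]
  int <- cl$is_interior
  cand <- (int[adj$i] & int[adj$j]) &
    ((wi == 5L & wj == 7L) | (wi == 7L & wj == 5L))
  five <- ifelse(cl$n_walls[adj$i][cand] == 5L, adj$i[cand], adj$j[cand])
  seven <- ifelse(cl$n_walls[adj$i][cand] == 5L, adj$j[cand], adj$i[cand])
  dist <- sqrt((cl$x[five] - cl$x[seven])^2 + (cl$y[five] - cl$y[seven])^2)
  ord <- order(dist, five, seven)
  used <- logical(nrow(cl))
  keep <- logical(length(ord))
  for (k in ord) {
    if (!used[five[k]] && !used[seven[k]]) {
      keep[k] <- TRUE
      used[five[k]] <- used[seven[k]] <- TRUE
    }
  }
  five <- five[keep]; seven <- seven[keep]; dist <- dist[keep]
  g <- a$comb$growth_direction
  oriented <- if (is.null(g)) rep(NA, length(five)) else
    ((cl$x[seven] - cl$x[five]) * g[1] + (cl$y[seven] - cl$y[five]) * g[2]) > 0
  pairs <- data.frame(
    five_id = cl$cell_id[five], seven_id = cl$cell_id[seven],
    five_label = cl$label[five], seven_label = cl$label[seven],
    five_x = cl$x[five], five_y = cl$y[five],
    distance = dist, oriented_correctly = oriented,
    stringsAsFactors = FALSE
  )
  wc <- cl$n_walls[int]
  n_by_class <- c(`4` = sum(wc == 4L), `5` = sum(wc == 5L),
                  `7` = sum(wc == 7L), `8` = sum(wc == 8L))
  n57 <- n_by_class[["5"]] + n_by_class[["7"]]
  structure(list(
    pairs = pairs,
    summary = list(
      n_by_class = n_by_class,
      n_pairs = nrow(pairs),
      fraction_paired = if (n57 > 0) 2 * nrow(pairs) / n57 else NA_real_,
      n_interior = sum(int),
      n_nonhex = sum(wc != 6L)
    )
  ), class = "pair_detection")
}

#' @export
print.pair_detection <- function(x, ...) {
  s <- x$summary
  cat("5-7 pair detection: ", s$n_pairs, " pairs among ", s$n_interior,
      " interior cells\n", sep = "")
  cat("  non-hexagonal by wall count: ",
      paste(names(s$n_by_class), s$n_by_class, sep = ":", collapse = "  "),
      "\n", sep = "")
  if (!is.na(s$fraction_paired))
    cat(sprintf("  fraction of 5/7-sided cells paired: %.3f\n",
                s$fraction_paired))
  invisible(x)
}

# Count detected dislocations whose 5-sided member lies on the nominal
# transition-line window of a generated comb (metadata$window, x-range).
dislocations_on_line <- function(x, edge_tol = 0.01) {
  a <- as_analysis(x, edge_tol)
  w <- a$comb$metadata$window
  det <- detect_57_pairs(a)
  if (is.null(w)) return(det$summary$n_pairs)
  sum(det$pairs$five_x >= w[1] & det$pairs$five_x < w[2])
}

# ---- defect-class summary ----------------------------------------------------

#' Percentages of non-hexagonal cells by wall-count class
#'
#' Summarises counts of 4-, 5-, 7- and 8-walled cells as percentages of all
#' non-hexagonal cells, plus the combined share of 5- and 7-sided cells (the
#' classes produced by dislocations).
#'
#' @param counts named numeric vector with elements `"4"`, `"5"`, `"7"`,
#'   `"8"` (a subset is allowed), e.g. the `n_by_class` entry of
#'   [detect_57_pairs()].
#' @return list: `percent` (named, same classes), `percent_57` (share of 5-
#'   and 7-sided cells), `total`.
#' @examples
#' defect_class_percentages(c(`4` = 2, `5` = 291, `7` = 259, `8` = 14))
#' @export
defect_class_percentages <- function(counts) {
  counts <- counts[counts >= 0]
  total <- sum(counts)
  if (total == 0) return(list(percent = counts, percent_57 = NA_real_, total = 0))
  pct <- 100 * counts / total
  p57 <- sum(pct[names(pct) %in% c("5", "7")])
  list(percent = pct, percent_57 = p57, total = total)
}

#' Per-comb summary metrics
#'
#' Runs the full measurement pipeline on one comb and returns a single-row
#' data frame: dimorphism, scale ratio, transition geometry, observed
#' layers, effective scale, defect counts and pairing.
#'
#' @inheritParams normalized_areas
#' @return one-row data frame with columns `D`, `alpha`, `delta`, `L_obs`,
#'   `depth`, `T_obs`, `alpha_E`, `n_interior`, `n_nonhex`, `n4`, `n5`,
#'   `n6`, `n7`, `n8`, `n_pairs`, `fraction_paired`, `prop_nonhex`.
#' @export
comb_summary <- function(x, edge_tol = 0.01) {
  a <- as_analysis(x, edge_tol)
  cl <- a$cells[a$cells$is_interior, ]
  D <- dimorphism_score(a)
  alpha <- if (is.na(D)) NA_real_ else sqrt(D + 1)
  det <- detect_57_pairs(a)
  fit <- tryCatch(fit_transition(a), error = function(e) NULL)
  L_obs <- if (is.null(fit)) NA_real_ else fit$L_obs
  depth <- if (is.null(fit)) NA_real_ else fit$depth
  T_obs <- if (is.null(fit) || is.na(alpha)) 0 else
    observed_layers(fit, alpha = alpha)
  alpha_E <- if (is.na(alpha) || alpha <= 1 || !is.finite(L_obs) || L_obs <= 1)
    alpha else suppressWarnings(
      effective_scale(alpha, max_defect_free(L_obs), T_obs))
  s <- det$summary
  data.frame(
    D = D, alpha = alpha, delta = alpha - 1,
    L_obs = L_obs, depth = depth, T_obs = T_obs, alpha_E = alpha_E,
    n_interior = s$n_interior, n_nonhex = s$n_nonhex,
    n4 = s$n_by_class[["4"]], n5 = s$n_by_class[["5"]],
    n6 = sum(cl$n_walls == 6L), n7 = s$n_by_class[["7"]],
    n8 = s$n_by_class[["8"]], n_pairs = s$n_pairs,
    fraction_paired = s$fraction_paired,
    prop_nonhex = s$n_nonhex / s$n_interior
  )
}
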