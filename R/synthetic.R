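# ---- synthetic comb generator ------------------------------------------------
#
# Emulates the statistical structure the analysis assumes in image-derived
# combs: two triangular-lattice patches of different pitch (worker spacing 1,
# reproductive spacing alpha) joined along a straight horizontal transition
# line, either in one step or through T layers of intermediate-sized cells,
# with optional isotropic Gaussian jitter of the cell centres.

ROW_PITCH <- sqrt(3) / 2  # vertical distance between rows, per unit spacing

#' Triangular-lattice patch of cell centres
#'
#' Builds `n_rows` x `n_cols` cell centres on a triangular lattice: row pitch
#' `spacing * sqrt(3)/2`, alternate rows offset laterally by `spacing / 2`.
#' The Voronoi cell of each interior centre is a regular hexagon of area
#' `spacing^2 * sqrt(3)/2`.
#'
#' @param n_rows,n_cols positive integers.
#' @param spacing centre-to-centre distance within a row (wall-to-wall cell
#'   width); must be positive.
#' @param origin length-2 numeric, position of the first centre.
#' @return an `n_rows * n_cols` x 2 matrix of coordinates.
#' @export
hex_patch <- function(n_rows, n_cols, spacing = 1, origin = c(0, 0)) {
  if (n_rows < 1 || n_cols < 1) stop("n_rows and n_cols must be >= 1")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  r <- rep(seq_len(n_rows) - 1L, each = n_cols)
  k <- rep(seq_len(n_cols) - 1L, times = n_rows)
  x <- origin[1] + k * spacing + (r %% 2) * spacing / 2
  y <- origin[2] + r * spacing * ROW_PITCH
  cbind(x = x, y = y)
}

#' Jitter cell centres
#'
#' Displaces each point by an isotropic Gaussian offset with standard
#' deviation `sigma` times the local cell spacing, reproducibly under a fixed
#' seed.  Emulates the natural positional noise of comb cells.
#'
#' @param centers n x 2 coordinate matrix.
#' @param sigma noise level as a fraction of the local cell width (>= 0).
#' @param seed integer seed.
#' @param local_spacing per-point cell width (recycled); default 1.
#' @return jittered n x 2 matrix.
#' @export
jitter_points <- function(centers, sigma, seed = 1L, local_spacing = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  centers <- as.matrix(centers)
  if (sigma == 0) return(centers)
  n <- nrow(centers)
  s <- rep_len(local_spacing, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  centers + cbind(stats::rnorm(n, 0, sigma * s), stats::rnorm(n, 0, sigma * s))
}

# Shared row-builder for one-step and layered merges.
#
# Rows are stacked bottom-to-top: `rows_each_side` worker rows (spacing 1),
# T intermediate layers with geometric spacing progression alpha^(t/T)
# (layer T reaches the reproductive pitch), then `rows_each_side`
# reproductive rows (spacing alpha).  The vertical gap between consecutive
# rows is the mean of the two row pitches, (s_below + s_above)/2 * sqrt(3)/2.
#
# Lateral registration follows the "0"-alignment chain: the last worker row
# has a centre at x = align_index; each row above has its aligned centre on
# the bisecting normal of the previous row's aligned edge, i.e. shifted by
# half the previous row's spacing.  For equal spacings this reduces to the
# regular triangular stacking.
build_merge <- function(L, alpha, T, rows_each_side, align_index, seed,
                        jitter_sigma, margin, generator,
                        phase_nudge = 0.015) {
  if (!is.finite(alpha) || alpha < 1) stop("alpha must be >= 1")
  if (!is.finite(L) || L < 2) stop("L must be >= 2")
  if (rows_each_side < 3) stop("rows_each_side must be >= 3")
  if (T < 0 || T != round(T)) stop("T must be a non-negative integer")
  W <- round(L)
  if (is.null(align_index)) align_index <- floor((W - 1) / 2)
  if (align_index < 0 || align_index > W)
    stop("align_index must lie on the transition line (0..L)")
  if (margin < 0) stop("margin must be >= 0")

  scales <- c(rep(1, rows_each_side),
              if (T > 0) alpha^(seq_len(T) / T),
              rep(alpha, rows_each_side))
  row_label <- c(rep("worker", rows_each_side),
                 if (T > 0) paste0("transition_", seq_len(T)),
                 rep("reproductive", rows_each_side))
  nr <- length(scales)

  # vertical positions, zero at the last worker row
  gaps <- (scales[-nr] + scales[-1]) / 2 * ROW_PITCH
  y <- c(0, cumsum(gaps)) - sum(gaps[seq_len(rows_each_side - 1)])

  # alignment chain; a deterministic lateral phase nudge at every
  # scale-change interface keeps commensurate ratios (e.g. alpha = 2, where
  # the mismatch is an exact multiple of the worker width) away from exact
  # cocircular ties, so dislocations resolve as localized 5-7 pairs rather
  # than degenerate merged vertices -- the geometric realization of the
  # strict-inequality convention for the Delaunay condition
  ax <- numeric(nr)
  ax[rows_each_side] <- align_index
  if (rows_each_side > 1)
    for (r in (rows_each_side - 1):1) ax[r] <- ax[r + 1] - scales[r + 1] / 2
  for (r in (rows_each_side + 1):nr)
    ax[r] <- ax[r - 1] + scales[r - 1] / 2 -
      (if (scales[r] != scales[r - 1]) phase_nudge else 0)

  # the transition-line window of length W is centred on the "0" alignment
  # point (the bisecting normal carrying the aligned centre), so the mismatch
  # budget W/2 * (step - 1) is identical on both sides
  x_star <- align_index + 0.5
  win <- c(x_star - W / 2, x_star + W / 2)
  xs <- vector("list", nr)
  for (r in seq_len(nr)) {
    s <- scales[r]
    m <- margin * s  # margin counts local cell widths: big cells need room too
    k <- seq(ceiling((win[1] - m - ax[r]) / s), floor((win[2] + m - ax[r]) / s))
    xs[[r]] <- ax[r] + k * s
  }
  centers <- cbind(x = unlist(xs),
                   y = rep(y, vapply(xs, length, integer(1))))
  labels <- rep(row_label, vapply(xs, length, integer(1)))
  local_s <- rep(scales, vapply(xs, length, integer(1)))

  if (jitter_sigma > 0)
    centers <- jitter_points(centers, jitter_sigma, seed, local_s)

  line_y <- mean(c(y[rows_each_side], y[nr - rows_each_side + 1]))
  comb(centers, labels, growth_direction = c(0, 1),
       species_tag = NA_character_,
       metadata = list(generator = generator, alpha = alpha, L = W, T = T,
                       seed = seed, jitter_sigma = jitter_sigma,
                       align_index = align_index, margin = margin,
                       window = win,
                       line = list(point = c(x_star, line_y),
                                   direction = c(1, 0))))
}

#' One-step merge of worker and reproductive patches
#'
#' Generates a synthetic comb in which the transition from worker-sized to
#' reproductive-sized cells happens suddenly, from one row to the next.  The
#' worker patch (spacing 1) sits growth-upstream of the transition line, the
#' reproductive patch (spacing `alpha`) downstream; the first reproductive
#' row is placed at the mean of the two row pitches, `(1 + alpha)/2 *
#' sqrt(3)/2`, above the last worker row, with one reproductive centre on the
#' bisecting normal of the worker edge at `align_index` (the "0" alignment of
#' the defect model).  The mismatch `alpha - 1` then accumulates laterally
#' away from that point, forcing a 5-7 defect pair roughly every
#' `alpha/(alpha - 1)` worker cell widths.
#'
#' The patches extend `margin` worker widths beyond the nominal transition
#' line of length `L` on both sides, so that cells on the line itself are
#' interior to the point set; the line window is recorded in
#' `metadata$window`.
#'
#' @param L transition-line length in worker-cell widths (>= 2).
#' @param alpha linear scale ratio between reproductive and worker cells
#'   (>= 1); `alpha = sqrt(D + 1)` for dimorphism score `D`.
#' @param rows_each_side number of lattice rows in each patch (>= 3).
#' @param align_index integer in `0..L`: which worker edge of the boundary
#'   row carries the aligned reproductive centre.  Default: mid-line.
#' @param seed integer seed for the jitter.
#' @param jitter_sigma positional noise as a fraction of the local cell width.
#' @param margin lateral padding beyond the line, in local cell widths.
#' @param phase_nudge deterministic lateral offset (worker widths) applied at
#'   each scale-change interface so that exactly commensurate ratios do not
#'   sit on degenerate cocircular ties; small relative to a cell width.
#' @return a [comb()] with generator parameters in `metadata`.
#' @export
one_step_merge <- function(L, alpha, rows_each_side = 6, align_index = NULL,
                           seed = 1L, jitter_sigma = 0, margin = 3,
                           phase_nudge = 0.015) {
  build_merge(L, alpha, 0L, rows_each_side, align_index, seed, jitter_sigma,
              margin, "one_step_merge", phase_nudge)
}

#' Layered merge through intermediate-sized cells
#'
#' Generates a synthetic comb whose worker-to-reproductive transition passes
#' through `T` layers of intermediate-sized hexagonal cells with geometric
#' spacing progression `alpha^(t/T)` (layer `T` reaches the reproductive
#' pitch), so each of the `T` steps increases the linear scale by
#' `alpha^(1/T)`.  When `alpha^(1/T)` does not exceed the maximum defect-free
#' step `alpha_L = L/(L - 1)` for the line length `L` (i.e. `T >=
#' layers_required(alpha, L)`), the whole transition is dislocation-free.
#'
#' @inheritParams one_step_merge
#' @param T number of transition layers (>= 0; `T = 0` delegates to
#'   [one_step_merge()]).
#' @return a [comb()]; layer rows carry labels `"transition_1"` ...
#'   `"transition_T"`.
#' @export
layered_merge <- function(L, alpha, T, rows_each_side = 6, align_index = NULL,
                          seed = 1L, jitter_sigma = 0, margin = 0,
                          phase_nudge = 0) {
  if (T == 0) return(one_step_merge(L, alpha, rows_each_side, align_index,
                                    seed, jitter_sigma, margin, phase_nudge))
  build_merge(L, alpha, as.integer(T), rows_each_side, align_index, seed,
              jitter_sigma, margin, "layered_merge", phase_nudge)
}
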