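# ---- closed-form defect theory -----------------------------------------------
#
# Quantities of the geometric model for joining two hexagonal lattices of
# linear scale ratio alpha along a straight line: mismatch accumulation,
# the Delaunay-violation index, 5-7 pair rates, defect-free transition
# lengths, required transition layers, and the effective residual scale
# after observed layers.

#' Convert an area dimorphism score to a linear scale ratio
#'
#' The dimorphism score `D` is the additional area of reproductive cells
#' relative to worker cells (`D = area ratio - 1`); the corresponding linear
#' scale ratio is `alpha = sqrt(D + 1)`, since hexagonal cell area scales with
#' the square of the cell width.
#'
#' @param D area dimorphism score (>= 0).
#' @return linear scale ratio `alpha` (>= 1).
#' @seealso [scale_to_dimorphism()] for the inverse.
#' @examples
#' dimorphism_to_scale(0)      # monomorphic: 1
#' dimorphism_to_scale(1.70)   # ~1.643
#' @export
dimorphism_to_scale <- function(D) {
  if (any(!is.finite(D) | D < 0)) stop("D must be >= 0")
  sqrt(D + 1)
}

#' @rdname dimorphism_to_scale
#' @param alpha linear scale ratio (>= 1).
#' @export
scale_to_dimorphism <- function(alpha) {
  if (any(!is.finite(alpha) | alpha < 1)) stop("alpha must be >= 1")
  alpha^2 - 1
}

#' First Delaunay-violating neighbour index
#'
#' Counting worker-cell edges laterally away from the aligned "0" position,
#' the mismatch between worker and reproductive cell centres accumulates by
#' `alpha - 1` per step.  The Delaunay condition is violated at the smallest
#' integer `N` with `N * (alpha - 1) > alpha / 2` (strictly: a mismatch of
#' exactly half a reproductive cell does not yet force a dislocation), at
#' which point a 5-7 pair must be inserted.
#'
#' @param alpha linear scale ratio, > 1.
#' @return smallest violating integer `N`; `Inf` when `alpha = 1`.
#' @examples
#' first_dislocation_index(2)       # 2
#' first_dislocation_index(1.6432)  # 2
#' @export
first_dislocation_index <- function(alpha) {
  if (!is.finite(alpha) || alpha < 1) stop("alpha must be >= 1")
  if (alpha == 1) return(Inf)
  # smallest integer N with N * (alpha - 1) > alpha / 2
  N <- floor(alpha / (2 * (alpha - 1))) + 1
  # guard the boundary case where alpha/(2(alpha-1)) is an exact integer
  if ((N - 1) * (alpha - 1) > alpha / 2) N <- N - 1
  as.integer(N)
}

#' Expected dislocation and non-hexagonal cell rates
#'
#' Along a one-step transition line, one dislocation (a 5-7 pair) is expected
#' every `alpha/(alpha - 1)` worker cell widths, i.e. a rate of
#' `(alpha - 1)/alpha` dislocations per worker cell and twice as many
#' non-hexagonal cells (each pair deforms one worker cell into a pentagon and
#' one reproductive cell into a heptagon).
#'
#' @param alpha linear scale ratio (>= 1).
#' @return named numeric vector: `dislocations_per_worker_cell`,
#'   `nonhex_cells_per_worker_cell`.
#' @examples
#' pair_rate(2)  # 0.5 dislocations, 1 non-hexagonal cell per worker cell
#' @export
pair_rate <- function(alpha) {
  if (any(!is.finite(alpha) | alpha < 1)) stop("alpha must be >= 1")
  c(dislocations_per_worker_cell = (alpha - 1) / alpha,
    nonhex_cells_per_worker_cell = 2 * (alpha - 1) / alpha)
}

#' Expected number of 5-7 pairs on a transition line
#'
#' For a one-step transition of length `L` worker-cell widths, the expected
#' number of 5-7 pairs is `floor((1 - 1/alpha) * L)`: the fractional part is
#' rounded down because the accumulated mismatch has not yet forced the next
#' pair.
#'
#' @param alpha linear scale ratio (>= 1).
#' @param L transition length in worker-cell widths (> 0).
#' @return integer number of expected pairs.
#' @examples
#' expected_pairs(2, 7)     # 3
#' expected_pairs(1.2, 4)   # 0: short, low-dimorphism lines stay defect-free
#' @export
expected_pairs <- function(alpha, L) {
  if (any(!is.finite(alpha) | alpha < 1)) stop("alpha must be >= 1")
  if (any(!is.finite(L) | L <= 0)) stop("L must be > 0")
  as.integer(floor((1 - 1 / alpha) * L))
}

#' Maximum defect-free scale step for a transition length
#'
#' A transition line of length `L` worker widths can absorb a scale step of
#' at most `alpha_L = L/(L - 1)` without introducing any dislocation (at that
#' ratio, `expected_pairs(alpha_L, L)` is still zero).  Equivalently, at
#' ratio `alpha` the longest defect-free line is `L_max = alpha/(alpha - 1)`.
#'
#' @param L transition length in worker-cell widths, > 1.
#' @return the maximum defect-free linear scale step `alpha_L`.
#' @examples
#' max_defect_free(10)  # 10/9
#' @export
max_defect_free <- function(L) {
  if (any(!is.finite(L) | L <= 1)) stop("L must be > 1")
  L / (L - 1)
}

#' Transition layers required for a defect-free merge
#'
#' A dislocation-free transition to scale `alpha` over a line of length `L`
#' can be accomplished with `T` successive layers of intermediate-sized cells
#' such that `alpha_L^T = alpha`, where `alpha_L = L/(L - 1)` is the largest
#' defect-free per-layer step; real `alpha` requires rounding up.
#'
#' @param alpha linear scale ratio, > 1.
#' @param L transition length in worker-cell widths, > 1.
#' @return smallest integer `T` with `alpha^(1/T) <= alpha_L`.
#' @examples
#' layers_required(1.6432, 10)  # 5
#' @export
layers_required <- function(alpha, L) {
  if (!is.finite(alpha) || alpha <= 1) stop("alpha must be > 1")
  aL <- max_defect_free(L)
  T <- ceiling(log(alpha) / log(aL) - 1e-12)
  as.integer(max(T, 1L))
}

#' Effective scale ratio after observed transition layers
#'
#' When a comb uses `T_obs` layers of intermediate-sized cells, each stepping
#' the linear scale by `alpha_L`, the residual ("effective") scale that still
#' has to be bridged by 5-7 pairs is `alpha_E = alpha / alpha_L^T_obs`,
#' floored at 1 (over-complete layering leaves nothing to bridge).
#' `T_obs` may be fractional: the last, largest layer is interpolated.
#'
#' @param alpha linear scale ratio (>= 1).
#' @param alpha_L per-layer scale step, > 1.
#' @param T_obs observed (possibly fractional) number of transition layers
#'   (>= 0).
#' @return effective scale ratio `alpha_E` in `[1, alpha]`.
#' @examples
#' effective_scale(1.3, 1.1, 2)  # ~1.0744
#' @export
effective_scale <- function(alpha, alpha_L, T_obs) {
  if (any(!is.finite(alpha) | alpha < 1)) stop("alpha must be >= 1")
  if (any(!is.finite(alpha_L) | alpha_L <= 1)) stop("alpha_L must be > 1")
  if (any(!is.finite(T_obs) | T_obs < 0)) stop("T_obs must be >= 0")
  aE <- alpha / alpha_L^T_obs
  if (any(aE < 1 - 1e-9))
    warning("over-complete layering: alpha_E clamped to 1")
  pmax(aE, 1)
}

#' Defect-theory parameter table
#'
#' Collects the closed-form quantities of the defect model for a given
#' dimorphism score and transition length: the scale ratio, per-step
#' mismatch, maximum defect-free length, first dislocation index, pair
#' rates, expected pairs, maximum defect-free step and layers required.
#'
#' @param D area dimorphism score (>= 0).
#' @param L transition length in worker-cell widths (> 1).
#' @param T_obs observed transition layers (default 0).
#' @return a list of class `"theory_params"`.
#' @examples
#' theory_params(D = 1.70, L = 10)
#' @export
theory_params <- function(D, L, T_obs = 0) {
  alpha <- dimorphism_to_scale(D)
  delta <- alpha - 1
  aL <- max_defect_free(L)
  aE <- if (alpha > 1) effective_scale(alpha, aL, T_obs) else 1
  structure(list(
    D = D, alpha = alpha, delta = delta,
    L = L,
    L_max = if (alpha > 1) alpha / (alpha - 1) else Inf,
    N_star = if (alpha > 1) first_dislocation_index(alpha) else Inf,
    rate = pair_rate(alpha),
    expected_pairs = expected_pairs(alpha, L),
    alpha_L = aL,
    T_required = if (alpha > 1) layers_required(alpha, L) else 0L,
    T_obs = T_obs, alpha_E = aE
  ), class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat("Defect-theory parameters\n")
  cat(sprintf("  D        = %.4f   (area dimorphism)\n", x$D))
  cat(sprintf("  alpha    = %.4f   (linear scale ratio)\n", x$alpha))
  cat(sprintf("  delta    = %.4f   (mismatch per lateral step)\n", x$delta))
  cat(sprintf("  L        = %.2f     (transition length, worker widths)\n", x$L))
  cat(sprintf("  L_max    = %s   (max defect-free length)\n",
              format(x$L_max, digits = 4)))
  cat(sprintf("  N*       = %s        (first dislocation index)\n",
              format(x$N_star)))
  cat(sprintf("  rate     = %.4f dislocations / worker cell (%.4f non-hex cells)\n",
              x$rate[1], x$rate[2]))
  cat(sprintf("  expected 5-7 pairs over L: %d\n", x$expected_pairs))
  cat(sprintf("  alpha_L  = %.4f   (max defect-free step for L)\n", x$alpha_L))
  cat(sprintf("  T needed = %s, T_obs = %.2f, alpha_E = %.4f\n",
              format(x$T_required), x$T_obs, x$alpha_E))
  invisible(x)
}
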