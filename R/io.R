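# ---- comb annotation files ---------------------------------------------------
#
# JSON schema for per-cell comb annotations (the interchange format standing
# in for hand-verified image extractions):
#   format_version   integer (currently 1)
#   species_tag      string or null
#   scale            worker cell width in native units (optional)
#   growth_direction [x, y] or absent
#   cells            [{id, center: [x, y], vertices: [[x, y], ...]?, label?}]
#   metadata         free-form provenance (generator parameters or image id)
# Coordinates are continuous 2-D Cartesian in worker-cell-width units;
# cell ids are 0-based; labels are worker | reproductive | unknown |
# transition_<k>.

#' Write a comb to an annotation JSON file
#'
#' @param x a [comb()].
#' @param path output file.
#' @param polygons optional list of vertex-ring matrices (e.g. from
#'   [voronoi_cells()]) written as per-cell `vertices`.
#' @return `path`, invisibly.
#' @seealso [read_comb()]
#' @export
write_comb <- function(x, path, polygons = NULL) {
  stopifnot(inherits(x, "comb"))
  n <- nrow(x$centers)
  cells <- lapply(seq_len(n), function(i) {
    cell <- list(id = i - 1L,
                 center = as.numeric(x$centers[i, ]),
                 label = x$labels[i])
    if (!is.null(polygons) && !is.null(polygons[[i]]))
      cell$vertices <- unname(apply(polygons[[i]], 1, as.numeric,
                                    simplify = FALSE))
    cell
  })
  doc <- list(format_version = 1L,
              species_tag = x$species_tag,
              growth_direction = x$growth_direction,
              cells = cells,
              metadata = x$metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a comb annotation JSON file
#'
#' Validates the schema (unique ids, finite length-2 centres, known labels,
#' simple vertex rings) and reports the offending cell id on failure.  A
#' file without `growth_direction` loads with orientation features disabled.
#'
#' @param path annotation file written by [write_comb()] or a compatible
#'   producer.
#' @return a [comb()]; any per-cell `vertices` are kept in the
#'   `"vertices"` attribute.
#' @export
read_comb <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$cells) || length(doc$cells) == 0)
    stop("annotation file has no cells: ", path)
  ids <- vapply(doc$cells, function(cl) as.integer(cl$id %||% NA), integer(1))
  if (anyNA(ids) || anyDuplicated(ids))
    stop("cell ids missing or duplicated in ", path)
  centers <- matrix(NA_real_, length(ids), 2)
  labels <- character(length(ids))
  vertices <- vector("list", length(ids))
  for (k in seq_along(doc$cells)) {
    cl <- doc$cells[[k]]
    ctr <- unlist(cl$center)
    if (length(ctr) != 2L || !all(is.finite(ctr)))
      stop("cell ", ids[k], ": center must be a finite [x, y] pair")
    centers[k, ] <- ctr
    labels[k] <- cl$label %||% "unknown"
    if (!is.null(cl$vertices)) {
      ring <- do.call(rbind, lapply(cl$vertices, unlist))
      if (ncol(ring) != 2L || !all(is.finite(ring)))
        stop("cell ", ids[k], ": malformed vertex ring")
      if (nrow(ring) >= 4L && ring_self_intersects(ring))
        stop("cell ", ids[k], ": self-intersecting vertex ring")
      vertices[[k]] <- ring
    }
  }
  gd <- if (!is.null(doc$growth_direction)) unlist(doc$growth_direction)
  out <- comb(centers, labels,
              growth_direction = gd,
              species_tag = doc$species_tag %||% NA_character_,
              metadata = lapply(doc$metadata %||% list(), simplify_meta))
  attr(out, "vertices") <- vertices
  out
}

simplify_meta <- function(v) {
  if (is.list(v) && all(vapply(v, function(e) is.atomic(e) && length(e) == 1L,
                               logical(1))))
    unlist(v) else v
}

# does the closed ring have any pair of non-adjacent crossing segments?
ring_self_intersects <- function(ring) {
  k <- nrow(ring)
  a <- ring
  b <- ring[c(2:k, 1), , drop = FALSE]
  for (i in seq_len(k - 2)) {
    for (j in (i + 2):k) {
      if (i == 1 && j == k) next  # adjacent around the ring
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2) && (o3 != o4) && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

# ---- trees -------------------------------------------------------------------

#' Read a Newick tree with validation
#'
#' Thin wrapper over [ape::read.tree()] that requires named tips and branch
#' lengths on every edge.
#'
#' @param path Newick file.
#' @return a `phylo`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stop("tree has unnamed tips: ", path)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("tree is missing branch lengths: ", path)
  tr
}

# ---- metrics output ----------------------------------------------------------

#' Per-cell metrics table
#'
#' @param x a [comb()] or [analyze_comb()] result.
#' @param edge_tol used if `x` still needs analysing.
#' @return data frame with one row per cell: `cell_id`, `x`, `y`, `label`,
#'   `n_walls`, `area` (worker-width^2), `normalized_area`, `is_interior`,
#'   `signed_distance` (worker widths from the transition line, positive on
#'   the reproductive side; `NA` when no line can be fit), `pair_id` (index
#'   of the 5-7 pair the cell belongs to, `NA` otherwise),
#'   `oriented_correctly`.
#' @export
per_cell_metrics <- function(x, edge_tol = 0.01) {
  a <- as_analysis(x, edge_tol)
  cl <- a$cells
  out <- data.frame(cell_id = cl$cell_id, x = cl$x, y = cl$y,
                    label = cl$label, n_walls = cl$n_walls, area = cl$area,
                    normalized_area = tryCatch(normalized_areas(a),
                                               error = function(e) NA_real_),
                    is_interior = cl$is_interior,
                    signed_distance = NA_real_,
                    pair_id = NA_integer_, oriented_correctly = NA,
                    stringsAsFactors = FALSE)
  line <- tryCatch(fit_transition_line(a), error = function(e) NULL)
  if (!is.null(line)) out$signed_distance <- signed_distances(cl, line)
  det <- detect_57_pairs(a)
  if (nrow(det$pairs) > 0) {
    for (p in seq_len(nrow(det$pairs))) {
      i5 <- match(det$pairs$five_id[p], cl$cell_id)
      i7 <- match(det$pairs$seven_id[p], cl$cell_id)
      out$pair_id[c(i5, i7)] <- p
      out$oriented_correctly[c(i5, i7)] <- det$pairs$oriented_correctly[p]
    }
  }
  out
}

#' Write per-cell and per-comb metric CSVs
#'
#' Writes `cells_<name>.csv` ([per_cell_metrics()] schema) and
#' `summary_<name>.csv` ([comb_summary()] schema) in full numeric precision;
#' areas are in worker-width^2 units, distances in worker widths.
#'
#' @param x a [comb()] or [analyze_comb()] result.
#' @param dir output directory (created if needed).
#' @param name basename used in the two file names.
#' @param edge_tol used if `x` still needs analysing.
#' @return named character vector of the two paths, invisibly.
#' @export
write_metrics <- function(x, dir, name = "comb", edge_tol = 0.01) {
  a <- as_analysis(x, edge_tol)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells_path <- file.path(dir, paste0("cells_", name, ".csv"))
  summary_path <- file.path(dir, paste0("summary_", name, ".csv"))
  utils::write.csv(per_cell_metrics(a), cells_path, row.names = FALSE)
  utils::write.csv(comb_summary(a), summary_path, row.names = FALSE)
  invisible(c(cells = cells_path, summary = summary_path))
}
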