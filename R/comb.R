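# ---- the comb container ------------------------------------------------------

#' Construct a comb object
#'
#' A comb is a set of labelled cell centres in worker-cell-width units,
#' optionally with per-cell polygon vertices and a growth direction (the
#' direction in which the comb was extended, pointing from the worker patch
#' towards the reproductive patch).
#'
#' @param centers n x 2 matrix of cell-centre coordinates (worker-cell widths).
#' @param labels character vector, one of `"worker"`, `"reproductive"`,
#'   `"unknown"`, or `"transition_<k>"` for generated intermediate layers;
#'   recycled if length 1.  Default `"unknown"`.
#' @param growth_direction unit 2-vector or `NULL` when unknown.
#' @param species_tag free-text species label.
#' @param metadata list of provenance fields (generator parameters or image
#'   identifiers).
#' @return An object of class `"comb"`.
#' @export
comb <- function(centers, labels = "unknown", growth_direction = NULL,
                 species_tag = NA_character_, metadata = list()) {
  centers <- as_centers(centers)
  n <- nrow(centers)
  labels <- rep_len(as.character(labels), n)
  ok <- labels %in% c("worker", "reproductive", "unknown") |
    grepl("^transition_[0-9]+$", labels)
  if (!all(ok))
    stop("invalid labels: ", paste(unique(labels[!ok]), collapse = ", "))
  if (!is.null(growth_direction)) {
    growth_direction <- as.numeric(growth_direction)
    if (length(growth_direction) != 2L || !all(is.finite(growth_direction)))
      stop("growth_direction must be a finite 2-vector")
    nrm <- sqrt(sum(growth_direction^2))
    if (nrm == 0) stop("growth_direction must be non-zero")
    growth_direction <- growth_direction / nrm
  }
  structure(list(centers = centers, labels = labels,
                 growth_direction = growth_direction,
                 species_tag = species_tag, metadata = metadata),
            class = "comb")
}

#' @export
print.comb <- function(x, ...) {
  n <- nrow(x$centers)
  cat("<comb> ", n, " cells", sep = "")
  if (!is.na(x$species_tag)) cat(" [", x$species_tag, "]", sep = "")
  cat("\n  labels: ")
  tl <- table(x$labels)
  cat(paste(names(tl), tl, sep = "="), sep = ", ")
  cat("\n")
  if (!is.null(x$growth_direction))
    cat(sprintf("  growth direction: (%.3f, %.3f)\n",
                x$growth_direction[1], x$growth_direction[2]))
  if (!is.null(x$metadata$alpha))
    cat(sprintf("  generator: alpha = %.4f, L = %s, T = %s, seed = %s\n",
                x$metadata$alpha, x$metadata$L,
                x$metadata$T %||% 0, x$metadata$seed %||% "none"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
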