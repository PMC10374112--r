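# ---- time-calibrated tree assembly -------------------------------------------

# children of each node as a list, and tip counts below each node
tree_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1]]] <- c(ch[[tree$edge[e, 1]]], tree$edge[e, 2])
  ch
}

descendant_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  ch <- tree_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    for (c in ch[[nd]]) {
      if (c <= ntip) out <- c(out, c) else stack <- c(stack, c)
    }
  }
  out
}

descendant_internal <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  ch <- tree_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd > ntip) { out <- c(out, nd); stack <- c(stack, ch[[nd]][ch[[nd]] > ntip]) }
  }
  out
}

#' Build an ultrametric time tree from divergence dates
#'
#' Assigns ages (millions of years) to the internal nodes of a fixed
#' topology and converts them to branch lengths.  Nodes are addressed as the
#' most recent common ancestor of a pair of tips.  A clade without
#' literature dates can be dated by the taxon-count heuristic - node age =
#' number of descending species minus one - and then linearly rescaled so
#' that the clade root matches an anchored age.
#'
#' @param topology a `phylo` object or Newick string (branch lengths, if
#'   any, are ignored).
#' @param ages data frame with columns `tip1`, `tip2`, `age`: the MRCA of
#'   `tip1` and `tip2` is set to `age` My.
#' @param rescale_clade optional list `list(tips = c(...), age = <My>)`: the
#'   clade spanned by `tips` gets taxon-count node ages linearly rescaled so
#'   its root age equals `age`.
#' @return an ultrametric `phylo` with branch lengths in My.
#' @examples
#' tr <- build_timetree("(A,B);", data.frame(tip1 = "A", tip2 = "B", age = 179))
#' tr$edge.length  # both tip branches 179
#' @export
build_timetree <- function(topology, ages, rescale_clade = NULL) {
  tree <- if (is.character(topology)) ape::read.tree(text = topology) else topology
  if (!inherits(tree, "phylo")) stop("topology must be a phylo or Newick string")
  ntip <- ape::Ntip(tree)
  age <- rep(NA_real_, ntip + tree$Nnode)
  age[seq_len(ntip)] <- 0

  if (!is.null(rescale_clade)) {
    miss <- setdiff(rescale_clade$tips, tree$tip.label)
    if (length(miss))
      stop("rescale anchor taxa absent from tree: ", paste(miss, collapse = ", "))
    root_r <- ape::getMRCA(tree, rescale_clade$tips)
    nodes <- descendant_internal(tree, root_r)
    counts <- vapply(nodes, function(nd) length(descendant_tips(tree, nd)),
                     integer(1))
    raw <- counts - 1
    age[nodes] <- raw * rescale_clade$age / raw[nodes == root_r]
  }

  if (!is.null(ages) && nrow(ages) > 0) {
    for (r in seq_len(nrow(ages))) {
      nd <- ape::getMRCA(tree, c(as.character(ages$tip1[r]),
                                 as.character(ages$tip2[r])))
      age[nd] <- ages$age[r]
    }
  }
  internal <- (ntip + 1):(ntip + tree$Nnode)
  if (anyNA(age[internal])) {
    bad <- internal[is.na(age[internal])]
    stop("no age for internal node(s): ",
         paste(vapply(bad, function(nd)
           paste(head(tree$tip.label[descendant_tips(tree, nd)], 2),
                 collapse = "|"), character(1)), collapse = ", "))
  }
  bl <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(bl < 0))
    stop("node ages are not monotone along the tree (negative branch length)")
  tree$edge.length <- bl
  if (!ape::is.ultrametric(tree, tol = 1e-8))
    stop("resulting tree is not ultrametric")
  tree
}

# ---- PGLS with Pagel's lambda ------------------------------------------------

# lambda-scaled Brownian covariance: off-diagonal elements multiplied by lambda
lambda_vcv <- function(V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# GLS fit of y ~ x under covariance V; returns estimates and ML log-likelihood
gls_fit_V <- function(X, y, V) {
  n <- length(y)
  C <- tryCatch(chol(V), error = function(e)
    stop("phylogenetic covariance not positive definite (condition: ",
         format(kappa(V)), ")"))
  # whiten: V = t(C) %*% C with C upper triangular
  yw <- backsolve(C, y, transpose = TRUE)
  Xw <- backsolve(C, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ldetV <- 2 * sum(log(diag(C)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + ldetV + n)
  list(coef = fit$coefficients, rss = rss, sigma2 = sigma2, loglik = ll,
       Xw = Xw, yw = yw)
}

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' Regresses a species-level response on a predictor under the Brownian
#' covariance implied by a time-calibrated tree, with the phylogenetic
#' signal of the residuals scaled by Pagel's lambda (off-diagonal elements
#' of the covariance multiplied by `lambda`).  `lambda` is estimated by
#' maximum likelihood over `[0, 1]` using a 25-point grid pre-scan followed
#' by bounded scalar optimization; at `lambda = 0` the fit reduces to
#' ordinary least squares (for an ultrametric tree).
#'
#' @param x,y named numeric vectors (names = tip labels), e.g. dimorphism
#'   score and proportion of non-hexagonal cells per species.
#' @param tree ultrametric `phylo`; tips must match the data names 1:1.
#' @param lambda fix lambda instead of estimating it (optional).
#' @return list of class `"pgls_fit"`: `lambda`, `intercept`, `slope`,
#'   `se_slope`, `F_stat`, `df` (c(1, n-2)), `p_value`, `adj_R2`, `R2`,
#'   `loglik`, `sigma2`, `n`, `lambda_profile` (grid of lambda vs log-lik).
#' @export
pgls_fit <- function(x, y, tree, lambda = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (is.null(names(x)) || is.null(names(y)))
    stop("x and y must be named by species (tree tip labels)")
  if (!setequal(names(x), tips) || !setequal(names(y), tips))
    stop("tree tips and data names do not match 1:1")
  x <- x[tips]; y <- y[tips]
  n <- length(y)
  if (n < 4L) stop("need at least 4 species")
  V <- ape::vcv(tree)
  X <- cbind(`(Intercept)` = 1, x = x)

  ll_of <- function(lam) gls_fit_V(X, y, lambda_vcv(V, lam))$loglik
  grid <- seq(0, 1, length.out = 25)
  gll <- vapply(grid, ll_of, numeric(1))
  if (is.null(lambda)) {
    i <- which.max(gll)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    if (lo < hi) {
      op <- stats::optimize(ll_of, c(lo, hi), maximum = TRUE, tol = 1e-8)
      lambda <- if (op$objective >= gll[i]) op$maximum else grid[i]
    } else lambda <- grid[i]
    # snap to the boundary when it is at least as good
    for (b in c(0, 1)) if (ll_of(b) >= ll_of(lambda)) lambda <- b
  }
  fit <- gls_fit_V(X, y, lambda_vcv(V, lambda))
  fit0 <- gls_fit_V(X[, 1, drop = FALSE], y, lambda_vcv(V, lambda))
  df2 <- n - 2L
  F_stat <- (fit0$rss - fit$rss) / (fit$rss / df2)
  p <- stats::pf(F_stat, 1, df2, lower.tail = FALSE)
  R2 <- 1 - fit$rss / fit0$rss
  adj_R2 <- 1 - (1 - R2) * (n - 1) / df2
  XtX <- crossprod(fit$Xw)
  se <- sqrt(diag(solve(XtX)) * fit$rss / df2)
  structure(list(
    lambda = lambda, intercept = unname(fit$coef[1]),
    slope = unname(fit$coef[2]), se_slope = unname(se[2]),
    F_stat = F_stat, df = c(1L, df2), p_value = p,
    adj_R2 = adj_R2, R2 = R2, loglik = fit$loglik, sigma2 = fit$sigma2,
    n = n, lambda_profile = data.frame(lambda = grid, loglik = gll)
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (Pagel's lambda, ML)\n")
  cat(sprintf("  lambda = %.4f\n", x$lambda))
  cat(sprintf("  slope = %.4f (SE %.4f), intercept = %.4f\n",
              x$slope, x$se_slope, x$intercept))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.4g, adj R2 = %.3f\n",
              x$df[1], x$df[2], x$F_stat, x$p_value, x$adj_R2))
  invisible(x)
}

#' Simulate Brownian trait evolution on a tree
#'
#' Draws one multivariate-normal sample with covariance `sigma2 * vcv(tree)`
#' around `mean`; used for parameter-recovery checks of [pgls_fit()].
#'
#' @param tree a `phylo`.
#' @param sigma2 Brownian rate.
#' @param mean root state.
#' @return named numeric vector over tips.
#' @export
sim_brownian <- function(tree, sigma2 = 1, mean = 0) {
  V <- ape::vcv(tree) * sigma2
  C <- chol(V)
  z <- stats::rnorm(nrow(V))
  stats::setNames(mean + as.numeric(crossprod(C, z)), rownames(V))
}

#' Example study time tree
#'
#' Assembles the ten-species time tree used by the bundled analysis scripts:
#' honey bees and social wasps anchored at their 179-My split, with the
#' *Vespula* clade dated by the taxon-count heuristic rescaled so the
#' *V. shidai* divergence is 8 My.  Divergence dates other than those two
#' anchors are illustrative example values shipped in
#' `inst/extdata/divergence_dates_example.csv`, not literature estimates;
#' substitute your own table for real analyses.
#'
#' @return an ultrametric 10-tip `phylo`, branch lengths in My.
#' @export
study_timetree <- function() {
  topo <- readLines(system.file("extdata", "study_topology_example.nwk",
                                package = "hexcomb"))
  ages <- utils::read.csv(system.file("extdata",
                                      "divergence_dates_example.csv",
                                      package = "hexcomb"))
  vesp <- c("V_vulgaris", "V_flavopilosa", "V_maculifrons", "V_shidai")
  build_timetree(topo, ages, rescale_clade = list(tips = vesp, age = 8))
}
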