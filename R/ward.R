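#' Euclidean occupancy distance between sites
#'
#' For binary incidence rows the Euclidean distance reduces to the square
#' root of the size of the symmetric difference of the two assemblages.
#'
#' @param x a [site_matrix()].
#' @return symmetric numeric matrix with site ids as dimnames.
#' @export
occupancy_distance <- function(x) {
  stopifnot(inherits(x, "site_matrix"))
  as.matrix(stats::dist(x$incidence, method = "euclidean"))
}

#' Convex alpha-combination of compositional and geographic dissimilarity
#'
#' Both matrices are first normalized by their maximum off-diagonal entry
#' (kilometres and occupancy units are not commensurable, and
#' normalization makes alpha directly interpretable on \[0, 1\]), then
#' mixed as `(1 - alpha) * D0* + alpha * D1*`. Low alpha emphasizes
#' composition, high alpha geography. Raw (unnormalized) mixing is
#' available for completeness.
#'
#' @param D0 compositional dissimilarity matrix (e.g.
#'   [occupancy_distance()]).
#' @param D1 geographic distance matrix (e.g. [geo_matrix()]), same site
#'   order.
#' @param alpha mixing weight in \[0, 1\].
#' @param normalize divide each matrix by its max off-diagonal entry first
#'   (default `TRUE`).
#' @return the mixed dissimilarity matrix.
#' @export
mixed_dissimilarity <- function(D0, D1, alpha, normalize = TRUE) {
  D0 <- as.matrix(D0); D1 <- as.matrix(D1)
  stopifnot(alpha >= 0, alpha <= 1, all(dim(D0) == dim(D1)))
  if (!is.null(rownames(D0)) && !is.null(rownames(D1)) &&
      !identical(rownames(D0), rownames(D1)))
    stop("D0 and D1 have different site orderings")
  if (normalize) {
    m0 <- max(D0[upper.tri(D0)]); m1 <- max(D1[upper.tri(D1)])
    if (m0 <= 0 || m1 <= 0)
      stop("degenerate dissimilarity matrix (all entries identical)")
    D0 <- D0 / m0; D1 <- D1 / m1
  }
  (1 - alpha) * D0 + alpha * D1
}

#' Ward agglomeration on a dissimilarity matrix
#'
#' Agglomerative Ward clustering via the Lance-Williams recursion on
#' squared dissimilarities (the "ward.D2" convention: merge heights are the
#' square roots of the Ward criterion, so two singletons merge at their
#' input distance). Ties are broken toward the pair with the lowest leaf
#' indices, making the tree fully deterministic.
#'
#' @param D symmetric, zero-diagonal dissimilarity matrix.
#' @return an object of class `ward_dendrogram`: list with `merge`
#'   (hclust-style merge matrix), `height`, `labels`, `n`. Convert with
#'   [as.hclust()] for plotting.
#' @export
ward_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 sites")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    stop("D must be symmetric with zero diagonal")
  labels <- rownames(D) %||% as.character(seq_len(n))

  S <- D^2                       # Ward criterion table (squared scale)
  active <- seq_len(n)
  node <- -seq_len(n)            # hclust convention: negatives are leaves
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); bval <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      i <- active[ii]
      js <- active[(ii + 1L):length(active)]
      vals <- S[i, js]
      jm <- which.min(vals)      # lowest index wins ties within the row
      if (vals[jm] < bval) { bval <- vals[jm]; best <- c(i, js[jm]) }
    }
    i <- best[1L]; j <- best[2L]
    a <- node[i]; b <- node[j]
    merge[step, ] <- if (a < b) c(a, b) else c(b, a)
    height[step] <- sqrt(bval)
    rest <- setdiff(active, c(i, j))
    ni <- size[i]; nj <- size[j]
    for (k in rest) {
      nk <- size[k]
      S[i, k] <- S[k, i] <-
        ((ni + nk) * S[i, k] + (nj + nk) * S[j, k] - nk * bval) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    node[i] <- step
    active <- rest_keep(active, i, j)
  }
  structure(list(merge = merge, height = height, labels = labels, n = n),
            class = "ward_dendrogram")
}

rest_keep <- function(active, i, j) active[active != j]

#' @export
as.hclust.ward_dendrogram <- function(x, ...) {
  ord <- dendrogram_order(x$merge, x$n)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "ward.D2",
                 call = match.call(), dist.method = "mixed"),
            class = "hclust")
}

dendrogram_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat(sprintf("ward_dendrogram: %d leaves, merge heights %.3f .. %.3f\n",
              x$n, min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a Ward dendrogram into k clusters
#'
#' Removes the k-1 highest merges (equivalently, stops the agglomeration
#' after n-k merges; Ward heights are monotone) and labels the resulting
#' clusters canonically: numbered by decreasing size, ties by smallest
#' member site id.
#'
#' @param dend a [ward_tree()] result.
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer labels in `1..k`.
#' @export
cut_ward <- function(dend, k) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  n <- dend$n
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  node_members <- vector("list", n - 1L)
  lab <- seq_len(n)
  take <- n - k
  if (take > 0L) {
    for (s in seq_len(take)) {
      l <- dend$merge[s, 1L]; r <- dend$merge[s, 2L]
      lm <- if (l < 0) -l else node_members[[l]]
      rm <- if (r < 0) -r else node_members[[r]]
      node_members[[s]] <- c(lm, rm)
      # member set is complete for this node, so one assignment unions it
      lab[node_members[[s]]] <- min(lab[node_members[[s]]])
    }
  }
  canonicalize_labels(match(lab, sort(unique(lab))), dend$labels)
}

#' Explained pseudo-inertia of a partition on a dissimilarity matrix
#'
#' The share of total pairwise pseudo-inertia captured between clusters:
#' \deqn{Q = 1 - \frac{\sum_c I(c)}{I(\mathrm{all})}, \quad
#'       I(A) = \frac{1}{|A|} \sum_{i<j \in A} D_{ij}^2}
#' Q is 0 for the single-cluster partition and 1 when every site is its
#' own cluster; along a fixed dendrogram's cut sequence it is
#' non-decreasing in k.
#'
#' @param labels cluster labels aligned with `D`.
#' @param D dissimilarity matrix.
#' @return Q in \[0, 1\].
#' @export
explained_inertia <- function(labels, D) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  inertia <- function(idx) {
    if (length(idx) < 2L) return(0)
    sum(D[idx, idx]^2) / 2 / length(idx)
  }
  tot <- inertia(seq_len(n))
  if (tot == 0) return(0)
  within <- sum(vapply(unique(labels),
                       function(c) inertia(which(labels == c)), numeric(1)))
  1 - within / tot
}

#' Geography-constrained Ward clustering with inertia-based alpha selection
#'
#' Ward clustering on the convex combination
#' `(1 - alpha) * D0* + alpha * D1*` of max-normalized compositional
#' (Euclidean occupancy) and geographic (great-circle) dissimilarities.
#' With `alpha = "auto"`, every alpha on a grid (default step 0.01, 101
#' values) is evaluated by cutting its tree at `k` and scoring the
#' explained pseudo-inertia on each normalized matrix separately (Q0 on
#' composition, Q1 on geography); the alpha maximizing the selection
#' criterion (default `Q0 + Q1`; `"min"` uses `min(Q0, Q1)`) is chosen,
#' ties toward the smallest alpha. k is typically fixed to the chase
#' result so the two methods are compared like for like.
#'
#' @param x a [site_matrix()].
#' @param k number of clusters to cut.
#' @param alpha mixing weight in \[0, 1\], or `"auto"` (default) for grid
#'   selection.
#' @param alpha_grid_step grid resolution for `"auto"` (default 0.01).
#' @param criterion `"sum"` (Q0 + Q1, default) or `"min"` (max-min).
#' @param normalize passed to [mixed_dissimilarity()].
#' @return object of class `ward_geo`: list with `labels` (canonical),
#'   `alpha`, `k`, `Q0`, `Q1`, `curve` (data frame alpha, Q0, Q1, one row
#'   per grid value; a single row for fixed alpha), `tree` (the selected
#'   [ward_tree()]), and the call.
#' @export
#' @examples
#' syn <- simulate_sites(synth_config(n_regions = 3, sites_per_region = 5,
#'                                    species_per_region = 20), seed = 7)
#' fit <- ward_geo(syn$matrix, k = 3)
#' fit
ward_geo <- function(x, k, alpha = "auto", alpha_grid_step = 0.01,
                     criterion = c("sum", "min"), normalize = TRUE) {
  cl <- match.call()
  criterion <- match.arg(criterion)
  stopifnot(inherits(x, "site_matrix"))
  k <- as.integer(k)
  D0 <- occupancy_distance(x)
  D1 <- unclass(geo_matrix(x))
  m0 <- max(D0[upper.tri(D0)]); m1 <- max(D1[upper.tri(D1)])
  if (normalize) {
    if (m0 <= 0 || m1 <= 0) stop("degenerate dissimilarity matrix")
    D0n <- D0 / m0; D1n <- D1 / m1
  } else {
    D0n <- D0; D1n <- D1
  }
  eval_alpha <- function(a) {
    Dm <- (1 - a) * D0n + a * D1n
    tree <- ward_tree(Dm)
    lab <- cut_ward(tree, k)
    list(tree = tree, labels = lab,
         Q0 = explained_inertia(lab, D0n), Q1 = explained_inertia(lab, D1n))
  }
  if (identical(alpha, "auto")) {
    grid <- seq(0, 1, by = alpha_grid_step)
    evals <- lapply(grid, eval_alpha)
    curve <- data.frame(alpha = grid,
                        Q0 = vapply(evals, `[[`, numeric(1), "Q0"),
                        Q1 = vapply(evals, `[[`, numeric(1), "Q1"))
    score <- if (criterion == "sum") curve$Q0 + curve$Q1
             else pmin(curve$Q0, curve$Q1)
    best <- which.max(score)  # first max: ties to smallest alpha
    sel <- evals[[best]]
    alpha_sel <- grid[best]
  } else {
    alpha_sel <- as.numeric(alpha)
    sel <- eval_alpha(alpha_sel)
    curve <- data.frame(alpha = alpha_sel, Q0 = sel$Q0, Q1 = sel$Q1)
  }
  structure(list(labels = sel$labels, alpha = alpha_sel, k = k,
                 Q0 = sel$Q0, Q1 = sel$Q1, curve = curve, tree = sel$tree,
                 criterion = criterion, normalize = normalize, call = cl),
            class = "ward_geo")
}

#' @export
print.ward_geo <- function(x, ...) {
  cat("Geography-constrained Ward clustering\n")
  cat(sprintf("  k = %d, alpha = %.2f (Q0 = %.3f composition, Q1 = %.3f geography)\n",
              x$k, x$alpha, x$Q0, x$Q1))
  cat(sprintf("  cluster sizes: %s\n",
              paste(tabulate(x$labels), collapse = ", ")))
  invisible(x)
}

#' @export
summary.ward_geo <- function(object, ...) {
  print(object)
  if (nrow(object$curve) > 1L) {
    cat("\nalpha curve (every 10th grid point):\n")
    idx <- seq(1L, nrow(object$curve), by = 10L)
    print(object$curve[idx, ], row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.ward_geo <- function(x, ...) {
  if (nrow(x$curve) > 1L) {
    oldpar <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(oldpar))
    plot(x$curve$alpha, x$curve$Q0 + x$curve$Q1, type = "l",
         xlab = expression(alpha), ylab = "Q0 + Q1",
         main = "Inertia criterion", ...)
    graphics::abline(v = x$alpha, lty = 2, col = "grey40")
  }
  plot(stats::as.hclust(x$tree), main = "Mixed-dissimilarity Ward tree",
       xlab = "", sub = "", cex = 0.7)
  invisible(x)
}
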