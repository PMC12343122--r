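EARTH_RADIUS_KM <- 6371.0088  # IUGG mean radius; fixed for reproducibility

#' Pairwise compositional similarity between two assemblages
#'
#' Set-overlap similarity between two species sets:
#' \deqn{jaccard = |a \cap b| / |a \cup b|}
#' \deqn{simpson = |a \cap b| / \min(|a|, |b|)}
#' \deqn{ochiai  = |a \cap b| / \sqrt{|a| |b|}}
#' All three lie in \[0, 1\] and satisfy simpson >= ochiai >= jaccard.
#'
#' @param a,b character vectors (species sets); must be non-empty.
#' @param metric one of `"jaccard"`, `"simpson"`, `"ochiai"`.
#' @return similarity in \[0, 1\].
#' @export
pair_similarity <- function(a, b, metric = c("jaccard", "simpson", "ochiai")) {
  metric <- match.arg(metric)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L || length(b) == 0L)
    stop("species sets must be non-empty")
  i <- length(intersect(a, b))
  switch(metric,
         jaccard = i / length(union(a, b)),
         simpson = i / min(length(a), length(b)),
         ochiai = i / sqrt(length(a) * length(b)))
}

#' Build the chase matrix: all-pairs compositional similarity among sites
#'
#' The chase matrix S drives chase clustering: `S[i, j]` is the set-overlap
#' similarity between the assemblages of sites i and j. It is symmetric
#' with unit diagonal, and invariant to taxon column order.
#'
#' @param x a [site_matrix()] that has passed richness filtering (no empty
#'   assemblages).
#' @inheritParams pair_similarity
#' @return an object of class `chase_matrix`: a symmetric numeric matrix
#'   with site ids as dimnames and a `metric` attribute.
#' @export
chase_matrix <- function(x, metric = c("jaccard", "simpson", "ochiai")) {
  metric <- match.arg(metric)
  stopifnot(inherits(x, "site_matrix"))
  A <- x$incidence
  if (nrow(A) < 2L) stop("need at least 2 sites for a chase matrix")
  n_i <- rowSums(A)
  if (any(n_i == 0L)) stop("empty assemblage present; apply filter_richness first")
  inter <- tcrossprod(A)  # |a_i intersect a_j|
  S <- switch(metric,
              jaccard = inter / (outer(n_i, n_i, "+") - inter),
              simpson = inter / outer(n_i, n_i, pmin),
              ochiai = inter / sqrt(outer(n_i, n_i)))
  diag(S) <- 1
  structure(S, metric = metric, class = c("chase_matrix", "matrix", "array"))
}

#' @export
print.chase_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("chase_matrix: %d sites, metric %s\n", nrow(x),
              attr(x, "metric")))
  cat(sprintf("  off-diagonal similarity: min %.3f, mean %.3f, max %.3f\n",
              min(off), mean(off), max(off)))
  invisible(x)
}

#' Great-circle distance between two points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius, fixed so distances are bit-reproducible across platforms).
#'
#' @param p,q numeric length-2 vectors `(latitude, longitude)` in decimal
#'   degrees.
#' @return distance in kilometres.
#' @export
#' @examples
#' great_circle_km(c(0, 0), c(0, 180))  # half the circumference
great_circle_km <- function(p, q) {
  check_coords(c(p[1], q[1]), c(p[2], q[2]))
  # geosphere expects (lon, lat); radius passed in km yields km
  geosphere::distHaversine(c(p[2], p[1]), c(q[2], q[1]), r = EARTH_RADIUS_KM)
}

#' All-pairs great-circle distance matrix
#'
#' @param sites a [site_matrix()], a site data frame (columns `site_id`,
#'   `latitude`, `longitude`), or a coordinate matrix with columns
#'   `latitude`, `longitude` and site row names.
#' @return symmetric numeric matrix of distances in kilometres with site
#'   ids as dimnames (class `geo_matrix`).
#' @export
geo_matrix <- function(sites) {
  coords <- site_coords(sites)
  if (nrow(coords) < 2L) stop("need at least 2 sites")
  lonlat <- coords[, c("longitude", "latitude"), drop = FALSE]
  D <- geosphere::distm(lonlat,
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM))
  dimnames(D) <- list(rownames(coords), rownames(coords))
  D <- (D + t(D)) / 2  # enforce exact symmetry
  diag(D) <- 0
  structure(D, class = c("geo_matrix", "matrix", "array"))
}

site_coords <- function(sites) {
  if (inherits(sites, "site_matrix")) return(sites$coords)
  if (is.data.frame(sites)) {
    coords <- cbind(latitude = as.numeric(sites$latitude),
                    longitude = as.numeric(sites$longitude))
    rownames(coords) <- if ("site_id" %in% names(sites))
      as.character(sites$site_id) else rownames(sites)
  } else {
    coords <- as.matrix(sites)[, c("latitude", "longitude"), drop = FALSE]
  }
  check_coords(coords[, "latitude"], coords[, "longitude"])
  coords
}
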