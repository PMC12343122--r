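#' Site-by-species incidence matrix with coordinates
#'
#' The central exchange object of the package: a binary site x taxon
#' incidence matrix together with per-site WGS84 coordinates (decimal
#' degrees). Rows are sites, columns are taxa; both are kept in
#' lexicographic (C-locale) order so that every downstream computation is
#' order-independent.
#'
#' @param incidence numeric or integer matrix of 0/1 values with site ids as
#'   row names and taxon names as column names.
#' @param coords numeric matrix or data frame with columns `latitude` and
#'   `longitude` (decimal degrees), one row per site, row names (or a
#'   `site_id` column) matching the incidence row names.
#' @param epoch optional epoch label for the whole matrix (e.g.
#'   `"pleistocene"`, `"holocene"`).
#' @param drop_empty_taxa drop all-zero taxon columns (default `TRUE`; the
#'   class invariant requires no empty columns, so disabling this is only
#'   useful in intermediate steps).
#'
#' @return An object of class `site_matrix`: a list with elements
#'   `incidence` (integer matrix), `coords` (numeric matrix with columns
#'   `latitude`, `longitude`) and `epoch`.
#' @export
#' @examples
#' inc <- matrix(c(1, 1, 0, 1, 1, 0), nrow = 2,
#'               dimnames = list(c("s1", "s2"), c("wolf", "bear", "vole")))
#' xy <- data.frame(site_id = c("s1", "s2"), latitude = c(45, 46),
#'                  longitude = c(7, 8))
#' site_matrix(inc, xy)
site_matrix <- function(incidence, coords, epoch = NA_character_,
                        drop_empty_taxa = TRUE) {
  if (!is.matrix(incidence)) incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence must have site row names and taxon column names")
  if (anyDuplicated(rownames(incidence)))
    stop("duplicate site ids in incidence rows")
  if (anyDuplicated(colnames(incidence)))
    stop("duplicate taxon ids in incidence columns")
  storage.mode(incidence) <- "integer"
  if (anyNA(incidence) || !all(incidence %in% c(0L, 1L)))
    stop("incidence entries must all be 0 or 1")

  coords <- as_coord_matrix(coords, rownames(incidence))

  ord_s <- lex_order(rownames(incidence))
  ord_t <- lex_order(colnames(incidence))
  incidence <- incidence[ord_s, ord_t, drop = FALSE]
  coords <- coords[rownames(incidence), , drop = FALSE]
  if (drop_empty_taxa) {
    keep <- colSums(incidence) > 0L
    incidence <- incidence[, keep, drop = FALSE]
  }
  structure(list(incidence = incidence, coords = coords,
                 epoch = as.character(epoch)[1L]),
            class = "site_matrix")
}

as_coord_matrix <- function(coords, site_ids) {
  if (is.data.frame(coords)) {
    if ("site_id" %in% names(coords)) {
      rn <- as.character(coords$site_id)
    } else {
      rn <- rownames(coords)
    }
    coords <- cbind(latitude = as.numeric(coords$latitude),
                    longitude = as.numeric(coords$longitude))
    rownames(coords) <- rn
  } else {
    coords <- as.matrix(coords)
    if (is.null(colnames(coords))) colnames(coords) <- c("latitude", "longitude")
    coords <- coords[, c("latitude", "longitude"), drop = FALSE]
  }
  if (is.null(rownames(coords)))
    stop("coords must identify sites via row names or a site_id column")
  missing <- setdiff(site_ids, rownames(coords))
  if (length(missing))
    stop("sites without coordinates: ", paste(missing, collapse = ", "))
  coords <- coords[site_ids, , drop = FALSE]
  check_coords(coords[, "latitude"], coords[, "longitude"])
  coords
}

check_coords <- function(lat, lon) {
  if (anyNA(lat) || anyNA(lon) || any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("coordinates must be finite")
  if (any(lat < -90 | lat > 90))
    stop("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180))
    stop("longitude out of [-180, 180]")
  invisible(TRUE)
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("site_matrix: %d sites x %d taxa", nrow(x$incidence),
              ncol(x$incidence)))
  if (!is.na(x$epoch)) cat(sprintf(" (epoch: %s)", x$epoch))
  cat("\n")
  rs <- rowSums(x$incidence)
  cat(sprintf("  richness: min %d, median %g, max %d\n",
              min(rs), stats::median(rs), max(rs)))
  cat(sprintf("  fill: %.1f%%\n", 100 * mean(x$incidence)))
  invisible(x)
}

#' @rdname site_matrix
#' @param x a `site_matrix`.
#' @export
site_ids <- function(x) rownames(x$incidence)

#' @rdname site_matrix
#' @export
taxon_ids <- function(x) colnames(x$incidence)

#' @rdname site_matrix
#' @export
richness <- function(x) rowSums(x$incidence)

#' Drop species-poor sites from an incidence matrix
#'
#' Removes sites whose species richness falls below a minimum (default 5,
#' the conventional cut-off for avoiding unstable compositional signals in
#' sparse assemblages), then drops taxa left with zero occurrences. The
#' operation is idempotent: a second application is a no-op, because
#' dropping empty taxon columns cannot reduce any remaining row sum.
#'
#' @param x a [site_matrix()].
#' @param min_richness minimum species count a site must have to be kept
#'   (sites with *fewer* species are removed); integer >= 1.
#' @return the filtered `site_matrix`.
#' @export
filter_richness <- function(x, min_richness = 5L) {
  stopifnot(inherits(x, "site_matrix"))
  min_richness <- as.integer(min_richness)
  if (is.na(min_richness) || min_richness < 1L)
    stop("min_richness must be an integer >= 1")
  keep <- rowSums(x$incidence) >= min_richness
  if (!any(keep))
    stop("richness filter removed every site (min_richness = ",
         min_richness, ")")
  site_matrix(x$incidence[keep, , drop = FALSE],
              x$coords[keep, , drop = FALSE], epoch = x$epoch)
}

#' Split an incidence matrix into wild-only and full versions
#'
#' Removes the taxon columns named in `domesticates` to produce a "wild"
#' matrix directly comparable across epochs, re-applies the richness filter
#' (a site whose assemblage was dominated by domesticates may fall below the
#' minimum once they are removed), and returns both matrices. Names in
#' `domesticates` that do not occur in the matrix are ignored with a
#' warning, so one curated domesticate list can be reused across epochs.
#'
#' @inheritParams filter_richness
#' @param domesticates character vector of taxon names flagged as
#'   domesticated.
#' @return list with elements `wild` (domesticates removed, richness filter
#'   re-applied) and `all` (the input, unchanged).
#' @export
split_domesticates <- function(x, domesticates, min_richness = 5L) {
  stopifnot(inherits(x, "site_matrix"))
  domesticates <- unique(as.character(domesticates))
  unknown <- setdiff(domesticates, taxon_ids(x))
  if (length(unknown))
    warning("ignoring domesticate names absent from the matrix: ",
            paste(unknown, collapse = ", "))
  keep <- !(taxon_ids(x) %in% domesticates)
  wild <- site_matrix(x$incidence[, keep, drop = FALSE], x$coords,
                      epoch = x$epoch)
  wild <- filter_richness(wild, min_richness)
  list(wild = wild, all = x)
}

#' Build an incidence matrix from occurrence records
#'
#' Reduces occurrence records (with or without specimen counts) to binary
#' presence-absence: `incidence[i, j] = 1` iff at least one record of taxon
#' j exists at site i. Counts are discarded; taxa with no occurrence in the
#' selected epoch are dropped; rows and columns are ordered
#' lexicographically.
#'
#' @param records data frame of occurrence records as returned by
#'   [read_occurrences()] (columns `site_id`, `taxon`, `epoch`, ...).
#' @param sites data frame of sites as returned by [read_sites()] (columns
#'   `site_id`, `latitude`, `longitude`, `epoch`).
#' @param epoch epoch to select (case-insensitive); `NULL` uses all records.
#' @return a [site_matrix()].
#' @export
build_matrix <- function(records, sites, epoch = NULL) {
  records <- as.data.frame(records)
  sites <- as.data.frame(sites)
  if (!is.null(epoch)) {
    epoch <- tolower(epoch)
    records <- records[tolower(records$epoch) == epoch, , drop = FALSE]
    sites <- sites[tolower(sites$epoch) == epoch, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no occurrence records for the selected epoch")
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id in site table within an epoch")
  unknown <- setdiff(unique(records$site_id), sites$site_id)
  if (length(unknown))
    stop("occurrence records reference unknown sites: ",
         paste(lex_sort(unknown), collapse = ", "))
  sid <- lex_sort(records$site_id)
  tax <- lex_sort(records$taxon)
  inc <- matrix(0L, length(sid), length(tax), dimnames = list(sid, tax))
  inc[cbind(match(records$site_id, sid), match(records$taxon, tax))] <- 1L
  rownames(sites) <- sites$site_id
  site_matrix(inc, sites[sid, c("latitude", "longitude")],
              epoch = if (is.null(epoch)) NA_character_ else epoch)
}
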