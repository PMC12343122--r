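#' Read long-form occurrence records from delimited text
#'
#' Parses an occurrence table with columns `site_id`, `taxon`, `epoch`
#' (mandatory) and `rank`, `nisp`, `is_domesticate` (optional). Comma and
#' tab separators are auto-detected from the header line. Enumerated and
#' boolean fields are normalised case-insensitively; a missing `rank`
#' defaults to `"species"`. Rows violating the record invariants (unknown
#' rank or epoch, `nisp` present but < 1) are dropped with a warning that
#' lists file line numbers; the dropped rows are also attached as the
#' `"problems"` attribute of the result.
#'
#' @param path path to a UTF-8 delimited text file.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma.
#' @return data frame with columns `site_id`, `taxon`, `rank`, `epoch`,
#'   `nisp` (integer, `NA` when absent), `is_domesticate` (logical).
#' @export
read_occurrences <- function(path, sep = NULL) {
  df <- read_delim_checked(path, sep,
                           mandatory = c("site_id", "taxon", "epoch"))
  n <- nrow(df)
  out <- data.frame(
    site_id = as.character(df$site_id),
    taxon = trimws(as.character(df$taxon)),
    rank = if ("rank" %in% names(df)) tolower(trimws(as.character(df$rank)))
           else rep(NA_character_, n),
    epoch = tolower(trimws(as.character(df$epoch))),
    nisp = if ("nisp" %in% names(df)) suppressWarnings(as.integer(df$nisp))
           else rep(NA_integer_, n),
    is_domesticate = if ("is_domesticate" %in% names(df))
      parse_flag(df$is_domesticate) else rep(FALSE, n),
    stringsAsFactors = FALSE)
  out$rank[is.na(out$rank) | out$rank == ""] <- "species"

  bad_rank <- !(out$rank %in% c("species", "genus", "family", "unranked"))
  bad_epoch <- !(out$epoch %in% c("pleistocene", "holocene"))
  if ("nisp" %in% names(df)) {
    raw <- suppressWarnings(as.numeric(df$nisp))
    given <- !is.na(df$nisp) & trimws(as.character(df$nisp)) != ""
    bad_nisp <- given & (is.na(raw) | raw < 1 | raw != floor(raw))
  } else {
    bad_nisp <- rep(FALSE, n)
  }
  bad_flag <- is.na(out$is_domesticate)
  bad <- bad_rank | bad_epoch | bad_nisp | bad_flag
  if (any(bad)) {
    reason <- character(sum(bad))
    reason[bad_rank[bad]] <- "unknown rank"
    reason[bad_epoch[bad]] <- "unknown epoch"
    reason[bad_nisp[bad]] <- "nisp must be a positive integer"
    reason[bad_flag[bad]] <- "unparseable is_domesticate"
    problems <- data.frame(line = which(bad) + 1L, reason = reason,
                           stringsAsFactors = FALSE)
    warning(sprintf("dropped %d unparseable row(s) at line(s) %s", sum(bad),
                    paste(problems$line, collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "problems") <- problems
  }
  if (nrow(out) == 0L) stop("no valid occurrence rows in ", path)
  out$is_domesticate[is.na(out$is_domesticate)] <- FALSE
  out
}

#' Read a site coordinate table from delimited text
#'
#' Columns `site_id`, `latitude`, `longitude`, `epoch` are mandatory (a
#' `name` column is carried through when present). Coordinates must be
#' finite decimal degrees (WGS84) in range; site ids must be unique within
#' an epoch.
#'
#' @inheritParams read_occurrences
#' @return data frame with columns `site_id`, `name`, `latitude`,
#'   `longitude`, `epoch`.
#' @export
read_sites <- function(path, sep = NULL) {
  df <- read_delim_checked(path, sep,
                           mandatory = c("site_id", "latitude", "longitude",
                                         "epoch"))
  out <- data.frame(
    site_id = as.character(df$site_id),
    name = if ("name" %in% names(df)) as.character(df$name)
           else as.character(df$site_id),
    latitude = as.numeric(df$latitude),
    longitude = as.numeric(df$longitude),
    epoch = tolower(trimws(as.character(df$epoch))),
    stringsAsFactors = FALSE)
  check_coords(out$latitude, out$longitude)
  dup <- duplicated(out[, c("site_id", "epoch")])
  if (any(dup))
    stop("duplicate site_id within an epoch: ",
         paste(unique(out$site_id[dup]), collapse = ", "))
  out
}

read_delim_checked <- function(path, sep, mandatory) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty input file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("no data rows in ", path)
  df
}

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n", "", "na")] <- FALSE
  out
}

#' Keep only the most specific non-overlapping identifications
#'
#' Within each site, a genus-rank record is redundant when at least one
#' species-rank record of the same genus is present there, and is removed;
#' the rule applies per site, so the same genus record can be kept at one
#' site and dropped at another. Family-rank and unranked records have no
#' resolvable lineage here and pass through unchanged (counted in a
#' message). Species-rank records are never removed. The genus of a
#' species-rank binomial defaults to its first whitespace-delimited token;
#' an explicit `genus_of` mapping overrides this.
#'
#' @param records occurrence data frame (see [read_occurrences()]).
#' @param genus_of optional named character vector mapping taxon name to
#'   genus.
#' @return the reduced occurrence data frame, ordered by site then taxon.
#' @export
reduce_min_unique <- function(records, genus_of = NULL) {
  records <- as.data.frame(records)
  if (!"rank" %in% names(records)) records$rank <- "species"
  genus_for <- function(taxon, rank) {
    g <- if (!is.null(genus_of)) unname(genus_of[taxon]) else NA_character_
    derived <- ifelse(rank == "genus", taxon,
                      ifelse(rank == "species",
                             sub("\\s.*$", "", taxon), NA_character_))
    ifelse(is.na(g), derived, g)
  }
  genus <- genus_for(records$taxon, records$rank)
  sp_keys <- unique(paste0(records$site_id, "\r", genus)[
    records$rank == "species" & !is.na(genus)])
  redundant <- records$rank == "genus" &
    paste0(records$site_id, "\r", genus) %in% sp_keys
  coarse <- sum(records$rank %in% c("family", "unranked"))
  if (coarse > 0L)
    message(coarse, " family/unranked record(s) passed through unchanged")
  out <- records[!redundant, , drop = FALSE]
  out <- out[lex_order(out$site_id, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a wide 0-1 incidence table
#'
#' Interchange format: delimited text, first column `site_id`, one column
#' per taxon, cells 0/1. Sites are rows. Coordinates are not part of the
#' wide format; `read_incidence()` takes them from a site table.
#'
#' @param x a [site_matrix()].
#' @param path output (input) path.
#' @param sep field separator, default comma.
#' @export
write_incidence <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "site_matrix"))
  df <- data.frame(site_id = site_ids(x), x$incidence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_incidence
#' @param sites site table (see [read_sites()]) supplying coordinates.
#' @param epoch optional epoch label passed to the resulting matrix.
#' @export
read_incidence <- function(path, sites, epoch = NA_character_, sep = NULL) {
  df <- read_delim_checked(path, sep, mandatory = "site_id")
  inc <- as.matrix(df[, setdiff(names(df), "site_id"), drop = FALSE])
  rownames(inc) <- as.character(df$site_id)
  sites <- as.data.frame(sites)
  rownames(sites) <- make.unique(as.character(sites$site_id))
  site_matrix(inc, sites[rownames(inc), c("latitude", "longitude")],
              epoch = epoch)
}
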