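#' Configuration for the planted-partition community generator
#'
#' Defines a world of `n_regions` disjoint regional species pools plus a
#' shared cosmopolitan pool. Each site detects each species of its own
#' region with probability `p_det`, each cosmopolitan with `p_cos`, and
#' each foreign-region species with the small leakage probability
#' `p_leak`; region pools are disjoint by construction, so expected
#' between-region similarity stays analytically tractable. Site
#' coordinates scatter isotropically around well-separated region centres,
#' making geography concordant with composition. A cross-regional
#' "domesticate" overlay and epoch pairs with controlled pool turnover
#' emulate the homogenizing and turnover signals of zooarchaeological
#' data.
#'
#' @param n_regions number of regions (>= 2), default 5.
#' @param species_per_region size of each regional pool, default 40.
#' @param n_cosmopolitan shared species occurring everywhere, default 10.
#' @param sites_per_region sites per region, default 12.
#' @param p_det within-region detection probability, default 0.6.
#' @param p_cos cosmopolitan detection probability, default 0.3.
#' @param p_leak cross-region leakage probability, default 0.02.
#' @param n_domesticates taxa in the domesticate overlay, default 6.
#' @param p_dom per-site domesticate inclusion probability, default 0.5.
#' @param region_centers matrix/data frame of (latitude, longitude) region
#'   centres; default: centres at least `10 * coord_sd` degrees apart.
#' @param coord_sd isotropic coordinate noise, degrees, default 1.5.
#' @param tau_loss,tau_gain per-region pool replacement fractions for
#'   epoch pairs (`tau_loss + tau_gain <= 1`), defaults 0.2 each.
#' @param min_richness richness filter applied to generated sites.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_regions = 5L, species_per_region = 40L,
                         n_cosmopolitan = 10L, sites_per_region = 12L,
                         p_det = 0.6, p_cos = 0.3, p_leak = 0.02,
                         n_domesticates = 6L, p_dom = 0.5,
                         region_centers = NULL, coord_sd = 1.5,
                         tau_loss = 0.2, tau_gain = 0.2,
                         min_richness = 5L) {
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 2L, species_per_region >= 1L, sites_per_region >= 1L)
  probs <- c(p_det, p_cos, p_leak, p_dom)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (tau_loss < 0 || tau_gain < 0 || tau_loss + tau_gain > 1)
    stop("need tau_loss, tau_gain >= 0 and tau_loss + tau_gain <= 1")
  if (is.null(region_centers)) {
    # default centres on a widely spaced grid, >= 10 * coord_sd apart
    spacing <- max(20, 10 * coord_sd)
    per_row <- ceiling(sqrt(n_regions))
    g <- expand.grid(row = seq_len(per_row) - 1L, col = seq_len(per_row) - 1L)
    g <- g[seq_len(n_regions), , drop = FALSE]
    region_centers <- cbind(latitude = -30 + g$row * spacing,
                            longitude = -60 + g$col * spacing)
  } else {
    region_centers <- as.matrix(as.data.frame(region_centers)[,
                                  c("latitude", "longitude")])
    if (nrow(region_centers) != n_regions)
      stop("region_centers must have one row per region")
    D <- unclass(geo_matrix(cbind(region_centers)))
    min_sep_km <- 10 * coord_sd * 111.19  # degrees to km at the equator
    if (min(D[upper.tri(D)]) < min_sep_km)
      warning("region centres closer than 10 * coord_sd; geographic signal ",
              "may not separate regions")
  }
  rownames(region_centers) <- NULL
  structure(list(n_regions = n_regions,
                 species_per_region = as.integer(species_per_region),
                 n_cosmopolitan = as.integer(n_cosmopolitan),
                 sites_per_region = as.integer(sites_per_region),
                 p_det = p_det, p_cos = p_cos, p_leak = p_leak,
                 n_domesticates = as.integer(n_domesticates), p_dom = p_dom,
                 region_centers = region_centers, coord_sd = coord_sd,
                 tau_loss = tau_loss, tau_gain = tau_gain,
                 min_richness = as.integer(min_richness)),
            class = "synth_config")
}

# Named substreams off one integer seed so single components can be
# regenerated independently (pools / sites / coords / domesticates / epochs).
synth_seed <- function(seed, stream) {
  offsets <- c(pools = 11L, sites = 23L, coords = 37L, domesticates = 53L,
               epochs = 71L)
  as.integer((as.double(seed) * 48271 + offsets[[stream]] * 9176) %% 2147483629)
}

region_pool_names <- function(cfg) {
  lapply(seq_len(cfg$n_regions), function(g)
    sprintf("sp_r%02d_%03d", g, seq_len(cfg$species_per_region)))
}

#' Simulate a planted-partition incidence matrix
#'
#' Draws `n_regions * sites_per_region` sites with Bernoulli detection
#' from their regional pool, the cosmopolitan pool, and (rarely) foreign
#' pools, plus noisy coordinates around the region centres; applies the
#' richness filter. Sites falling below the richness minimum are redrawn
#' (up to 100 attempts each).
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return list with `matrix` (a [site_matrix()]) and `true_labels` (named
#'   integer region labels, the planted partition).
#' @export
simulate_sites <- function(cfg = synth_config(), seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  pools <- region_pool_names(cfg)
  cosmo <- sprintf("sp_cosmo_%03d", seq_len(cfg$n_cosmopolitan))
  set.seed(synth_seed(seed, "sites"))
  rows <- list(); labels <- integer(0); ids <- character(0)
  for (g in seq_len(cfg$n_regions)) {
    for (s in seq_len(cfg$sites_per_region)) {
      sid <- sprintf("site_r%02d_%02d", g, s)
      for (attempt in seq_len(100L)) {
        present <- character(0)
        for (h in seq_len(cfg$n_regions)) {
          p <- if (h == g) cfg$p_det else cfg$p_leak
          if (p > 0)
            present <- c(present,
                         pools[[h]][runif(cfg$species_per_region) < p])
        }
        if (cfg$n_cosmopolitan > 0L)
          present <- c(present, cosmo[runif(cfg$n_cosmopolitan) < cfg$p_cos])
        if (length(present) >= cfg$min_richness) break
        if (attempt == 100L)
          stop("site ", sid, " failed the richness minimum in 100 draws; ",
               "raise detection probabilities or lower min_richness")
      }
      rows[[sid]] <- present
      labels <- c(labels, g); ids <- c(ids, sid)
    }
  }
  taxa <- lex_sort(unlist(rows))
  inc <- matrix(0L, length(ids), length(taxa), dimnames = list(ids, taxa))
  for (i in seq_along(rows)) inc[ids[i], rows[[i]]] <- 1L
  set.seed(synth_seed(seed, "coords"))
  centers <- cfg$region_centers[labels, , drop = FALSE]
  coords <- cbind(latitude = centers[, "latitude"] +
                    rnorm(length(ids), 0, cfg$coord_sd),
                  longitude = centers[, "longitude"] +
                    rnorm(length(ids), 0, cfg$coord_sd))
  coords[, "latitude"] <- pmin(pmax(coords[, "latitude"], -90), 90)
  coords[, "longitude"] <- pmin(pmax(coords[, "longitude"], -180), 180)
  rownames(coords) <- ids
  names(labels) <- ids
  m <- site_matrix(inc, coords)
  m <- filter_richness(m, cfg$min_richness)
  labels <- labels[site_ids(m)]
  list(matrix = m, true_labels = labels)
}

#' Overlay cross-regional domesticate taxa
#'
#' Adds `n_domesticates` new taxon columns; every site acquires each
#' domesticate independently with probability `p_dom`, regardless of
#' region — the homogenizing signal that cross-regional livestock impose
#' on otherwise regionally structured assemblages.
#'
#' @inheritParams simulate_sites
#' @param x the [site_matrix()] to overlay (e.g. from [simulate_sites()]).
#' @return list with `matrix` (the overlaid [site_matrix()]) and
#'   `domesticates` (the overlay taxon names).
#' @export
overlay_domesticates <- function(x, cfg = synth_config(), seed = 1L) {
  stopifnot(inherits(x, "site_matrix"))
  doms <- sprintf("dom_%02d", seq_len(cfg$n_domesticates))
  set.seed(synth_seed(seed, "domesticates"))
  n <- nrow(x$incidence)
  add <- matrix(as.integer(runif(n * cfg$n_domesticates) < cfg$p_dom),
                n, cfg$n_domesticates,
                dimnames = list(site_ids(x), doms))
  m <- site_matrix(cbind(x$incidence, add), x$coords, epoch = x$epoch)
  list(matrix = m, domesticates = doms)
}

#' Simulate an epoch pair with controlled pool turnover
#'
#' The later epoch's regional pool replaces a `tau_loss` fraction of the
#' earlier pool (uniformly chosen) and adds `tau_gain * species_per_region`
#' novel species, giving a pool-level Jaccard turnover of
#' `(tau_loss + tau_gain) / (1 + tau_gain)` in closed form. Cosmopolitans
#' persist across epochs. Both epochs share region centres and per-site
#' coordinates, so radius aggregation pairs them; the epoch-pair default
#' coordinate noise is small (0.1 degrees) so each region forms one
#' multi-site locality whose pooled assemblage approaches the full
#' regional pool.
#'
#' @inheritParams simulate_sites
#' @param coord_sd coordinate noise for the epoch pair, degrees.
#' @return list with `pleistocene` and `holocene` ([site_matrix()]
#'   objects), `true_labels`, and `expected_turnover` (the pool-level
#'   closed form, one value per region).
#' @export
simulate_epoch_pair <- function(cfg = synth_config(), seed = 1L,
                                coord_sd = 0.1) {
  stopifnot(inherits(cfg, "synth_config"))
  B <- cfg$species_per_region
  pools_p <- region_pool_names(cfg)
  set.seed(synth_seed(seed, "pools"))
  pools_h <- lapply(seq_len(cfg$n_regions), function(g) {
    keep <- sample.int(B, round((1 - cfg$tau_loss) * B))
    novel <- sprintf("sp_r%02d_new_%03d", g, seq_len(round(cfg$tau_gain * B)))
    c(pools_p[[g]][sort(keep)], novel)
  })
  cosmo <- sprintf("sp_cosmo_%03d", seq_len(cfg$n_cosmopolitan))
  set.seed(synth_seed(seed, "coords"))
  labels <- rep(seq_len(cfg$n_regions), each = cfg$sites_per_region)
  centers <- cfg$region_centers[labels, , drop = FALSE]
  coords <- cbind(latitude = pmin(pmax(centers[, "latitude"] +
                    rnorm(length(labels), 0, coord_sd), -90), 90),
                  longitude = pmin(pmax(centers[, "longitude"] +
                    rnorm(length(labels), 0, coord_sd), -180), 180))

  draw_epoch <- function(pools, tag, stream_seed) {
    set.seed(stream_seed)
    ids <- sprintf("site_%s_r%02d_%02d", tag, labels,
                   sequence(rep(cfg$sites_per_region, cfg$n_regions)))
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      g <- labels[i]
      for (attempt in seq_len(100L)) {
        present <- pools[[g]][runif(length(pools[[g]])) < cfg$p_det]
        if (cfg$p_leak > 0)
          for (h in seq_len(cfg$n_regions)[-g])
            present <- c(present, pools[[h]][runif(length(pools[[h]])) <
                                               cfg$p_leak])
        if (cfg$n_cosmopolitan > 0L)
          present <- c(present, cosmo[runif(cfg$n_cosmopolitan) < cfg$p_cos])
        if (length(present) >= cfg$min_richness) break
        if (attempt == 100L)
          stop("site ", ids[i], " failed the richness minimum in 100 draws")
      }
      rows[[i]] <- unique(present)
    }
    taxa <- lex_sort(unlist(rows))
    inc <- matrix(0L, length(ids), length(taxa), dimnames = list(ids, taxa))
    for (i in seq_along(ids)) inc[i, rows[[i]]] <- 1L
    cc <- coords; rownames(cc) <- ids
    filter_richness(site_matrix(inc, cc, epoch = if (tag == "p")
      "pleistocene" else "holocene"), cfg$min_richness)
  }
  ple <- draw_epoch(pools_p, "p", synth_seed(seed, "sites"))
  hol <- draw_epoch(pools_h, "h", synth_seed(seed, "epochs"))
  names(labels) <- sprintf("site_p_r%02d_%02d", labels,
                           sequence(rep(cfg$sites_per_region, cfg$n_regions)))
  list(pleistocene = ple, holocene = hol, true_labels = labels,
       expected_turnover = rep((cfg$tau_loss + cfg$tau_gain) /
                                 (1 + cfg$tau_gain), cfg$n_regions))
}

#' Nested (hierarchical) planted structure for regularization sweeps
#'
#' Generates super-regions that each contain several subregions: sites
#' share a super-regional pool fraction with all subregions of their
#' super-region, and a private subregional pool with their own subregion
#' only; different super-regions overlap only through cosmopolitans. The
#' resulting similarity structure has two merge scales, so the number of
#' clusters selected by [chase()] grows stepwise as gamma becomes more
#' negative — the fixture for gamma-monotonicity checks.
#'
#' @param n_super number of super-regions (default 2).
#' @param sub_per_super subregions per super-region (default 3).
#' @param b_shared species in each super-regional shared pool (default 15).
#' @param b_sub species private to each subregion (default 35).
#' @param n_cosmopolitan globally shared species (default 8).
#' @param sites_per_sub sites per subregion (default 8).
#' @param p_det,p_cos detection probabilities (defaults 0.7 and 0.3).
#' @param coord_sd coordinate noise, degrees (default 1).
#' @param min_richness richness filter minimum.
#' @param seed integer seed.
#' @return list with `matrix`, `sub_labels` (the fine planted partition)
#'   and `super_labels` (the coarse one), both named by site id.
#' @export
simulate_nested <- function(n_super = 2L, sub_per_super = 3L, b_shared = 15L,
                            b_sub = 35L, n_cosmopolitan = 8L,
                            sites_per_sub = 8L, p_det = 0.7, p_cos = 0.3,
                            coord_sd = 1, min_richness = 5L, seed = 1L) {
  set.seed(synth_seed(seed, "sites"))
  cosmo <- sprintf("sp_cosmo_%03d", seq_len(n_cosmopolitan))
  ids <- character(0); subl <- integer(0); supl <- integer(0)
  rows <- list()
  sub_id <- 0L
  for (a in seq_len(n_super)) {
    shared <- sprintf("sp_s%02d_shared_%03d", a, seq_len(b_shared))
    for (b in seq_len(sub_per_super)) {
      sub_id <- sub_id + 1L
      own <- sprintf("sp_s%02d_sub%02d_%03d", a, b, seq_len(b_sub))
      for (s in seq_len(sites_per_sub)) {
        sid <- sprintf("site_s%02d_sub%02d_%02d", a, b, s)
        for (attempt in seq_len(100L)) {
          present <- c(shared[runif(b_shared) < p_det],
                       own[runif(b_sub) < p_det],
                       cosmo[runif(n_cosmopolitan) < p_cos])
          if (length(present) >= min_richness) break
          if (attempt == 100L) stop("site ", sid, " failed richness minimum")
        }
        rows[[sid]] <- present
        ids <- c(ids, sid); subl <- c(subl, sub_id); supl <- c(supl, a)
      }
    }
  }
  taxa <- lex_sort(unlist(rows))
  inc <- matrix(0L, length(ids), length(taxa), dimnames = list(ids, taxa))
  for (i in seq_along(ids)) inc[ids[i], rows[[ids[i]]]] <- 1L
  set.seed(synth_seed(seed, "coords"))
  spacing <- max(20, 10 * coord_sd)
  centers <- cbind(latitude = -20 + (supl - 1) * spacing,
                   longitude = -40 + ((subl - 1) %% sub_per_super) * spacing)
  coords <- cbind(latitude = pmin(pmax(centers[, "latitude"] +
                    rnorm(length(ids), 0, coord_sd), -90), 90),
                  longitude = pmin(pmax(centers[, "longitude"] +
                    rnorm(length(ids), 0, coord_sd), -180), 180))
  rownames(coords) <- ids
  names(subl) <- ids; names(supl) <- ids
  m <- filter_richness(site_matrix(inc, coords), min_richness)
  list(matrix = m, sub_labels = subl[site_ids(m)],
       super_labels = supl[site_ids(m)])
}

#' Write a synthetic world in the package's occurrence/site file formats
#'
#' Emits the long-form occurrence table and the site coordinate table that
#' [read_occurrences()] and [read_sites()] read, so generated data
#' round-trips through the ingestion path.
#'
#' @param x a [site_matrix()].
#' @param occ_path,site_path output paths.
#' @param epoch epoch label to write (default the matrix's own).
#' @param domesticates taxon names to flag as domesticates.
#' @return invisible list of the two paths.
#' @export
write_synthetic_files <- function(x, occ_path, site_path,
                                  epoch = NULL, domesticates = character(0)) {
  stopifnot(inherits(x, "site_matrix"))
  epoch <- epoch %||% if (is.na(x$epoch)) "holocene" else x$epoch
  idx <- which(x$incidence == 1L, arr.ind = TRUE)
  occ <- data.frame(site_id = site_ids(x)[idx[, 1L]],
                    taxon = taxon_ids(x)[idx[, 2L]],
                    rank = "species", epoch = epoch, nisp = 1L,
                    stringsAsFactors = FALSE)
  occ$is_domesticate <- occ$taxon %in% domesticates
  occ <- occ[lex_order(occ$site_id, occ$taxon), , drop = FALSE]
  utils::write.table(occ, occ_path, sep = ",", row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  sites <- data.frame(site_id = site_ids(x), name = site_ids(x),
                      latitude = x$coords[, "latitude"],
                      longitude = x$coords[, "longitude"], epoch = epoch,
                      stringsAsFactors = FALSE)
  utils::write.table(sites, site_path, sep = ",", row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(list(occurrences = occ_path, sites = site_path))
}
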