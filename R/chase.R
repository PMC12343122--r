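#' Control parameters for chase clustering
#'
#' @param n_starts independent random starts per requested k (default 250).
#' @param n_shuffles stochastic shuffle proposals per start (default 10000).
#' @param singleton_penalty objective deduction per one-site cluster
#'   (default 5, larger than any plausible single pair term, so singletons
#'   survive only when every merge is strongly negative).
#' @param anneal_t0 initial temperature for Metropolis acceptance with
#'   geometric cooling; 0 gives pure greedy hill-climbing. The deepest
#'   objective barrier on any merge path is a transient singleton: its cost
#'   is the singleton penalty minus the pair terms regained when the lone
#'   site re-attaches, so a starting temperature somewhat below the penalty
#'   (default 3 against a penalty of 5) lets runs cross it early while
#'   preserving the seeded structure; greedy search cannot cross it at all
#'   and stalls at too-fine partitions.
#' @param anneal_decay per-step temperature decay factor in (0, 1).
#' @param seed_similarity_cap maximum similarity a candidate seed may have
#'   to an already-chosen seed (relaxed in +0.1 steps when no candidate
#'   qualifies), keeping seeds compositionally distinct.
#' @param pair_form `"sum"` (default) scores each cluster by the sum of its
#'   within-cluster pair terms `S + gamma`; `"mean"` uses the mean pair
#'   similarity plus gamma instead.
#' @return a list of class `chase_control`.
#' @export
chase_control <- function(n_starts = 250L, n_shuffles = 10000L,
                          singleton_penalty = 5, anneal_t0 = 3,
                          anneal_decay = 0.995,
                          seed_similarity_cap = 0.5,
                          pair_form = c("sum", "mean")) {
  pair_form <- match.arg(pair_form)
  n_starts <- as.integer(n_starts)
  n_shuffles <- as.integer(n_shuffles)
  stopifnot(n_starts >= 1L, n_shuffles >= 1L, singleton_penalty > 0,
            anneal_t0 >= 0, anneal_decay > 0, anneal_decay < 1,
            seed_similarity_cap >= 0, seed_similarity_cap <= 1)
  structure(list(n_starts = n_starts, n_shuffles = n_shuffles,
                 singleton_penalty = singleton_penalty,
                 anneal_t0 = anneal_t0, anneal_decay = anneal_decay,
                 seed_similarity_cap = seed_similarity_cap,
                 pair_form = pair_form),
            class = "chase_control")
}

#' Penalized coherence objective of a partition
#'
#' The quantity chase clustering maximizes:
#' \deqn{F(P) = \sum_{c} \sum_{\{i,j\} \subseteq c} (S_{ij} + \gamma)
#'       - \rho \cdot \#\{c : |c| = 1\}}
#' where the inner sum runs over unordered within-cluster site pairs, gamma
#' (<= 0) is the regularization added to each pair term and rho is the
#' singleton penalty. More negative gamma makes weakly overlapping pairs
#' costly to keep together, so the optimal number of clusters grows as
#' gamma decreases. With `pair_form = "mean"` the per-cluster sum is
#' replaced by the mean pair similarity plus gamma.
#'
#' @param labels integer cluster labels (1-based), one per site, aligned
#'   with the rows of `S`.
#' @param S a [chase_matrix()] (or any symmetric similarity matrix).
#' @param gamma pair regularization, typically in \[-0.5, 0\].
#' @param singleton_penalty deduction per single-site cluster.
#' @param pair_form `"sum"` or `"mean"` (see [chase_control()]).
#' @return the objective value (higher is better).
#' @export
chase_objective <- function(labels, S, gamma = -0.1, singleton_penalty = 5,
                            pair_form = c("sum", "mean")) {
  pair_form <- match.arg(pair_form)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(S), !anyNA(labels))
  F <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    m <- length(idx)
    if (m == 1L) {
      F <- F - singleton_penalty
    } else {
      ps <- (sum(S[idx, idx]) - m) / 2  # unit diagonal removed
      np <- m * (m - 1) / 2
      F <- F + if (pair_form == "sum") ps + gamma * np else ps / np + gamma
    }
  }
  F
}

#' Incremental objective change for moving one site
#'
#' Exact change in [chase_objective()] when site `i` moves from its current
#' cluster to `target`, computed locally (only the two affected clusters
#' are touched). Equals the difference of full recomputations.
#'
#' @inheritParams chase_objective
#' @param i site index to move.
#' @param target destination cluster label.
#' @return the objective change `F(after) - F(before)`.
#' @export
chase_move_delta <- function(labels, i, target, S, gamma = -0.1,
                             singleton_penalty = 5,
                             pair_form = c("sum", "mean")) {
  pair_form <- match.arg(pair_form)
  labels <- as.integer(labels)
  a <- labels[i]; b <- as.integer(target)
  if (a == b) return(0)
  term <- function(idx) {
    m <- length(idx)
    if (m == 0L) return(0)
    if (m == 1L) return(-singleton_penalty)
    ps <- (sum(S[idx, idx]) - m) / 2
    np <- m * (m - 1) / 2
    if (pair_form == "sum") ps + gamma * np else ps / np + gamma
  }
  ia <- which(labels == a); ib <- which(labels == b)
  term(setdiff(ia, i)) + term(c(ib, i)) - term(ia) - term(ib)
}

#' Seed a partition from richness-weighted, compositionally distinct sites
#'
#' Draws k seed sites sequentially with probability proportional to species
#' richness, rejecting any candidate whose similarity to an already-chosen
#' seed exceeds `cap` (the cap is relaxed in +0.1 steps when no candidate
#' qualifies, and resets for each seed). Every remaining site is then
#' "chased" into the seed cluster it most resembles (ties go to the lowest
#' cluster index). Reproducible given the RNG state.
#'
#' @param S similarity matrix ([chase_matrix()]).
#' @param richness per-site richness weights (positive), aligned with `S`.
#' @param k number of seed clusters; must not exceed the number of sites.
#' @param cap seed similarity cap (see [chase_control()]).
#' @return integer labels in `1..k`.
#' @export
seed_partition <- function(S, richness, k, cap = 0.5) {
  n <- nrow(S)
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds the number of sites (", n, ")")
  stopifnot(length(richness) == n, all(richness > 0))
  seeds <- integer(0)
  avail <- seq_len(n)
  for (s in seq_len(k)) {
    cc <- cap
    repeat {
      ok <- if (length(seeds) == 0L) avail
            else avail[apply(S[avail, seeds, drop = FALSE], 1L, max) <= cc]
      if (length(ok) > 0L) break
      cc <- cc + 0.1
    }
    pick <- if (length(ok) == 1L) ok
            else ok[sample.int(length(ok), 1L, prob = richness[ok])]
    seeds <- c(seeds, pick)
    avail <- setdiff(avail, pick)
  }
  labels <- integer(n)
  labels[seeds] <- seq_len(k)
  if (length(avail))
    labels[avail] <- apply(S[avail, seeds, drop = FALSE], 1L, which.max)
  labels
}

#' One optimization run: stochastic shuffling from a starting partition
#'
#' Performs `n_shuffles` single-site move proposals (uniform site, uniform
#' target among the alive clusters plus at most one dormant cluster),
#' accepting improvements (and, when `anneal_t0 > 0`, occasional
#' deteriorations with Metropolis probability under geometric cooling).
#' Clusters may empty and die. The best labelling ever visited is
#' returned, so the result never scores below the start.
#'
#' @inheritParams seed_partition
#' @param labels0 starting labels in `1..k`.
#' @param gamma pair regularization.
#' @param control a [chase_control()].
#' @return list with `labels` (best visited), `objective`, and `accepted`
#'   (number of accepted moves).
#' @export
optimize_partition <- function(S, labels0, k, gamma = -0.1,
                               control = chase_control()) {
  res <- chase_optimize_cpp(S = unclass(S), labels0 = as.integer(labels0),
                            k = as.integer(k),
                            n_shuffles = control$n_shuffles,
                            gamma = gamma,
                            penalty = control$singleton_penalty,
                            t0 = control$anneal_t0,
                            decay = control$anneal_decay,
                            mean_form = control$pair_form == "mean")
  res[c("labels", "objective", "accepted")]
}

# Relabel so clusters are numbered by decreasing size, ties by the
# lexicographically smallest member site id; labels become 1..k_effective.
canonicalize_labels <- function(labels, site_ids) {
  labels <- as.integer(labels)
  cl <- unique(labels)
  sizes <- vapply(cl, function(c) sum(labels == c), integer(1))
  firsts <- vapply(cl, function(c) min(sort(site_ids[labels == c],
                                            method = "radix")), character(1))
  ord <- order(-sizes, firsts, method = "radix")
  out <- match(labels, cl[ord])
  names(out) <- site_ids
  out
}

# Independent substream seed per (gamma, k, start) so results do not depend
# on loop execution order; kept below 2^31.
substream_seed <- function(seed, k, start, gamma = 0) {
  g <- as.integer(round(abs(gamma) * 1000))
  as.integer((as.double(seed) * 2654435761 + k * 1000003 + start * 7919 +
                g * 104729) %% 2147483629)
}

#' Chase clustering of a site-by-species incidence matrix
#'
#' Fits the unconstrained "chase" clustering model: partitions sites by
#' compositional similarity alone, with the number of clusters inferred
#' endogenously. For each requested k in `k_min..k_max`, `n_starts`
#' independent runs are launched, each seeding k clusters from
#' richness-weighted, compositionally distinct sites, chasing the remaining
#' sites into their most similar cluster, and then stochastically shuffling
#' assignments to maximize the penalized coherence objective
#' [chase_objective()]. Clusters can empty during shuffling, so the
#' effective number of clusters is data-driven. The global best partition
#' across all k is returned (ties broken toward fewer effective clusters,
#' then smaller requested k), with per-site stability measured across the
#' random starts at the winning k.
#'
#' @param x a [site_matrix()] (a [chase_matrix()] is also accepted if
#'   `richness` is supplied).
#' @param gamma pair regularization in \[-0.5, 0\]; more negative values
#'   yield more clusters. Default -0.1.
#' @param k_min,k_max range of requested cluster numbers (defaults 2 and
#'   15).
#' @param seed integer seed; every random draw flows from it through
#'   per-(k, start) substreams, so results are fully reproducible.
#' @param metric similarity metric for the chase matrix (when `x` is a
#'   `site_matrix`).
#' @param control a [chase_control()].
#' @param richness per-site richness weights, required only when `x` is
#'   already a similarity matrix.
#' @return an object of class `chase` with components `best` (labels,
#'   `k_effective`, `objective`, `k_requested`), `per_k` (one row per
#'   requested k), `runs` (canonical labels per start at the winning k),
#'   `stability` (per-site fraction of runs agreeing with the best
#'   partition), `consistent_fraction` (share of sites with stability >=
#'   0.9), plus the settings used.
#' @seealso [sweep_gamma()], [ward_geo()], [adjusted_rand_index()]
#' @export
#' @examples
#' syn <- simulate_sites(synth_config(n_regions = 3, sites_per_region = 6,
#'                                    species_per_region = 25), seed = 42)
#' fit <- chase(syn$matrix, gamma = -0.1, k_max = 6, seed = 1,
#'              control = chase_control(n_starts = 20, n_shuffles = 1000))
#' fit
#' adjusted_rand_index(fit$best$labels, syn$true_labels)
chase <- function(x, gamma = -0.1, k_min = 2L, k_max = 15L, seed = 1L,
                  metric = c("jaccard", "simpson", "ochiai"),
                  control = chase_control(), richness = NULL) {
  cl <- match.call()
  metric <- match.arg(metric)
  stopifnot(gamma <= 0, gamma >= -0.5)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  stopifnot(k_min >= 2L, k_max >= k_min)
  if (inherits(x, "site_matrix")) {
    S <- chase_matrix(x, metric)
    rich <- richness(x)
  } else {
    S <- x
    metric <- attr(S, "metric") %||% metric
    if (is.null(richness)) stop("richness weights required when x is a similarity matrix")
    rich <- richness
  }
  n <- nrow(S)
  ids <- rownames(S)
  if (n < k_min) stop("need at least k_min = ", k_min, " sites, have ", n)
  k_max <- min(k_max, n)

  per_k <- data.frame(k_requested = k_min:k_max, objective = -Inf,
                      k_effective = NA_integer_)
  best <- NULL
  runs_by_k <- vector("list", k_max - k_min + 1L)
  Sm <- unclass(S)

  for (ki in seq_len(nrow(per_k))) {
    k <- per_k$k_requested[ki]
    run_labels <- matrix(NA_integer_, n, control$n_starts,
                         dimnames = list(ids, NULL))
    run_obj <- numeric(control$n_starts)
    for (s in seq_len(control$n_starts)) {
      set.seed(substream_seed(seed, k, s, gamma))
      p0 <- seed_partition(Sm, rich, k, control$seed_similarity_cap)
      opt <- optimize_partition(Sm, p0, k, gamma, control)
      run_labels[, s] <- canonicalize_labels(opt$labels, ids)
      run_obj[s] <- opt$objective
    }
    ib <- which.max(run_obj)
    per_k$objective[ki] <- run_obj[ib]
    per_k$k_effective[ki] <- max(run_labels[, ib])
    runs_by_k[[ki]] <- run_labels
    cand <- list(labels = run_labels[, ib], k_effective = per_k$k_effective[ki],
                 objective = run_obj[ib], k_requested = k)
    if (is.null(best) ||
        cand$objective > best$objective ||
        (cand$objective == best$objective &&
         (cand$k_effective < best$k_effective ||
          (cand$k_effective == best$k_effective &&
           cand$k_requested < best$k_requested))))
      best <- cand
  }

  runs <- runs_by_k[[match(best$k_requested, per_k$k_requested)]]
  st <- stability(runs, best$labels)
  structure(list(best = best, per_k = per_k, runs = runs,
                 stability = st$per_site,
                 consistent_fraction = st$consistent_fraction,
                 gamma = gamma, metric = metric, seed = seed,
                 control = control, n_sites = n, call = cl),
            class = "chase")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chase <- function(x, ...) {
  cat("Chase clustering\n")
  cat(sprintf("  %d sites, metric %s, gamma = %g\n", x$n_sites, x$metric,
              x$gamma))
  cat(sprintf("  selected k = %d (requested %d), objective = %.4f\n",
              x$best$k_effective, x$best$k_requested, x$best$objective))
  cat(sprintf("  cluster sizes: %s\n",
              paste(tabulate(x$best$labels), collapse = ", ")))
  cat(sprintf("  stability: %.1f%% of sites consistent (>= 0.9) across %d starts\n",
              100 * x$consistent_fraction, ncol(x$runs)))
  invisible(x)
}

#' @export
summary.chase <- function(object, ...) {
  structure(list(fit = object), class = "summary.chase")
}

#' @export
print.summary.chase <- function(x, ...) {
  print(x$fit)
  cat("\nObjective by requested k:\n")
  print(x$fit$per_k, row.names = FALSE)
  invisible(x)
}

#' @export
plot.chase <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  plot(x$per_k$k_requested, x$per_k$objective, type = "b", pch = 19,
       xlab = "requested k", ylab = "best objective",
       main = "Penalized coherence by k", ...)
  graphics::abline(v = x$best$k_requested, lty = 2, col = "grey40")
  graphics::hist(x$stability, breaks = seq(0, 1, 0.05),
                 xlab = "per-site stability", main = "Run-to-run stability")
  invisible(x)
}

#' Extract the cluster assignment table from a fit
#'
#' @param object a `chase` or `ward_geo` fit.
#' @return data frame with columns `site_id`, `cluster` and (for chase)
#'   `stability`.
#' @export
cluster_assignments <- function(object) {
  if (inherits(object, "chase"))
    return(data.frame(site_id = names(object$best$labels),
                      cluster = unname(object$best$labels),
                      stability = unname(object$stability),
                      stringsAsFactors = FALSE))
  if (inherits(object, "ward_geo"))
    return(data.frame(site_id = names(object$labels),
                      cluster = unname(object$labels),
                      stringsAsFactors = FALSE))
  stop("unsupported object")
}

#' Serialize a chase fit to JSON
#'
#' Writes the selected partition, the per-k summary, per-site stability
#' and the settings used to a single JSON document.
#'
#' @param fit a `chase` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chase_json <- function(fit, path) {
  stopifnot(inherits(fit, "chase"))
  doc <- list(
    gamma = fit$gamma, metric = fit$metric, seed = fit$seed,
    control = unclass(fit$control),
    selected = list(k_requested = fit$best$k_requested,
                    k_effective = fit$best$k_effective,
                    objective = fit$best$objective),
    per_k = fit$per_k,
    assignments = cluster_assignments(fit),
    consistent_fraction = fit$consistent_fraction)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Gamma sweep: cluster count response to regularization strength
#'
#' Re-runs [chase()] over a grid of gamma values and tabulates the selected
#' number of clusters. On data with nested compositional structure the
#' selected k grows as gamma becomes more negative, which is the usual way
#' to pick a gamma producing coherent but not fragmented clusters.
#'
#' @inheritParams chase
#' @param gammas numeric vector of gamma values (<= 0).
#' @param keep_fits keep the full `chase` objects (default `FALSE`).
#' @return data frame with columns `gamma`, `k_selected`, `k_requested`,
#'   `objective` (and attribute `"fits"` when `keep_fits`), ordered as
#'   given.
#' @export
sweep_gamma <- function(x, gammas, k_min = 2L, k_max = 15L, seed = 1L,
                        metric = c("jaccard", "simpson", "ochiai"),
                        control = chase_control(), keep_fits = FALSE) {
  if (length(gammas) == 0L) stop("gammas must be non-empty")
  metric <- match.arg(metric)
  fits <- lapply(gammas, function(g)
    chase(x, gamma = g, k_min = k_min, k_max = k_max, seed = seed,
          metric = metric, control = control))
  out <- data.frame(gamma = gammas,
                    k_selected = vapply(fits, function(f)
                      f$best$k_effective, integer(1)),
                    k_requested = vapply(fits, function(f)
                      f$best$k_requested, integer(1)),
                    objective = vapply(fits, function(f)
                      f$best$objective, numeric(1)))
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Per-site stability across repeated random-start runs
#'
#' Each run's clusters are matched one-to-one to the reference clusters by
#' maximizing total overlap on the contingency table (exact matching via
#' dynamic programming over cluster subsets). A site's stability is the
#' fraction of runs in which it lands in the cluster matched to its
#' reference cluster; the consistent fraction is the share of sites with
#' stability at least 0.9.
#'
#' @param runs matrix of labels (sites x runs) or list of label vectors,
#'   all covering the same sites as `reference`.
#' @param reference labels of the reference partition (named by site id
#'   when `runs` carries site names).
#' @return list with `per_site` (named numeric vector in \[0, 1\]) and
#'   `consistent_fraction`.
#' @export
stability <- function(runs, reference) {
  if (is.list(runs)) runs <- do.call(cbind, runs)
  runs <- as.matrix(runs)
  if (nrow(runs) != length(reference))
    stop("runs and reference cover different site sets")
  if (!is.null(rownames(runs)) && !is.null(names(reference))) {
    if (!setequal(rownames(runs), names(reference)))
      stop("runs and reference cover different site sets: ",
           paste(c(setdiff(rownames(runs), names(reference)),
                   setdiff(names(reference), rownames(runs))),
                 collapse = ", "))
    runs <- runs[names(reference), , drop = FALSE]
  }
  ref <- as.integer(factor(reference))
  hits <- matrix(FALSE, nrow(runs), ncol(runs))
  for (r in seq_len(ncol(runs))) {
    run <- as.integer(factor(runs[, r]))
    ct <- table(factor(ref, levels = seq_len(max(ref))),
                factor(run, levels = seq_len(max(run))))
    m <- match_clusters(ct)  # per ref-cluster matched run-cluster (or NA)
    hits[, r] <- !is.na(m[ref]) & m[ref] == run
  }
  per_site <- rowMeans(hits)
  names(per_site) <- names(reference)
  list(per_site = per_site, consistent_fraction = mean(per_site >= 0.9))
}

# Exact maximum-weight one-to-one matching of rows to columns of a
# non-negative count matrix, via subset dynamic programming over the
# smaller dimension (fine for k <= 15). Returns, per row, the matched
# column index or NA.
match_clusters <- function(C) {
  C <- as.matrix(C)
  transposed <- ncol(C) > nrow(C)
  if (transposed) C <- t(C)
  nr <- nrow(C); nc <- ncol(C)
  nmask <- bitwShiftL(1L, nc)
  masks <- 0:(nmask - 1L)
  dp <- rep(-Inf, nmask); dp[1L] <- 0
  choice <- matrix(0L, nmask, nr)  # 0 = row skipped
  for (r in seq_len(nr)) {
    new_dp <- dp  # skipping row r
    new_choice <- integer(nmask)
    for (j in seq_len(nc)) {
      bit <- bitwShiftL(1L, j - 1L)
      has <- bitwAnd(masks, bit) > 0L
      cand <- dp[masks[has] - bit + 1L] + C[r, j]
      better <- cand > new_dp[has]
      if (any(better)) {
        idx <- which(has)[better]
        new_dp[idx] <- cand[better]
        new_choice[idx] <- j
      }
    }
    dp <- new_dp
    choice[, r] <- new_choice
  }
  best_mask <- which.max(dp)
  assign_row <- rep(NA_integer_, nr)
  mask <- masks[best_mask]
  state <- best_mask
  for (r in rev(seq_len(nr))) {
    j <- choice[state, r]
    if (j > 0L) {
      assign_row[r] <- j
      bit <- bitwShiftL(1L, j - 1L)
      mask <- mask - bit
      state <- mask + 1L
    }
  }
  if (transposed) {
    out <- rep(NA_integer_, ncol(C))  # per original row (= column here)
    out[assign_row[!is.na(assign_row)]] <-
      which(!is.na(assign_row))
    out
  } else {
    assign_row
  }
}

#' Brute-force reference optimum for small instances
#'
#' Exhaustively enumerates every partition of the sites into at most
#' `max_blocks` non-empty clusters and returns the labelling with the
#' highest [chase_objective()]. Exponential in the number of sites; meant
#' as a verification reference for n <= 10.
#'
#' @inheritParams chase_objective
#' @param max_blocks maximum number of clusters to enumerate (default 3).
#' @return list with `labels` (canonical) and `objective`.
#' @export
exhaustive_chase <- function(S, gamma = -0.1, singleton_penalty = 5,
                             max_blocks = 3L, pair_form = c("sum", "mean")) {
  pair_form <- match.arg(pair_form)
  n <- nrow(S)
  if (n > 12L) stop("exhaustive enumeration is limited to n <= 12")
  best <- NULL
  # restricted-growth strings with at most max_blocks blocks
  rec <- function(lab, used) {
    pos <- length(lab) + 1L
    if (pos > n) {
      obj <- chase_objective(lab, S, gamma, singleton_penalty, pair_form)
      if (is.null(best) || obj > best$objective)
        best <<- list(labels = lab, objective = obj)
      return(invisible(NULL))
    }
    for (c in seq_len(min(used + 1L, max_blocks)))
      rec(c(lab, c), max(used, c))
    invisible(NULL)
  }
  rec(integer(0), 0L)
  best$labels <- canonicalize_labels(best$labels,
                                     rownames(S) %||% as.character(seq_len(n)))
  best
}
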