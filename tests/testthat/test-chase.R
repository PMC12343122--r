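two_site_S <- function(s) {
  S <- matrix(c(1, s, s, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  S
}

test_that("objective matches its stated formula on forced examples", {
  S <- two_site_S(0.5)
  expect_equal(chase_objective(c(1, 1), S, gamma = -0.1,
                               singleton_penalty = 5), 0.4)
  expect_equal(chase_objective(c(1, 2), S, gamma = -0.1,
                               singleton_penalty = 5), -10)
  # 4 sites, all pairwise S = 0.05: splitting into two pairs scores higher
  S4 <- matrix(0.05, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(S4) <- 1
  expect_equal(chase_objective(rep(1, 4), S4, -0.1, 5), 6 * -0.05)
  expect_equal(chase_objective(c(1, 1, 2, 2), S4, -0.1, 5), 2 * -0.05)
  expect_gt(chase_objective(c(1, 1, 2, 2), S4, -0.1, 5),
            chase_objective(rep(1, 4), S4, -0.1, 5))
})

test_that("objective is invariant under label permutation and matches the oracle", {
  set.seed(31)
  for (rep in 1:10) {
    m <- random_matrix(7, 12)
    S <- unclass(chase_matrix(m))
    lab <- sample.int(3, 7, replace = TRUE)
    perm <- sample.int(3)
    expect_equal(chase_objective(lab, S, -0.1, 5),
                 chase_objective(perm[lab], S, -0.1, 5))
    expect_equal(chase_objective(lab, S, -0.1, 5),
                 oracle_objective(lab, S, -0.1, 5))
  }
})

test_that("incremental move delta equals full recomputation", {
  set.seed(77)
  m <- random_matrix(10, 16)
  S <- unclass(chase_matrix(m))
  for (rep in 1:100) {
    lab <- sample.int(4, 10, replace = TRUE)
    i <- sample.int(10, 1)
    target <- sample.int(4, 1)
    full <- local({
      lab2 <- lab; lab2[i] <- target
      chase_objective(lab2, S, -0.1, 5) - chase_objective(lab, S, -0.1, 5)
    })
    expect_equal(chase_move_delta(lab, i, target, S, -0.1, 5), full,
                 tolerance = 1e-12)
  }
})

test_that("mean pair form agrees with a direct recomputation", {
  set.seed(13)
  m <- random_matrix(8, 14)
  S <- unclass(chase_matrix(m))
  lab <- sample.int(3, 8, replace = TRUE)
  direct <- 0
  for (c in unique(lab)) {
    idx <- which(lab == c)
    if (length(idx) == 1) direct <- direct - 5
    else {
      ps <- c()
      for (i in idx) for (j in idx) if (i < j) ps <- c(ps, S[i, j])
      direct <- direct + mean(ps) - 0.1
    }
  }
  expect_equal(chase_objective(lab, S, -0.1, 5, pair_form = "mean"), direct)
})

test_that("seeding respects richness weighting, distinctness cap and chase-in", {
  S <- unclass(chase_matrix(block_matrix(b = 2L, m = 3L)))
  rich <- rep(6, 6)
  # k = n: every site its own cluster
  set.seed(1)
  expect_equal(sort(seed_partition(S, rich, 6L)), 1:6)
  # two perfect blocks, k = 2: the seeded partition is the blocks for any seed
  for (s in 1:25) {
    set.seed(s)
    lab <- seed_partition(S, rich, 2L, cap = 0.5)
    expect_equal(length(unique(lab[1:3])), 1L)
    expect_equal(length(unique(lab[4:6])), 1L)
    expect_true(lab[1] != lab[4])
  }
  # compositionally identical sites are never both seeds before relaxation:
  # with cap 0.5 and two identical pairs, seeds land in different pairs
  S2 <- matrix(c(1, 1, 0, 0,
                 1, 1, 0, 0,
                 0, 0, 1, 1,
                 0, 0, 1, 1), 4, 4)
  dimnames(S2) <- list(letters[1:4], letters[1:4])
  for (s in 1:25) {
    set.seed(s)
    lab <- seed_partition(S2, rep(5, 4), 2L, cap = 0.5)
    expect_equal(lab[1], lab[2])
    expect_equal(lab[3], lab[4])
  }
  expect_error(seed_partition(S2, rep(5, 4), 9L), "exceeds")
})

test_that("optimizer keeps an already-optimal start and never degrades", {
  m <- block_matrix(b = 2L, m = 4L)
  S <- unclass(chase_matrix(m))
  lab0 <- rep(1:2, each = 4L)
  set.seed(9)
  opt <- optimize_partition(S, lab0, 2L, gamma = -0.1,
                            control = chase_control(n_shuffles = 2000))
  # same partition (up to cluster numbering), same objective
  expect_equal(adjusted_rand_index(opt$labels, lab0), 1)
  expect_equal(opt$objective, chase_objective(lab0, S, -0.1, 5),
               tolerance = 1e-10)
  # objective reported by the C++ path equals an R recomputation of its labels
  set.seed(10)
  mr <- random_matrix(9, 14)
  Sr <- unclass(chase_matrix(mr))
  lab <- seed_partition(Sr, richness(mr), 3L)
  o2 <- optimize_partition(Sr, lab, 3L, gamma = -0.15,
                           control = chase_control(n_shuffles = 3000))
  expect_equal(o2$objective, chase_objective(o2$labels, Sr, -0.15, 5),
               tolerance = 1e-10)
  expect_gte(o2$objective, chase_objective(lab, Sr, -0.15, 5) - 1e-10)
})

test_that("chase recovers planted blocks and selects k endogenously", {
  m <- block_matrix(b = 3L, m = 4L)
  fit <- chase(m, gamma = -0.1, k_min = 2L, k_max = 6L, seed = 5,
               control = chase_control(n_starts = 15, n_shuffles = 1500))
  expect_equal(fit$best$k_effective, 3L)
  truth <- rep(1:3, each = 4L)
  names(truth) <- site_ids(m)
  expect_equal(adjusted_rand_index(fit$best$labels, truth), 1)
  # canonical labels: cluster 1 contains the lexicographically first site
  expect_equal(unname(fit$best$labels[["s01"]]), 1L)
})

test_that("gamma = 0 collapses to the zero-similarity components", {
  # two connected components of positive similarity
  m <- block_matrix(b = 2L, m = 3L)
  fit <- chase(m, gamma = 0, k_min = 2L, k_max = 4L, seed = 2,
               control = chase_control(n_starts = 10, n_shuffles = 1000))
  expect_equal(fit$best$k_effective, 2L)
  # verified against exhaustive search on the same instance
  S <- unclass(chase_matrix(m))
  ex <- exhaustive_chase(S, gamma = 0, singleton_penalty = 5, max_blocks = 4L)
  expect_equal(fit$best$objective, ex$objective, tolerance = 1e-10)
})

test_that("same seed gives bit-identical results, different seeds may differ", {
  set.seed(1234)
  m <- random_matrix(12, 20)
  ctl <- chase_control(n_starts = 8, n_shuffles = 800)
  f1 <- chase(m, gamma = -0.12, k_max = 5L, seed = 99, control = ctl)
  f2 <- chase(m, gamma = -0.12, k_max = 5L, seed = 99, control = ctl)
  expect_identical(f1$best, f2$best)
  expect_identical(f1$per_k, f2$per_k)
  expect_identical(f1$stability, f2$stability)
})

test_that("stability matching hand cases", {
  ref <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 3L)
  runs_same <- matrix(rep(ref, 10), 5, 10, dimnames = list(names(ref), NULL))
  st <- stability(runs_same, ref)
  expect_equal(unname(st$per_site), rep(1, 5))
  expect_equal(st$consistent_fraction, 1)
  # label permutation is absorbed by the matching
  perm <- c(3L, 1L, 2L)
  runs_perm <- matrix(rep(perm[ref], 10), 5, 10,
                      dimnames = list(names(ref), NULL))
  expect_equal(unname(stability(runs_perm, ref)$per_site), rep(1, 5))
  # one site flips cluster in 3 of 10 runs -> stability 0.7 there
  runs_flip <- runs_same
  flipped <- ref; flipped["e"] <- 2L
  runs_flip[, 1:3] <- matrix(rep(flipped, 3), 5, 3)
  st2 <- stability(runs_flip, ref)
  expect_equal(unname(st2$per_site[["e"]]), 0.7)
  expect_equal(st2$consistent_fraction, 4 / 5)
  expect_error(stability(runs_same[1:4, ], ref), "different site sets")
})

test_that("cluster matching on contingency tables is the exact optimum", {
  # 3x3 table where greedy row-by-row matching is suboptimal
  C <- matrix(c(10, 9, 0,
                9, 0, 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  m <- chasecluster:::match_clusters(C)
  # optimal total = 9 + 9 + 1 = 19 (row1->col2, row2->col1, row3->col3),
  # beating greedy 10 + 0 + 1
  expect_equal(m, c(2L, 1L, 3L))
  # rectangular tables: every matched column distinct
  set.seed(21)
  for (rep in 1:20) {
    C2 <- matrix(rpois(12, 3), sample(2:4, 1))
    m2 <- chasecluster:::match_clusters(C2)
    m2 <- m2[!is.na(m2)]
    expect_equal(anyDuplicated(m2), 0L)
  }
})

test_that("gamma sweep output is well-formed and errors on empty input", {
  m <- block_matrix(b = 2L, m = 3L)
  ctl <- chase_control(n_starts = 5, n_shuffles = 500)
  sw <- sweep_gamma(m, c(0, -0.2), k_max = 4L, seed = 3, control = ctl)
  expect_equal(nrow(sw), 2L)
  expect_named(sw, c("gamma", "k_selected", "k_requested", "objective"))
  expect_error(sweep_gamma(m, numeric(0)), "non-empty")
})

test_that("chase result serializes to JSON", {
  m <- block_matrix(b = 2L, m = 3L)
  fit <- chase(m, gamma = -0.1, k_max = 3L, seed = 1,
               control = chase_control(n_starts = 4, n_shuffles = 400))
  p <- tempfile(fileext = ".json")
  write_chase_json(fit, p)
  doc <- jsonlite::read_json(p)
  expect_equal(doc$selected$k_effective, fit$best$k_effective)
  expect_equal(length(doc$assignments), fit$n_sites)
})
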