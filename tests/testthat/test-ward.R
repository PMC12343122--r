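test_that("occupancy distance is the root symmetric difference", {
  inc <- matrix(c(1, 1, 1, 1, 0, 0,
                  1, 1, 0, 0, 1, 1,
                  1, 1, 1, 1, 0, 0), 3, 6, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), sprintf("t%d", 1:6)))
  xy <- cbind(latitude = 1:3, longitude = 1:3)
  rownames(xy) <- rownames(inc)
  D <- occupancy_distance(site_matrix(inc, xy))
  expect_equal(D["a", "c"], 0)        # identical rows
  expect_equal(D["a", "b"], 2)        # differ in exactly 4 taxa -> sqrt(4)
  set.seed(66)
  m <- random_matrix(5, 8)
  D5 <- occupancy_distance(m)
  for (i in 1:4) for (j in (i + 1):5) {
    sym <- sum(xor(m$incidence[i, ] == 1L, m$incidence[j, ] == 1L))
    expect_equal(D5[i, j], sqrt(sym))
  }
})

test_that("mixed dissimilarity interpolates normalized matrices", {
  D0 <- matrix(c(0, 2, 2, 0), 2, 2)
  D1 <- matrix(c(0, 500, 500, 0), 2, 2)
  expect_equal(mixed_dissimilarity(D0, D1, 0), D0 / 2)
  expect_equal(mixed_dissimilarity(D0, D1, 1), D1 / 500)
  # midpoint of normalized entries 0.2 and 0.6 is 0.4
  Da <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  Db <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  mid <- mixed_dissimilarity(Da, Db, 0.5, normalize = FALSE)
  expect_equal(mid[1, 2], 0.4)
  expect_error(mixed_dissimilarity(D0 * 0, D1, 0.5), "degenerate")
})

test_that("mixed dissimilarity is 1-Lipschitz in alpha entrywise", {
  set.seed(42)
  m <- random_matrix(6, 10)
  D0 <- occupancy_distance(m)
  D1 <- unclass(geo_matrix(m))
  alphas <- runif(10)
  for (i in 1:9) {
    A <- mixed_dissimilarity(D0, D1, alphas[i])
    B <- mixed_dissimilarity(D0, D1, alphas[i + 1])
    expect_lte(max(abs(A - B)), abs(alphas[i] - alphas[i + 1]) + 1e-12)
  }
})

test_that("ward merge heights match stats::hclust ward.D2 to 1e-9", {
  set.seed(17)
  for (rep in 1:10) {
    m <- random_matrix(6, 12)
    D <- occupancy_distance(m)
    mine <- ward_tree(D)
    ref <- hclust(as.dist(D), method = "ward.D2")
    expect_equal(mine$height, ref$height, tolerance = 1e-9)
    expect_true(all(diff(mine$height) >= -1e-12))  # monotone dendrogram
  }
})

test_that("ward tree handles forced merge orders and rejects bad input", {
  # two well-separated pairs: within-pair merges precede the cross merge
  D <- matrix(c(0, 1, 9, 9,
                1, 0, 9, 9,
                9, 9, 0, 1,
                9, 9, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- ward_tree(D)
  expect_equal(tr$height[1:2], c(1, 1))
  expect_equal(cut_ward(tr, 2L),
               setNames(c(1L, 1L, 2L, 2L), letters[1:4]))
  # 2 leaves merge at their distance (ward.D2 convention)
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_equal(ward_tree(D2)$height, 3)
  expect_error(ward_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("cut_ward spans k = 1 to n with canonical labels", {
  set.seed(23)
  m <- random_matrix(7, 11)
  tr <- ward_tree(occupancy_distance(m))
  expect_equal(unname(cut_ward(tr, 1L)), rep(1L, 7))
  expect_equal(sort(unname(cut_ward(tr, 7L))), 1:7)
  for (k in 2:6) {
    lab <- cut_ward(tr, k)
    expect_equal(length(unique(lab)), k)
    # agreement with stats::cutree up to relabelling
    ref <- cutree(as.hclust(tr), k = k)
    expect_equal(adjusted_rand_index(lab, ref[names(lab)]), 1)
  }
  expect_error(cut_ward(tr, 0L), "k must be")
})

test_that("explained inertia has its closed-form extremes and hand value", {
  set.seed(29)
  m <- random_matrix(6, 9)
  D <- occupancy_distance(m)
  expect_equal(explained_inertia(rep(1L, 6), D), 0)
  expect_equal(explained_inertia(1:6, D), 1)
  # 4 points in two tight pairs, evaluated by hand from the 6 distances
  Dp <- matrix(c(0, 1, 10, 10,
                 1, 0, 10, 10,
                 10, 10, 0, 1,
                 10, 10, 1, 0), 4, 4)
  tot <- sum(Dp[upper.tri(Dp)]^2) / 4
  expect_equal(explained_inertia(c(1, 1, 2, 2), Dp), 1 - (0.5 + 0.5) / tot)
  # Q non-decreasing in k along the cut sequence
  tr <- ward_tree(D)
  q <- vapply(1:6, function(k) explained_inertia(cut_ward(tr, k), D),
              numeric(1))
  expect_true(all(diff(q) >= -1e-12))
})

test_that("alpha selection ties break to 0 and the grid has 101 points", {
  m <- block_matrix(b = 2L, m = 3L)
  D0 <- occupancy_distance(m)
  # force geography identical to composition: selection curve is flat
  fit <- ward_geo(m, k = 2L, alpha = "auto", alpha_grid_step = 0.25)
  expect_true(fit$alpha %in% seq(0, 1, 0.25))
  full <- ward_geo(m, k = 2L, alpha = "auto")
  expect_equal(nrow(full$curve), 101L)
})

test_that("concordant fixture: blocks recovered at every alpha", {
  m <- block_matrix(b = 3L, m = 4L)
  truth <- setNames(rep(1:3, each = 4L), site_ids(m))
  for (a in seq(0, 1, 0.2)) {
    fit <- ward_geo(m, k = 3L, alpha = a)
    expect_equal(adjusted_rand_index(fit$labels, truth), 1)
  }
  auto <- ward_geo(m, k = 3L)
  expect_equal(adjusted_rand_index(auto$labels, truth), 1)
})
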