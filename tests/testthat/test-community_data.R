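test_that("occurrence reader parses valid rows and applies defaults", {
  p <- write_occ_fixture(c(
    "site_id,taxon,rank,epoch,nisp,is_domesticate",
    "A,Bos taurus,species,holocene,12,true",
    "A,Canis lupus,,holocene,3,false",
    "B,Cervus elaphus,species,Pleistocene,1,"))
  occ <- read_occurrences(p)
  expect_equal(nrow(occ), 3L)
  expect_equal(occ$rank[2], "species")      # absent rank defaults to species
  expect_equal(occ$epoch[3], "pleistocene") # case-insensitive epoch
  expect_true(occ$is_domesticate[1])
  expect_false(occ$is_domesticate[3])
})

test_that("invalid rows are dropped with line-number diagnostics", {
  p <- write_occ_fixture(c(
    "site_id,taxon,rank,epoch,nisp",
    "A,Bos taurus,species,holocene,0",
    "A,Canis lupus,species,holocene,4",
    "B,Felis,genus,eocene,2"))
  expect_warning(occ <- read_occurrences(p), "line")
  expect_equal(nrow(occ), 1L)
  probs <- attr(occ, "problems")
  expect_equal(probs$line, c(2L, 4L))  # header is line 1
  expect_match(probs$reason[1], "nisp")
})

test_that("reader errors on missing mandatory column and empty file", {
  p <- write_occ_fixture(c("site_id,rank,epoch", "A,species,holocene"))
  expect_error(read_occurrences(p), "taxon")
  expect_error(read_occurrences(write_occ_fixture(character(0))), "empty")
})

test_that("minimum-unique rule removes genus records subsumed per site", {
  occ <- data.frame(
    site_id = c("A", "A", "B"),
    taxon = c("Bos", "Bos taurus", "Bos"),
    rank = c("genus", "species", "genus"),
    epoch = "holocene", stringsAsFactors = FALSE)
  red <- reduce_min_unique(occ)
  # site A: genus Bos subsumed by Bos taurus; site B keeps its lone genus
  expect_setequal(red$taxon[red$site_id == "A"], "Bos taurus")
  expect_setequal(red$taxon[red$site_id == "B"], "Bos")
  # order-independence and no species-rank removals
  red2 <- reduce_min_unique(occ[c(3, 2, 1), ])
  expect_equal(red, red2)
  expect_equal(sum(red$rank == "species"), sum(occ$rank == "species"))
})

test_that("family and unranked records pass through unchanged", {
  occ <- data.frame(site_id = "A", taxon = c("Bovidae", "Bos taurus"),
                    rank = c("family", "species"), epoch = "holocene",
                    stringsAsFactors = FALSE)
  expect_message(red <- reduce_min_unique(occ), "family/unranked")
  expect_equal(nrow(red), 2L)
})

test_that("build_matrix reduces counts to presence and drops empty taxa", {
  occ <- data.frame(
    site_id = c("A", "A", "B", "B", "A"),
    taxon = c("x", "y", "x", "y", "z"),
    epoch = c(rep("holocene", 4), "pleistocene"),
    nisp = c(500L, 1L, 2L, 3L, 9L), stringsAsFactors = FALSE)
  sites <- data.frame(site_id = c("A", "B", "A"), latitude = c(0, 1, 0),
                      longitude = c(0, 1, 0),
                      epoch = c("holocene", "holocene", "pleistocene"))
  m <- build_matrix(occ, sites, "holocene")
  expect_equal(dim(m$incidence), c(2L, 2L))
  expect_true(all(m$incidence == 1L))      # nisp 500 and 1 contribute equally
  expect_false("z" %in% taxon_ids(m))      # zero-occurrence taxon dropped
  # record order never matters
  m2 <- build_matrix(occ[sample.int(5), ], sites, "holocene")
  expect_identical(m$incidence, m2$incidence)
})

test_that("build_matrix enforces referential integrity", {
  occ <- data.frame(site_id = "ghost", taxon = "x", epoch = "holocene")
  sites <- data.frame(site_id = "A", latitude = 0, longitude = 0,
                      epoch = "holocene")
  expect_error(build_matrix(occ, sites, "holocene"), "ghost")
})

test_that("richness filter drops below-minimum sites, keeps boundary, idempotent", {
  inc <- matrix(0L, 3, 6, dimnames = list(c("poor", "edge", "rich"),
                                          sprintf("t%d", 1:6)))
  inc["poor", 1:4] <- 1L   # 4 species: below the default minimum of 5
  inc["edge", 1:5] <- 1L   # exactly 5: retained
  inc["rich", 1:6] <- 1L
  xy <- cbind(latitude = c(0, 1, 2), longitude = c(0, 1, 2))
  rownames(xy) <- rownames(inc)
  m <- site_matrix(inc, xy)
  f <- filter_richness(m, 5L)
  expect_setequal(site_ids(f), c("edge", "rich"))
  expect_identical(filter_richness(f, 5L)$incidence, f$incidence)
  expect_error(filter_richness(m, 10L), "every site")
})

test_that("domesticate split removes columns then re-filters richness", {
  inc <- matrix(0L, 2, 7,
                dimnames = list(c("farm", "wildsite"),
                                c(sprintf("dom%d", 1:5), "w1", "w2")))
  inc["farm", 1:5] <- 1L                # only domesticates: 5 species
  inc["wildsite", ] <- 1L               # everything: 7 species
  xy <- cbind(latitude = c(0, 1), longitude = c(0, 1))
  rownames(xy) <- rownames(inc)
  m <- site_matrix(inc, xy)
  expect_warning(sp <- split_domesticates(m, c(sprintf("dom%d", 1:5), "unseen"),
                                          min_richness = 2L), "unseen")
  expect_identical(sp$all$incidence, m$incidence)
  # farm site loses all its species and is dropped by the re-applied filter
  expect_setequal(site_ids(sp$wild), "wildsite")
  expect_setequal(taxon_ids(sp$wild), c("w1", "w2"))
  # empty domesticate set leaves the matrix unchanged
  sp0 <- split_domesticates(m, character(0), min_richness = 2L)
  expect_identical(sp0$wild$incidence, m$incidence)
})

test_that("wide incidence table round-trips", {
  set.seed(11)
  m <- random_matrix(6, 10)
  p <- tempfile(fileext = ".csv")
  write_incidence(m, p)
  sites <- data.frame(site_id = site_ids(m),
                      latitude = m$coords[, "latitude"],
                      longitude = m$coords[, "longitude"],
                      epoch = "holocene")
  m2 <- read_incidence(p, sites)
  expect_identical(m$incidence, m2$incidence)
  expect_equal(m$coords, m2$coords)
})
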