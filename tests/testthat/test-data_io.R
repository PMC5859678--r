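test_that("datasets are constructed, counted and sorted correctly", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cluster,case,y", "2,1,4", "1,2,2", "2,2,6", "1,1,0"), tf)
  ds <- read_dataset(tf)
  expect_equal(ds$N, 4)
  expect_equal(ds$G, 2)
  expect_equal(ds$p, 1)
  # sorted ascending by cluster then case
  expect_equal(ds$cluster_id, c("1", "1", "2", "2"))
  expect_equal(unname(ds$values[, "y"]), c(0, 2, 4, 6))

  # shuffled input gives an identical dataset to sorted input
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cluster,case,y", "1,1,0", "1,2,2", "2,1,4", "2,2,6"), tf2)
  expect_equal(read_dataset(tf2), ds)
})

test_that("sorting preserves the multiset of rows", {
  set.seed(1)
  vals <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  cl <- sample(letters[1:4], 15, replace = TRUE)
  cl[1:2] <- c("a", "b")              # guarantee two clusters
  ds <- multilevel_dataset(vals, cl)
  expect_equal(sort(ds$values[, "a"]), sort(vals[, "a"]))
  expect_equal(unname(sort(table(ds$cluster_id))), unname(sort(table(cl))))
})

test_that("singleton clusters are accepted and decomposable", {
  ds <- multilevel_dataset(cbind(y = c(1, 2, 3, 9)),
                           cluster_id = c("a", "a", "a", "b"))
  expect_equal(unname(ds$n_g), c(3, 1))
  dec <- compute_decomposition(ds)   # N - G = 2 > 0
  expect_true(is.finite(dec$S_PW[1, 1]))
  # additivity still holds with a singleton cluster
  expect_equal((ds$N - 1) * dec$S_T,
               (ds$N - ds$G) * dec$S_PW + (ds$G - 1) * dec$S_B,
               tolerance = 1e-10)
})

test_that("malformed input is rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cl,case,y", "1,1,0", "2,1,1"), tf)
  expect_error(read_dataset(tf, cluster_col = "cluster"), "not found")

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cluster,case,y", "1,1,0", "1,2,oops", "2,1,1"), tf2)
  expect_error(read_dataset(tf2), "oops.*column 'y'.*row 2")

  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cluster,case,y", "1,1,0", "1,2,2"), tf3)
  expect_error(read_dataset(tf3), "2 distinct clusters")

  expect_error(multilevel_dataset(cbind(a = 1:4, a = 5:8),
                                  rep(1:2, each = 2)),
               "unique")
})

test_that("write/read round trip reproduces values bit for bit", {
  ds <- random_dataset(5, p = 3, G = 6, balanced = FALSE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  # write full precision: values already finite doubles
  write_dataset(ds, tf)
  ds2 <- read_dataset(tf)
  expect_equal(ds2$values, ds$values, tolerance = 1e-12)
  expect_identical(ds2$cluster_id, ds$cluster_id)
  expect_identical(ds2$case_id, ds$case_id)
})

test_that("missing-data policies count and filter as documented", {
  vals <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  cl <- rep(1:2, each = 4)
  ds0 <- multilevel_dataset(vals, cl)
  # no missing cells: both policies return the data unchanged
  expect_equal(apply_missing_policy(ds0, "listwise"), ds0)
  expect_equal(apply_missing_policy(ds0, "pairwise")$values, ds0$values)

  vals[3, 2] <- -999999            # one missing cell in indicator b
  ds1 <- multilevel_dataset(vals, cl)
  lw <- apply_missing_policy(ds1, "listwise")
  expect_equal(lw$N, 7)
  pw <- apply_missing_policy(ds1, "pairwise")
  pn <- attr(pw, "pairwise_n")
  expect_equal(pn["a", "b"], 7)
  expect_equal(pn["b", "c"], 7)
  expect_equal(pn["b", "b"], 7)
  expect_equal(pn["a", "c"], 8)    # pairs not involving b keep N
  expect_equal(attr(pw, "effective_n"), 7)

  # a cluster losing all rows under listwise triggers a warning
  vals2 <- rbind(vals, matrix(rnorm(12), 4, 3))
  vals2[9:12, 1] <- -999999
  ds2 <- multilevel_dataset(vals2, c(cl, rep(3, 4)))
  expect_warning(lw2 <- apply_missing_policy(ds2, "listwise"),
                 "removed entirely")
  expect_equal(lw2$G, 2)
  # an indicator with no observed values is an error
  vals3 <- vals
  vals3[, 3] <- -999999
  expect_error(apply_missing_policy(multilevel_dataset(vals3, cl)),
               "all rows missing")
})

test_that("pairwise decomposition uses pairwise-complete entries", {
  ds <- random_dataset(9, p = 3, G = 10)
  vals <- ds$values
  vals[2, 1] <- NA
  dsm <- multilevel_dataset(vals, ds$cluster_id, ds$case_id)
  expect_error(compute_decomposition(dsm), "apply_missing_policy")
  pw <- apply_missing_policy(dsm, "pairwise")
  dec <- compute_decomposition(pw)
  # entries not involving the incomplete indicator match the full-data ones
  full <- compute_decomposition(ds)
  expect_equal(dec$S_PW[2:3, 2:3], full$S_PW[2:3, 2:3], tolerance = 1e-12)
  expect_equal(dec$N, nrow(vals) - 1)  # minimum pairwise count
})
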