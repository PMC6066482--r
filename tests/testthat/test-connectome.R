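make_evd <- function(dense, grid = c(3, 3, 3), edge = "a--b") {
  rownames(dense) <- sprintf("S%03d", seq_len(nrow(dense)))
  as_edge_voxel_data(edge, dense, grid)
}

test_that("streamline region is empty for all-zero maps", {
  d <- matrix(0, 5, 27)
  reg <- define_streamline_region(make_evd(d), 0.05)
  expect_length(reg$mask, 0)
})

test_that("region recovers exactly a planted block, matching the closed-form t", {
  set.seed(3)
  n <- 20
  block <- c(5, 6)
  d <- matrix(0, n, 27)
  d[, block] <- rnorm(n * 2, mean = 5, sd = 1)
  d <- abs(d)
  reg <- define_streamline_region(make_evd(d), 0.05)
  expect_equal(reg$mask, block)
  # per-voxel closed-form oracle t = mean / (sd / sqrt(n))
  for (v in block) {
    t_or <- mean(d[, v]) / (sd(d[, v]) / sqrt(n))
    expect_lt(pt(t_or, n - 1, lower.tail = FALSE), 0.05)
  }
})

test_that("zero-variance voxels follow the limiting t rule", {
  d <- matrix(0, 6, 27)
  d[, 4] <- 0.7                      # constant positive -> included
  reg <- define_streamline_region(make_evd(d), 0.05)
  expect_equal(reg$mask, 4L)         # constant-zero voxels excluded
})

test_that("region definition needs >= 2 subjects", {
  d <- matrix(1, 1, 27)
  expect_error(define_streamline_region(make_evd(d)), "2 subjects")
})

test_that("region estimation is invariant to subject order", {
  set.seed(9)
  d <- matrix(rexp(10 * 27), 10, 27)
  evd <- make_evd(d)
  ids <- rownames(evd$values)
  r1 <- define_streamline_region(evd, 0.05, subjects = ids)
  r2 <- define_streamline_region(evd, 0.05, subjects = rev(ids))
  expect_equal(r1$mask, r2$mask)
})

test_that("edge strength is the mean FA over the mask", {
  reg <- structure(list(edge = "a--b", group = NA, mask = c(2L, 5L, 9L),
                        grid_shape = c(3L, 3L, 3L)),
                   class = "streamline_region")
  fa <- rep(0.5, 27)
  expect_equal(edge_strength(fa, reg), 0.5)
  fa[c(2, 5, 9)] <- c(0.2, 0.4, 0.6)
  expect_equal(edge_strength(fa, reg), 0.4)
})

test_that("edge strength equals a brute-force re-summation on random data", {
  set.seed(4)
  fa <- runif(64)
  mask <- sort(sample(64, 10))
  reg <- structure(list(edge = "a--b", group = NA, mask = mask,
                        grid_shape = c(4L, 4L, 4L)),
                   class = "streamline_region")
  brute <- sum(vapply(mask, function(v) fa[v], numeric(1))) / length(mask)
  expect_equal(edge_strength(fa, reg), brute)
})

test_that("empty region gives a flagged NA, never a silent zero", {
  reg <- structure(list(edge = "a--b", group = NA, mask = integer(0),
                        grid_shape = c(3L, 3L, 3L)),
                   class = "streamline_region")
  s <- edge_strength(runif(27), reg)
  expect_true(is.na(s))
  expect_true(attr(s, "undefined"))
})

test_that("strengths are invariant to voxels outside the region", {
  set.seed(5)
  cfg <- small_config(n_per_group = 5, n_edges = 1, seed = 2)
  co <- simulate_cohort(cfg)
  conn1 <- build_connectivity(co$voxel_data[1:3], co$fa, co$subjects)
  fa2 <- co$fa
  outside <- setdiff(seq_len(ncol(fa2)),
                     unlist(co$truth$regions[names(co$voxel_data)[1:3]]))
  fa2[, sample(outside, 50)] <- runif(50 * nrow(fa2))
  conn2 <- build_connectivity(co$voxel_data[1:3], fa2, co$subjects)
  expect_equal(conn1$strengths, conn2$strengths)
})

test_that("connectivity is deterministic and errors on missing subjects", {
  cfg <- small_config(n_per_group = 4, seed = 3)
  co <- simulate_cohort(cfg)
  vd <- co$voxel_data[1:5]
  c1 <- build_connectivity(vd, co$fa, co$subjects)
  c2 <- build_connectivity(vd, co$fa, co$subjects)
  expect_identical(c1$strengths, c2$strengths)
  expect_true(isSymmetric(conn_matrix(c1, co$subjects$id[1])))
  bad <- co$subjects
  bad$id[1] <- "S999"
  expect_error(build_connectivity(vd, co$fa, bad), "S999")
})

test_that("group and union region modes both score every subject", {
  cfg <- small_config(n_per_group = 6, seed = 8)
  co <- simulate_cohort(cfg)
  vd <- co$voxel_data[1:4]
  for (mode in c("group", "union")) {
    cc <- build_connectivity(vd, co$fa, co$subjects, region_mode = mode)
    expect_false(anyNA(cc$strengths))
  }
})

test_that("subnetwork means match a brute-force average and flag empty Diff", {
  cfg <- small_config(n_per_group = 5, seed = 4)
  co <- simulate_cohort(cfg)
  conn <- build_connectivity(co$voxel_data, co$fa, co$subjects)
  et <- atlas_edges(reward_atlas())
  diff_set <- sample(et$edge, 10)
  sm <- subnetwork_means(conn, reward_atlas(), diff_set)
  s1 <- conn$strengths[1, ]
  for (cl in c("Control", "Driving", "BTN")) {
    brute <- mean(s1[et$edge[et$class == cl]])
    expect_equal(sm[[cl]][1], brute)
  }
  expect_equal(sm$Diff[1], mean(s1[diff_set]))
  # singleton diff set
  sm1 <- subnetwork_means(conn, reward_atlas(), diff_set[1])
  expect_equal(sm1$Diff[1], unname(s1[diff_set[1]]))
  # empty -> flagged NA; unknown edge -> error
  expect_true(all(is.na(subnetwork_means(conn)$Diff)))
  expect_error(subnetwork_means(conn, reward_atlas(), "x--y"), "unknown")
})
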