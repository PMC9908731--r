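test_that("identity columns carry the proportions, split by year", {
  d <- tiny_data(rbind(c(0, 0, 1), c(0.5, 0, 0.5)), pool3, years = 2)
  X <- identity_columns(d, by_year = TRUE)
  expect_equal(ncol(X), 6L)
  # monoculture of species 3 -> third basis vector within its year block
  r <- which(d$plot == "t01" & d$year == 1)
  expect_equal(unname(X[r, ]), c(0, 0, 1, 0, 0, 0))
  # identity columns within each row's year sum to 1
  expect_equal(unname(rowSums(X)), rep(1, nrow(d)))
})

test_that("interaction structures match brute-force pair enumeration", {
  set.seed(71)
  pool <- pool9()
  P <- rbind(rand_simplex(6, 9), diag(9)[1, , drop = FALSE],
             matrix(1 / 9, 1, 9))
  d <- tiny_data(P, pool, years = 1)
  avg <- interaction_columns(d, "average")
  fg <- interaction_columns(d, "fg")
  add <- interaction_columns(d, "additive")
  full <- interaction_columns(d, "full")
  for (r in seq_len(nrow(P))) {
    bf <- brute_pair_sum(P[r, ])
    expect_equal(unname(avg[r, 1]), bf, tolerance = 1e-12)
    # FG columns partition the average column
    expect_equal(unname(sum(fg[r, ])), bf, tolerance = 1e-12)
    # full pairwise columns sum to the average column
    expect_equal(unname(sum(full[r, ])), bf, tolerance = 1e-12)
    # additive closed form P_i(1-P_i): columns sum to twice the pair sum
    expect_equal(unname(sum(add[r, ])), 2 * bf, tolerance = 1e-12)
  }
  # equal-proportion 9-species plot: average column = 36/81
  expect_equal(unname(avg[8, 1]), 36 / 81, tolerance = 1e-12)
  # monoculture rows are zero in every interaction column
  expect_true(all(avg[7, ] == 0) && all(fg[7, ] == 0) &&
                all(add[7, ] == 0) && all(full[7, ] == 0))
})

test_that("FG columns of a one-per-FG community isolate the cross pairs", {
  d <- space_design(seed = 5)
  pool <- attr(d, "pool")
  P <- prop_cols(d)[d$year == 1, ]
  r4 <- which(rowSums(P > 0) == 4)[1]
  row1 <- which(d$year == 1)[r4]
  fg <- interaction_columns(d, "fg")
  within <- grep("^within", colnames(fg))
  between <- grep("^between", colnames(fg))
  expect_equal(unname(fg[row1, within]), rep(0, 4))
  expect_equal(unname(fg[row1, between]), rep(1 / 16, 6), tolerance = 1e-12)
})

test_that("structure column spaces are nested identity < avg < fg < full", {
  set.seed(12)
  pool <- pool9()
  d <- tiny_data(rand_simplex(40, 9), pool, years = 1)
  blocks <- list(identity_columns(d, FALSE),
                 interaction_columns(d, "average"),
                 interaction_columns(d, "fg"),
                 interaction_columns(d, "full"))
  spaces <- Reduce(cbind, blocks, accumulate = TRUE)
  for (lvl in 2:4) {
    small <- spaces[[lvl - 1]]; big <- spaces[[lvl]]
    resid <- stats::lm.fit(big, small)$residuals
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("treatment crossing partitions columns by level and rejects bad rows", {
  pool <- pool3
  d <- tiny_data(rbind(c(0.5, 0, 0.5), c(0.5, 0.5, 0), c(1, 0, 0)), pool,
                 years = 2,
                 treatment = c("aggregated", "dispersed", "none"))
  B <- interaction_columns(d, "average")
  CB <- cross_with_treatment(B, d)
  expect_equal(ncol(CB), 2L)
  agg_rows <- d$treatment == "aggregated"
  # other level's copies are zero; copies sum back to the uncrossed column
  expect_true(all(CB[agg_rows, grep("dispersed", colnames(CB))] == 0))
  expect_equal(unname(rowSums(CB)), unname(B[, 1]))
  # monoculture rows are zero in all copies
  expect_true(all(CB[d$treatment == "none", ] == 0))
  # mixture with treatment 'none' is an error
  bad <- tiny_data(rbind(c(0.5, 0, 0.5), c(0.5, 0.5, 0)), pool, years = 1,
                   treatment = c("aggregated", "none"))
  bad$treatment <- "none"   # force a mixture to none after validation
  expect_error(cross_with_treatment(interaction_columns(bad, "average"), bad),
               "treatment")
})

test_that("covariate scaling multiplies elementwise", {
  pool <- species_pool(paste0("s", 1:4), c("G", "G", "L", "L"))
  d <- tiny_data(rbind(c(0.5, 0, 0.5, 0), c(0.25, 0.25, 0.25, 0.25),
                       c(0.5, 0.5, 0, 0)), pool, years = 1)
  add <- interaction_columns(d, "additive")
  sc <- scale_by_covariate(add, d, c("s3", "s4"))
  # 50:50 grass+legume plot: additive column 0.25 scaled by legume share 0.5
  expect_equal(unname(sc[1, c(1, 3)]), c(0.125, 0.125))
  # zero legume share zeroes the block
  expect_true(all(sc[3, ] == 0))
  # unit covariate leaves the block unchanged
  sc1 <- scale_by_covariate(add, d, pool$species)
  expect_equal(unname(sc1), unname(add))
  expect_error(scale_by_covariate(add, d, "nope"), "not in pool")
})

test_that("random design Z has pair-by-year structure and 510 x 360 shape", {
  d <- space_design(seed = 1)
  Z <- build_Z(d)
  expect_equal(dim(Z), c(510L, 360L))
  # monoculture rows are all zero
  mono <- di_richness(d) == 1
  expect_true(all(Z[mono, ] == 0))
  # a 2-species plot row has exactly one nonzero entry, in its pair's column
  # for that row's year
  two <- which(di_richness(d) == 2 & d$year == 2)[1]
  nz <- which(Z[two, ] != 0)
  expect_equal(length(nz), 1L)
  expect_equal(attr(Z, "col_year")[nz], 2L)
  expect_equal(unname(Z[two, nz]), 0.25)
  # column order is pair-major, year-minor
  expect_equal(attr(Z, "col_year")[1:6], rep(1:3, 2))
  expect_equal(attr(Z, "col_pair")[1:6], rep(1:2, each = 3))
  # restricting active years restricts columns; empty years give 0 columns
  expect_equal(ncol(build_Z(d, 3)), 120L)
  expect_equal(ncol(build_Z(d, integer(0))), 0L)
  expect_error(build_Z(d, 5), "outside")
})

test_that("aliased fixed-design columns are detected and reported", {
  d <- space_design(seed = 1)
  # full pairwise on the restricted layout is partially confounded
  bx <- dimix:::build_X(d, di_fixed("full"))
  expect_gt(length(bx$dropped), 0L)
  expect_equal(qr(bx$X)$rank, ncol(bx$X))
})
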