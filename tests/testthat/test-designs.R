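test_that("design_a reproduces the 206-plot nine-species layout", {
  d <- design_a(seed = 1)
  expect_s3_class(d, "di_data")
  expect_equal(length(unique(d$plot)), 206L)
  expect_equal(nrow(d), 618L)
  P <- prop_cols(d)[d$year == 1, ]
  rich <- rowSums(P > 0)
  expect_equal(as.integer(table(rich)[c("1", "2", "3", "4", "6", "9")]),
               c(18L, 72L, 48L, 36L, 24L, 8L))
  # monocultures have a single proportion equal to 1
  expect_true(all(apply(P[rich == 1, ], 1, max) == 1))
  # every pair occurs in exactly two equal-proportion 2-species plots
  # (brute-force count over the generated design)
  pool <- attr(d, "pool")
  for (pr in list(c(1, 2), c(3, 7), c(8, 9))) {
    hits <- sum(P[, pr[1]] == 0.5 & P[, pr[2]] == 0.5 & rich == 2)
    expect_equal(hits, 2L)
  }
  # design symmetry: species are interchangeable in the proportion totals
  cs <- colSums(P)
  expect_equal(max(cs) - min(cs), 0, tolerance = 1e-9)
  # proportions identical across years for each plot
  expect_equal(prop_cols(d)[d$year == 2, ], P, ignore_attr = TRUE)
})

test_that("design_a higher-richness compositions are balanced per richness", {
  d <- design_a(seed = 42)
  P <- prop_cols(d)[d$year == 1, ]
  rich <- rowSums(P > 0)
  for (r in c(3, 4, 6)) {
    counts <- colSums(P[rich == r, ] > 0)
    expect_true(all(counts == counts[1]), info = paste("richness", r))
  }
})

test_that("space-like design satisfies its composition constraints", {
  d <- space_design(seed = 3)
  expect_equal(length(unique(d$plot)), 170L)
  expect_equal(nrow(d), 510L)
  pool <- attr(d, "pool")
  expect_equal(length(pool$fg_levels), 4L)
  P <- prop_cols(d)[d$year == 1, ]
  rich <- rowSums(P > 0)
  expect_equal(sort(unique(rich)), c(1, 2, 4, 8))
  fg <- as.integer(pool$fg)
  # four-species plots: exactly one species per FG
  for (r4 in which(rich == 4)) {
    expect_equal(sort(unique(fg[P[r4, ] > 0])), 1:4)
    expect_equal(as.integer(table(fg[P[r4, ] > 0])), rep(1L, 4))
  }
  # two-species plots pair one grass with one forb or legume
  for (r2 in which(rich == 2)) {
    groups <- sort(fg[P[r2, ] > 0])
    expect_true(groups[1] %in% 1:2 && groups[2] %in% 3:4)
  }
  # eight-species plots: two per FG
  for (r8 in which(rich == 8)) {
    expect_equal(as.integer(table(fg[P[r8, ] > 0])), rep(2L, 4))
  }
  # monocultures carry no spatial-pattern treatment; mixtures always do
  first <- d[d$year == 1, ]
  expect_true(all(first$treatment[rowSums(prop_cols(d)[d$year == 1, ] > 0) == 1] == "none"))
  expect_true(all(first$treatment[rich > 1] %in% c("aggregated", "dispersed")))
  expect_equal(sort(unique(d$block)), 1:5)
})

test_that("validation enforces proportion sums and uniqueness", {
  df <- data.frame(plot = c("a", "a", "b", "b"), block = 1,
                   year = c(1, 2, 1, 2), treatment = "none", y = NA_real_,
                   s1 = c(0.5, 0.5, 0.45, 0.45), s2 = c(0.5, 0.5, 0.45, 0.45),
                   s3 = 0)
  expect_error(di_data(df, pool3), "sum to 1")
  # renormalization rescales rows in (0, 1] and records them
  ok <- di_data(df, pool3, renormalize = TRUE)
  expect_equal(unname(prop_cols(ok)[ok$plot == "b", "s1"]), c(0.5, 0.5))
  expect_equal(length(attr(ok, "renormalized")), 2L)
  # duplicate plot-year rows are structural errors
  dup <- df; dup$year <- c(1, 1, 1, 2)
  dup$s1 <- 0.5; dup$s2 <- 0.5
  # over-unity sums are never renormalized
  over <- df; over$s1 <- c(0.5, 0.5, 0.7, 0.7); over$s2 <- c(0.5, 0.5, 0.7, 0.7)
  expect_error(di_data(over, pool3, renormalize = TRUE), "not renormalizable")
  expect_error(di_data(dup, pool3), "duplicated")
  # years must be a contiguous 1..K index
  gap <- df; gap$year <- c(1, 3, 1, 3); gap$s1 <- 0.5; gap$s2 <- 0.5
  expect_error(di_data(gap, pool3), "contiguous")
  # generated designs pass validation at tight tolerance
  expect_silent(di_data(as.data.frame(design_a(seed = 2)), pool9(),
                        tolerance = 1e-9))
})

test_that("lagged proportions follow the preceding-year convention", {
  d <- tiny_data(rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), pool3, years = 3)
  realized <- data.frame(plot = rep(c("t01", "t02"), 2),
                         year = rep(1:2, each = 2),
                         s1 = c(0.7, 0, 0.8, 0), s2 = c(0.3, 0.6, 0.1, 0.5),
                         s3 = c(0, 0.4, 0, 0.5))
  lag <- lag_proportions(d, realized, renormalize = TRUE)
  # year 1 keeps planted proportions
  expect_equal(unname(unlist(lag[lag$plot == "t01" & lag$year == 1,
                                 pool3$species])), c(0.5, 0.5, 0))
  # year 2 predictors copy realized year-1 proportions
  expect_equal(unname(unlist(lag[lag$plot == "t01" & lag$year == 2,
                                 pool3$species])), c(0.7, 0.3, 0))
  # a realized row summing to 0.9 is renormalized: (0.8, 0.1) -> (8/9, 1/9)
  expect_equal(unname(unlist(lag[lag$plot == "t01" & lag$year == 3,
                                 pool3$species])), c(8 / 9, 1 / 9, 0) )
  # identity when realized == planted
  same <- data.frame(plot = rep(c("t01", "t02"), 2), year = rep(1:2, each = 2))
  same[pool3$species] <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5))[c(1, 2, 1, 2), ]
  expect_equal(as.data.frame(lag_proportions(d, same)), as.data.frame(d))
  # missing realized year is an error naming the plot
  expect_error(lag_proportions(d, realized[realized$plot == "t01", ]), "t02")
})
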