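test_that("profile_beta solves the GLS normal equations", {
  set.seed(5)
  # V = I reduces to ordinary least squares
  X <- cbind(1, rnorm(10))
  y <- rnorm(10)
  g <- profile_beta(X, diag(10), y)
  expect_equal(g$beta, unname(coef(lm(y ~ X - 1))), tolerance = 1e-10)
  expect_equal(profile_beta(matrix(1, 3), diag(3), c(1, 2, 3))$beta, 2)
  # random instance vs direct dense-inverse arithmetic
  A <- matrix(rnorm(36), 6); V <- crossprod(A) + diag(6)
  X2 <- matrix(rnorm(18), 6)
  y2 <- rnorm(6)
  bdirect <- solve(t(X2) %*% solve(V) %*% X2) %*% t(X2) %*% solve(V) %*% y2
  g2 <- profile_beta(X2, V, y2)
  expect_equal(g2$beta, as.numeric(bdirect), tolerance = 1e-10)
  expect_equal(g2$cov, solve(t(X2) %*% solve(V) %*% X2), tolerance = 1e-10)
  # aliased columns are reported by name
  X3 <- cbind(a = X2[, 1], b = X2[, 1])
  expect_error(profile_beta(X3, V, y2), "aliased")
})

test_that("-2 logLik equals the explicit multivariate-normal density", {
  set.seed(21)
  # 4 plots x 3 years = 12 observations, random effects in all years
  P <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(1 / 3, 1 / 3, 1 / 3))
  d <- tiny_data(P, pool3, years = 3, y = rnorm(12, 5, 2))
  fx <- di_fixed("average", by_year = FALSE)
  rp <- list(all = list(v = 2.5, c = 0.8))
  s2 <- c(0.7, 1.2, 0.4)
  X <- dimix:::build_X(d, fx)$X
  Z <- build_Z(d)
  R <- build_R(d, di_rstruct("cs"), rp)
  V <- marginal_covariance(Z, build_G(3, sigma2 = s2), R)
  for (m in c("ML", "REML")) {
    got <- di_neg2ll(d, fx, di_rstruct("cs"), di_gstruct(1:3), rp,
                     sigma2 = s2, method = m)
    expect_equal(got, dense_neg2ll(d$y, X, V, m), tolerance = 1e-8)
  }
  # AR1 and UN block types agree with the dense oracle too
  rp_ar <- list(all = list(v = 2, rho = 0.4))
  Var <- marginal_covariance(Z, build_G(3, sigma2 = s2),
                             build_R(d, di_rstruct("ar1"), rp_ar))
  expect_equal(di_neg2ll(d, fx, di_rstruct("ar1"), di_gstruct(1:3), rp_ar,
                         sigma2 = s2, method = "REML"),
               dense_neg2ll(d$y, X, Var, "REML"), tolerance = 1e-8)
  S <- matrix(c(2, .5, .2, .5, 1.5, .4, .2, .4, 1), 3)
  Vun <- marginal_covariance(Z, build_G(3, sigma2 = s2),
                             build_R(d, di_rstruct("un"), list(all = list(S = S))))
  expect_equal(di_neg2ll(d, fx, di_rstruct("un"), di_gstruct(1:3),
                         list(all = list(S = S)), sigma2 = s2, method = "ML"),
               dense_neg2ll(d$y, X, Vun, "ML"), tolerance = 1e-8)
  # year-covariance M block
  M <- matrix(c(1, .6, .3, .6, 1.2, .5, .3, .5, 0.9), 3)
  VM <- marginal_covariance(Z, build_G(3, M = M), R)
  expect_equal(di_neg2ll(d, fx, di_rstruct("cs"), di_gstruct(1:3, year_cov = TRUE),
                         rp, M = M, method = "REML"),
               dense_neg2ll(d$y, X, VM, "REML"), tolerance = 1e-8)
})

test_that("REML is invariant to translations in the fixed-effect span", {
  set.seed(31)
  P <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0, 0, 1), c(1 / 3, 1 / 3, 1 / 3))
  d <- tiny_data(P, pool3, years = 3, y = rnorm(12, 4, 1.5))
  fx <- di_fixed("average", by_year = FALSE)
  rp <- list(all = list(v = 1.5, c = 0.3))
  base <- di_neg2ll(d, fx, di_rstruct("cs"), di_gstruct(2), rp,
                    sigma2 = 0.5, method = "REML")
  X <- dimix:::build_X(d, fx)$X
  d2 <- d
  d2$y <- d$y + as.numeric(X %*% rnorm(ncol(X), 0, 10))
  shifted <- di_neg2ll(d2, fx, di_rstruct("cs"), di_gstruct(2), rp,
                       sigma2 = 0.5, method = "REML")
  expect_equal(base, shifted, tolerance = 1e-8)
})

test_that("fits agree with gls and lmer on equivalent special cases", {
  library(nlme)
  library(lme4)
  d0 <- design_a(seed = 1)
  eff <- di_sim_effects(attr(d0, "pool"), 3)
  d <- simulate_response(d0, eff, sd_resid = 100, sd_pair = 300, seed = 5)
  # CS residuals, no random effects: nlme::gls oracle on the full design
  f0 <- dimix(d, di_fixed("fg"), di_rstruct("cs"), di_gstruct(),
              method = "REML")
  X <- dimix:::build_X(d, di_fixed("fg"))$X
  df <- data.frame(y = d$y, plot = d$plot)
  df <- cbind(df, as.data.frame(X))
  xn <- paste0("x", seq_len(ncol(X))); names(df)[-(1:2)] <- xn
  g <- nlme::gls(as.formula(paste("y ~ 0 +", paste(xn, collapse = "+"))),
                 data = df,
                 correlation = nlme::corCompSymm(form = ~ 1 | plot),
                 method = "REML")
  expect_equal(f0$neg2ll, -2 * as.numeric(logLik(g)), tolerance = 1e-5)
  expect_equal(unname(f0$beta), unname(coef(g)), tolerance = 1e-4)
  rho_gls <- coef(g$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(f0$varpar$rside$all$c / f0$varpar$rside$all$v,
               unname(rho_gls), tolerance = 1e-4)
  # one-year random interactions on the monoculture+pairs subset: lmer
  # (plot intercept + pair slope == CS with c>0 + pair-year effects)
  pool <- attr(d, "pool")
  ds <- di_data(as.data.frame(d)[di_richness(d) <= 2, ], pool)
  f1 <- dimix(ds, di_fixed("fg"), di_rstruct("cs"), di_gstruct(years = 3),
              method = "REML")
  Xs <- dimix:::build_X(ds, di_fixed("fg"))$X
  Zs <- build_Z(ds, 3)
  pairidx <- apply(Zs, 1, function(r)
    if (any(r != 0)) attr(Zs, "col_pair")[which(r != 0)[1]] else NA)
  dfs <- data.frame(y = ds$y, plot = ds$plot,
                    pair = factor(ifelse(is.na(pairidx), "none",
                                         attr(Zs, "pairs")$label[pairidx])),
                    ppx = apply(Zs, 1, function(r)
                      if (any(r != 0)) r[r != 0][1] else 0))
  dfs <- cbind(dfs, as.data.frame(Xs))
  xn <- paste0("x", seq_len(ncol(Xs))); names(dfs)[-(1:4)] <- xn
  m1 <- lme4::lmer(as.formula(paste("y ~ 0 +", paste(xn, collapse = "+"),
                                    "+ (1|plot) + (0+ppx|pair)")),
                   dfs, REML = TRUE)
  expect_equal(f1$neg2ll, -2 * as.numeric(logLik(m1)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m1))
  v_lmer <- vc$vcov[vc$grp == "plot"] + vc$vcov[vc$grp == "Residual"]
  expect_equal(f1$varpar$rside$all$v, v_lmer, tolerance = 1e-3)
  expect_equal(f1$varpar$rside$all$c, vc$vcov[vc$grp == "plot"],
               tolerance = 1e-2)
  expect_equal(unname(f1$varpar$gside$sigma2),
               vc$vcov[vc$grp == "pair"], tolerance = 1e-2)
})

test_that("nested models never worsen and monoculture data ignore G", {
  d0 <- design_a(seed = 2)
  eff <- di_sim_effects(attr(d0, "pool"), 3)
  d <- simulate_response(d0, eff, sd_resid = 100, sd_pair = 200, seed = 9)
  f0 <- dimix(d, di_fixed("fg"), di_rstruct("cs"), di_gstruct(),
              method = "REML")
  f1 <- dimix(d, di_fixed("fg"), di_rstruct("cs"), di_gstruct(years = 2),
              method = "REML")
  expect_gte(f0$neg2ll, f1$neg2ll - 1e-6)
  # ML: fixed-structure nesting
  m_avg <- dimix(d, di_fixed("average"), di_rstruct("cs"), method = "ML")
  m_fg <- dimix(d, di_fixed("fg"), di_rstruct("cs"), method = "ML")
  expect_gte(m_avg$neg2ll, m_fg$neg2ll - 1e-6)
  # monoculture-only data: all Z rows vanish so G-years change nothing
  pool <- attr(d, "pool")
  mono <- di_data(as.data.frame(d)[di_richness(d) == 1, ], pool)
  g0 <- dimix(mono, di_fixed("identity"), di_rstruct("cs"), di_gstruct(),
              method = "REML")
  g1 <- dimix(mono, di_fixed("identity"), di_rstruct("cs"),
              di_gstruct(years = 1:3), method = "REML")
  expect_equal(g0$neg2ll, g1$neg2ll, tolerance = 1e-6)
  expect_true(all(g1$blups$d == 0) || all(abs(g1$blups$d) < 1e-10))
})

test_that("BLUPs match the dense mixed-model equations and shrink with G", {
  set.seed(44)
  P <- rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(1, 0, 0))
  d <- tiny_data(P, pool3, years = 3, y = rnorm(12, 3, 1))
  f <- dimix(d, di_fixed("average", by_year = FALSE), di_rstruct("cs"),
             di_gstruct(1:3), method = "REML",
             control = dimix_control(restarts = 5))
  X <- dimix:::build_X(d, di_fixed("average", by_year = FALSE))$X
  Z <- build_Z(d)
  R <- build_R(d, di_rstruct("cs"),
               list(all = list(v = f$varpar$rside$all$v,
                               c = f$varpar$rside$all$c)))
  G <- build_G(3, sigma2 = unname(f$varpar$gside$sigma2))
  expect_equal(f$blups$d, dense_blups(d$y, X, Z, G, R), tolerance = 1e-6)
  # |BLUP| decreases monotonically as the G variance shrinks toward zero
  dmax <- sapply(c(1, 0.3, 0.05, 0.01), function(sc) {
    max(abs(dense_blups(d$y, X, Z,
                        build_G(3, sigma2 = sc * unname(f$varpar$gside$sigma2) + 1e-12),
                        R)))
  })
  expect_true(all(diff(dmax) < 1e-12))
})

test_that("optimum is reproducible and satisfies the GLS stationarity check", {
  d0 <- design_a(seed = 3)
  eff <- di_sim_effects(attr(d0, "pool"), 3)
  d <- simulate_response(d0, eff, sd_resid = 100, sd_pair = 800, seed = 13)
  f1 <- dimix(d, di_fixed("fg"), di_rstruct("cs"), di_gstruct(3),
              method = "REML")
  f2 <- dimix(d, di_fixed("fg"), di_rstruct("cs"), di_gstruct(3),
              method = "REML")
  expect_identical(f1$neg2ll, f2$neg2ll)
  expect_identical(f1$beta, f2$beta)
  # beta satisfies the GLS normal equations at the fitted variance parameters
  X <- f1$X
  Z <- f1$Z
  R <- build_R(d, di_rstruct("cs"),
               list(all = list(v = f1$varpar$rside$all$v,
                               c = f1$varpar$rside$all$c)))
  V <- marginal_covariance(Z, build_G(choose(9, 2),
                                      sigma2 = unname(f1$varpar$gside$sigma2)),
                           R)
  gls <- profile_beta(X, V, d$y)
  expect_equal(unname(f1$beta), gls$beta, tolerance = 1e-6)
})
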