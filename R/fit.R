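#' Fit a multi-year Diversity-Interactions mixed model
#'
#' Maximizes the marginal (ML) or restricted (REML) log-likelihood of the
#' model y = X beta + Z u + e, where X carries species identity effects,
#' DI interaction terms and design structures ([di_fixed()]), Z holds one
#' column per species pair and active year with entries P_i P_j
#' ([build_Z()]), u ~ N(0, G) with one variance per year shared across pairs
#' ([di_gstruct()]) and e ~ N(0, R) with per-plot repeated-measures blocks
#' ([di_rstruct()]). The fixed effects beta are profiled out by generalized
#' least squares at every variance-parameter evaluation; with CS or AR(1)
#' residual blocks a global variance scale is also profiled analytically.
#' Optimization is bound-constrained quasi-Newton (yearly random-interaction
#' variances are optimized on their natural scale with a floor at zero, so
#' the boundary value 0 is attainable); on failure the fit is retried with
#' variance starting values inflated tenfold, up to
#' `control$restarts` times.
#'
#' @param data a [di_data()] with a complete numeric response `y`.
#' @param fixed a [di_fixed()] specification.
#' @param rstruct a [di_rstruct()] residual-covariance specification.
#' @param gstruct a [di_gstruct()] random-interaction specification.
#' @param method `"REML"` (default) or `"ML"`.
#' @param control a [dimix_control()] list.
#' @return an object of class `"dimix"`; see [summary.dimix()],
#'   [predict.dimix()], [blups()], [di_lrt()].
#' @examples
#' d <- design_a(seed = 1)
#' eff <- di_sim_effects(attr(d, "pool"), K = 3)
#' d <- simulate_response(d, eff, sd_resid = 100, sd_pair = 0, seed = 7)
#' fit <- dimix(d, di_fixed("fg"), di_rstruct("cs"), method = "REML")
#' fit
#' @export
dimix <- function(data, fixed = di_fixed("average"),
                  rstruct = di_rstruct("cs"), gstruct = di_gstruct(),
                  method = c("REML", "ML"), control = dimix_control()) {
  method <- match.arg(method)
  stopifnot(inherits(data, "di_data"), inherits(fixed, "di_fixed"),
            inherits(rstruct, "di_rstruct"), inherits(gstruct, "di_gstruct"))
  if (anyNA(data$y)) stop("response contains missing values")
  ctx <- make_ctx(data, fixed, rstruct, gstruct, method)
  st <- start_values(ctx, control$start)
  best <- NULL
  restarts_used <- 0L
  par <- st$par
  for (att in 0:control$restarts) {
    opt <- try(run_opt(par, ctx, control), silent = TRUE)
    ok <- !inherits(opt, "try-error") && is.finite(opt$value) &&
      opt$value < penalty_value() / 2 && opt$convergence == 0L
    if (!inherits(opt, "try-error") && is.finite(opt$value) &&
        opt$value < penalty_value() / 2 &&
        (is.null(best) || opt$value < best$value - 1e-9)) best <- opt
    if (ok && !is.null(best)) break
    restarts_used <- att + 1L
    par <- st$par
    par[ctx$layout$tau_idx] <- pmax(par[ctx$layout$tau_idx], st$tau0) *
      control$restart_mult^restarts_used
  }
  if (is.null(best))
    return(fail_fit(ctx, method, restarts_used, match.call()))
  finish_fit(best, ctx, method, restarts_used, match.call())
}

#' Optimizer control for [dimix()]
#'
#' @param maxit maximum quasi-Newton iterations.
#' @param factr L-BFGS-B relative convergence tolerance factor.
#' @param pgtol projected-gradient tolerance.
#' @param restarts maximum refits with inflated variance starting values.
#' @param restart_mult multiplier applied to variance starts per restart.
#' @param start optional named list overriding starting values
#'   (`rho`, `tau`).
#' @export
dimix_control <- function(maxit = 200L, factr = 1e7, pgtol = 1e-6,
                          restarts = 3L, restart_mult = 10, start = NULL) {
  list(maxit = maxit, factr = factr, pgtol = pgtol, restarts = restarts,
       restart_mult = restart_mult, start = start)
}

penalty_value <- function() 1e10

# ---- context: precomputed cross-product tensors -----------------------------

make_ctx <- function(data, fixed, rstruct, gstruct, method) {
  pool <- di_pool(data)
  K <- di_K(data)
  bx <- build_X(data, fixed)
  X <- bx$X
  y <- as.numeric(data$y)
  Z <- build_Z(data, gstruct$years)
  q <- ncol(Z)
  n <- length(y)
  p <- ncol(X)
  grp <- r_groups(data, rstruct$groups)
  glev <- unique(unname(grp))
  rows_by_plot <- split(seq_len(n), factor(data$plot, levels = unique(data$plot)))
  C <- cbind(y, X, Z)
  cells <- list()
  for (pl in names(rows_by_plot)) {
    rows <- rows_by_plot[[pl]]
    yrs <- data$year[rows]
    key <- paste(match(grp[[pl]], glev), paste(yrs, collapse = ","), sep = "|")
    if (is.null(cells[[key]]))
      cells[[key]] <- list(g = match(grp[[pl]], glev), yrs = yrs,
                           rowsets = vector("list", length(yrs)), n_plots = 0L)
    for (i in seq_along(yrs))
      cells[[key]]$rowsets[[i]] <- c(cells[[key]]$rowsets[[i]], rows[i])
    cells[[key]]$n_plots <- cells[[key]]$n_plots + 1L
  }
  for (key in names(cells)) {
    ce <- cells[[key]]
    Kp <- length(ce$yrs)
    S <- vector("list", Kp * Kp)
    for (i in seq_len(Kp)) for (j in i:Kp) {
      S[[(i - 1L) * Kp + j]] <- crossprod(C[ce$rowsets[[i]], , drop = FALSE],
                                          C[ce$rowsets[[j]], , drop = FALSE])
      if (j > i) S[[(j - 1L) * Kp + i]] <- t(S[[(i - 1L) * Kp + j]])
    }
    cells[[key]]$S <- S
    cells[[key]]$rowsets <- NULL
  }
  layout <- par_layout(rstruct, gstruct, K, length(glev))
  list(data = data, pool = pool, K = K, n = n, p = p, q = q,
       y = y, X = X, Z = Z, dropped = bx$dropped,
       fixed = fixed, rstruct = rstruct, gstruct = gstruct, method = method,
       grp = grp, glev = glev, cells = cells, layout = layout,
       col_year = attr(Z, "col_year"), col_pair = attr(Z, "col_pair"),
       pairs = attr(Z, "pairs"),
       tlevels = sort(unique(data$treatment[data$treatment != "none"])),
       blevels = unique(as.character(data$block)))
}

# parameter layout; `profile` = analytic global-scale profiling (cs/ar1 only)
par_layout <- function(rstruct, gstruct, K, n_groups) {
  profile <- rstruct$type %in% c("cs", "ar1")
  nm <- character(0); lb <- numeric(0)
  if (profile) {
    for (g in seq_len(n_groups)) {
      if (g > 1L) { nm <- c(nm, paste0("lvr", g)); lb <- c(lb, -Inf) }
      nm <- c(nm, paste0("rho", g)); lb <- c(lb, -Inf)
    }
  } else {
    nch <- K * (K + 1L) / 2L
    for (g in seq_len(n_groups)) {
      nm <- c(nm, paste0("un", g, "_", seq_len(nch)))
      lb <- c(lb, rep(-Inf, nch))
    }
  }
  ny <- length(gstruct$years)
  tau_idx <- integer(0)
  if (ny > 0L) {
    if (!gstruct$year_cov) {
      tau_idx <- length(nm) + seq_len(ny)
      nm <- c(nm, paste0("tau", gstruct$years)); lb <- c(lb, rep(0, ny))
    } else {
      # lower-tri Cholesky of the shared M block; diagonal floored at zero
      for (cjj in seq_len(ny)) for (rii in cjj:ny) {
        diagel <- rii == cjj
        nm <- c(nm, paste0("Lm", rii, cjj))
        lb <- c(lb, if (diagel) 0 else -Inf)
        if (diagel) tau_idx <- c(tau_idx, length(nm))
      }
    }
  }
  list(names = nm, lb = lb, npar = length(nm), profile = profile,
       tau_idx = tau_idx, ny = ny)
}

# decode parameter vector -> per-group K x K blocks + G-side scaling
decode_par <- function(par, ctx) {
  K <- ctx$K; lay <- ctx$layout
  Sig <- vector("list", length(ctx$glev))
  pos <- 1L
  if (lay$profile) {
    lo <- -1 / (K - 1)
    for (g in seq_along(Sig)) {
      scl <- 1
      if (g > 1L) { scl <- exp(par[pos]); pos <- pos + 1L }
      th <- par[pos]; pos <- pos + 1L
      Sig[[g]] <- if (ctx$rstruct$type == "cs") {
        rho <- lo + (1 - lo) / (1 + exp(-th))
        m <- matrix(rho, K, K); diag(m) <- 1; scl * m
      } else {
        rho <- tanh(th)
        scl * rho^abs(outer(seq_len(K), seq_len(K), "-"))
      }
    }
  } else {
    nch <- K * (K + 1L) / 2L
    for (g in seq_along(Sig)) {
      th <- par[pos + seq_len(nch) - 1L]; pos <- pos + nch
      L <- matrix(0, K, K)
      ix <- 1L
      for (cjj in seq_len(K)) for (rii in cjj:K) {
        L[rii, cjj] <- if (rii == cjj) exp(th[ix]) else th[ix]
        ix <- ix + 1L
      }
      Sig[[g]] <- L %*% t(L)
    }
  }
  gs <- NULL
  ny <- lay$ny
  if (ny > 0L) {
    if (!ctx$gstruct$year_cov) {
      tau <- pmax(par[pos + seq_len(ny) - 1L], 0)
      gs <- list(kind = "diag", tau = tau)
    } else {
      Lm <- matrix(0, ny, ny)
      ix <- pos
      for (cjj in seq_len(ny)) for (rii in cjj:ny) {
        Lm[rii, cjj] <- if (rii == cjj) max(par[ix], 0) else par[ix]
        ix <- ix + 1L
      }
      gs <- list(kind = "chol", Lm = Lm)
    }
  }
  list(Sig = Sig, gs = gs)
}

# sd multiplier per Z column (diag G case) or q x q right factor (chol case)
g_right_factor <- function(gs, ctx) {
  if (is.null(gs) || ctx$q == 0L) return(NULL)
  yrs <- ctx$gstruct$years
  if (gs$kind == "diag") {
    s <- sqrt(gs$tau)[match(ctx$col_year, yrs)]
    list(kind = "diag", s = s)
  } else {
    list(kind = "chol", Lm = gs$Lm, npairs = nrow(ctx$pairs))
  }
}

# core evaluation: returns -2 logLik plus GLS byproducts
eval_core <- function(par, ctx, want = "value", dec = NULL) {
  if (is.null(dec)) dec <- try(decode_par(par, ctx), silent = TRUE)
  if (inherits(dec, "try-error")) return(list(value = penalty_value()))
  n <- ctx$n; p <- ctx$p; q <- ctx$q
  m <- 1L + p + q
  AtA <- matrix(0, m, m)
  logdetR <- 0
  for (ce in ctx$cells) {
    Kp <- length(ce$yrs)
    Sg <- dec$Sig[[ce$g]][ce$yrs, ce$yrs, drop = FALSE]
    ch <- try(chol(Sg), silent = TRUE)
    if (inherits(ch, "try-error")) return(list(value = penalty_value()))
    Om <- chol2inv(ch)
    logdetR <- logdetR + ce$n_plots * 2 * sum(log(diag(ch)))
    for (i in seq_len(Kp)) for (j in seq_len(Kp))
      if (Om[i, j] != 0)
        AtA <- AtA + Om[i, j] * ce$S[[(i - 1L) * Kp + j]]
  }
  iy <- 1L; iX <- if (p) 1L + seq_len(p) else integer(0); iZ <- if (q) 1L + p + seq_len(q) else integer(0)
  logdetMid <- 0
  AVA <- AtA[c(iX, iy), c(iX, iy), drop = FALSE]
  Tq <- NULL; rf <- g_right_factor(dec$gs, ctx)
  if (q > 0L && !is.null(rf)) {
    ZtZ <- AtA[iZ, iZ, drop = FALSE]
    AZ <- AtA[c(iX, iy), iZ, drop = FALSE]
    if (rf$kind == "diag") {
      UtU <- ZtZ * tcrossprod(rf$s)
      AU <- AZ * rep(rf$s, each = nrow(AZ))
    } else {
      Krf <- diag(rf$npairs) %x% rf$Lm
      UtU <- crossprod(Krf, ZtZ %*% Krf)
      AU <- AZ %*% Krf
    }
    Mid <- UtU; diag(Mid) <- diag(Mid) + 1
    CU <- try(chol(Mid), silent = TRUE)
    if (inherits(CU, "try-error")) return(list(value = penalty_value()))
    logdetMid <- 2 * sum(log(diag(CU)))
    Tq <- backsolve(CU, t(AU), transpose = TRUE)
    AVA <- AVA - crossprod(Tq)
  }
  if (p > 0L) {
    XtVX <- AVA[seq_len(p), seq_len(p), drop = FALSE]
    XtVy <- AVA[seq_len(p), p + 1L]
    chX <- try(chol(XtVX), silent = TRUE)
    if (inherits(chX, "try-error")) return(list(value = penalty_value()))
    beta <- backsolve(chX, backsolve(chX, XtVy, transpose = TRUE))
    rss <- max(AVA[p + 1L, p + 1L] - sum(beta * XtVy), 1e-12)
    logdetXVX <- 2 * sum(log(diag(chX)))
  } else {
    beta <- numeric(0); rss <- max(AVA[1L, 1L], 1e-12)
    logdetXVX <- 0; chX <- NULL
  }
  logdetV <- logdetR + logdetMid
  if (ctx$layout$profile) {
    df <- if (ctx$method == "REML") n - p else n
    phi <- rss / df
    val <- if (ctx$method == "REML")
      (n - p) * log(2 * pi) + logdetV + logdetXVX +
        (n - p) * log(phi) + (n - p)
    else n * log(2 * pi) + logdetV + n * log(phi) + n
  } else {
    phi <- 1
    val <- if (ctx$method == "REML")
      (n - p) * log(2 * pi) + logdetV + logdetXVX + rss
    else n * log(2 * pi) + logdetV + rss
  }
  if (!is.finite(val)) return(list(value = penalty_value()))
  if (want == "value") return(list(value = val))
  list(value = val, beta = beta, chX = chX, phi = phi, rss = rss,
       dec = dec, AtA = AtA, rf = rf,
       CU = if (q > 0L) CU else NULL, iX = iX, iy = iy, iZ = iZ)
}

# bound-aware central/forward finite-difference gradient
fd_grad <- function(fn, par, lb, eps = 1e-5) {
  g <- numeric(length(par)); f0 <- NULL
  for (i in seq_along(par)) {
    h <- eps * max(1, abs(par[i]))
    up <- par; up[i] <- par[i] + h
    if (par[i] - h >= lb[i]) {
      dn <- par; dn[i] <- par[i] - h
      g[i] <- (fn(up) - fn(dn)) / (2 * h)
    } else {
      if (is.null(f0)) f0 <- fn(par)
      g[i] <- (fn(up) - f0) / h
    }
  }
  g
}

run_opt <- function(par, ctx, control) {
  fn <- function(p) eval_core(p, ctx)$value
  if (length(par) == 0L) {
    v <- fn(par)
    return(list(par = par, value = v, convergence = 0L,
                counts = c(`function` = 1L, gradient = 0L)))
  }
  gr <- function(p) fd_grad(fn, p, ctx$layout$lb)
  stats::optim(par, fn, gr, method = "L-BFGS-B", lower = ctx$layout$lb,
               control = list(maxit = control$maxit, factr = control$factr,
                              pgtol = control$pgtol))
}

# ---- starting values --------------------------------------------------------

start_values <- function(ctx, override = NULL) {
  y <- ctx$y; X <- ctx$X
  e <- if (ctx$p > 0L) stats::lm.fit(X, y)$residuals else y
  data <- ctx$data
  # per-group moment estimates from OLS residuals
  vg <- cg <- l1g <- numeric(length(ctx$glev))
  for (g in seq_along(ctx$glev)) {
    pls <- names(ctx$grp)[unname(ctx$grp) == ctx$glev[g]]
    rows <- data$plot %in% pls
    E <- e[rows]; yr <- data$year[rows]; pl <- data$plot[rows]
    vg[g] <- max(stats::var(E), 1e-8)
    wide <- tapply(E, list(pl, yr), identity)
    cc <- try(suppressWarnings(stats::cov(wide, use = "pairwise.complete.obs")),
              silent = TRUE)
    if (!inherits(cc, "try-error") && is.matrix(cc) && ncol(cc) >= 2 &&
        all(is.finite(cc))) {
      vg[g] <- max(mean(diag(cc)), 1e-8)
      off <- cc[upper.tri(cc)]
      cg[g] <- mean(off)
      l1 <- cc[cbind(seq_len(ncol(cc) - 1L), 2:ncol(cc))]
      l1g[g] <- mean(l1)
    } else { cg[g] <- 0; l1g[g] <- 0 }
  }
  lay <- ctx$layout
  par <- numeric(lay$npar); names(par) <- lay$names
  K <- ctx$K
  if (lay$profile) {
    lo <- -1 / (K - 1)
    pos <- 1L
    for (g in seq_along(ctx$glev)) {
      if (g > 1L) { par[pos] <- log(vg[g] / vg[1L]); pos <- pos + 1L }
      rho <- if (ctx$rstruct$type == "cs") cg[g] / vg[g] else l1g[g] / vg[g]
      rho <- min(max(rho, lo + 0.05 * (1 - lo)), 0.95)
      par[pos] <- if (ctx$rstruct$type == "cs")
        -log((1 - lo) / (rho - lo) - 1) else atanh(rho)
      pos <- pos + 1L
    }
  } else {
    nch <- K * (K + 1L) / 2L
    pos <- 1L
    for (g in seq_along(ctx$glev)) {
      S0 <- diag(vg[g], K)
      S0[S0 == 0] <- 0
      S0[upper.tri(S0)] <- S0[lower.tri(S0)] <- 0.5 * cg[g]
      L <- t(chol(S0))
      th <- numeric(nch); ix <- 1L
      for (cjj in seq_len(K)) for (rii in cjj:K) {
        th[ix] <- if (rii == cjj) log(L[rii, cjj]) else L[rii, cjj]
        ix <- ix + 1L
      }
      par[pos + seq_len(nch) - 1L] <- th
      pos <- pos + nch
    }
  }
  # yearly random-interaction variances start at 10% of residual variance
  tau0 <- if (lay$profile) 0.1 else 0.1 * mean(vg)
  if (length(lay$tau_idx)) par[lay$tau_idx] <- if (is.null(override$tau)) tau0 else override$tau
  if (!is.null(override$rho) && lay$profile) {
    lo <- -1 / (K - 1)
    par[grep("^rho", names(par))] <- if (ctx$rstruct$type == "cs")
      -log((1 - lo) / (override$rho - lo) - 1) else atanh(override$rho)
  }
  list(par = par, tau0 = tau0)
}

# ---- assembling the result --------------------------------------------------

finish_fit <- function(opt, ctx, method, restarts, call) {
  res <- eval_core(opt$par, ctx, want = "full")
  p <- ctx$p; q <- ctx$q; n <- ctx$n
  phi <- res$phi
  vcov_beta <- if (p > 0L) phi * chol2inv(res$chX) else matrix(0, 0, 0)
  beta <- res$beta
  if (p > 0L) { names(beta) <- colnames(ctx$X)
    dimnames(vcov_beta) <- list(colnames(ctx$X), colnames(ctx$X)) }
  varpar <- user_varpar(res$dec, phi, ctx)
  blup <- compute_blups(res, ctx)
  npar <- p + ctx$layout$npar + as.integer(ctx$layout$profile)
  ll <- -0.5 * res$value
  out <- list(call = call, method = method, n = n, p = p, q = q,
              beta = beta, vcov_beta = vcov_beta,
              varpar = varpar, phi = phi,
              neg2ll = res$value, logLik = ll, npar = npar,
              converged = TRUE, restarts = restarts,
              counts = opt$counts, opt_par = opt$par,
              blups = blup, dropped = ctx$dropped,
              fixed = ctx$fixed, rstruct = ctx$rstruct, gstruct = ctx$gstruct,
              pool = ctx$pool, K = ctx$K,
              tlevels = ctx$tlevels, blevels = ctx$blevels,
              X = ctx$X, Z = ctx$Z, y = ctx$y,
              data = ctx$data, glev = ctx$glev)
  class(out) <- "dimix"
  out
}

fail_fit <- function(ctx, method, restarts, call) {
  out <- list(call = call, method = method, n = ctx$n, p = ctx$p, q = ctx$q,
              beta = NULL, vcov_beta = NULL, varpar = NULL,
              neg2ll = NA_real_, logLik = NA_real_,
              npar = ctx$p + ctx$layout$npar + as.integer(ctx$layout$profile),
              converged = FALSE, restarts = restarts,
              fixed = ctx$fixed, rstruct = ctx$rstruct, gstruct = ctx$gstruct,
              pool = ctx$pool, K = ctx$K, data = ctx$data)
  class(out) <- "dimix"
  out
}

# user-scale variance parameters
user_varpar <- function(dec, phi, ctx) {
  K <- ctx$K
  rside <- list()
  for (g in seq_along(ctx$glev)) {
    S <- phi * dec$Sig[[g]]
    rside[[ctx$glev[g]]] <- switch(ctx$rstruct$type,
      cs  = list(v = S[1, 1], c = S[1, 2]),
      ar1 = list(v = S[1, 1], rho = S[1, 2] / S[1, 1]),
      un  = list(S = S))
  }
  gside <- NULL
  if (!is.null(dec$gs)) {
    if (dec$gs$kind == "diag") {
      s2 <- phi * dec$gs$tau
      names(s2) <- paste0("year", ctx$gstruct$years)
      gside <- list(sigma2 = s2)
    } else {
      M <- phi * tcrossprod(dec$gs$Lm)
      dimnames(M) <- list(paste0("year", ctx$gstruct$years),
                          paste0("year", ctx$gstruct$years))
      gside <- list(M = M, sigma2 = stats::setNames(diag(M), rownames(M)))
    }
  }
  list(rside = rside, gside = gside)
}

# BLUPs: d_hat = G Z' V^-1 (y - X beta), via the whitened cross-products
compute_blups <- function(res, ctx) {
  q <- ctx$q
  if (q == 0L || is.null(res$rf)) return(NULL)
  p <- ctx$p
  AtA <- res$AtA
  iZ <- res$iZ
  ZtRy <- AtA[iZ, res$iy]
  ZtRr <- if (p > 0L) ZtRy - AtA[iZ, res$iX, drop = FALSE] %*% res$beta else ZtRy
  rf <- res$rf
  if (rf$kind == "diag") {
    Utr <- rf$s * as.numeric(ZtRr)
  } else {
    Krf <- diag(rf$npairs) %x% rf$Lm
    Utr <- crossprod(Krf, as.numeric(ZtRr))
  }
  # Vtilde^-1-weighted: Z~' V~^-1 r~ = Z'R^-1 r - Z'R^-1 U (I+U'U)^-1 U' R^-1 r
  w <- backsolve(res$CU, backsolve(res$CU, Utr, transpose = TRUE))
  if (rf$kind == "diag") {
    ZVr <- as.numeric(ZtRr) - (AtA[iZ, iZ, drop = FALSE] %*% (rf$s * w)) * 1
    d <- rf$s^2 * as.numeric(ZVr)
  } else {
    Krf <- diag(rf$npairs) %x% rf$Lm
    ZVr <- as.numeric(ZtRr) - AtA[iZ, iZ, drop = FALSE] %*% (Krf %*% w)
    Gq <- diag(rf$npairs) %x% tcrossprod(rf$Lm)
    d <- as.numeric(Gq %*% ZVr)
  }
  pr <- ctx$pairs
  data.frame(pair = pr$label[ctx$col_pair],
             i = pr$i[ctx$col_pair], j = pr$j[ctx$col_pair],
             year = ctx$col_year, d = d, stringsAsFactors = FALSE)
}

#' Evaluate the -2 log-likelihood at given variance parameters
#'
#' Computes the profiled (over beta only) ML or REML -2 log-likelihood of a
#' DI mixed model at user-supplied absolute variance parameters, without any
#' optimization. Useful for audit and for checking against an explicit
#' multivariate-normal density.
#'
#' @inheritParams dimix
#' @param rparams named list of per-group residual block parameters (see
#'   [build_R()]).
#' @param sigma2 yearly random-interaction variances for the active years of
#'   `gstruct` (ignored when no years are active).
#' @param M optional shared year-covariance block overriding `sigma2`.
#' @return scalar -2 log-likelihood.
#' @export
di_neg2ll <- function(data, fixed, rstruct, gstruct, rparams,
                      sigma2 = NULL, M = NULL, method = c("REML", "ML")) {
  method <- match.arg(method)
  ctx <- make_ctx(data, fixed, rstruct, gstruct, method)
  K <- ctx$K
  dec <- list(
    Sig = lapply(ctx$glev, function(g)
      r_block_from_params(rstruct$type, K, rparams[[g]])),
    gs = if (length(gstruct$years) == 0L) NULL
         else if (!is.null(M)) list(kind = "chol", Lm = t(chol(M)))
         else list(kind = "diag", tau = sigma2))
  ctx$layout$profile <- FALSE
  eval_core(numeric(0), ctx, want = "value", dec = dec)$value
}

#' Generalized least squares with a known covariance
#'
#' Solves beta = (X' V^-1 X)^-1 X' V^-1 y through Cholesky factorization
#' (never an explicit inverse of V) and returns the estimate with its
#' covariance.
#'
#' @param X n x p design matrix of full column rank.
#' @param V n x n positive-definite covariance.
#' @param y response vector.
#' @return list with `beta` and `cov` ((X'V^-1 X)^-1).
#' @export
profile_beta <- function(X, V, y) {
  L <- chol(V)
  Xt <- backsolve(L, X, transpose = TRUE)
  yt <- backsolve(L, y, transpose = TRUE)
  qx <- qr(Xt)
  if (qx$rank < ncol(X))
    stop("X is rank deficient (aliased columns): ",
         paste(colnames(X)[qx$pivot[-seq_len(qx$rank)]], collapse = ", "))
  XtX <- crossprod(Xt)
  ch <- chol(XtX)
  beta <- backsolve(ch, backsolve(ch, crossprod(Xt, yt), transpose = TRUE))
  list(beta = as.numeric(beta), cov = chol2inv(ch))
}
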