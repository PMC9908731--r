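#' Residual (R-side) covariance specification
#'
#' The residual covariance is block diagonal with one K x K block per plot
#' (K repeated-measures years). Blocks follow one of three structures —
#' compound symmetry (`"cs"`: common variance v, common covariance c),
#' first-order autoregressive (`"ar1"`: variance v, lag-one correlation rho)
#' or unstructured (`"un"`: any symmetric positive-definite K x K matrix) —
#' and can be shared by all plots (`"pooled"`), differ between monocultures
#' and mixtures (`"monomix"`), or differ across functional-group
#' monocultures with a common mixture block (`"fgmono"`; with T functional
#' groups this gives T + 1 distinct blocks).
#'
#' @param type `"cs"`, `"ar1"` or `"un"`.
#' @param groups `"pooled"`, `"monomix"` or `"fgmono"`.
#' @return an object of class `"di_rstruct"`.
#' @export
di_rstruct <- function(type = c("cs", "ar1", "un"),
                       groups = c("pooled", "monomix", "fgmono")) {
  out <- list(type = match.arg(type), groups = match.arg(groups))
  class(out) <- "di_rstruct"
  out
}

#' Random-effect (G-side) covariance specification
#'
#' Pair-by-year random interaction effects d_ijk share one variance per year
#' (sigma_k^2) across all species pairs, so G is block diagonal with one
#' identical K_a x K_a block M per pair (K_a = number of active years). With
#' `year_cov = TRUE` the M block additionally carries off-diagonal
#' year-to-year covariances (still shared across pairs).
#'
#' @param years integer vector of years with active random interactions
#'   (empty = no random effects).
#' @param year_cov allow nonzero covariances between years within M.
#' @return an object of class `"di_gstruct"`.
#' @export
di_gstruct <- function(years = integer(0), year_cov = FALSE) {
  out <- list(years = sort(unique(as.integer(years))),
              year_cov = isTRUE(year_cov))
  class(out) <- "di_gstruct"
  out
}

# ---- block builders ---------------------------------------------------------

#' Repeated-measures covariance blocks
#'
#' `cs_block()` and `ar1_block()` build single K x K residual blocks;
#' exported mainly for direct inspection and testing.
#'
#' @param K block dimension (years).
#' @param v variance (diagonal value), `v > 0`.
#' @param c covariance (CS off-diagonal); positive-definiteness requires
#'   `-v/(K-1) < c < v`.
#' @param rho AR(1) lag-one correlation in (-1, 1).
#' @return K x K numeric matrix.
#' @export
cs_block <- function(K, v, c) {
  if (v <= 0) stop("CS variance must be positive")
  if (c >= v || c <= -v / (K - 1)) stop("CS block not positive definite")
  m <- matrix(c, K, K); diag(m) <- v
  m
}

#' @rdname cs_block
#' @export
ar1_block <- function(K, v, rho) {
  if (v <= 0) stop("AR1 variance must be positive")
  if (abs(rho) >= 1) stop("AR1 correlation must be in (-1, 1)")
  v * rho^abs(outer(seq_len(K), seq_len(K), "-"))
}

# map each plot to its residual-covariance group label
r_groups <- function(data, groups) {
  plots <- !duplicated(data$plot)
  rich <- di_richness(data)[plots]
  lab <- switch(groups,
    pooled  = rep("all", sum(plots)),
    monomix = ifelse(rich == 1L, "mono", "mix"),
    fgmono  = {
      pool <- di_pool(data)
      P <- prop_matrix(data)[plots, , drop = FALSE]
      mono_sp <- apply(P, 1L, which.max)
      ifelse(rich == 1L,
             paste0("mono:", as.character(pool$fg[mono_sp])), "mix")
    })
  names(lab) <- data$plot[plots]
  lab
}

#' Build the full residual covariance matrix R
#'
#' Assembles the n x n block-diagonal residual covariance from per-group
#' K x K blocks. Plots with fewer than K observed years receive the
#' corresponding sub-block (row/column deletion). Mostly useful for audit and
#' testing; the fitting engine factors the blocks directly.
#'
#' @param data a [di_data()] (rows ordered plot-major, year-minor, as
#'   constructed).
#' @param rstruct a [di_rstruct()].
#' @param params named list mapping each group label (see Details) to its
#'   block parameters: CS `list(v=, c=)`, AR1 `list(v=, rho=)`, UN
#'   `list(S = <K x K PD matrix>)`.
#' @details Group labels are `"all"` (pooled), `"mono"`/`"mix"` (monomix) or
#'   `"mono:<FG>"` and `"mix"` (fgmono).
#' @return n x n numeric matrix, plus attribute `groups` (per-plot labels).
#' @export
build_R <- function(data, rstruct, params) {
  K <- di_K(data)
  grp <- r_groups(data, rstruct$groups)
  blocks <- lapply(params, function(p) r_block_from_params(rstruct$type, K, p))
  miss <- setdiff(unique(grp), names(blocks))
  if (length(miss)) stop("no parameters for group(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(data)
  R <- matrix(0, n, n)
  for (pl in names(grp)) {
    rows <- which(data$plot == pl)
    yrs <- data$year[rows]
    R[rows, rows] <- blocks[[grp[[pl]]]][yrs, yrs, drop = FALSE]
  }
  attr(R, "groups") <- grp
  R
}

r_block_from_params <- function(type, K, p) {
  switch(type,
    cs  = cs_block(K, p$v, p$c),
    ar1 = ar1_block(K, p$v, p$rho),
    un  = {
      S <- p$S
      stopifnot(is.matrix(S), nrow(S) == K, isSymmetric(unname(S)))
      if (inherits(try(chol(S), silent = TRUE), "try-error"))
        stop("UN block is not positive definite")
      S
    })
}

#' Build the random-effects covariance matrix G
#'
#' G is block diagonal with `n_pairs` identical blocks M; without year
#' covariance M = diag(sigma_k^2) over the active years.
#'
#' @param n_pairs number of species pairs (blocks).
#' @param sigma2 nonnegative yearly variances (length = number of active
#'   years), or `NULL` when `M` is given.
#' @param M optional full (active years) x (active years) PSD block shared
#'   by all pairs.
#' @return block-diagonal numeric matrix of size `n_pairs * nrow(M)`.
#' @export
build_G <- function(n_pairs, sigma2 = NULL, M = NULL) {
  if (is.null(M)) {
    if (any(sigma2 < 0)) stop("yearly random-effect variances must be >= 0")
    M <- diag(sigma2, nrow = length(sigma2))
  } else {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("M block is not PSD")
  }
  Ka <- nrow(M)
  G <- matrix(0, n_pairs * Ka, n_pairs * Ka)
  for (b in seq_len(n_pairs)) {
    ix <- (b - 1L) * Ka + seq_len(Ka)
    G[ix, ix] <- M
  }
  G
}

#' Marginal covariance of the observations
#'
#' V = Z G Z' + R. Note V is generally *not* block diagonal by plot: two
#' plots sharing a species pair in a given year are correlated through that
#' pair's random interaction effect.
#'
#' @param Z random design matrix ([build_Z()]).
#' @param G random-effect covariance ([build_G()]).
#' @param R residual covariance ([build_R()]).
#' @return n x n symmetric positive-definite matrix.
#' @export
marginal_covariance <- function(Z, G, R) {
  if (ncol(Z) != nrow(G)) stop("Z and G are not conformable")
  if (nrow(Z) != nrow(R)) stop("Z and R are not conformable")
  if (ncol(Z) == 0L) return(R)
  Z %*% G %*% t(Z) + R
}
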