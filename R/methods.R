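#' @export
print.dimix <- function(x, ...) {
  cat("Multi-year Diversity-Interactions mixed model (", x$method, ")\n",
      sep = "")
  print(x$fixed)
  cat("Residual blocks: ", toupper(x$rstruct$type), ", grouping ",
      x$rstruct$groups, "\n", sep = "")
  if (length(x$gstruct$years))
    cat("Random pairwise interactions in year(s): ",
        paste(x$gstruct$years, collapse = ", "),
        if (x$gstruct$year_cov) " (with year covariance)", "\n", sep = "")
  if (!x$converged) {
    cat("** fit did not converge (", x$restarts, " restarts) **\n", sep = "")
    return(invisible(x))
  }
  cat("n = ", x$n, ", fixed effects = ", x$p,
      ", variance parameters = ", x$npar - x$p, "\n", sep = "")
  cat("-2 logLik = ", format(x$neg2ll, digits = 8), "  (", x$restarts,
      " restarts)\n", sep = "")
  invisible(x)
}

#' Summarize a fitted DI mixed model
#'
#' @param object a fitted [dimix()] model.
#' @param ... unused.
#' @return an object of class `"summary.dimix"`: coefficient table with
#'   standard errors, variance-parameter estimates, and fit statistics.
#' @export
summary.dimix <- function(object, ...) {
  if (!object$converged) stop("model did not converge")
  se <- sqrt(diag(object$vcov_beta))
  tab <- cbind(Estimate = object$beta, `Std. Error` = se,
               `z value` = object$beta / se)
  out <- list(call = object$call, coefficients = tab,
              varpar = object$varpar, method = object$method,
              neg2ll = object$neg2ll, npar = object$npar, n = object$n,
              dropped = object$dropped,
              blup_summary = blup_qq_summary(object))
  class(out) <- "summary.dimix"
  out
}

#' @export
print.summary.dimix <- function(x, ...) {
  cat("Fixed effects (", x$method, "):\n", sep = "")
  stats::printCoefmat(x$coefficients, ...)
  cat("\nResidual covariance blocks:\n")
  for (g in names(x$varpar$rside)) {
    p <- x$varpar$rside[[g]]
    cat("  ", g, ": ", paste(names(unlist(p)),
        signif(unlist(p), 5), sep = " = ", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$varpar$gside)) {
    cat("Random pairwise-interaction variances:\n")
    print(signif(x$varpar$gside$sigma2, 5))
  }
  if (length(x$dropped))
    cat("Non-estimable (aliased, dropped):",
        paste(x$dropped, collapse = ", "), "\n")
  cat("-2 logLik =", format(x$neg2ll, digits = 8),
      " parameters =", x$npar, " n =", x$n, "\n")
  if (!is.null(x$blup_summary)) {
    cat("\nBLUP normality check (per year):\n")
    print(x$blup_summary, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.dimix <- function(object, ...) object$beta

#' @export
vcov.dimix <- function(object, ...) object$vcov_beta

#' @export
logLik.dimix <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.dimix <- function(object, ...) as.numeric(object$X %*% object$beta)

#' @export
residuals.dimix <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$y - fitted(object)
  if (type == "conditional" && !is.null(object$blups))
    r <- r - as.numeric(object$Z %*% object$blups$d)
  r
}

#' Best linear unbiased predictors of the pairwise interaction effects
#'
#' Returns the BLUPs d_hat_ijk = G Z' V^-1 (y - X beta_hat) of the
#' pair-by-year random interaction effects, labelled by species pair and
#' year. For years with variance estimated at the zero boundary all BLUPs
#' are zero.
#'
#' @param fit a converged [dimix()] fit with active random-interaction years.
#' @return data frame with columns `pair`, `i`, `j`, `year`, `d`; `NULL`
#'   when the model has no random effects.
#' @export
blups <- function(fit) {
  stopifnot(inherits(fit, "dimix"))
  fit$blups
}

# per-year normal QQ summary of BLUPs (correlation with normal quantiles)
blup_qq_summary <- function(fit) {
  b <- fit$blups
  if (is.null(b) || !nrow(b)) return(NULL)
  do.call(rbind, lapply(split(b$d, b$year), function(d) {
    qn <- stats::qnorm(stats::ppoints(length(d)))
    data.frame(n = length(d), sd = stats::sd(d),
               qq_cor = if (stats::sd(d) > 0) stats::cor(sort(d), qn) else NA_real_)
  })) -> s
  s$year <- as.integer(rownames(s))
  s[, c("year", "n", "sd", "qq_cor")]
}

#' Predict expected responses for communities
#'
#' Computes the fixed-effects linear predictor (and its standard error from
#' the fixed-effect covariance) for new communities. Rows of `newdata` give
#' species proportions, a `year`, and for mixtures a `treatment` level when
#' the model crosses interactions with treatment. When the model contains
#' block effects and `newdata` has no `block` column (or `NA` blocks),
#' predictions are at the average block level. Columns dropped from the
#' training design as aliased are non-estimable: rows with nonzero values in
#' such columns trigger a warning.
#'
#' @param object a converged [dimix()] fit.
#' @param newdata data frame with one column per pool species plus `year`
#'   and optionally `treatment`, `block`.
#' @param se.fit return standard errors alongside predictions.
#' @param ... unused.
#' @return numeric vector of predictions, or a list with `fit` and `se.fit`.
#' @export
predict.dimix <- function(object, newdata, se.fit = FALSE, ...) {
  if (!object$converged) stop("model did not converge")
  pool <- object$pool
  nd <- as.data.frame(newdata)
  miss <- setdiff(pool$species, names(nd))
  if (length(miss)) stop("newdata lacks proportion columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(nd$year)) stop("newdata needs a 'year' column")
  if (any(!(nd$year %in% seq_len(object$K))))
    stop("year outside the modeled 1..K range")
  if (is.null(nd$treatment)) nd$treatment <- "none"
  if (is.null(nd$block)) nd$block <- NA
  if (is.null(nd$y)) nd$y <- NA_real_
  if (is.null(nd$plot)) nd$plot <- paste0("new", seq_len(nrow(nd)))
  P <- as.matrix(nd[, pool$species, drop = FALSE])
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop("newdata proportions must sum to 1")
  rich <- rowSums(P > 1e-6)
  nd$treatment[rich == 1L] <- "none"
  attr(nd, "pool") <- pool
  attr(nd, "K") <- object$K
  class(nd) <- c("di_data", "data.frame")
  bx <- build_X(nd, object$fixed, tlevels = object$tlevels,
                blevels = object$blevels, drop_aliased = FALSE)
  Xn <- bx$X
  if (length(object$dropped)) {
    inal <- intersect(object$dropped, colnames(Xn))
    if (length(inal) && any(abs(Xn[, inal, drop = FALSE]) > 1e-12))
      warning("prediction involves non-estimable (aliased) terms; ",
              "their contribution is omitted")
  }
  keep <- names(object$beta)
  missing_cols <- setdiff(keep, colnames(Xn))
  if (length(missing_cols))
    stop("cannot reconstruct design columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  Xn <- Xn[, keep, drop = FALSE]
  est <- as.numeric(Xn %*% object$beta)
  if (!se.fit) return(est)
  se <- sqrt(pmax(rowSums((Xn %*% object$vcov_beta) * Xn), 0))
  list(fit = est, se.fit = se)
}

#' Simulate responses from a fitted DI mixed model
#'
#' Draws new response vectors y* = X beta_hat + Z u* + e* with u* from the
#' estimated G and e* from the estimated R.
#'
#' @param object a converged [dimix()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns, rows aligned with the model data.
#' @export
simulate.dimix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("model did not converge")
  if (!is.null(seed)) set.seed(seed)
  data <- object$data
  mu <- fitted(object)
  n <- object$n
  grp <- r_groups(data, object$rstruct$groups)
  blocks <- lapply(object$varpar$rside, function(p)
    r_block_from_params(object$rstruct$type, object$K, p))
  out <- matrix(0, n, nsim)
  plots <- split(seq_len(n), factor(data$plot, levels = unique(data$plot)))
  for (s in seq_len(nsim)) {
    ys <- mu
    if (object$q > 0L) {
      if (!is.null(object$varpar$gside$M)) {
        Lm <- t(chol(object$varpar$gside$M))
        u <- as.numeric(Lm %*% matrix(stats::rnorm(object$q), nrow(Lm)))
      } else {
        sig2 <- object$varpar$gside$sigma2
        u <- stats::rnorm(object$q, 0,
                          sqrt(sig2[match(attr(object$Z, "col_year"),
                                          object$gstruct$years)]))
      }
      ys <- ys + as.numeric(object$Z %*% u)
    }
    for (pl in names(plots)) {
      rows <- plots[[pl]]
      S <- blocks[[grp[[pl]]]][data$year[rows], data$year[rows], drop = FALSE]
      ys[rows] <- ys[rows] + as.numeric(t(chol(S)) %*% stats::rnorm(length(rows)))
    }
    out[, s] <- ys
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Likelihood-ratio comparison of two nested DI mixed models
#'
#' `anova()` on two fits delegates to [di_lrt()]; pass `boundary = TRUE`
#' when the null pins a single variance component at zero.
#'
#' @param object,... two fitted [dimix()] models (null first).
#' @param boundary halve the chi-square(1) p-value for a variance component
#'   tested on its boundary.
#' @export
anova.dimix <- function(object, ..., boundary = FALSE) {
  alt <- list(...)
  if (!length(alt) || !inherits(alt[[1]], "dimix"))
    stop("supply the alternative model as the second argument")
  di_lrt(object, alt[[1]], boundary = boundary)
}
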