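#' Likelihood-ratio test between nested DI mixed models
#'
#' The statistic is the difference of -2 log-likelihoods (clipped at zero)
#' referred to a chi-square with df equal to the parameter-count difference.
#' When a single variance component is tested on its zero boundary
#' (`boundary = TRUE`, df must be 1), the null distribution is the 50:50
#' mixture of a point mass at zero and chi-square(1), so the chi-square(1)
#' upper-tail p-value is halved. Fixed-effect comparisons must use ML fits;
#' variance-structure comparisons must use REML fits with identical fixed
#' effects — both are enforced.
#'
#' @param null,alt fitted [dimix()] models on the same data, null nested in
#'   alt, fitted with the same method.
#' @param boundary is a single variance component being tested at its zero
#'   boundary?
#' @return an object of class `"di_lrt"` with `statistic`, `df`, `p_value`,
#'   `boundary_halved`, `method`.
#' @examples
#' # the halved boundary p-values for statistics 0, 0.4 and 5.6 on 1 df:
#' sapply(c(0, 0.4, 5.6), function(s) 0.5 * pchisq(s, 1, lower.tail = FALSE))
#' @export
di_lrt <- function(null, alt, boundary = FALSE) {
  stopifnot(inherits(null, "dimix"), inherits(alt, "dimix"))
  if (null$method != alt$method)
    stop("models were fitted with different methods (", null$method,
         " vs ", alt$method, ")")
  if (!null$converged || !alt$converged)
    stop("both models must have converged")
  if (null$n != alt$n) stop("models were fitted to different data")
  if (alt$npar <= null$npar)
    stop("alternative must have more parameters than the null")
  if (null$method == "REML" &&
      !identical(names(null$beta), names(alt$beta)))
    stop("REML comparisons require identical fixed effects")
  if (null$method == "ML" &&
      identical(names(null$beta), names(alt$beta)) &&
      !var_spec_differs(null, alt))
    stop("models are not nested with a parameter difference")
  stat <- max(0, null$neg2ll - alt$neg2ll)
  df <- alt$npar - null$npar
  if (boundary && df != 1L)
    stop("boundary halving applies only to a single variance component (df = 1)")
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  if (boundary) p <- p / 2
  out <- list(statistic = stat, df = df, p_value = p,
              boundary_halved = isTRUE(boundary), method = null$method)
  class(out) <- "di_lrt"
  out
}

var_spec_differs <- function(a, b) {
  !identical(a$rstruct, b$rstruct) || !identical(a$gstruct, b$gstruct)
}

#' @export
print.di_lrt <- function(x, ...) {
  cat("Likelihood ratio test (", x$method, "): LRT = ",
      format(x$statistic, digits = 4), ", df = ", x$df,
      ", p = ", format.pval(x$p_value, digits = 3),
      if (x$boundary_halved) "  [boundary-halved]", "\n", sep = "")
  invisible(x)
}

#' Yearly boundary tests for random pairwise interactions
#'
#' Fits the base model by REML without random pairwise interactions, then
#' for each year k refits with random interactions active in year k only and
#' compares by a boundary-halved chi-square(1) likelihood-ratio test. Years
#' whose halved p-value falls below `alpha` are flagged; the recommended
#' model activates exactly the significant years.
#'
#' @param data a [di_data()] with responses.
#' @param fixed,rstruct fixed-effect and residual specifications shared by
#'   all fits.
#' @param alpha significance level (default 0.05).
#' @param control optimizer control.
#' @return an object of class `"di_yearly_test"`: data frame `tests` (year,
#'   statistic, df, p, significant, converged), `significant_years`, and the
#'   base fit.
#' @export
test_yearly_interactions <- function(data, fixed = di_fixed("fg"),
                                     rstruct = di_rstruct("cs"),
                                     alpha = 0.05,
                                     control = dimix_control()) {
  base <- dimix(data, fixed, rstruct, di_gstruct(), method = "REML",
                control = control)
  K <- di_K(data)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    altk <- dimix(data, fixed, rstruct, di_gstruct(years = k),
                  method = "REML", control = control)
    if (base$converged && altk$converged) {
      lr <- di_lrt(base, altk, boundary = TRUE)
      rows[[k]] <- data.frame(year = k, statistic = lr$statistic, df = lr$df,
                              p = lr$p_value, significant = lr$p_value < alpha,
                              converged = TRUE)
    } else {
      rows[[k]] <- data.frame(year = k, statistic = NA_real_, df = 1L,
                              p = NA_real_, significant = NA, converged = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  out <- list(tests = tests,
              significant_years = tests$year[which(tests$significant)],
              alpha = alpha, base = base)
  class(out) <- "di_yearly_test"
  out
}

#' @export
print.di_yearly_test <- function(x, ...) {
  cat("Yearly random pairwise-interaction tests (REML, boundary-halved p)\n")
  print(x$tests, row.names = FALSE, digits = 4)
  cat("Significant years at alpha =", x$alpha, ":",
      if (length(x$significant_years))
        paste(x$significant_years, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Stepwise selection of a multi-year DI model
#'
#' Runs the four-step selection workflow: (1) choose the fixed interaction
#' structure by ML likelihood-ratio tests under a baseline residual
#' structure; (2) choose the repeated-measures residual structure and plot
#' grouping by REML LRTs holding the step-1 fixed effects; (3) re-check the
#' fixed structure under the chosen residual structure and test treatment
#' and covariate crossings of the interaction terms by ML; (4) test random
#' pairwise interactions year by year with boundary-halved REML LRTs and
#' activate the significant years. Every comparison is recorded in an
#' auditable trace.
#'
#' Structure nesting is identity < average < fg < full, with `additive` also
#' compared against `average`; when both `fg` and `additive` improve on
#' `average`, the one with smaller -2 logLik wins (recorded in the trace).
#' Candidates that fail to converge are treated as not selected and logged.
#'
#' @param data a [di_data()] with responses.
#' @param structures fixed structures to consider, in nesting order.
#' @param rtypes residual block types to consider.
#' @param rgroups residual grouping menu (ordered pooled < monomix < fgmono).
#' @param alpha significance level for every LRT.
#' @param step1_rstruct baseline residual structure for step 1.
#' @param test_treatment,covariate step-3 crossings: cross interactions with
#'   the spatial-pattern treatment; scale additive interactions by the
#'   summed proportion of `covariate` species (skipped when `NULL`).
#' @param control optimizer control.
#' @return an object of class `"di_selection"`: `trace` data frame
#'   (step, comparison, statistic, df, p, decision), `fixed`, `rstruct`,
#'   `gstruct` of the selected model, and the final `fit`.
#' @export
di_select <- function(data,
                      structures = c("identity", "average", "fg", "additive"),
                      rtypes = c("cs", "ar1", "un"),
                      rgroups = c("pooled", "monomix", "fgmono"),
                      alpha = 0.05,
                      step1_rstruct = di_rstruct("un", "pooled"),
                      test_treatment = FALSE, covariate = NULL,
                      control = dimix_control()) {
  trace <- list()
  note <- function(step, comparison, lr, decision) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, comparison = comparison,
      statistic = if (is.null(lr)) NA_real_ else lr$statistic,
      df = if (is.null(lr)) NA_integer_ else lr$df,
      p = if (is.null(lr)) NA_real_ else lr$p_value,
      decision = decision, stringsAsFactors = FALSE)
  }
  fit_struct <- function(str, rst, method) {
    dimix(data, di_fixed(str), rst, di_gstruct(), method = method,
          control = control)
  }
  pick_structure <- function(rst, step_label) {
    fits <- list()
    getfit <- function(s) {
      if (is.null(fits[[s]])) fits[[s]] <<- fit_struct(s, rst, "ML")
      fits[[s]]
    }
    current <- structures[1L]
    chain <- intersect(c("average"), structures)
    for (s in chain) {
      f0 <- getfit(current); f1 <- getfit(s)
      if (!f1$converged) { note(step_label, paste(s, "vs", current), NULL,
                                paste(s, "did not converge")) ; next }
      lr <- di_lrt(f0, f1)
      sel <- lr$p_value < alpha
      note(step_label, paste(s, "vs", current), lr,
           if (sel) paste("adopt", s) else paste("keep", current))
      if (sel) current <- s
    }
    mids <- intersect(c("fg", "additive"), structures)
    winners <- character(0)
    for (s in mids) {
      f0 <- getfit(current); f1 <- getfit(s)
      if (!f1$converged) { note(step_label, paste(s, "vs", current), NULL,
                                paste(s, "did not converge")); next }
      lr <- di_lrt(f0, f1)
      sel <- lr$p_value < alpha
      note(step_label, paste(s, "vs", current), lr,
           if (sel) paste(s, "improves on", current) else paste("keep", current))
      if (sel) winners <- c(winners, s)
    }
    if (length(winners) == 1L) current <- winners
    if (length(winners) == 2L) {
      n2 <- vapply(winners, function(s) getfit(s)$neg2ll, numeric(1))
      current <- winners[which.min(n2)]
      note(step_label, "fg vs additive (non-nested)", NULL,
           paste("choose", current, "by smaller -2 logLik"))
    }
    if ("full" %in% structures) {
      f0 <- getfit(current); f1 <- getfit("full")
      if (f1$converged) {
        lr <- di_lrt(f0, f1)
        sel <- lr$p_value < alpha
        note(step_label, paste("full vs", current), lr,
             if (sel) "adopt full" else paste("keep", current))
        if (sel) current <- "full"
      } else note(step_label, paste("full vs", current), NULL,
                  "full did not converge")
    }
    current
  }

  # step 1: fixed structure under the baseline residual structure
  str1 <- pick_structure(step1_rstruct, "1:fixed")

  # step 2: residual type, then grouping, REML with fixed effects held
  cur_rst <- di_rstruct(rtypes[1L], "pooled")
  remlfit <- function(rst) dimix(data, di_fixed(str1), rst, di_gstruct(),
                                 method = "REML", control = control)
  fits2 <- list()
  g2 <- function(rst) {
    key <- paste(rst$type, rst$groups)
    if (is.null(fits2[[key]])) fits2[[key]] <<- remlfit(rst)
    fits2[[key]]
  }
  if (all(c("cs", "ar1") %in% rtypes)) {
    fcs <- g2(di_rstruct("cs", "pooled")); far <- g2(di_rstruct("ar1", "pooled"))
    if (fcs$converged && far$converged) {
      pick <- if (far$neg2ll < fcs$neg2ll) "ar1" else "cs"
      note("2:rstruct", "cs vs ar1 (non-nested)", NULL,
           paste("choose", pick, "by smaller -2 logLik"))
      cur_rst <- di_rstruct(pick, "pooled")
    }
  } else cur_rst <- di_rstruct(intersect(rtypes, c("cs", "ar1", "un"))[1L], "pooled")
  if ("un" %in% rtypes && cur_rst$type != "un") {
    f0 <- g2(cur_rst); f1 <- g2(di_rstruct("un", "pooled"))
    if (f1$converged) {
      lr <- di_lrt(f0, f1)
      sel <- lr$p_value < alpha
      note("2:rstruct", paste("un vs", cur_rst$type), lr,
           if (sel) "adopt un" else paste("keep", cur_rst$type))
      if (sel) cur_rst <- di_rstruct("un", "pooled")
    } else note("2:rstruct", paste("un vs", cur_rst$type), NULL,
                "un did not converge")
  }
  grp_order <- intersect(c("pooled", "monomix", "fgmono"), rgroups)
  for (gi in seq_along(grp_order)[-1L]) {
    f0 <- g2(di_rstruct(cur_rst$type, grp_order[gi - 1L]))
    f1 <- g2(di_rstruct(cur_rst$type, grp_order[gi]))
    if (!f1$converged) { note("2:rgroups", paste(grp_order[gi], "vs",
        grp_order[gi - 1L]), NULL, "did not converge"); break }
    lr <- di_lrt(f0, f1)
    sel <- lr$p_value < alpha
    note("2:rgroups", paste(grp_order[gi], "vs", grp_order[gi - 1L]), lr,
         if (sel) paste("adopt", grp_order[gi])
         else paste("keep", grp_order[gi - 1L]))
    if (!sel) break
    cur_rst <- di_rstruct(cur_rst$type, grp_order[gi])
  }

  # step 3: re-check fixed structure under the chosen residual structure,
  # then treatment / covariate crossings by ML
  str3 <- if (!identical(cur_rst, step1_rstruct))
    pick_structure(cur_rst, "3:fixed-recheck") else str1
  fixed_sel <- di_fixed(str3)
  f_base <- dimix(data, fixed_sel, cur_rst, di_gstruct(), method = "ML",
                  control = control)
  if (test_treatment && str3 != "identity" &&
      length(unique(data$treatment[data$treatment != "none"])) > 1L) {
    fx <- di_fixed(terms = list(di_term(str3, treatment = TRUE)))
    f1 <- dimix(data, fx, cur_rst, di_gstruct(), method = "ML",
                control = control)
    if (f1$converged) {
      lr <- di_lrt(f_base, f1)
      sel <- lr$p_value < alpha
      note("3:crossings", paste(str3, "x treatment"), lr,
           if (sel) "adopt treatment crossing" else "no treatment crossing")
      if (sel) { fixed_sel <- fx; f_base <- f1 }
    } else note("3:crossings", paste(str3, "x treatment"), NULL,
                "did not converge")
  }
  if (!is.null(covariate)) {
    fx <- di_fixed(terms = c(fixed_sel$terms,
                             list(di_term("additive", covariate = covariate))))
    f1 <- dimix(data, fx, cur_rst, di_gstruct(), method = "ML",
                control = control)
    if (f1$converged) {
      lr <- di_lrt(f_base, f1)
      sel <- lr$p_value < alpha
      note("3:crossings", "additive x covariate", lr,
           if (sel) "adopt covariate term" else "no covariate term")
      if (sel) { fixed_sel <- fx; f_base <- f1 }
    } else note("3:crossings", "additive x covariate", NULL,
                "did not converge")
  }

  # step 4: yearly random pairwise interactions (REML, halved p)
  yt <- test_yearly_interactions(data, fixed_sel, cur_rst, alpha = alpha,
                                 control = control)
  for (r in seq_len(nrow(yt$tests))) {
    tr <- yt$tests[r, ]
    note("4:random-years", paste("random interactions year", tr$year),
         if (tr$converged) list(statistic = tr$statistic, df = tr$df,
                                p_value = tr$p) else NULL,
         if (!tr$converged) "did not converge"
         else if (isTRUE(tr$significant)) "include year" else "exclude year")
  }
  gsel <- di_gstruct(years = yt$significant_years)
  final <- dimix(data, fixed_sel, cur_rst, gsel, method = "REML",
                 control = control)
  out <- list(trace = do.call(rbind, trace), fixed = fixed_sel,
              rstruct = cur_rst, gstruct = gsel, fit = final, alpha = alpha)
  class(out) <- "di_selection"
  out
}

#' @export
print.di_selection <- function(x, ...) {
  cat("Stepwise DI model selection (alpha = ", x$alpha, ")\n", sep = "")
  print(x$trace, row.names = FALSE, digits = 4)
  cat("\nSelected model:\n")
  print(x$fit)
  invisible(x)
}
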