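#' Built-in fixed-effect values for the simulation study
#'
#' Returns a default set of identity and functional-group interaction
#' effects used to simulate multi-year DI responses: distinct per-species
#' identity effects that change across years, and distinct within- and
#' between-FG interaction values per year (response scale: grams of weed
#' biomass per plot, matching residual standard deviations of 100-300). The
#' REML variance-component tests at the heart of the power study are
#' invariant to these values as long as the fitted fixed model contains the
#' true mean structure; that invariance is a tested property of the package.
#'
#' @param pool a [species_pool()].
#' @param K number of years.
#' @return list with `beta` (species x year matrix) and `omega`
#'   (FG-interaction-class x year matrix, rows ordered as the FG interaction
#'   columns).
#' @export
di_sim_effects <- function(pool, K = 3L) {
  s <- pool$n_species
  beta <- outer(seq_len(s), seq_len(K),
                function(i, k) 1200 + 180 * i + c(0, 700, 350)[pmin(k, 3)] -
                  60 * i * (k - 1))
  rownames(beta) <- pool$species
  colnames(beta) <- paste0("y", seq_len(K))
  cls <- unique_fg_classes(pool)
  base <- seq(-2200, 1800, length.out = length(cls))
  omega <- outer(seq_along(cls), seq_len(K),
                 function(a, k) base[a] * (1 + 0.25 * (k - 1) * (-1)^a))
  rownames(omega) <- cls
  colnames(omega) <- paste0("y", seq_len(K))
  list(beta = beta, omega = omega)
}

#' Simulate multi-year DI responses on a design skeleton
#'
#' Draws responses from the functional-group DI model with random pairwise
#' interactions: y = sum_i beta_ik P_ik + FG interaction terms +
#' sum_pairs d_ijk P_ik P_jk + e, where d_ijk ~ N(0, sd_pair^2) is drawn
#' independently per species pair and year but shared across all plots
#' containing the pair, and the per-plot residual K-vector follows compound
#' symmetry with variance sd_resid^2 and covariance resid_cor * sd_resid^2
#' (the study convention: covariance half the variance).
#'
#' @param design a [di_data()] skeleton (e.g. [design_a()]).
#' @param effects fixed-effect values from [di_sim_effects()].
#' @param sd_resid residual standard deviation (per year).
#' @param sd_pair random pairwise-interaction standard deviation: a scalar
#'   (the study convention, same in every year) or a length-K vector of
#'   per-year values; 0 disables the random effects.
#' @param resid_cor year-to-year residual correlation (default 0.5).
#' @param seed optional seed.
#' @return the design with simulated responses in `y`.
#' @export
simulate_response <- function(design, effects, sd_resid = 100, sd_pair = 0,
                              resid_cor = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pool <- di_pool(design)
  K <- di_K(design)
  Xid <- identity_columns(design, by_year = TRUE)
  Xfg <- interaction_columns(design, "fg", by_year = TRUE)
  mu <- as.numeric(Xid %*% as.numeric(effects$beta)) +
    as.numeric(Xfg %*% as.numeric(effects$omega))
  y <- mu
  sd_pair <- rep_len(sd_pair, K)
  if (any(sd_pair > 0)) {
    Z <- build_Z(design, years = seq_len(K))
    d <- stats::rnorm(ncol(Z), 0, sd_pair[attr(Z, "col_year")])
    y <- y + as.numeric(Z %*% d)
  }
  n <- nrow(design)
  if (n %% K != 0L)
    stop("simulate_response needs a balanced design (every plot in all years)")
  Sig <- sd_resid^2 * ((1 - resid_cor) * diag(K) + resid_cor)
  Lt <- t(chol(Sig))
  nplot <- n / K
  eps <- as.numeric(Lt %*% matrix(stats::rnorm(n), K, nplot))
  out <- design
  out$y <- y + eps
  out
}

#' Run one power / type-I-error simulation setting
#'
#' Simulates `reps` datasets at the given residual and random-interaction
#' standard deviations, fits the functional-group model with compound-
#' symmetry residuals by REML without random interactions, tests random
#' pairwise interactions year by year with boundary-halved LRTs, and
#' tallies how many datasets had 0, 1, 2 or 3 significant years. For
#' `sd_pair = 0` the family-level type-I error (at least one significant
#' year) is reported; for `sd_pair > 0` the power to flag all K years.
#' Datasets on which any fit fails to converge are counted and excluded
#' from denominators.
#'
#' @param sd_resid,sd_pair simulation standard deviations.
#' @param reps number of simulated datasets.
#' @param alpha per-test significance level.
#' @param seed base seed; dataset r uses `seed + r`.
#' @param design design skeleton (default [design_a()]).
#' @param effects fixed-effect values (default [di_sim_effects()]).
#' @param fixed,rstruct analysis model (defaults: FG structure, pooled CS).
#' @param control optimizer control.
#' @return object of class `"di_power_setting"` with counts and the
#'   estimated probability plus its binomial Monte-Carlo standard error.
#' @export
run_power_setting <- function(sd_resid, sd_pair, reps = 200, alpha = 0.05,
                              seed = 1, design = NULL, effects = NULL,
                              fixed = di_fixed("fg"),
                              rstruct = di_rstruct("cs"),
                              control = dimix_control()) {
  if (is.null(design)) design <- design_a(seed = 1)
  if (is.null(effects)) effects <- di_sim_effects(di_pool(design), di_K(design))
  K <- di_K(design)
  counts <- integer(K + 1L)
  names(counts) <- as.character(0:K)
  nonconv <- 0L
  for (r in seq_len(reps)) {
    d <- simulate_response(design, effects, sd_resid, sd_pair,
                           seed = seed + r)
    yt <- test_yearly_interactions(d, fixed, rstruct, alpha = alpha,
                                   control = control)
    if (any(!yt$tests$converged)) { nonconv <- nonconv + 1L; next }
    nsig <- sum(yt$tests$significant)
    counts[nsig + 1L] <- counts[nsig + 1L] + 1L
  }
  used <- reps - nonconv
  null_setting <- all(sd_pair == 0)
  prob <- if (null_setting) sum(counts[-1L]) / used else counts[K + 1L] / used
  out <- list(sd_resid = sd_resid, sd_pair = sd_pair, reps = reps,
              counts = counts, nonconverged = nonconv,
              type1_error = if (null_setting) prob else NA_real_,
              power = if (!null_setting) prob else NA_real_,
              mc_se = sqrt(prob * (1 - prob) / used), alpha = alpha)
  class(out) <- "di_power_setting"
  out
}

#' @export
print.di_power_setting <- function(x, ...) {
  cat("Setting sd_resid = ", x$sd_resid, ", sd_pair = ", x$sd_pair,
      " (", x$reps, " reps, ", x$nonconverged, " non-converged)\n", sep = "")
  cat("Datasets by number of significant years:\n")
  print(x$counts)
  if (!is.na(x$type1_error))
    cat("Type-I error (>=1 year): ", round(x$type1_error, 4),
        " +/- ", round(x$mc_se, 4), "\n", sep = "")
  if (!is.na(x$power))
    cat("Power (all years): ", round(x$power, 4),
        " +/- ", round(x$mc_se, 4), "\n", sep = "")
  invisible(x)
}

#' Fixed-structure selection frequencies under simulation
#'
#' Simulates `reps` datasets, fits the identity, average pairwise,
#' functional group and full pairwise fixed structures by ML with pooled
#' compound-symmetry residuals, selects a structure by sequential nested
#' LRTs at `alpha` (each richer structure tested against the current
#' selection in the order average, fg, full), and reports how often each
#' structure wins.
#'
#' @inheritParams run_power_setting
#' @return object of class `"di_structure_sel"` with per-structure counts
#'   and proportions.
#' @export
run_structure_selection <- function(sd_resid, sd_pair, reps = 200,
                                    alpha = 0.05, seed = 1, design = NULL,
                                    effects = NULL,
                                    control = dimix_control()) {
  if (is.null(design)) design <- design_a(seed = 1)
  if (is.null(effects)) effects <- di_sim_effects(di_pool(design), di_K(design))
  menu <- c("identity", "average", "fg", "full")
  wins <- stats::setNames(integer(4), menu)
  nonconv <- 0L
  rst <- di_rstruct("cs")
  for (r in seq_len(reps)) {
    d <- simulate_response(design, effects, sd_resid, sd_pair,
                           seed = seed + r)
    fits <- lapply(menu, function(s)
      dimix(d, di_fixed(s), rst, di_gstruct(), method = "ML",
            control = control))
    names(fits) <- menu
    if (any(!vapply(fits, `[[`, logical(1), "converged"))) {
      nonconv <- nonconv + 1L; next
    }
    # each richer structure is tested against the current selection, so a
    # weak average term cannot mask strong FG or full-pairwise structure
    sel <- "identity"
    for (s in c("average", "fg", "full")) {
      lr <- di_lrt(fits[[sel]], fits[[s]])
      if (lr$p_value < alpha) sel <- s
    }
    wins[sel] <- wins[sel] + 1L
  }
  used <- reps - nonconv
  out <- list(sd_resid = sd_resid, sd_pair = sd_pair, reps = reps,
              counts = wins, proportions = wins / used,
              nonconverged = nonconv, alpha = alpha)
  class(out) <- "di_structure_sel"
  out
}

#' @export
print.di_structure_sel <- function(x, ...) {
  cat("Fixed-structure selection (sd_resid = ", x$sd_resid,
      ", sd_pair = ", x$sd_pair, ", ", x$reps, " reps)\n", sep = "")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Run the full power / type-I-error study grid
#'
#' Crosses the residual and random-interaction standard deviations and runs
#' [run_power_setting()] for each combination, producing the study's summary
#' table: per setting, the counts of datasets with 0..K significant yearly
#' tests, the type-I error (settings with `sd_pair = 0`) or the power to
#' flag all years (`sd_pair > 0`).
#'
#' @param sd_resid_values,sd_pair_values grids of standard deviations; the
#'   study defaults are 100/200/300 and 0/500/1000/1500/2000/2500.
#' @param reps datasets per setting (the full study uses 1000; desk-scale
#'   runs use 200-300).
#' @param alpha per-test significance level.
#' @param seed base seed; setting s uses `seed + 10000 * (s - 1)`.
#' @param ... further arguments to [run_power_setting()].
#' @return object of class `"di_power_study"`: list of settings plus a
#'   summary data frame from [summarize_study()].
#' @export
power_study <- function(sd_resid_values = c(100, 200, 300),
                        sd_pair_values = c(0, 500, 1000, 1500, 2000, 2500),
                        reps = 200, alpha = 0.05, seed = 1, ...) {
  grid <- expand.grid(sd_pair = sd_pair_values, sd_resid = sd_resid_values)
  grid <- grid[order(grid$sd_resid, grid$sd_pair), , drop = FALSE]
  settings <- vector("list", nrow(grid))
  for (s in seq_len(nrow(grid))) {
    settings[[s]] <- run_power_setting(grid$sd_resid[s], grid$sd_pair[s],
                                       reps = reps, alpha = alpha,
                                       seed = seed + 10000 * (s - 1), ...)
  }
  out <- list(settings = settings, summary = summarize_study(settings))
  class(out) <- "di_power_study"
  out
}

#' Summarize power-study settings into the study table
#'
#' @param settings list of [run_power_setting()] results.
#' @return data frame with one row per setting: `sd_resid`, `sd_pair`, the
#'   significant-year counts, `type1_error` (`NA` for `sd_pair > 0` rows),
#'   `power` (`NA` for `sd_pair = 0` rows), `mc_se`, `nonconverged`.
#' @export
summarize_study <- function(settings) {
  stopifnot(length(settings) >= 1L)
  do.call(rbind, lapply(settings, function(s) {
    cnt <- as.list(s$counts)
    names(cnt) <- paste0("sig", names(s$counts))
    cbind(data.frame(sd_resid = s$sd_resid, sd_pair = s$sd_pair),
          as.data.frame(cnt),
          data.frame(type1_error = s$type1_error, power = s$power,
                     mc_se = s$mc_se, nonconverged = s$nonconverged))
  }))
}

#' @export
print.di_power_study <- function(x, ...) {
  cat("Power / type-I-error study (", length(x$settings), " settings)\n",
      sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
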