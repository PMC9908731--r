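#' Construct and validate a long-format Diversity-Interactions dataset
#'
#' The long format holds one row per plot and year with columns `plot`,
#' `block`, `year`, `treatment`, a response `y` (may be `NA` for design
#' skeletons) and one proportion column per species in the pool. Validation
#' checks that each plot appears once per year, that years form a contiguous
#' 1..K index, and that the proportions of every row sum to 1 within
#' `tolerance`. With `renormalize = TRUE`, rows whose proportions sum to a
#' positive value within `(0, 1 + tolerance]` are rescaled to sum to 1 and
#' recorded in the `renormalized` attribute.
#'
#' @param df data frame in the long schema described above.
#' @param pool a [species_pool()]; its species labels must match proportion
#'   columns of `df`.
#' @param tolerance allowed absolute deviation of a row's proportion sum
#'   from 1 (default `1e-6`).
#' @param renormalize rescale near-miss rows instead of failing.
#' @return `df`, ordered by (plot, year), with class `"di_data"` and
#'   attributes `pool`, `K` (number of years) and `renormalized` (row
#'   indices that were rescaled).
#' @seealso [design_a()], [space_design()], [read_di_csv()]
#' @export
di_data <- function(df, pool, tolerance = 1e-6, renormalize = FALSE) {
  stopifnot(inherits(pool, "species_pool"))
  df <- as.data.frame(df)
  need <- c("plot", "block", "year", "treatment", "y", pool$species)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  df$year <- as.integer(df$year)
  yrs <- sort(unique(df$year))
  if (!identical(yrs, seq_along(yrs)))
    stop("years must form a contiguous 1..K index, got: ",
         paste(yrs, collapse = ","))
  key <- paste(df$plot, df$year, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated plot-year rows: ",
         paste(unique(df$plot[duplicated(key)]), collapse = ", "))
  P <- as.matrix(df[, pool$species, drop = FALSE])
  if (!is.numeric(P) || anyNA(P) || any(P < -tolerance))
    stop("proportion columns must be numeric, non-missing and non-negative")
  rs <- rowSums(P)
  bad <- which(abs(rs - 1) > tolerance)
  renorm <- integer(0)
  if (length(bad)) {
    if (!renormalize)
      stop("proportions do not sum to 1 (tolerance ", tolerance,
           ") in rows: ", paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "")
    fixable <- bad[rs[bad] > 0 & rs[bad] <= 1 + tolerance]
    if (length(fixable) < length(bad))
      stop("proportions not renormalizable (sum <= 0 or > 1) in rows: ",
           paste(utils::head(setdiff(bad, fixable), 5L), collapse = ", "))
    P[fixable, ] <- P[fixable, , drop = FALSE] / rs[fixable]
    df[, pool$species] <- P
    renorm <- fixable
  }
  df$treatment <- as.character(df$treatment)
  richness <- rowSums(P > tolerance)
  df$treatment[richness == 1L] <- "none"
  ord <- order(df$plot, df$year)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "pool") <- pool
  attr(df, "K") <- length(yrs)
  attr(df, "renormalized") <- match(renorm, ord)
  class(df) <- c("di_data", "data.frame")
  df
}

#' @export
print.di_data <- function(x, ...) {
  pool <- attr(x, "pool")
  cat("Diversity-Interactions data: ", length(unique(x$plot)), " plots x ",
      attr(x, "K"), " years (", nrow(x), " rows), ",
      pool$n_species, " species in ", length(pool$fg_levels), " FGs\n",
      sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

di_pool <- function(data) attr(data, "pool")
di_K <- function(data) attr(data, "K")

# proportion matrix (rows aligned with data rows)
prop_matrix <- function(data) {
  as.matrix(as.data.frame(data)[, di_pool(data)$species, drop = FALSE])
}

di_richness <- function(data, tolerance = 1e-6) {
  rowSums(prop_matrix(data) > tolerance)
}

#' Replace predictor proportions with lagged realized proportions
#'
#' In multi-year DI models the proportions driving year k's response are the
#' planted proportions when k = 1 and the realized (measured end-of-season)
#' proportions of year k - 1 when k > 1. This helper rewrites the proportion
#' columns of a long dataset accordingly.
#'
#' @param data a [di_data()] whose proportion columns hold the planted
#'   proportions (replicated across years).
#' @param realized data frame with columns `plot`, `year` and one column per
#'   species, holding realized proportions measured at the end of each year
#'   `1..K-1`.
#' @param tolerance,renormalize passed to the revalidation of the result.
#' @return a new `di_data` with year-k predictor proportions equal to the
#'   planted proportions (k = 1) or realized proportions of year k - 1.
#' @export
lag_proportions <- function(data, realized, tolerance = 1e-6,
                            renormalize = FALSE) {
  pool <- di_pool(data)
  K <- di_K(data)
  realized <- as.data.frame(realized)
  out <- as.data.frame(data)
  if (K > 1L) {
    for (k in 2:K) {
      rows <- which(out$year == k)
      src <- realized[realized$year == k - 1L, , drop = FALSE]
      idx <- match(out$plot[rows], src$plot)
      if (anyNA(idx))
        stop("missing realized proportions for year ", k - 1L, ", plots: ",
             paste(utils::head(out$plot[rows][is.na(idx)], 5L), collapse = ", "))
      out[rows, pool$species] <- src[idx, pool$species]
    }
  }
  di_data(out, pool, tolerance = tolerance, renormalize = renormalize)
}
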