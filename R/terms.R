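#' Describe the fixed-effect structure of a Diversity-Interactions model
#'
#' A DI linear predictor is built from species identity columns (one per
#' species, per year by default) plus zero or more interaction terms. Each
#' interaction term uses one of the structures of the DI family:
#' \describe{
#'   \item{`average`}{one column, the sum of all pairwise products
#'     \eqn{\sum_{i<j} P_i P_j};}
#'   \item{`fg`}{within- and between-functional-group pair sums
#'     (T + choose(T,2) columns);}
#'   \item{`additive`}{one column per species, \eqn{P_i(1 - P_i)}, the
#'     closed form of \eqn{\sum_{j \ne i} P_i P_j};}
#'   \item{`full`}{one column per species pair, \eqn{P_i P_j}.}
#' }
#' A term may be crossed with the spatial-pattern treatment (one copy of each
#' column per treatment level, zero on rows of other levels; monoculture rows
#' are zero in every copy, so no monoculture treatment level is needed) and/or
#' scaled elementwise by a covariate computed from the proportions (for
#' example legume percentage, `covariate = <legume species>`).
#'
#' `di_fixed()` bundles identity columns, interaction terms, and block
#' effects (block-by-year contrasts, included when the data has more than one
#' block) into the model's fixed-effect specification.
#'
#' @param structure one of `"average"`, `"fg"`, `"additive"`, `"full"`.
#' @param treatment logical: cross this term's columns with the treatment
#'   factor?
#' @param covariate `NULL`, or a character vector of pool species whose
#'   summed proportion scales this term's columns.
#' @param by_year logical: separate coefficients per year (default `TRUE`,
#'   the repeated-measures convention).
#' @param terms list of [di_term()] objects; for convenience
#'   `di_fixed("fg")` is shorthand for one plain term of that structure and
#'   `di_fixed("identity")` for no interaction terms.
#' @param block include block effects when blocks are present?
#' @return an object of class `"di_fixed"` / `"di_term"`.
#' @export
di_term <- function(structure = c("average", "fg", "additive", "full"),
                    treatment = FALSE, covariate = NULL) {
  structure <- match.arg(structure)
  out <- list(structure = structure, treatment = isTRUE(treatment),
              covariate = covariate)
  class(out) <- "di_term"
  out
}

#' @rdname di_term
#' @export
di_fixed <- function(structure = "average", by_year = TRUE, terms = NULL,
                     block = TRUE) {
  if (is.null(terms)) {
    structure <- match.arg(structure,
                           c("identity", "average", "fg", "additive", "full"))
    terms <- if (structure == "identity") list() else list(di_term(structure))
  } else {
    stopifnot(all(vapply(terms, inherits, logical(1), "di_term")))
  }
  out <- list(by_year = isTRUE(by_year), terms = terms, block = isTRUE(block))
  class(out) <- "di_fixed"
  out
}

#' @export
print.di_fixed <- function(x, ...) {
  lab <- vapply(x$terms, function(t) {
    paste0(t$structure,
           if (t$treatment) " x treatment" else "",
           if (!is.null(t$covariate)) " x covariate" else "")
  }, character(1))
  cat("DI fixed effects: identities",
      if (length(lab)) paste("+", paste(lab, collapse = " + ")) else "(no interactions)",
      if (x$by_year) "[per year]" else "[pooled years]", "\n")
  invisible(x)
}

#' Species identity columns
#'
#' One column per pool species holding its proportion, split by year when
#' `by_year` so each year gets its own identity coefficients.
#'
#' @param data a [di_data()].
#' @param by_year separate columns per year.
#' @return numeric matrix with named columns.
#' @export
identity_columns <- function(data, by_year = TRUE) {
  P <- prop_matrix(data)
  colnames(P) <- paste0("id:", di_pool(data)$species)
  split_by_year(P, data, by_year)
}

#' Interaction columns for a DI structure
#'
#' Builds the pairwise-interaction block of the fixed design for one of the
#' structures described in [di_term()]. Monoculture rows are zero in every
#' interaction column.
#'
#' @param data a [di_data()].
#' @param structure `"average"`, `"fg"`, `"additive"` or `"full"`.
#' @param by_year separate columns per year.
#' @return numeric matrix with named columns.
#' @export
interaction_columns <- function(data,
                                structure = c("average", "fg", "additive", "full"),
                                by_year = FALSE) {
  structure <- match.arg(structure)
  pool <- di_pool(data)
  P <- prop_matrix(data)
  B <- switch(structure,
    average = {
      m <- cbind(0.5 * (rowSums(P)^2 - rowSums(P^2)))
      colnames(m) <- "avg"
      m
    },
    fg = {
      cls <- pair_fg_class(pool)
      pr <- pool_pairs(pool)
      PP <- P[, pr$i, drop = FALSE] * P[, pr$j, drop = FALSE]
      classes <- unique_fg_classes(pool)
      m <- matrix(0, nrow(P), length(classes),
                  dimnames = list(NULL, classes))
      for (cl in classes)
        m[, cl] <- rowSums(PP[, cls == cl, drop = FALSE])
      m
    },
    additive = {
      m <- P * (1 - P)
      colnames(m) <- paste0("add:", pool$species)
      m
    },
    full = {
      pr <- pool_pairs(pool)
      m <- P[, pr$i, drop = FALSE] * P[, pr$j, drop = FALSE]
      colnames(m) <- paste0("pair:", pr$label)
      m
    })
  split_by_year(B, data, by_year)
}

# canonical FG-class column order: within groups first, then between pairs
unique_fg_classes <- function(pool) {
  lv <- pool$fg_levels
  T <- length(lv)
  within <- paste0("within:", lv)
  between <- character(0)
  if (T > 1L)
    for (q in 1:(T - 1L)) for (r in (q + 1L):T)
      between <- c(between, paste0("between:", lv[q], ":", lv[r]))
  c(within, between)
}

#' Cross interaction columns with the spatial-pattern treatment
#'
#' Produces one copy of each column per treatment level observed among
#' mixture rows; rows of other levels are zero. Monoculture rows (treatment
#' `none`) are already zero in interaction columns, so the treatment factor
#' needs no monoculture level. A mixture row with treatment `none` is an
#' error: the treatment is only defined for mixtures, but must be defined for
#' all of them when a crossing is requested.
#'
#' @param block matrix of interaction columns (rows aligned with `data`).
#' @param data the [di_data()] the block was built from.
#' @param levels optional explicit treatment levels (used when scoring new
#'   data against a fitted model's level set).
#' @return numeric matrix with `ncol(block) * n_levels` columns.
#' @export
cross_with_treatment <- function(block, data, levels = NULL) {
  rich <- di_richness(data)
  if (any(data$treatment == "none" & rich > 1L))
    stop("treatment crossing requested but mixture rows have treatment 'none'")
  levs <- if (is.null(levels))
    sort(unique(data$treatment[data$treatment != "none"])) else levels
  if (!length(levs)) stop("no treatment levels present among mixtures")
  out <- do.call(cbind, lapply(levs, function(l)
    block * (data$treatment == l)))
  colnames(out) <- as.vector(t(outer(levs, colnames(block),
                                     function(l, b) paste0(b, "@", l))))
  out
}

#' Scale interaction columns by a proportion-derived covariate
#'
#' @param block matrix of interaction columns.
#' @param data the [di_data()] the block was built from.
#' @param species character vector of pool species; the covariate is the
#'   rowwise sum of their proportions (e.g. legume percentage).
#' @return `block` with each column multiplied elementwise by the covariate.
#' @export
scale_by_covariate <- function(block, data, species) {
  pool <- di_pool(data)
  bad <- setdiff(species, pool$species)
  if (length(bad)) stop("covariate species not in pool: ",
                        paste(bad, collapse = ", "))
  cov <- rowSums(prop_matrix(data)[, species, drop = FALSE])
  out <- block * cov
  colnames(out) <- paste0(colnames(block), "*cov")
  out
}

#' Random design matrix for pair-by-year interaction effects
#'
#' For each species pair (i < j) and each active year k, a column holding
#' \eqn{P_{ik} P_{jk}} on rows of year k and zero elsewhere. Columns are
#' ordered pair-major, year-minor. With all pairs and years of the 170-plot,
#' 16-species layout this is the 510 x 360 random design of the multi-year DI
#' model.
#'
#' @param data a [di_data()].
#' @param years integer vector of active years (subset of `1..K`); empty
#'   means no random effects.
#' @return numeric matrix with `choose(s,2) * length(years)` columns and
#'   attributes `pairs` (data frame i, j, label) and `col_year`,
#'   `col_pair` index vectors.
#' @export
build_Z <- function(data, years = seq_len(di_K(data))) {
  pool <- di_pool(data)
  years <- sort(unique(as.integer(years)))
  if (length(years) && (min(years) < 1L || max(years) > di_K(data)))
    stop("active years outside 1..K")
  pr <- pool_pairs(pool)
  n <- nrow(data)
  if (!length(years)) {
    Z <- matrix(numeric(0), nrow = n, ncol = 0L)
    attr(Z, "pairs") <- pr
    attr(Z, "col_year") <- integer(0)
    attr(Z, "col_pair") <- integer(0)
    return(Z)
  }
  P <- prop_matrix(data)
  PP <- P[, pr$i, drop = FALSE] * P[, pr$j, drop = FALSE]
  ny <- length(years)
  Z <- matrix(0, n, nrow(pr) * ny)
  col_year <- rep(years, times = nrow(pr))
  col_pair <- rep(seq_len(nrow(pr)), each = ny)
  for (a in seq_len(ny)) {
    rows <- data$year == years[a]
    cols <- which(col_year == years[a])
    Z[rows, cols] <- PP[rows, , drop = FALSE]
  }
  colnames(Z) <- paste0("d:", pr$label[col_pair], ":y", col_year)
  attr(Z, "pairs") <- pr
  attr(Z, "col_year") <- col_year
  attr(Z, "col_pair") <- col_pair
  Z
}

# split a column block into per-year copies (zero outside each year)
split_by_year <- function(B, data, by_year) {
  if (!by_year) return(B)
  K <- di_K(data)
  out <- do.call(cbind, lapply(seq_len(K), function(k)
    B * (data$year == k)))
  colnames(out) <- as.vector(t(outer(seq_len(K), colnames(B),
                                     function(k, b) paste0(b, ":y", k))))
  out
}

# assemble the full fixed design matrix; drops aliased columns by pivoted QR
# (tlevels/blevels pin factor level sets when scoring new data; rows whose
# block is NA receive the average-block encoding 1/B on every block contrast)
build_X <- function(data, fixed, tol = 1e-8, tlevels = NULL, blevels = NULL,
                    drop_aliased = TRUE) {
  stopifnot(inherits(fixed, "di_fixed"))
  X <- identity_columns(data, by_year = fixed$by_year)
  for (tm in fixed$terms) {
    B <- interaction_columns(data, tm$structure, by_year = fixed$by_year)
    if (tm$treatment) B <- cross_with_treatment(B, data, levels = tlevels)
    if (!is.null(tm$covariate)) B <- scale_by_covariate(B, data, tm$covariate)
    X <- cbind(X, B)
  }
  if (is.null(blevels)) blevels <- unique(as.character(data$block[!is.na(data$block)]))
  if (fixed$block && length(blevels) > 1L) {
    contr <- blevels[-1L]
    Bm <- outer(as.character(data$block), contr, "==") * 1
    Bm[is.na(data$block), ] <- 1 / length(blevels)
    colnames(Bm) <- paste0("block:", contr)
    Bm <- split_by_year(Bm, data, fixed$by_year)
    X <- cbind(X, Bm)
  }
  dropped <- character(0)
  if (drop_aliased) {
    qx <- qr(X, tol = tol)
    if (qx$rank < ncol(X)) {
      keep <- sort(qx$pivot[seq_len(qx$rank)])
      dropped <- colnames(X)[-keep]
      X <- X[, keep, drop = FALSE]
    }
  }
  list(X = X, dropped = dropped)
}
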