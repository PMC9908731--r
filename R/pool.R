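#' Define a species pool with functional-group membership
#'
#' A species pool lists the species that can occur in a community together
#' with the functional group (FG) each belongs to. Every Diversity-
#' Interactions dataset carries a pool, and all design-matrix builders derive
#' their column layout from it.
#'
#' @param species character vector of species labels (defines column order of
#'   the proportion variables).
#' @param fg functional-group membership: a character vector the same length
#'   as `species`, or a named vector mapping species to group labels.
#' @return An object of class `"species_pool"` with elements `species`, `fg`
#'   (factor named by species), `n_species`, `fg_levels` and `fg_sizes`.
#' @examples
#' pool9 <- species_pool(paste0("sp", 1:9), rep(c("FG1", "FG2", "FG3"), each = 3))
#' pool9
#' @export
species_pool <- function(species, fg) {
  species <- as.character(species)
  if (anyDuplicated(species))
    stop("duplicated species labels in pool")
  if (!is.null(names(fg))) {
    if (!all(species %in% names(fg)))
      stop("fg map does not cover every species")
    fg <- fg[species]
  }
  if (length(fg) != length(species))
    stop("fg must have one entry per species")
  fg <- factor(as.character(fg), levels = unique(as.character(fg)))
  names(fg) <- species
  out <- list(
    species   = species,
    fg        = fg,
    n_species = length(species),
    fg_levels = levels(fg),
    fg_sizes  = as.integer(table(fg))
  )
  names(out$fg_sizes) <- levels(fg)
  class(out) <- "species_pool"
  out
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Species pool:", x$n_species, "species in",
      length(x$fg_levels), "functional groups\n")
  for (g in x$fg_levels)
    cat("  ", g, ": ", paste(x$species[x$fg == g], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# all unordered species pairs (i < j) in pool column order
pool_pairs <- function(pool) {
  s <- pool$n_species
  i <- rep(seq_len(s - 1L), times = (s - 1L):1L)
  j <- unlist(lapply(seq_len(s - 1L), function(a) (a + 1L):s))
  data.frame(i = i, j = j,
             label = paste(pool$species[i], pool$species[j], sep = ":"),
             stringsAsFactors = FALSE)
}

# pair classification by FG: "within:<g>" or "between:<q>:<r>"
pair_fg_class <- function(pool) {
  pr <- pool_pairs(pool)
  gi <- as.integer(pool$fg[pr$i])
  gj <- as.integer(pool$fg[pr$j])
  lv <- pool$fg_levels
  ifelse(gi == gj, paste0("within:", lv[gi]),
         paste0("between:", lv[pmin(gi, gj)], ":", lv[pmax(gi, gj)]))
}
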