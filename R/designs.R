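#' Built-in experimental designs
#'
#' `design_a()` builds the 206-plot, nine-species simulation design: three
#' functional groups of three species; every species in monoculture twice;
#' every pair of species twice at 50:50 in a two-species plot; and 48, 36, 24
#' and 8 equal-proportion plots of richness 3, 4, 6 and 9. The higher-richness
#' community compositions are constructed so that each species appears equally
#' often at every richness level (richness-3 plots come from 16 partitions of
#' the nine species into triples, richness-4 plots from cyclic shifts of four
#' base quadruples, richness-6 plots from complements of triple partitions).
#' Proportions are replicated across `years` growing seasons; the response
#' column is `NA` (a design skeleton to be filled by [simulate_response()]).
#'
#' `space_design()` builds a 170-plot layout in the style of a grassland
#' spatial-pattern experiment: 16 species in four functional groups of four
#' (warm-season grass, cool-season grass, forb, legume), five blocks, plots of
#' richness 1, 2, 4 or 8. Two-species plots pair one grass with one forb or
#' legume; four-species plots take one species per FG; eight-species plots two
#' per FG. Mixture plots carry an `aggregated`/`dispersed` spatial-pattern
#' label (balanced, seeded); monocultures carry `none`. The paper-style
#' allocation of plots to richness levels (16 / 64 / 48 / 42) is this
#' package's documented choice.
#'
#' @param seed integer seed driving all random choices in the generator.
#' @param years number of repeated-measures years K (default 3).
#' @return a [di_data()] skeleton (response `y` is `NA`).
#' @examples
#' d <- design_a(seed = 1)
#' table(rowSums(prop_cols(d) > 0)[d$year == 1])
#' @export
design_a <- function(seed = 1L, years = 3L) {
  pool <- species_pool(paste0("sp", 1:9), rep(paste0("FG", 1:3), each = 3))
  set.seed(as.integer(seed))
  s <- 9L
  comp <- list()
  # monocultures, twice each
  for (i in seq_len(s)) {
    e <- numeric(s); e[i] <- 1
    comp <- c(comp, list(e, e))
  }
  # all 36 pairs, twice each, 50:50
  pr <- pool_pairs(pool)
  for (r in seq_len(nrow(pr))) {
    e <- numeric(s); e[c(pr$i[r], pr$j[r])] <- 0.5
    comp <- c(comp, list(e, e))
  }
  triple_partition <- function() {
    p <- sample.int(s)
    lapply(1:3, function(b) sort(p[(3 * b - 2):(3 * b)]))
  }
  # richness 3: 16 partitions into triples -> 48 plots
  for (rep in 1:16) for (tr in triple_partition()) {
    e <- numeric(s); e[tr] <- 1 / 3
    comp <- c(comp, list(e))
  }
  # richness 4: 4 base quadruples, each shifted through 0..8 -> 36 plots
  for (b in 1:4) {
    base <- sort(sample.int(s, 4L))
    for (sh in 0:8) {
      e <- numeric(s); e[(base + sh - 1L) %% s + 1L] <- 0.25
      comp <- c(comp, list(e))
    }
  }
  # richness 6: complements of 8 triple partitions -> 24 plots
  for (rep in 1:8) for (tr in triple_partition()) {
    e <- rep(1 / 6, s); e[tr] <- 0
    comp <- c(comp, list(e))
  }
  # richness 9: 8 centroid plots
  for (rep in 1:8) comp <- c(comp, list(rep(1 / 9, s)))
  P <- do.call(rbind, comp)
  skeleton_from_props(P, pool, blocks = rep(1L, nrow(P)),
                      treatment = rep("none", nrow(P)), years = years)
}

#' @rdname design_a
#' @export
space_design <- function(seed = 1L, years = 3L) {
  pool <- species_pool(
    paste0("sp", 1:16),
    rep(c("WSG", "CSG", "Forb", "Legume"), each = 4))
  set.seed(as.integer(seed))
  s <- 16L
  fg_idx <- split(seq_len(s), pool$fg)
  comp <- list()
  # 16 monocultures
  for (i in seq_len(s)) { e <- numeric(s); e[i] <- 1; comp <- c(comp, list(e)) }
  # 64 two-species plots: each grass x each forb/legume, 50:50
  for (g in 1:8) for (f in 9:16) {
    e <- numeric(s); e[c(g, f)] <- 0.5
    comp <- c(comp, list(e))
  }
  # 48 four-species plots: one random species per FG
  for (r in 1:48) {
    pick <- vapply(fg_idx, function(ix) ix[sample.int(4L, 1L)], integer(1))
    e <- numeric(s); e[pick] <- 0.25
    comp <- c(comp, list(e))
  }
  # 42 eight-species plots: two random species per FG
  for (r in 1:42) {
    pick <- unlist(lapply(fg_idx, function(ix) sort(ix[sample.int(4L, 2L)])))
    e <- numeric(s); e[pick] <- 0.125
    comp <- c(comp, list(e))
  }
  P <- do.call(rbind, comp)
  rich <- rowSums(P > 0)
  treatment <- rep("none", nrow(P))
  for (r in c(2L, 4L, 8L)) {
    ix <- which(rich == r)
    lab <- rep(c("aggregated", "dispersed"), length.out = length(ix))
    treatment[ix] <- sample(lab)
  }
  blocks <- integer(nrow(P))
  blocks[sample.int(nrow(P))] <- rep(1:5, length.out = nrow(P))
  skeleton_from_props(P, pool, blocks = blocks, treatment = treatment,
                      years = years)
}

# replicate per-plot proportion rows across years into a di_data skeleton
skeleton_from_props <- function(P, pool, blocks, treatment, years) {
  n <- nrow(P)
  df <- data.frame(
    plot = rep(sprintf("p%03d", seq_len(n)), each = years),
    block = rep(blocks, each = years),
    year = rep(seq_len(years), times = n),
    treatment = rep(treatment, each = years),
    y = NA_real_,
    stringsAsFactors = FALSE)
  df[pool$species] <- P[rep(seq_len(n), each = years), , drop = FALSE]
  di_data(df, pool)
}

#' Extract the proportion columns of a DI dataset as a matrix
#'
#' @param data a [di_data()].
#' @return numeric matrix, one column per pool species, rows aligned with
#'   `data`.
#' @export
prop_cols <- function(data) prop_matrix(data)
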