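# shared fixtures: tiny pools/designs and dense-matrix oracles built in code

pool3 <- species_pool(paste0("s", 1:3), c("A", "A", "B"))
pool9 <- function() attr(design_a(seed = 1), "pool")

# small hand-built long dataset: `props` is a plot x species matrix,
# replicated over `years`, treatment optional
tiny_data <- function(props, pool, years = 3, y = NULL, treatment = NULL,
                      blocks = NULL) {
  n <- nrow(props)
  if (is.null(treatment)) treatment <- rep("none", n)
  if (is.null(blocks)) blocks <- rep(1L, n)
  df <- data.frame(
    plot = rep(sprintf("t%02d", seq_len(n)), each = years),
    block = rep(blocks, each = years),
    year = rep(seq_len(years), n),
    treatment = rep(treatment, each = years),
    y = if (is.null(y)) NA_real_ else y)
  df[pool$species] <- props[rep(seq_len(n), each = years), , drop = FALSE]
  di_data(df, pool)
}

# random simplex points for property tests
rand_simplex <- function(n, s) {
  x <- matrix(stats::rexp(n * s), n, s)
  x / rowSums(x)
}

# brute-force pairwise products sum over an explicit pair enumeration
brute_pair_sum <- function(p) {
  s <- length(p); tot <- 0
  for (i in seq_len(s - 1)) for (j in (i + 1):s) tot <- tot + p[i] * p[j]
  tot
}

# dense-matrix -2 log-likelihood oracle (explicit determinant and solve)
dense_neg2ll <- function(y, X, V, method = "REML") {
  n <- length(y); p <- ncol(X)
  b <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% y)
  r <- y - X %*% b
  quad <- as.numeric(t(r) %*% solve(V) %*% r)
  ld <- as.numeric(determinant(V)$modulus)
  if (method == "ML") n * log(2 * pi) + ld + quad
  else (n - p) * log(2 * pi) + ld +
    as.numeric(determinant(t(X) %*% solve(V) %*% X)$modulus) + quad
}

# dense mixed-model-equations BLUP oracle
dense_blups <- function(y, X, Z, G, R) {
  V <- Z %*% G %*% t(Z) + R
  b <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% y)
  as.numeric(G %*% t(Z) %*% solve(V, y - X %*% b))
}
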