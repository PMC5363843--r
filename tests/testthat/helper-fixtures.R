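# Shared fixtures and independent oracles, all built in code.

# minimal record table builder
rec <- function(site, night, species, time_min, family = "Phyllostomidae",
                guild = "FR", count = 1L, dataset = "toy") {
  data.frame(dataset = dataset, site = site, night = night,
             species = species, family = family, guild = guild,
             time_min = as.integer(time_min), count = as.integer(count),
             stringsAsFactors = FALSE)
}

# 7 records over 2 nights x 3 species (hand-tallied totals)
toy_records <- function() {
  rbind(
    rec("S1", "N1", "spA", 30, count = 1),
    rec("S1", "N1", "spA", 60, count = 1),
    rec("S1", "N1", "spB", 90, count = 1),
    rec("S1", "N2", "spA", 300, count = 1),
    rec("S1", "N2", "spC", 420, count = 1),
    rec("S1", "N2", "spC", 600, count = 1),
    rec("S1", "N2", "spB", 660, count = 1)
  )
}

write_captures_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# small random abundance matrix (nights x species)
random_matrix <- function(n_rows = 12, n_cols = 8, lambda = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_rows * n_cols, lambda), nrow = n_rows,
              dimnames = list(paste0("S1:N", seq_len(n_rows)),
                              paste0("sp", seq_len(n_cols))))
  m
}

# Exhaustive-enumeration oracle for individual-based rarefaction: mean
# richness over every m-subset of the n individuals.
enum_rarefy <- function(abundance, m) {
  inds <- rep(seq_along(abundance), abundance)
  subs <- utils::combn(length(inds), m)
  mean(apply(subs, 2, function(ix) length(unique(inds[ix]))))
}

# Exhaustive oracle for sample-based rarefaction over unit subsets.
enum_rarefy_samples <- function(mat, t) {
  subs <- utils::combn(nrow(mat), t)
  mean(apply(subs, 2, function(ix)
    sum(colSums(mat[ix, , drop = FALSE]) > 0)))
}

# Brute-force Procrustes m2 oracle for 2-D configurations: both centered
# and unit-scaled, then grid search over rotation angle and reflection with
# golden-section refinement; optimal scale for a fixed rotation is applied
# in closed residual form (residual = 1 - t^2 for alignment t > 0).
brute_m2 <- function(X, Y) {
  norm1 <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / sqrt(sum(M^2))
  }
  X <- norm1(X); Y <- norm1(Y)
  tfun <- function(theta, refl) {
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
    if (refl) R[, 2] <- -R[, 2]
    sum(X * (Y %*% R))
  }
  best <- -Inf
  for (refl in c(FALSE, TRUE)) {
    grid <- seq(0, 2 * pi, length.out = 20001)
    vals <- vapply(grid, tfun, numeric(1), refl = refl)
    i <- which.max(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- tfun(c1, refl); f2 <- tfun(c2, refl)
    while (b - a > 1e-12) {
      if (f1 < f2) {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + gr * (b - a); f2 <- tfun(c2, refl)
      } else {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - gr * (b - a); f1 <- tfun(c1, refl)
      }
    }
    best <- max(best, tfun((a + b) / 2, refl))
  }
  1 - max(best, 0)^2
}

# Vector with exact Pearson correlation rho to x (Gram-Schmidt construction)
with_correlation <- function(x, rho, seed = 1) {
  set.seed(seed)
  e <- rnorm(length(x))
  zx <- scale(x)[, 1]
  ze <- scale(stats::residuals(stats::lm(e ~ zx)))[, 1]
  rho * zx + sqrt(1 - rho^2) * ze
}
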