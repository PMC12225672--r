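# Independent oracles and fixture builders used across the suite.

# Exhaustive grid search over the 3-simplex: the brute-force reference
# for the simplex-constrained least-squares deconvolution. The grid is
# cached per step size.
.simplex_grid_cache <- new.env(parent = emptyenv())

simplex_grid <- function(step = 1e-3) {
  key <- format(step, digits = 12)
  if (!is.null(.simplex_grid_cache[[key]]))
    return(.simplex_grid_cache[[key]])
  s1 <- seq(0, 1, by = step)
  g <- expand.grid(p = s1, c = s1)
  g <- g[g$p + g$c <= 1 + 1e-12, ]
  S <- rbind(g$p, g$c, pmax(1 - g$p - g$c, 0))
  .simplex_grid_cache[[key]] <- S
  S
}

# argmin over the grid of ||M s - m||_2
oracle_simplex_lsq <- function(M, m, step = 1e-3) {
  S <- simplex_grid(step)
  r <- M %*% S - as.numeric(m)
  rn <- sqrt(colSums(r^2))
  i <- which.min(rn)
  list(s = S[, i], rn = rn[i])
}

# Random normalized marker matrix (full rank w.h.p.) and metabolite
# profile over n fractions.
random_deconv_problem <- function(n_fractions = 6) {
  M <- matrix(stats::rexp(n_fractions * 3), n_fractions, 3)
  M <- apply(M, 2, function(x) x / sum(x))
  colnames(M) <- c("plastid", "cytosol", "vacuole")
  m <- stats::rexp(n_fractions)
  list(M = M, m = m / sum(m))
}

# Random point on the 3-simplex.
random_simplex_point <- function() {
  s <- stats::rexp(3)
  s / sum(s)
}
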