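# Shared fixtures: the reference parameter point used throughout the
# bound sweeps (p1 = 0.5, q1 = 0.05, pmax = 1, qmax = 0.2), random valid
# parameter generators, and small independent oracles.

ref_params <- function(u = 0.5, v = u) {
  synapse_params(p1 = 0.5, q1 = 0.05, pmax = 1, qmax = 0.2, u = u, v = v)
}

# n random valid (params, alpha) points as a data frame
random_points <- function(n) {
  p1 <- runif(n); pmax <- p1 + runif(n) * (1 - p1)
  q1 <- runif(n); qmax <- q1 + runif(n) * (1 - q1)
  data.frame(p1 = p1, q1 = q1, pmax = pmax, qmax = qmax,
             u = runif(n), v = runif(n), alpha = runif(n))
}

# plug-in empirical mutual information (bits) of paired binary samples,
# from the 2x2 joint frequency table — independent of the CTW path
plugin_mi <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  n <- length(x)
  p <- table(factor(x, 0:1), factor(y, 0:1)) / n
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0)
      mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  as.numeric(mi)
}
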