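# Small cohort fixtures built in code; all deterministic given the seed.

small_cohort <- function(n_hc = 60, n_uhc = 20, seed = 11L,
                         null_effects = FALSE) {
  spec <- cohort_spec(n_hc = n_hc, n_uhc = n_uhc)
  generate_cohort(spec, default_generator_config(spec, null_effects),
                  seed = seed)
}

# two-group, two-feature toy matrix with tunable separation
toy_xy <- function(n_per_class = 30, shift = 2, p = 2, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = shift), ncol = p))
  y <- factor(rep(c("HC", "uHC"), each = n_per_class),
              levels = c("HC", "uHC"))
  list(X = X, y = y)
}

# brute-force ReliefF (k = 1) for tiny instances: literal enumeration of
# the nearest hit and miss per anchor on range-scaled Manhattan distance
relieff_bruteforce_k1 <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  rng <- apply(X, 2, function(c) diff(range(c)))
  scale <- ifelse(rng > 0, rng, 1)
  diff_f <- function(a, b) ifelse(rng > 0, abs(a - b) / scale, 0)
  W <- numeric(ncol(X))
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j)
      if (j == i) Inf else sum(diff_f(X[i, ], X[j, ])))
    hits <- setdiff(which(y == y[i]), i)
    misses <- which(y != y[i])
    nh <- hits[which.min(d[hits])]
    nm <- misses[which.min(d[misses])]
    W <- W - diff_f(X[i, ], X[nh, ]) / n + diff_f(X[i, ], X[nm, ]) / n
  }
  W
}
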