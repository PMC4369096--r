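# Shared fixture builders. All randomness is seeded at the call site via the
# generators' own seed arguments, so every test is reproducible.

# small random Gaussian fixture with arbitrary group structure
randomFixture <- function(n = 20, p = 3, J = 2, seed = 7,
                          separation = 2) {
  set.seed(seed)
  labels <- rep(paste0("c", seq_len(J)), length.out = n)
  shift <- matrix(stats::rnorm(J * p, sd = separation), J, p)
  raw <- matrix(stats::rnorm(n * p), n, p) + shift[match(labels, unique(labels)), ]
  centreAndIndex(raw, labels)
}

# the bundled 150 x 4 three-group benchmark (normal version)
benchmarkFixture <- function(seed = 42, sizes = c(50L, 50L, 50L)) {
  simulateNormal(threeGroupSpec(sizes = sizes, seed = seed))
}

# two-group subset of the benchmark parameters, for J = 2 displays
twoGroupFixture <- function(n = 100, seed = 11) {
  spec <- threeGroupSpec(sizes = c(50L, 50L, 50L), seed = seed)
  spec@means <- spec@means[c(1, 3), , drop = FALSE]
  spec@covs <- spec@covs[c(1, 3)]
  spec@sizes <- as.integer(rep(n / 2, 2))
  simulateNormal(spec)
}

# explicit-inverse oracle for the per-class quadratic score
phiOracle <- function(x, mean, S) {
  d <- x - mean
  drop(t(d) %*% solve(S) %*% d) + log(det(S))
}

# brute-force discriminant criterion evaluation
discriminantOracle <- function(phi, priors) {
  unname(which.max(unname(log(priors)) - 0.5 * unname(phi)))
}
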