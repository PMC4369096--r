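#' Three-group multivariate-normal benchmark specification
#'
#' The bundled benchmark: J = 3 four-variate normal groups of 50 samples
#' each with means (1,1,1,1), (-1,2,3,4) and (1,1,5,5) and covariances
#' \eqn{I_4}, \eqn{2 I_4} and the compound-symmetric matrix with unit
#' diagonal and off-diagonal 0.7. The third group's equicorrelation gives it
#' a covariance structure qualitatively different from the two spherical
#' groups, which is exactly the regime quadratic discrimination is for.
#'
#' @param sizes per-group sample sizes (default 50 each).
#' @param seed RNG seed stored with the specification (default 42).
#' @return a [SimulationSpec-class].
#' @export
threeGroupSpec <- function(sizes = c(50L, 50L, 50L), seed = 42L) {
  means <- rbind(g1 = c(1, 1, 1, 1),
                 g2 = c(-1, 2, 3, 4),
                 g3 = c(1, 1, 5, 5))
  colnames(means) <- paste0("V", 1:4)
  cs <- matrix(0.7, 4, 4); diag(cs) <- 1
  new("SimulationSpec",
      means = means,
      covs = list(diag(4), 2 * diag(4), cs),
      sizes = as.integer(sizes), seed = as.integer(seed))
}

#' Draw a multivariate-normal labelled sample
#'
#' Generates \code{sizes[j]} draws from \eqn{N(\mu_j, \Sigma_j)} per group
#' via the Cholesky factor of each covariance, labels them g1, g2, ... in
#' group order, and returns the centred, indexed data. Deterministic for a
#' fixed seed.
#'
#' @param spec a [SimulationSpec-class].
#' @param seed optional seed overriding \code{spec@seed}.
#' @return a [LabeledData-class].
#' @export
simulateNormal <- function(spec, seed = NULL) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  set.seed(if (is.null(seed)) spec@seed else as.integer(seed))
  J <- nrow(spec@means)
  p <- ncol(spec@means)
  blocks <- vector("list", J)
  for (j in seq_len(J)) {
    R <- chol(spec@covs[[j]])
    Z <- matrix(stats::rnorm(spec@sizes[j] * p), ncol = p)
    blocks[[j]] <- sweep(Z %*% R, 2, spec@means[j, ], "+")
  }
  raw <- do.call(rbind, blocks)
  colnames(raw) <- colnames(spec@means) %||% paste0("V", seq_len(p))
  labels <- rep(paste0("g", seq_len(J)), spec@sizes)
  centreAndIndex(raw, labels)
}

#' Dichotomize at the pooled median
#'
#' Converts every variable to a 0/1 indicator: values below the variable's
#' pooled median (over all samples, midpoint convention for even counts)
#' become 0 and values at or above it become 1. A constant column maps to
#' all ones (its median equals the value) with a warning.
#'
#' @param data a [LabeledData-class].
#' @return a binary [LabeledData-class] with the same group structure.
#' @export
dichotomizeAtMedian <- function(data) {
  stopifnot(is(data, "LabeledData"))
  raw <- sweep(data@X, 2, -data@centreOffset)  # original units
  meds <- apply(raw, 2, stats::median)
  const <- apply(raw, 2, function(v) max(v) - min(v) < 1e-12)
  if (any(const))
    warning(sprintf("constant column(s) %s dichotomize to all ones",
                    paste(colnames(raw)[const], collapse = ", ")))
  bin <- sweep(raw, 2, meds, ">=") * 1
  colnames(bin) <- colnames(raw)
  centreAndIndex(bin, as.character(data@groups))
}

#' Simulate a binary presence/absence panel
#'
#' Independent per-variable Bernoulli draws with class-specific presence
#' probabilities, emulating pathogen-detection panels (0 = absent,
#' 1 = present). With p binary variables the attainable pattern space has
#' 2^p distinct response patterns.
#'
#' @param nPerGroup samples per group (scalar or one value per group).
#' @param p number of binary variables.
#' @param probs presence probabilities: a J by p matrix, or a list/vector
#'   giving one probability (or p probabilities) per group. All must lie
#'   strictly in (0, 1).
#' @param seed RNG seed.
#' @return a binary [LabeledData-class].
#' @export
pathogenPanel <- function(nPerGroup, p, probs, seed = 1L) {
  if (is.list(probs)) probs <- do.call(rbind, lapply(probs, rep_len, p))
  if (is.vector(probs)) probs <- matrix(rep(probs, each = p), ncol = p,
                                        byrow = TRUE)
  J <- nrow(probs)
  if (any(probs <= 0) || any(probs >= 1))
    configError("presence probabilities must lie strictly in (0, 1)")
  nPerGroup <- rep_len(as.integer(nPerGroup), J)
  if (any(nPerGroup < 2L)) configError("need at least 2 samples per group")
  set.seed(as.integer(seed))
  blocks <- lapply(seq_len(J), function(j) {
    matrix(stats::rbinom(nPerGroup[j] * p, 1,
                         rep(probs[j, ], each = nPerGroup[j])),
           ncol = p)
  })
  raw <- do.call(rbind, blocks)
  colnames(raw) <- paste0("path", seq_len(p))
  centreAndIndex(raw, rep(paste0("g", seq_len(J)), nPerGroup))
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: %d groups, %d variables, sizes %s, seed %d\n",
              nrow(object@means), ncol(object@means),
              paste(object@sizes, collapse = "/"), object@seed))
})
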