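#' Gaussian-mixture test channels
#'
#' A discrete-input/continuous-output channel whose conditional distributions
#' are isotropic Gaussians is the standard fixture for validating the kNN MI
#' estimator: its MI can be computed to high accuracy by deterministic
#' quadrature ([mi_oracle_numeric()]) and compared with [estimate_mi()] on
#' samples.
#'
#' @param means Numeric matrix, one row per component (d columns, d <= 3).
#' @param sd Isotropic standard deviation, recycled across components.
#' @param p Component probabilities (default uniform).
#' @return An object of class `gauss_mixture`.
#' @export
gauss_mixture <- function(means, sd, p = NULL) {
  means <- as.matrix(means)
  stopifnot(ncol(means) <= 3, nrow(means) <= 16, all(is.finite(means)))
  sd <- rep_len(sd, nrow(means))
  stopifnot(all(sd > 0))
  p <- p %||% rep(1 / nrow(means), nrow(means))
  if (length(p) != nrow(means) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("`p` must be a probability vector with one entry per component.", call. = FALSE)
  }
  structure(list(means = means, sd = sd, p = p), class = "gauss_mixture")
}

#' Eight overlapping Gaussians at the vertices of the unit cube
#'
#' Three-dimensional fixture with components centred at the corners of the
#' unit cube. At the default spread the numerically integrated MI is about
#' 1.8 bits, well below the 3-bit ceiling, so estimator bias is visible.
#'
#' @param sd Isotropic component SD (default 0.42).
#' @return A [gauss_mixture()].
#' @export
mix_cube_vertices <- function(sd = 0.42) {
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  dimnames(g) <- NULL
  gauss_mixture(g, sd = sd)
}

#' Eight overlapping Gaussians along an S-shaped curve
#'
#' Components placed along a planar S-curve (two half-turns), a harder
#' geometry for the estimator because neighbouring components overlap
#' unevenly.
#'
#' @param sd Isotropic component SD (default 0.45).
#' @return A [gauss_mixture()].
#' @export
mix_s_curve <- function(sd = 0.45) {
  t <- seq(0, 1, length.out = 8)
  means <- cbind(
    x = t * 3,
    y = sin(2 * pi * t),
    z = 0.5 * cos(2 * pi * t)
  )
  dimnames(means) <- NULL
  gauss_mixture(means, sd = sd)
}

log_comp_density <- function(mix, Y, j) {
  d <- ncol(mix$means)
  mu <- mix$means[j, ]
  s <- mix$sd[j]
  -0.5 * rowSums(sweep(Y, 2, mu)^2) / s^2 - d * log(s * sqrt(2 * pi))
}

log_mix_density <- function(mix, Y) {
  ll <- vapply(
    seq_len(nrow(mix$means)),
    function(j) log(mix$p[j]) + log_comp_density(mix, Y, j),
    numeric(nrow(Y))
  )
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  mx <- apply(ll, 1, max)
  mx + log(rowSums(exp(ll - mx)))
}

#' Numerically exact MI of a Gaussian-mixture channel
#'
#' Deterministic tensor-product Gauss–Hermite quadrature of
#' `MI = sum_x p(x) * E_x[ log2 f_x(Y) - log2 f(Y) ]`, where `f_x` is the
#' component density and `f` the mixture density. With the default 24 nodes
#' per dimension the absolute error is far below 0.005 bit for the fixtures
#' used here. This is the independent oracle against which the kNN estimator
#' is validated.
#'
#' @param mix A [gauss_mixture()].
#' @param nodes Gauss–Hermite nodes per dimension (default 24).
#' @return MI in bits.
#' @export
mi_oracle_numeric <- function(mix, nodes = 24) {
  stopifnot(inherits(mix, "gauss_mixture"))
  d <- ncol(mix$means)
  gh <- pracma::gaussHermite(nodes)
  grids <- rep(list(seq_len(nodes)), d)
  idx <- as.matrix(expand.grid(grids))
  Z <- matrix(gh$x[idx], ncol = d) # quadrature nodes in standard space
  Wlog <- rowSums(matrix(log(gh$w)[idx], ncol = d)) - d / 2 * log(pi)
  mi_nats <- 0
  for (j in seq_len(nrow(mix$means))) {
    # y = mu_j + sd_j * sqrt(2) * z
    Y <- sweep(Z * mix$sd[j] * sqrt(2), 2, mix$means[j, ], `+`)
    integrand <- log_comp_density(mix, Y, j) - log_mix_density(mix, Y)
    mi_nats <- mi_nats + mix$p[j] * sum(exp(Wlog) * integrand)
  }
  max(mi_nats / log(2), 0)
}

#' Sample a channel dataset from a Gaussian mixture
#'
#' Draws `M` response vectors per component and returns them in the standard
#' channel-dataset layout (`sequence` = component label `"g1" ... "gC"`,
#' response columns `R_1 ... R_d`), ready for [estimate_mi()].
#'
#' @param mix A [gauss_mixture()].
#' @param M Samples per component.
#' @param seed RNG seed.
#' @return A tibble with columns `sequence`, `cell_id`, `R_1 ... R_d`.
#' @export
sample_mixture <- function(mix, M, seed = 1L) {
  stopifnot(M >= 1)
  set.seed(seed)
  d <- ncol(mix$means)
  C <- nrow(mix$means)
  rows <- purrr::map(seq_len(C), function(j) {
    Y <- matrix(stats::rnorm(M * d, sd = mix$sd[j]), ncol = d)
    Y <- sweep(Y, 2, mix$means[j, ], `+`)
    colnames(Y) <- paste0("R_", seq_len(d))
    dplyr::bind_cols(
      tibble::tibble(sequence = sprintf("g%d", j), cell_id = seq_len(M)),
      tibble::as_tibble(Y)
    )
  })
  dplyr::bind_rows(rows)
}
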