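#' Extrinsic-noise specification
#'
#' Two noise sources act on the simulated single-cell responses:
#' * cell-specific noise: every cell-variable model parameter (protein
#'   abundances and pseudo-first-order rates) is drawn once per cell from a
#'   lognormal distribution with median equal to its default value and
#'   log-scale standard deviation `sigma`;
#' * additive noise: each integrated response `R_i` receives an independent
#'   lognormal background term with log-scale SD `sigma0` and median
#'   `mu_star = mu0 * R_max * T / 60 min`, representing ERK activity driven
#'   by pathways outside the model.
#'
#' @param sigma Cell-specific log-SD; the study grid is
#'   `{0, 0.1, 0.3, 0.5, 0.7, 1.0}` (default 0.3).
#' @param mu0 Additive-noise relative median; grid `{0, 0.01, 0.03, 0.1, 0.3}`
#'   (default 0.03).
#' @param sigma0 Additive-noise log-SD (default 1).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.3, mu0 = 0.03, sigma0 = 1) {
  stopifnot(sigma >= 0, mu0 >= 0, sigma0 >= 0)
  structure(list(sigma = sigma, mu0 = mu0, sigma0 = sigma0), class = "noise_spec")
}

#' Sample a population of cell-specific parameter sets
#'
#' Draws `M` cells; in each, every cell-variable parameter is replaced by an
#' independent draw from `exp(Normal(log(default), sigma^2))`, so the median
#' of each marginal equals the default and `sigma = 0` reproduces the default
#' cell exactly. Other parameters are left untouched.
#'
#' @param base A [mapk_params()] table.
#' @param noise A [noise_spec()] (only `sigma` is used here).
#' @param M Number of cells.
#' @param seed RNG seed for the population draw.
#' @return A list of `M` `mapk_params` tables; each carries attributes
#'   `cell_id` and `seed`.
#' @export
sample_population <- function(base, noise, M, seed = 1L) {
  stopifnot(inherits(base, "mapk_params"), inherits(noise, "noise_spec"), M >= 1)
  varied <- base$cell_variable
  if (any(base$value[varied] <= 0)) {
    stop("Cell-variable parameters must have positive defaults.", call. = FALSE)
  }
  set.seed(seed)
  lapply(seq_len(M), function(cell) {
    p <- base
    if (noise$sigma > 0) {
      n_var <- sum(varied)
      p$value[varied] <- p$value[varied] *
        exp(stats::rnorm(n_var, mean = 0, sd = noise$sigma))
    }
    attr(p, "cell_id") <- cell
    attr(p, "seed") <- seed
    p
  })
}

#' Additive lognormal background terms for integrated responses
#'
#' One independent draw per pulse window, from a lognormal with median
#' `mu_star = mu0 * R_max * T_min / 60` and log-SD `sigma0`. With `mu0 = 0`
#' the terms are exactly zero.
#'
#' @param noise A [noise_spec()].
#' @param R_max Reference single-pulse response (molecule*s).
#' @param T_min Window length, minutes.
#' @param L Number of windows.
#' @return Numeric vector of `L` non-negative terms (molecule*s). Uses the
#'   caller's RNG stream.
#' @export
additive_noise <- function(noise, R_max, T_min, L) {
  stopifnot(inherits(noise, "noise_spec"), is.finite(R_max), T_min > 0, L >= 1)
  if (noise$mu0 == 0) {
    return(numeric(L))
  }
  mu_star <- noise$mu0 * R_max * T_min / 60
  stats::rlnorm(L, meanlog = log(mu_star), sdlog = noise$sigma0)
}
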