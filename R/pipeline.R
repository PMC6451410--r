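#' Generate a channel dataset from the ODE model
#'
#' The ODE counterpart of [generate_dataset()]: for each input sequence,
#' draws `M` cell-specific parameter sets ([sample_population()]), simulates
#' each cell deterministically, integrates the per-window responses
#' (molecule*s) and adds the additive lognormal background.
#'
#' @param sequences Character vector of binary input sequences.
#' @param T_min Base repeating time, minutes.
#' @param params Base [mapk_params()].
#' @param noise A [noise_spec()].
#' @param M Cells per sequence.
#' @param seed RNG seed.
#' @param dt_out_s Trajectory output grid, seconds (default 6).
#' @return A tibble with columns `sequence`, `cell_id`, `R_1 ... R_L`.
#' @export
generate_dataset_ode <- function(sequences, T_min, params = mapk_params(),
                                 noise = noise_spec(), M = 1000, seed = 1L,
                                 dt_out_s = 6) {
  L <- unique(nchar(sequences))
  stopifnot(length(L) == 1L)
  R_max <- single_pulse_response(params, dt_out_s = dt_out_s)
  rows <- purrr::map(seq_along(sequences), function(si) {
    s <- sequences[si]
    cells <- sample_population(params, noise, M, seed = seed + si * 10007L)
    set.seed(seed + si * 20011L) # additive-noise stream
    R <- t(vapply(cells, function(cp) {
      prot <- protocol_spec(s, T_min)
      traj <- simulate_mapk(cp, prot, t_end_min = L * T_min + 30, dt_out_s = dt_out_s)
      integrated_response(traj, T_min, L) + additive_noise(noise, R_max, T_min, L)
    }, numeric(L)))
    colnames(R) <- paste0("R_", seq_len(L))
    dplyr::bind_cols(
      tibble::tibble(sequence = s, cell_id = seq_len(M)),
      tibble::as_tibble(R)
    )
  })
  dplyr::bind_rows(rows)
}

backend_dataset <- function(backend, sequences, T_min, M, seed, params, noise,
                            surrogate, dt_out_s = 6) {
  switch(backend,
    surrogate = generate_dataset(sequences, T_min, surrogate, M = M, seed = seed),
    ode = generate_dataset_ode(sequences, T_min,
      params = params, noise = noise,
      M = M, seed = seed, dt_out_s = dt_out_s
    ),
    stop("`backend` must be 'surrogate' or 'ode'.", call. = FALSE)
  )
}

run_manifest <- function(...) {
  cfg <- list(...)
  cfg$package_version <- as.character(utils::packageVersion("erkchannel"))
  cfg
}

#' Fraction of cells responding to the second of two pulses
#'
#' For each interval `T` and each cell-specific noise level `sigma`,
#' simulates cells receiving two 5-min 100 pg/ml pulses and reports the
#' fraction with `R_2 > 0.5 * R_1`. With `sigma = 0` and no additive noise
#' the curve is a step at the relaxation time `tau`; increasing `sigma`
#' smears it out.
#'
#' @param T_grid Inter-pulse intervals, minutes.
#' @param sigma_grid Cell-specific noise levels.
#' @param mu0 Additive-noise relative median (default 0.03).
#' @param M Cells per condition (>= 500 for production runs).
#' @param backend `"ode"` or `"surrogate"`.
#' @param params Base [mapk_params()] (ode backend).
#' @param surrogate Base [surrogate_spec()] (surrogate backend; its
#'   `cell_cv` is overridden by each `sigma`).
#' @param seed RNG seed.
#' @param dt_out_s Trajectory grid, seconds (ode backend).
#' @return A tibble with columns `T_min`, `sigma`, `fraction`, `n_cells`,
#'   carrying a `manifest` attribute.
#' @export
run_fraction_responding <- function(T_grid = c(40, 45, 50, 55, 60, 70),
                                    sigma_grid = c(0, 0.1, 0.3), mu0 = 0.03,
                                    M = 500, backend = c("ode", "surrogate"),
                                    params = mapk_params(),
                                    surrogate = surrogate_spec(), seed = 1L,
                                    dt_out_s = 6) {
  backend <- match.arg(backend)
  out <- purrr::map_dfr(sigma_grid, function(sg) {
    purrr::map_dfr(seq_along(T_grid), function(ti) {
      T_min <- T_grid[ti]
      cond_seed <- seed + ti * 101L + round(sg * 1000) * 7919L
      M_use <- if (backend == "ode" && sg == 0 && mu0 == 0) 1L else M
      noise <- noise_spec(sigma = sg, mu0 = mu0)
      d <- if (backend == "surrogate") {
        sp <- surrogate
        sp$cell_cv <- sg
        sp$mu0 <- mu0
        generate_dataset("11", T_min, sp, M = M_use, seed = cond_seed)
      } else {
        generate_dataset_ode("11", T_min,
          params = params, noise = noise,
          M = M_use, seed = cond_seed, dt_out_s = dt_out_s
        )
      }
      tibble::tibble(
        T_min = T_min, sigma = sg,
        fraction = mean(d$R_2 > 0.5 * d$R_1),
        n_cells = M_use
      )
    })
  })
  attr(out, "manifest") <- run_manifest(
    experiment = "fraction_responding", T_grid = T_grid,
    sigma_grid = sigma_grid, mu0 = mu0, M = M, backend = backend, seed = seed
  )
  out
}

#' Information transmitted in L-pulse sequences, theory vs estimate
#'
#' For each base repeating time `T`, tabulates the exact theory of the
#' deterministic transcoding channel (equal-probability MI and the capacity
#' `log2(K)`) next to numerical estimates on simulated noisy data under the
#' three input-probability schemes, plus the extreme optimized group masses.
#'
#' @param T_grid Base repeating times, minutes.
#' @param L Sequence length (default 4).
#' @param sigma,mu0 Noise parameters (defaults 0.1 and 0.03).
#' @param M Cells per sequence.
#' @param backend `"surrogate"` (default) or `"ode"`.
#' @param knn Nearest neighbours for the estimator.
#' @param tau Relaxation time used for the theory columns, minutes.
#' @param params,surrogate Backend base configurations.
#' @param seed RNG seed.
#' @param dt_out_s Trajectory grid, seconds (ode backend).
#' @param ... Passed to [maximize_mi()].
#' @return A tibble with one row per `T`: columns `T_min`, `k`, `K`,
#'   `mi_equal_all_theory`, `mi_max_theory`, `mi_maximized`,
#'   `mi_equal_representatives`, `mi_equal_all`, `group_mass_max`,
#'   `group_mass_min`.
#' @export
run_mi_table <- function(T_grid = c(60, 30, 20, 15), L = 4, sigma = 0.1,
                         mu0 = 0.03, M = 1000,
                         backend = c("surrogate", "ode"), knn = 15,
                         tau = 51.5, params = mapk_params(),
                         surrogate = surrogate_spec(), seed = 1L,
                         dt_out_s = 6, ...) {
  backend <- match.arg(backend)
  seqs <- all_sequences(L)
  out <- purrr::map_dfr(seq_along(T_grid), function(ti) {
    T_min <- T_grid[ti]
    k <- refractory_index(T_min, tau)
    part <- enumerate_groups(L, k)
    theory_all <- exact_mi_partition(part, scheme = "equal-all")
    sp <- surrogate
    sp$cell_cv <- sigma
    sp$mu0 <- mu0
    d <- backend_dataset(
      backend, seqs, T_min, M, seed + ti * 30013L,
      params, noise_spec(sigma = sigma, mu0 = mu0), sp, dt_out_s
    )
    str <- mi_precompute(d, knn = knn)
    cap <- maximize_mi(structure = str, ...)
    reps <- unique(part$representative)
    p_rep <- stats::setNames(
      ifelse(str$categories %in% reps, 1 / length(reps), 0), str$categories
    )
    gm <- group_mass(cap, part)
    tibble::tibble(
      T_min = T_min, k = k, K = attr(part, "K"),
      mi_equal_all_theory = theory_all$MI,
      mi_max_theory = log2(attr(part, "K")),
      mi_maximized = cap$C_bits,
      mi_equal_representatives = mi_eval(str, p_rep),
      mi_equal_all = cap$mi_uniform,
      group_mass_max = max(gm$mass),
      group_mass_min = min(gm$mass)
    )
  })
  attr(out, "manifest") <- run_manifest(
    experiment = "mi_table", T_grid = T_grid, L = L, sigma = sigma, mu0 = mu0,
    M = M, backend = backend, knn = knn, tau = tau, seed = seed
  )
  out
}

#' Bitrate versus pulse frequency across noise levels
#'
#' Scans base repeating times and noise levels, reporting the bitrate
#' `MI / (L * T)` in bit/h under the three input-probability schemes.
#'
#' @inheritParams run_mi_table
#' @param sigma_grid Cell-specific noise levels to scan.
#' @param mu0_grid Additive-noise medians to scan (crossed with `sigma_grid`).
#' @return A tibble with columns `T_min`, `phi_per_h`, `sigma`, `mu0`,
#'   `scheme`, `MI`, `bitrate_bit_per_h`.
#' @export
run_bitrate_scan <- function(T_grid = c(60, 30, 20, 15), L = 4,
                             sigma_grid = 0.3, mu0_grid = 0.03, M = 1000,
                             backend = c("surrogate", "ode"), knn = 15,
                             tau = 51.5, params = mapk_params(),
                             surrogate = surrogate_spec(), seed = 1L,
                             dt_out_s = 6, ...) {
  backend <- match.arg(backend)
  grid <- tidyr::expand_grid(T_min = T_grid, sigma = sigma_grid, mu0 = mu0_grid)
  seqs <- all_sequences(L)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    T_min <- grid$T_min[i]
    sp <- surrogate
    sp$cell_cv <- grid$sigma[i]
    sp$mu0 <- grid$mu0[i]
    part <- enumerate_groups(L, refractory_index(T_min, tau))
    d <- backend_dataset(
      backend, seqs, T_min, M, seed + i * 40009L,
      params, noise_spec(sigma = grid$sigma[i], mu0 = grid$mu0[i]), sp, dt_out_s
    )
    schemes <- mi_under_schemes(d, part, knn = knn, ...)
    dplyr::mutate(schemes,
      T_min = T_min, phi_per_h = 60 / T_min,
      sigma = grid$sigma[i], mu0 = grid$mu0[i],
      bitrate_bit_per_h = bitrate(.data$MI, L, T_min),
      .before = 1
    )
  })
  attr(out, "manifest") <- run_manifest(
    experiment = "bitrate_scan", T_grid = T_grid, L = L,
    sigma_grid = sigma_grid, mu0_grid = mu0_grid, M = M, backend = backend,
    knn = knn, tau = tau, seed = seed
  )
  out
}

# Uniform-input MI between a binary relabelling of the sequences and a
# coordinate subset (pools categories sharing a label).
relabel_mi <- function(data, labels, coords, knn = 15) {
  d <- data
  d$sequence <- labels[as.character(data$sequence)]
  estimate_mi(d, coords = coords, knn = knn)
}

#' Two-pulse resolution experiment
#'
#' Generates responses to the four length-2 sequences and quantifies how well
#' the channel resolves them: the joint two-dimensional MI and the
#' one-dimensional marginal MIs of the second-pulse response (conditioned on
#' the first pulse being 0, conditioned on it being 1, and unconditioned),
#' plus the first-pulse MI. A receiver with memory (joint MI) extracts more
#' information than a memoryless one reading the two pulses separately.
#'
#' @inheritParams run_mi_table
#' @param T_grid Base repeating times (default `c(40, 50, 60)`).
#' @param sigma,mu0 Noise parameters (defaults 0.3 and 0.03).
#' @return A tibble with columns `T_min`, `mi_joint`, `mi_R2_given_first_0`,
#'   `mi_R2_given_first_1`, `mi_R2_marginal`, `mi_R1`,
#'   `memoryless_sum` (`mi_R1 + mi_R2_marginal`).
#' @export
run_two_pulse <- function(T_grid = c(40, 50, 60), sigma = 0.3, mu0 = 0.03,
                          M = 1000, backend = c("surrogate", "ode"), knn = 15,
                          params = mapk_params(), surrogate = surrogate_spec(),
                          seed = 1L, dt_out_s = 6) {
  backend <- match.arg(backend)
  seqs <- all_sequences(2)
  out <- purrr::map_dfr(seq_along(T_grid), function(ti) {
    T_min <- T_grid[ti]
    sp <- surrogate
    sp$cell_cv <- sigma
    sp$mu0 <- mu0
    d <- backend_dataset(
      backend, seqs, T_min, M, seed + ti * 50021L,
      params, noise_spec(sigma = sigma, mu0 = mu0), sp, dt_out_s
    )
    second <- c("00" = "0", "01" = "1", "10" = "0", "11" = "1")
    first <- c("00" = "0", "01" = "0", "10" = "1", "11" = "1")
    mi_R2_marg <- relabel_mi(d, second, coords = "R_2", knn = knn)
    mi_R1 <- relabel_mi(d, first, coords = "R_1", knn = knn)
    tibble::tibble(
      T_min = T_min,
      mi_joint = estimate_mi(d, knn = knn),
      mi_R2_given_first_0 = estimate_mi(
        dplyr::filter(d, .data$sequence %in% c("00", "01")),
        coords = "R_2", knn = knn
      ),
      mi_R2_given_first_1 = estimate_mi(
        dplyr::filter(d, .data$sequence %in% c("10", "11")),
        coords = "R_2", knn = knn
      ),
      mi_R2_marginal = mi_R2_marg,
      mi_R1 = mi_R1,
      memoryless_sum = mi_R1 + mi_R2_marg
    )
  })
  attr(out, "manifest") <- run_manifest(
    experiment = "two_pulse", T_grid = T_grid, sigma = sigma, mu0 = mu0,
    M = M, backend = backend, knn = knn, seed = seed
  )
  out
}

#' Write a channel dataset (or any run table) to CSV with its manifest
#'
#' @param x A tibble produced by the package.
#' @param path CSV output path; the manifest, if present, is written next to
#'   it as `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  mf <- attr(x, "manifest")
  if (!is.null(mf)) {
    jsonlite::write_json(mf, paste0(path, ".manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(path)
}

#' Read a channel dataset written by [write_run_csv()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(sequence = "character"))
  tibble::as_tibble(d)
}
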