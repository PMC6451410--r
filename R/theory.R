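#' Refractory index of a pulse-interval code
#'
#' After the MAPK/ERK pathway emits a pulse of ERK activity it is refractory
#' for the relaxation time `tau` (about 51.5 min for the calibrated model).
#' When EGF pulses are delivered on a grid with base repeating time `T_min`,
#' the number of grid slots blocked after an emitted response is
#' `k = max{ j >= 0 : j * T_min < tau }`, i.e. the unique integer with
#' `k * T_min < tau <= (k + 1) * T_min`. `k = 0` means every slot can be
#' transmitted (`T_min >= tau`).
#'
#' @param T_min Base repeating time between pulse slots, in minutes.
#' @param tau Relaxation (refractory) time, in minutes. Default 51.5.
#' @return Integer refractory index `k >= 0`.
#' @examples
#' refractory_index(30)  # 1: one slot blocked after each ERK pulse
#' refractory_index(60)  # 0
#' @export
refractory_index <- function(T_min, tau = 51.5) {
  stopifnot(is.numeric(T_min), is.numeric(tau), length(T_min) == 1L, length(tau) == 1L)
  if (!is.finite(T_min) || !is.finite(tau) || T_min <= 0 || tau <= 0) {
    stop("`T_min` and `tau` must be positive and finite.", call. = FALSE)
  }
  k <- ceiling(tau / T_min) - 1L
  # strict inequality j*T < tau: when tau is an exact multiple of T the slot
  # exactly tau after a response is already transmittable
  if (k * T_min >= tau) k <- k - 1L
  as.integer(max(k, 0L))
}

# "101" <-> c(1L, 0L, 1L)
seq_to_bits <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) >= 1L)
  bits <- as.integer(strsplit(x, "", fixed = TRUE)[[1]])
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("Sequences must be strings of '0' and '1'.", call. = FALSE)
  }
  bits
}

bits_to_seq <- function(bits) paste(bits, collapse = "")

#' Transcode an EGF pulse sequence through the refractory channel
#'
#' Deterministic (noise-free) response rule: scanning left to right, an input
#' pulse elicits an ERK response only if no response was emitted in the
#' preceding `k` slots. The refractory window is counted from the most recent
#' *emitted* response, so e.g. `"111"` at `k = 1` becomes `"101"`: the second
#' pulse is absorbed, which frees the third slot.
#'
#' @param sequence A string of `'0'`/`'1'` characters (one slot per character),
#'   or a character vector of such strings (transcoded element-wise).
#' @param k Refractory index, a non-negative integer (see [refractory_index()]).
#' @return Transcoded sequence(s), same length and type as `sequence`.
#' @examples
#' transcode("111", k = 1)  # "101"
#' transcode("111", k = 2)  # "100"
#' @export
transcode <- function(sequence, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0, k == floor(k))
  k <- as.integer(k)
  out <- vapply(sequence, function(s) {
    bits <- seq_to_bits(s)
    res <- integer(length(bits))
    last_emit <- -Inf
    for (i in seq_along(bits)) {
      if (bits[i] == 1L && (i - last_emit) > k) {
        res[i] <- 1L
        last_emit <- i
      }
    }
    bits_to_seq(res)
  }, character(1), USE.NAMES = FALSE)
  out
}

#' All binary sequences of length L
#'
#' @param L Sequence length (number of pulse slots).
#' @return Character vector of the `2^L` sequences in lexicographic order.
#' @export
all_sequences <- function(L) {
  stopifnot(L >= 1, L == floor(L))
  if (L > 20) stop("Enumeration of 2^L sequences is limited to L <= 20.", call. = FALSE)
  grids <- rep(list(c("0", "1")), L)
  do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
}

#' Partition input sequences into transcoding groups
#'
#' Two input sequences that elicit the same ERK response sequence are
#' indistinguishable at the output; the preimages of the transcoding map
#' partition the `2^L` inputs into `K` groups. Each group contains exactly one
#' fixed point of the map (its "accurately transmitted" representative).
#'
#' @param L Sequence length, `1 <= L <= 20`.
#' @param k Refractory index.
#' @return A tibble of class `transcoding_partition` with one row per input
#'   sequence: columns `sequence` and `representative` (the transcoded output,
#'   shared within a group). Attributes `L`, `k` and `K` (number of groups).
#' @examples
#' enumerate_groups(L = 3, k = 1)   # K = 5 groups
#' @export
enumerate_groups <- function(L, k) {
  seqs <- all_sequences(L)
  reps <- transcode(seqs, k)
  out <- tibble::tibble(sequence = seqs, representative = reps)
  out <- dplyr::arrange(out, .data$representative, .data$sequence)
  structure(out,
    L = as.integer(L), k = as.integer(k),
    K = dplyr::n_distinct(reps),
    class = c("transcoding_partition", class(out))
  )
}

#' @export
print.transcoding_partition <- function(x, ...) {
  cat(sprintf(
    "Transcoding partition: L = %d, k = %d, K = %d groups\n",
    attr(x, "L"), attr(x, "k"), attr(x, "K")
  ))
  NextMethod()
}

#' Count accurately transmitted sequences
#'
#' Number of length-`L` binary sequences whose 1s are pairwise more than `k`
#' slots apart — the fixed points of [transcode()] and therefore the number of
#' transcoding groups. Satisfies the Fibonacci-type recurrence
#' `n_{L+1} = n_L + n_{L-k}`, with `n_L = L + 1` for `L <= k + 1`; for
#' `k = 0` this is `2^L`.
#'
#' @param L Sequence length (may be a vector).
#' @param k Refractory index.
#' @return Count(s) `n_L` as a double (exact for the ranges used here).
#' @examples
#' count_fixed_points(3, 1)  # 5
#' @export
count_fixed_points <- function(L, k) {
  stopifnot(all(L >= 1), k >= 0)
  k <- as.integer(k)
  Lmax <- max(L)
  if (k == 0L) return(2^L)
  n <- numeric(Lmax)
  upto <- min(k + 1L, Lmax)
  n[seq_len(upto)] <- seq_len(upto) + 1
  if (Lmax > k + 1L) {
    for (ell in (k + 2L):Lmax) n[ell] <- n[ell - 1L] + n[ell - 1L - k]
  }
  n[L]
}

#' Dominant root of the pulse-code recurrence
#'
#' The growth rate of `n_L` (see [count_fixed_points()]): the unique root in
#' (1, 2) of `a^(k+1) = a^k + 1`. For `k = 1` this is the golden ratio.
#'
#' @param k Refractory index, `1 <= k <= 100`.
#' @param tol Absolute root tolerance (default 1e-12).
#' @return The root `a_k`.
#' @export
dominant_root <- function(k, tol = 1e-12) {
  stopifnot(length(k) == 1L, k == floor(k))
  if (k < 1) stop("`k` must be >= 1.", call. = FALSE)
  f <- function(a) a^(k + 1) - a^k - 1
  stats::uniroot(f, c(1 + 1e-9, 2), tol = tol)$root
}

#' Prefactor of the asymptotic sequence count
#'
#' The constant `a_k0` with `n_L ~ a_k0 * a_k^L` as `L` grows. Computed as the
#' numerical limit of `n_L / a_k^L` from the recurrence, iterating until
#' successive estimates differ by less than `tol`.
#'
#' @param k Refractory index, `1 <= k <= 10`.
#' @param tol Convergence tolerance on successive estimates (default 1e-6).
#' @return The prefactor `a_k0`.
#' @export
prefactor <- function(k, tol = 1e-6) {
  stopifnot(k >= 1, k <= 10, k == floor(k))
  a <- dominant_root(k)
  est_prev <- -Inf
  for (L in seq(10, 400, by = 5)) {
    est <- count_fixed_points(L, k) / a^L
    if (abs(est - est_prev) < tol) return(est)
    est_prev <- est
  }
  est
}

#' Asymptotic channel capacity of the refractory pulse-interval code
#'
#' With slot duration `T = 60 / (k + 1)` minutes (so that a refractory window
#' spans just under one hour), the bitrate achievable by coding on accurately
#' transmitted sequences tends to `C(k) = (k + 1) * log2(a_k)` bits per hour.
#'
#' @param k Refractory index (vectorised), `k >= 1`.
#' @return Asymptotic capacity in bit/h.
#' @examples
#' asymptotic_bitrate(1:3)  # ~1.39, 1.65, 1.86 bit/h
#' @export
asymptotic_bitrate <- function(k) {
  vapply(k, function(ki) (ki + 1) * log2(dominant_root(ki)), numeric(1))
}

#' Maximal information in a finite pulse sequence
#'
#' Exact value `log2(n_L)` (bits transmittable over length-`L` sequences by
#' coding on fixed points) alongside the asymptotic approximation
#' `log2(a_k0) + L * log2(a_k)`. The two agree to ~0.02 bit for `L >= 10`.
#'
#' @param k Refractory index, `>= 1`.
#' @param L Sequence length (vectorised).
#' @return A tibble with columns `k`, `L`, `mi_exact`, `mi_asymptotic` (bits).
#' @export
finite_L_mi <- function(k, L) {
  stopifnot(k >= 1, all(L >= 1))
  a <- dominant_root(k)
  a0 <- prefactor(k)
  mi_exact <- log2(count_fixed_points(L, k))
  tibble::tibble(
    k = as.integer(k), L = as.integer(L),
    mi_exact = mi_exact,
    mi_asymptotic = log2(a0) + L * log2(a)
  )
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Exact mutual information of the deterministic transcoding channel
#'
#' For the noise-free channel the output is a deterministic function of the
#' input, so `H(Y|X) = 0` and `MI = H(Y)`: the entropy of the total input
#' probability mass per transcoding group. Three input-distribution schemes
#' are supported: `"equal-all"` (uniform over all `2^L` sequences),
#' `"equal-representatives"` (uniform over the `K` fixed points) and
#' `"maximized"` (any distribution with mass `1/K` per group; capacity
#' `log2(K)`). A custom probability vector over the sequences of the partition
#' may be supplied instead.
#'
#' @param partition A [enumerate_groups()] result.
#' @param p Optional numeric probabilities, named by sequence or in the row
#'   order of `partition`; must sum to 1 (tolerance 1e-9). Overrides `scheme`.
#' @param scheme One of `"equal-all"`, `"equal-representatives"`, `"maximized"`.
#' @return A one-row tibble: `scheme`, `H_X`, `H_X_given_Y`, `MI` (bits), `K`.
#' @examples
#' part <- enumerate_groups(4, 1)
#' exact_mi_partition(part, scheme = "equal-all")$MI  # 23/8 = 2.875
#' @export
exact_mi_partition <- function(partition, p = NULL,
                               scheme = c("equal-all", "equal-representatives", "maximized")) {
  stopifnot(inherits(partition, "transcoding_partition"))
  K <- attr(partition, "K")
  n_seq <- nrow(partition)
  if (is.null(p)) {
    scheme <- match.arg(scheme)
    p <- switch(scheme,
      "equal-all" = rep(1 / n_seq, n_seq),
      "equal-representatives" = ifelse(partition$sequence == partition$representative,
        1 / K, 0
      ),
      "maximized" = ifelse(partition$sequence == partition$representative, 1 / K, 0)
    )
  } else {
    scheme <- "custom"
    if (!is.null(names(p))) {
      if (!setequal(names(p), partition$sequence)) {
        stop("Names of `p` must be exactly the sequences of the partition.", call. = FALSE)
      }
      p <- p[partition$sequence]
    }
    if (length(p) != n_seq || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("`p` must be a probability vector over the partition's sequences.", call. = FALSE)
    }
  }
  q_group <- tapply(p, partition$representative, sum)
  H_X <- entropy_bits(p)
  MI <- entropy_bits(as.numeric(q_group))
  tibble::tibble(
    scheme = scheme, H_X = H_X, H_X_given_Y = H_X - MI, MI = MI, K = K
  )
}

#' Convert mutual information to a bitrate
#'
#' @param MI Mutual information in bits.
#' @param L Number of pulse slots.
#' @param T_min Slot duration in minutes.
#' @return Bitrate in bit/h: `MI / (L * T_min / 60)`.
#' @examples
#' bitrate(log2(5), L = 3, T_min = 30)  # ~1.55 bit/h
#' @export
bitrate <- function(MI, L, T_min) {
  stopifnot(all(MI >= 0), all(L >= 1), all(T_min > 0))
  MI / (L * T_min / 60)
}

#' Summary table of the pulse-interval coding theory
#'
#' One row per refractory index: slot duration on the one-hour convention,
#' dominant root, prefactor, and asymptotic capacity.
#'
#' @param k Integer vector of refractory indices (default 1:3).
#' @return A tibble with columns `k`, `n_slots_per_hour`, `T_min`, `a_k`,
#'   `a_k0`, `C_bit_per_h`.
#' @export
theory_table <- function(k = 1:3) {
  tibble::tibble(
    k = as.integer(k),
    n_slots_per_hour = k + 1L,
    T_min = 60 / (k + 1),
    a_k = vapply(k, dominant_root, numeric(1)),
    a_k0 = vapply(k, function(ki) if (ki <= 10) prefactor(ki) else NA_real_, numeric(1)),
    C_bit_per_h = asymptotic_bitrate(k)
  )
}
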