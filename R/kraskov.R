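#' @title Weighted k-nearest-neighbour mutual information for discrete inputs
#' @description
#' The channel of interest has a discrete input (a pulse sequence) and a
#' continuous multi-dimensional output (the vector of integrated ERK
#' responses). [estimate_mi()] implements a Kraskov-type kNN estimator for
#' this mixed case: for each sample the distance to its `knn`-th nearest
#' same-category neighbour (Chebyshev metric) defines a radius, and the
#' number of samples of *all* categories within that radius estimates the
#' output marginal. Counts of category `x'` are weighted by
#' `p(x') * N / M_x'`, so the same sampled dataset can be re-scored under any
#' input distribution — this is what makes direct capacity maximization over
#' `p` possible (see [maximize_mi()]).
#' @name mi-estimation
NULL

response_cols <- function(data) {
  cols <- grep("^R_[0-9]+$", names(data), value = TRUE)
  if (length(cols) == 0) {
    stop("Dataset must contain response columns R_1, R_2, ...", call. = FALSE)
  }
  cols[order(as.integer(sub("^R_", "", cols)))]
}

# Split a dataset tibble into per-category response matrices.
split_by_category <- function(data, coords = NULL) {
  stopifnot(is.data.frame(data), "sequence" %in% names(data))
  cols <- response_cols(data)
  if (!is.null(coords)) {
    if (is.numeric(coords)) coords <- paste0("R_", coords)
    stopifnot(all(coords %in% cols))
    cols <- coords
  }
  Y <- as.matrix(data[, cols, drop = FALSE])
  if (!all(is.finite(Y))) stop("Non-finite response values in dataset.", call. = FALSE)
  cats <- as.character(data$sequence)
  levels <- sort(unique(cats))
  mats <- lapply(levels, function(lv) Y[cats == lv, , drop = FALSE])
  names(mats) <- levels
  mats
}

# Draw deterministic jitter without disturbing the caller's RNG stream.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Precompute the neighbour structure of a channel dataset
#'
#' Computes, once per dataset, everything the weighted estimator needs:
#' per-point radii (Chebyshev distance to the `knn`-th same-category
#' neighbour) and the integer matrix of strict within-radius counts against
#' every category. Re-scoring under a new input distribution then only
#' re-weights these counts, so one precomputation supports thousands of
#' optimizer iterations.
#'
#' Exactly duplicated response vectors (e.g. the noise-free surrogate limit)
#' would give zero radii; when any duplicate is present a deterministic
#' symmetric jitter of relative scale `jitter` is added to all points first.
#'
#' @param data Tibble with a `sequence` column and response columns
#'   `R_1 ... R_d` (see [generate_dataset()]).
#' @param knn Number of nearest neighbours (default 15).
#' @param coords Optional subset of response coordinates (names `"R_i"` or
#'   integer indices) onto which the dataset is projected first.
#' @param jitter Relative duplicate-breaking jitter scale (default 1e-10).
#' @param jitter_seed Seed of the private jitter stream (default 421).
#' @return An object of class `mi_structure`.
#' @export
mi_precompute <- function(data, knn = 15, coords = NULL, jitter = 1e-10,
                          jitter_seed = 421L) {
  stopifnot(knn >= 1)
  mats <- split_by_category(data, coords = coords)
  M <- vapply(mats, nrow, integer(1))
  if (any(M < knn + 1)) {
    stop(sprintf(
      "Every category needs at least knn + 1 = %d samples (smallest has %d).",
      knn + 1, min(M)
    ), call. = FALSE)
  }
  Yall <- do.call(rbind, mats)
  scale <- max(apply(Yall, 2, function(v) diff(range(v))), na.rm = TRUE)
  if (scale == 0) scale <- max(abs(Yall), 1)
  if (anyDuplicated(Yall) > 0) {
    eps <- jitter * scale
    jit <- with_private_seed(jitter_seed, {
      matrix(stats::runif(length(Yall), -eps, eps), nrow = nrow(Yall))
    })
    Yall <- Yall + jit
    start <- cumsum(c(0L, M))
    mats <- lapply(seq_along(mats), function(c) {
      Yall[(start[c] + 1L):start[c + 1L], , drop = FALSE]
    })
    names(mats) <- names(M)
  }
  eps_list <- lapply(mats, cheby_knn_dist, k = knn)
  X <- do.call(rbind, mats)
  eps_all <- unlist(eps_list, use.names = FALSE)
  cat_idx <- rep(seq_along(mats), M) # 1-based category of each point
  self_idx <- unlist(lapply(M, seq_len), use.names = FALSE) - 1L
  counts <- cheby_count_within(X, eps_all, mats, cat_idx - 1L, self_idx)
  structure(
    list(
      categories = names(M), M = M, knn = knn,
      cat_idx = cat_idx, counts = counts, N = sum(M)
    ),
    class = "mi_structure"
  )
}

# Resolve an input distribution against the structure's categories.
resolve_p <- function(p, categories) {
  if (is.null(p)) {
    p <- rep(1 / length(categories), length(categories))
    names(p) <- categories
    return(p)
  }
  if (is.data.frame(p)) p <- stats::setNames(p[[2]], p[[1]])
  if (!is.null(names(p))) {
    missing <- setdiff(categories, names(p))
    if (length(missing)) {
      stop("`p` is missing categories: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    p <- p[categories]
  } else if (length(p) != length(categories)) {
    stop("Unnamed `p` must have one entry per category.", call. = FALSE)
  }
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("`p` must be non-negative and sum to 1 (tolerance 1e-9).", call. = FALSE)
  }
  names(p) <- categories
  p
}

# Core weighted evaluation, in bits. Categories with p = 0 contribute
# nothing to the average and weight 0 to the marginal counts.
mi_eval <- function(str, p, clip = TRUE) {
  w <- p * str$N / str$M # weight carried by one point of each category
  m <- as.numeric(str$counts %*% w) + w[str$cat_idx]
  active <- p[str$cat_idx] > 0
  A <- digamma(str$knn) - digamma(str$M) + digamma(str$N)
  val <- A[str$cat_idx] - digamma(m)
  per_cat <- tapply(val[active], str$cat_idx[active], mean)
  mi <- sum(p[as.integer(names(per_cat))] * per_cat) / log(2)
  if (clip) mi <- max(mi, 0)
  mi
}

#' Estimate mutual information between pulse sequences and ERK responses
#'
#' Weighted Kraskov-type kNN estimate of MI (in bits) between the discrete
#' `sequence` labels and the continuous response vectors of a channel
#' dataset, under an arbitrary input distribution `p`. See [mi-estimation]
#' for the method and [mi_precompute()] for the reusable neighbour structure.
#'
#' @inheritParams mi_precompute
#' @param p Input distribution over sequences: a named numeric vector, a
#'   two-column data frame (sequence, probability), or `NULL` for uniform
#'   over the categories present.
#' @param structure Optionally a precomputed [mi_precompute()] result (then
#'   `data`, `knn`, `coords`, `jitter` are ignored).
#' @param clip Clip the estimate below at 0 bits (default TRUE).
#' @return MI estimate in bits.
#' @examples
#' spec <- surrogate_spec(miss_width = 0, cell_cv = 0, mu0 = 0)
#' d <- generate_dataset(all_sequences(3), T_min = 30, spec = spec, M = 25, seed = 1)
#' estimate_mi(d, knn = 5) # ~ log2(5): five distinguishable groups
#' @export
estimate_mi <- function(data, p = NULL, knn = 15, coords = NULL,
                        jitter = 1e-10, structure = NULL, clip = TRUE) {
  str <- structure %||% mi_precompute(data, knn = knn, coords = coords, jitter = jitter)
  p <- resolve_p(p, str$categories)
  mi_eval(str, p, clip = clip)
}

#' Marginal mutual information of a coordinate subset
#'
#' Projects the dataset onto a subset of response coordinates before
#' estimation — e.g. MI between `{"10","11"}` and the second-pulse response
#' alone, as used to compare a memoryless receiver with one that sees the
#' full response vector.
#'
#' @inheritParams estimate_mi
#' @param coords Response coordinates to keep: integer indices or `"R_i"` names.
#' @return MI estimate in bits.
#' @export
marginal_mi <- function(data, coords, p = NULL, knn = 15, jitter = 1e-10) {
  stopifnot(length(coords) >= 1)
  estimate_mi(data, p = p, knn = knn, coords = coords, jitter = jitter)
}

#' Pool a long-sequence dataset into a shorter one by truncation
#'
#' Keeps the first `d` response coordinates and relabels each sample by the
#' first `d` characters of its input sequence, pooling across suffixes. This
#' mirrors the analysis of short sequences on data simulated for longer ones,
#' multiplying the effective sample count per category.
#'
#' @param data Channel dataset tibble.
#' @param d Number of leading pulses to keep.
#' @return A channel dataset tibble with `R_1 ... R_d`.
#' @export
truncate_dataset <- function(data, d) {
  cols <- response_cols(data)
  stopifnot(d >= 1, d <= length(cols))
  out <- data[, c("sequence", intersect("cell_id", names(data)), cols[seq_len(d)])]
  out$sequence <- substr(as.character(out$sequence), 1, d)
  tibble::as_tibble(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
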