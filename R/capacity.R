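#' Channel capacity by gradient ascent over the input distribution
#'
#' Maximizes the weighted kNN MI estimate ([estimate_mi()]) over the input
#' distribution `p`. The neighbour structure is computed once; each iteration
#' only re-weights the stored counts, so an evaluation is a single
#' matrix-vector product. `p` is parametrized as `softmax(logits)` (the
#' simplex constraint is built in) and ascended with an Adam-style adaptive
#' gradient method using the analytic gradient of the weighted estimator;
#' several random restarts guard against poor starts.
#'
#' @param data Channel dataset tibble (see [generate_dataset()]); ignored if
#'   `structure` is supplied.
#' @param knn Number of nearest neighbours (default 15).
#' @param structure Optional precomputed [mi_precompute()] result.
#' @param step Adam learning rate (default 0.05).
#' @param iterations Maximum iterations per restart (default 2000).
#' @param restarts Number of restarts (default 3); the first starts from the
#'   uniform distribution, the rest from random logits.
#' @param tol Convergence: stop when MI improves by less than `tol` bits over
#'   `patience` iterations (defaults 1e-4 bits, 50 iterations).
#' @param patience See `tol`.
#' @param seed Seed for restart initialization.
#' @return An object of class `capacity_estimate`: a list with elements
#'   `C_bits`, `p_star` (tibble `sequence`, `p`), `mi_uniform`, `trace`
#'   (tibble `restart`, `iter`, `mi`), `knn`, `seed`, `restarts`,
#'   `converged`.
#' @examples
#' spec <- surrogate_spec(miss_width = 0, cell_cv = 0, mu0 = 0)
#' d <- generate_dataset(all_sequences(2), 30, spec, M = 30, seed = 2)
#' cap <- maximize_mi(d, knn = 5, iterations = 300, restarts = 1)
#' glance(cap)
#' @export
maximize_mi <- function(data = NULL, knn = 15, structure = NULL, step = 0.05,
                        iterations = 2000, restarts = 3, tol = 1e-4,
                        patience = 50, seed = 1L) {
  str <- structure %||% mi_precompute(data, knn = knn)
  C <- length(str$categories)
  mi_uniform <- mi_eval(str, stats::setNames(rep(1 / C, C), str$categories))
  set.seed(seed)
  best <- list(mi = -Inf)
  traces <- list()
  converged <- logical(restarts)
  for (r in seq_len(restarts)) {
    logits <- if (r == 1) rep(0, C) else stats::rnorm(C)
    fit <- adam_ascend(str, logits, step, iterations, tol, patience)
    converged[r] <- fit$converged
    traces[[r]] <- tibble::tibble(
      restart = r, iter = seq_along(fit$trace), mi = fit$trace
    )
    if (fit$mi > best$mi) best <- fit
  }
  p_star <- unname(softmax(best$logits))
  structure(
    list(
      C_bits = max(best$mi, mi_uniform),
      p_star = tibble::tibble(sequence = str$categories, p = p_star),
      mi_uniform = mi_uniform,
      trace = dplyr::bind_rows(traces),
      knn = str$knn, seed = seed, restarts = restarts,
      converged = all(converged)
    ),
    class = "capacity_estimate"
  )
}

softmax <- function(z) {
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

# Objective (nats) and analytic gradient wrt p of the weighted estimator.
mi_objective_grad <- function(str, p) {
  N <- str$N
  M <- str$M
  ci <- str$cat_idx
  w <- p * N / M
  g <- as.numeric(str$counts %*% w) + w[ci]
  g <- pmax(g, 1e-12)
  A <- digamma(str$knn) - digamma(M) + digamma(N)
  val <- A[ci] - digamma(g) # per-point log-density ratio estimate
  per_cat_sum <- tapply(val, ci, sum)
  obj <- sum(p / M * as.numeric(per_cat_sum))
  # d obj / d p_y = mean_{j in y} val_j  -  sum_j (p_cj / M_cj) psi'(g_j) * Ctilde[j, y] * N / M_y
  v <- (p[ci] / M[ci]) * trigamma(g)
  cross <- as.numeric(crossprod(str$counts, v)) # sum_j v_j * counts[j, y]
  self_term <- as.numeric(tapply(v, ci, sum)) # counts matrix excludes self
  grad <- as.numeric(per_cat_sum) / M - (cross + self_term) * N / M
  list(obj = obj, grad = grad)
}

adam_ascend <- function(str, logits, step, iterations, tol, patience,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  C <- length(logits)
  m <- v <- numeric(C)
  trace <- numeric(iterations)
  best_mi <- -Inf
  best_logits <- logits
  converged <- FALSE
  for (it in seq_len(iterations)) {
    p <- softmax(logits)
    og <- mi_objective_grad(str, p)
    mi_bits <- og$obj / log(2)
    trace[it] <- mi_bits
    if (mi_bits > best_mi) {
      best_mi <- mi_bits
      best_logits <- logits
    }
    if (it > patience && (best_mi - max(trace[seq_len(it - patience)])) < tol) {
      converged <- TRUE
      trace <- trace[seq_len(it)]
      break
    }
    grad_logits <- p * (og$grad - sum(p * og$grad))
    m <- beta1 * m + (1 - beta1) * grad_logits
    v <- beta2 * v + (1 - beta2) * grad_logits^2
    mhat <- m / (1 - beta1^it)
    vhat <- v / (1 - beta2^it)
    logits <- logits + step * mhat / (sqrt(vhat) + eps)
    logits <- pmin(pmax(logits - mean(logits), -20), 20)
  }
  if (!converged) {
    warning("Capacity optimizer did not converge; returning best iterate.", call. = FALSE)
  }
  list(mi = best_mi, logits = best_logits, trace = trace, converged = converged)
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat(sprintf(
    "Channel capacity estimate: C = %.3f bits (uniform-input MI %.3f bits)\n",
    x$C_bits, x$mi_uniform
  ))
  cat(sprintf(
    "  %d categories, knn = %d, %d restart(s), converged: %s\n",
    nrow(x$p_star), x$knn, x$restarts, x$converged
  ))
  invisible(x)
}

#' @describeIn maximize_mi Optimal input distribution, one row per sequence.
#' @param x A `capacity_estimate`.
#' @param ... Unused.
#' @export
tidy.capacity_estimate <- function(x, ...) x$p_star

#' @describeIn maximize_mi One-row model summary.
#' @export
glance.capacity_estimate <- function(x, ...) {
  tibble::tibble(
    C_bits = x$C_bits, mi_uniform = x$mi_uniform,
    n_categories = nrow(x$p_star), knn = x$knn,
    restarts = x$restarts, iterations = nrow(x$trace),
    converged = x$converged
  )
}

#' Optimal mass per transcoding group
#'
#' Sums the optimized input distribution over the groups of a transcoding
#' partition; on a noise-free partition channel the capacity-achieving
#' distribution puts mass `1/K` on each group.
#'
#' @param cap A [maximize_mi()] result.
#' @param partition A [enumerate_groups()] partition covering the dataset's
#'   sequences.
#' @return A tibble with columns `representative`, `mass`.
#' @export
group_mass <- function(cap, partition) {
  stopifnot(inherits(cap, "capacity_estimate"), inherits(partition, "transcoding_partition"))
  joined <- dplyr::inner_join(cap$p_star, partition, by = "sequence")
  if (nrow(joined) != nrow(cap$p_star)) {
    stop("Partition does not cover all dataset sequences.", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(joined, .data$representative),
    mass = sum(.data$p), .groups = "drop"
  )
}

#' MI of a dataset under the three canonical input-probability schemes
#'
#' Scheme `"equal-all"`: uniform over all input sequences. Scheme
#' `"equal-representatives"`: uniform over the group representatives (fixed
#' points of the transcoding map), zero elsewhere. Scheme `"maximized"`: MI
#' maximized over the input distribution ([maximize_mi()]). For small noise
#' the maximized value coincides with the equal-representatives value.
#'
#' @param data Channel dataset tibble covering all sequences of `partition`.
#' @param partition A [enumerate_groups()] partition.
#' @param knn Number of nearest neighbours.
#' @param ... Passed to [maximize_mi()].
#' @return A tibble with columns `scheme`, `MI` (bits).
#' @export
mi_under_schemes <- function(data, partition, knn = 15, ...) {
  stopifnot(inherits(partition, "transcoding_partition"))
  str <- mi_precompute(data, knn = knn)
  if (!setequal(str$categories, partition$sequence)) {
    stop("Dataset categories must match the partition's sequences.", call. = FALSE)
  }
  reps <- unique(partition$representative)
  p_rep <- stats::setNames(
    ifelse(str$categories %in% reps, 1 / length(reps), 0),
    str$categories
  )
  cap <- maximize_mi(structure = str, ...)
  tibble::tibble(
    scheme = c("equal-all", "equal-representatives", "maximized"),
    MI = c(
      mi_eval(str, resolve_p(NULL, str$categories)),
      mi_eval(str, p_rep),
      cap$C_bits
    )
  )
}
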