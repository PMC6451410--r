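test_that("refractory index brackets the relaxation time", {
  expect_identical(refractory_index(30, 51.5), 1L)
  expect_identical(refractory_index(60, 51.5), 0L)
  expect_identical(refractory_index(15, 51.5), 3L)
  expect_identical(refractory_index(20, 51.5), 2L)
  # strict inequality j*T < tau at an exact multiple
  expect_identical(refractory_index(30, 60), 1L)
  expect_error(refractory_index(-5, 51.5), "positive")
  expect_error(refractory_index(30, 0), "positive")
})

test_that("transcoding reproduces the worked response patterns", {
  expect_identical(transcode("111", 1), "101")
  expect_identical(transcode("111", 2), "100")
  expect_identical(transcode("110", 1), "100")
  expect_identical(transcode("011", 1), "010")
  expect_identical(transcode(c("100", "110", "101", "111"), 2), rep("100", 4))
  expect_identical(transcode("000", 3), "000")
  # k = 0 is the identity
  expect_identical(transcode(all_sequences(4), 0), all_sequences(4))
})

test_that("transcoding is idempotent and its fixed points are the gap-constrained sequences", {
  for (k in 0:4) {
    for (L in c(3, 6, 9)) {
      seqs <- all_sequences(L)
      once <- transcode(seqs, k)
      expect_identical(transcode(once, k), once)
      fixed <- seqs[once == seqs]
      gap_ok <- vapply(seqs, function(s) {
        ones <- which(strsplit(s, "")[[1]] == "1")
        length(ones) < 2 || min(diff(ones)) > k
      }, logical(1))
      expect_setequal(fixed, seqs[gap_ok])
      expect_identical(length(fixed), as.integer(count_fixed_points(L, k)))
    }
  }
})

test_that("group enumeration reproduces the published L = 4, k = 1 partition", {
  part <- enumerate_groups(4, 1)
  expect_identical(attr(part, "K"), 8L)
  groups <- split(part$sequence, part$representative)
  expected <- list(
    c("0000"), c("0001"), c("0010", "0011"), c("0100", "0110"),
    c("0101", "0111"), c("1000", "1100"), c("1001", "1101"),
    c("1010", "1110", "1011", "1111")
  )
  for (g in expected) {
    expect_true(g[1] %in% names(groups))
    expect_setequal(groups[[g[1]]], g)
  }
  # every representative is a fixed point and member of its own group
  expect_true(all(transcode(names(groups), 1) == names(groups)))
})

test_that("group counts match fixed-point counts across L and k", {
  expect_identical(attr(enumerate_groups(3, 0), "K"), 8L)
  expect_identical(attr(enumerate_groups(3, 1), "K"), 5L)
  expect_identical(attr(enumerate_groups(3, 2), "K"), 4L)
  expect_identical(attr(enumerate_groups(2, 0), "K"), 4L)
  for (k in 0:3) {
    for (L in c(2, 5, 8)) {
      expect_identical(
        attr(enumerate_groups(L, k), "K"),
        as.integer(count_fixed_points(L, k))
      )
    }
  }
  expect_error(all_sequences(25), "20")
})

test_that("fixed-point counts satisfy the recurrence and brute force", {
  expect_equal(count_fixed_points(3, 1), 5)
  expect_equal(count_fixed_points(4, 2), 6)
  expect_equal(count_fixed_points(1, 5), 2)
  expect_equal(count_fixed_points(1:6, 0), 2^(1:6))
  for (k in 1:4) {
    for (L in c(2, 6, 10)) {
      expect_equal(count_fixed_points(L, k), brute_count_valid(L, k))
    }
    # recurrence n_{L+1} = n_L + n_{L-k}
    n <- count_fixed_points(1:20, k)
    for (L in (k + 2):19) expect_equal(n[L + 1], n[L] + n[L - k])
  }
})

test_that("dominant roots match an independent bisection oracle", {
  bisect <- function(k) {
    lo <- 1
    hi <- 2
    f <- function(a) a^(k + 1) - a^k - 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    mid
  }
  expect_equal(dominant_root(1), (1 + sqrt(5)) / 2, tolerance = 1e-10)
  for (k in c(1, 2, 3, 10)) {
    expect_equal(dominant_root(k), bisect(k), tolerance = 1e-10)
  }
  expect_equal(dominant_root(2), 1.4655712319, tolerance = 1e-8)
  expect_equal(dominant_root(3), 1.3802775691, tolerance = 1e-8)
  expect_error(dominant_root(0), "k")
})

test_that("prefactors agree with the closed form and the eigen-decomposition oracle", {
  phi <- (1 + sqrt(5)) / 2
  expect_equal(prefactor(1), phi^2 / sqrt(5), tolerance = 1e-4)
  # linear-recurrence eigen oracle: solve for the coefficient of the dominant
  # root from the seeds n_1..n_{k+1} using all characteristic roots
  eigen_prefactor <- function(k) {
    roots <- polyroot(c(-1, rep(0, k - 1), -1, 1)) # a^{k+1} - a^k - 1
    V <- t(vapply(1:(k + 1), function(L) roots^L, complex(k + 1)))
    coef <- solve(V, as.complex((1:(k + 1)) + 1))
    dom <- which.max(Mod(roots))
    expect_lt(max(Mod(roots[-dom])), Mod(roots[dom]))
    Re(coef[dom])
  }
  for (k in 1:3) {
    expect_equal(prefactor(k), eigen_prefactor(k), tolerance = 1e-6)
  }
  # self-consistency: n_L / (a_k0 * a_k^L) -> 1 within 1% at L = 40
  for (k in c(1, 2, 3, 10)) {
    ratio <- count_fixed_points(40, k) / (prefactor(k) * dominant_root(k)^40)
    expect_equal(ratio, 1, tolerance = 0.01)
  }
})

test_that("asymptotic capacity is monotone and approaches log2(k)", {
  C <- asymptotic_bitrate(1:20)
  expect_true(all(diff(C) > 0))
  expect_true(1 < dominant_root(50) && dominant_root(50) < 2)
  expect_true(all(diff(vapply(1:20, dominant_root, numeric(1))) < 0))
  # C(k) ~ log2(k) - log2(ln k) for large k: the leading ratio sits in a
  # narrow window over the computable range (the log-log correction decays
  # only at astronomically large k)
  ratio <- asymptotic_bitrate(c(10, 30, 100)) / log2(c(10, 30, 100))
  expect_true(all(ratio > 0.7 & ratio < 1))
  corrected <- asymptotic_bitrate(c(10, 30, 100)) -
    (log2(c(10, 30, 100)) - log2(log(c(10, 30, 100))))
  expect_true(all(abs(corrected) < 1))
})

test_that("finite-length MI interpolates between exact and asymptotic forms", {
  expect_equal(finite_L_mi(1, 4)$mi_exact, 3)
  expect_equal(finite_L_mi(1, 3)$mi_exact, log2(5))
  for (k in 1:3) {
    tab <- finite_L_mi(k, c(10, 20, 30))
    expect_true(all(abs(tab$mi_exact - tab$mi_asymptotic) < 0.02))
  }
})

test_that("exact partition MI matches hand calculations and the brute-force sum", {
  part <- enumerate_groups(4, 1)
  expect_equal(exact_mi_partition(part, scheme = "equal-all")$MI, 23 / 8)
  expect_equal(exact_mi_partition(part, scheme = "maximized")$MI, 3)
  expect_equal(exact_mi_partition(part, scheme = "equal-representatives")$MI, 3)
  expect_equal(exact_mi_partition(enumerate_groups(4, 2), scheme = "equal-all")$MI, 4 - 13 / 8)
  expect_equal(exact_mi_partition(enumerate_groups(4, 3), scheme = "equal-all")$MI, 4 - 17 / 8)
  # any p with mass 1/8 per group achieves the maximum
  masses <- rep(1 / 8, 8)
  p <- numeric(nrow(part))
  for (rep_seq in unique(part$representative)) {
    idx <- which(part$representative == rep_seq)
    w <- stats::runif(length(idx))
    p[idx] <- (1 / 8) * w / sum(w)
  }
  expect_equal(exact_mi_partition(part, p = p)$MI, 3, tolerance = 1e-12)
  # agreement with direct evaluation of the finite double sum
  set.seed(42)
  for (spec in list(c(3, 1), c(4, 2), c(5, 1))) {
    pt <- enumerate_groups(spec[1], spec[2])
    pr <- stats::runif(nrow(pt))
    pr <- pr / sum(pr)
    expect_equal(exact_mi_partition(pt, p = pr)$MI, brute_mi_deterministic(pt, pr))
    # schemes ordering: equal-all never beats maximized = log2(K)
    expect_lte(
      exact_mi_partition(pt, scheme = "equal-all")$MI,
      exact_mi_partition(pt, scheme = "maximized")$MI
    )
  }
  expect_error(exact_mi_partition(part, p = rep(0.1, 16)), "probability")
})

test_that("bitrate converts MI per protocol duration to bits per hour", {
  expect_equal(bitrate(log2(5), 3, 30), log2(5) / 1.5)
  expect_equal(bitrate(log2(8), 3, 60), 1)
  expect_equal(bitrate(0, 5, 20), 0)
  tab <- theory_table(1:3)
  expect_equal(tab$C_bit_per_h, asymptotic_bitrate(1:3))
  expect_equal(tab$n_slots_per_hour, 2:4)
})
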