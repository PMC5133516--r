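test_that("nearest-neighbor windows contain k sites with the anchor inside", {
  pos <- seq(1e5, 1e7, length.out = 100)
  win <- build_windows(pos, window_spec(b_percent = 5))
  expect_equal(nrow(win), 100L)
  expect_true(all(win$hi - win$lo + 1L == 5L))          # k = ceil(0.05*100)
  expect_true(all(win$anchor >= win$lo & win$anchor <= win$hi))
  # first anchor: one-sided window of the 5 left-most sites
  expect_equal(c(win$lo[1], win$hi[1]), c(1L, 5L))
  # interior anchor with uniform spacing and odd k: symmetric members
  expect_equal(win$anchor[50] - win$lo[50], win$hi[50] - win$anchor[50])
  # every member strictly inside the bandwidth
  for (i in c(1, 3, 50, 98, 100)) {
    d <- abs(pos[win$lo[i]:win$hi[i]] - pos[win$anchor[i]])
    expect_true(all(d < win$h[i]))
  }
})

test_that("window construction breaks distance ties toward lower position", {
  pos <- c(100, 200, 300, 400, 500)
  win <- build_windows(pos, window_spec(b_percent = 40))  # k = 2
  # anchor 3: sites 2 and 4 are equidistant; tie goes left
  expect_equal(c(win$lo[3], win$hi[3]), c(2L, 3L))
})

test_that("oversized windows are rejected", {
  expect_error(build_windows(c(1, 2), window_spec(b_percent = 100,
                                                  anchor_stride = 1)), NA)
  expect_error(
    build_windows(seq_len(10), structure(list(b_percent = 200, degree = 1L,
                                              anchor_stride = 1L,
                                              clamp = TRUE),
                                         class = "window_spec")),
    "smaller b_percent")
})

test_that("cubic kernel matches direct evaluation and its symmetries", {
  expect_equal(kernel_weight(0), 1)
  expect_equal(kernel_weight(1), 0)
  expect_equal(kernel_weight(0.5), 0.669921875)
  u <- seq(-2, 2, by = 0.01)
  expect_equal(kernel_weight(u), kernel_weight(-u))     # even
  au <- seq(0, 1.5, by = 0.01)
  expect_true(all(diff(kernel_weight(au)) <= 1e-12))    # nonincreasing in |u|
  expect_true(all(kernel_weight(u) >= 0 & kernel_weight(u) <= 1))
})

test_that("locus weight follows the MAF/0.05 rule", {
  expect_equal(locus_weight(0.05), 1)
  expect_equal(locus_weight(0.025), 0.5)
  expect_equal(locus_weight(0), 0)
  expect_equal(locus_weight(0.5), 1)
  expect_equal(locus_weight(NA), 0)
  maf <- seq(0, 0.5, by = 0.005)
  expect_true(all(diff(locus_weight(maf)) >= 0))        # nondecreasing
  expect_error(locus_weight(0.6), "MAF")
  expect_error(locus_weight(-0.1), "MAF")
})

test_that("local polynomial fit matches a brute-force WLS oracle", {
  set.seed(42)
  for (degree in 0:2) {
    dx <- sort(runif(30, -100, 100))
    y <- rbinom(30, 1, 0.7)
    w <- runif(30)
    fit <- fit_local_polynomial(dx, y, w, degree = degree, clamp = FALSE)
    oracle <- brute_force_wls(dx, y, w, degree)
    expect_equal(fit$alpha, as.numeric(oracle), tolerance = 1e-10)
  }
})

test_that("degree-0 fit is the weighted mean and is monotone in y", {
  dx <- c(-200, -100, 0, 100, 200)
  y <- c(1, 0, 1, 1, 0)
  w <- c(0.2, 0.5, 1, 0.5, 0.2)
  fit <- fit_local_polynomial(dx, y, w, degree = 0)
  expect_equal(fit$intensity, sum(w * y) / sum(w))
  # flipping any 0 to 1 never decreases the weighted mean
  for (j in which(y == 0)) {
    y2 <- y; y2[j] <- 1
    f2 <- fit_local_polynomial(dx, y2, w, degree = 0)
    expect_gte(f2$intensity, fit$intensity)
  }
})

test_that("all-homozygous members give intensity 1 at any degree", {
  dx <- seq(-300, 300, by = 100)
  y <- rep(1, 7)
  w <- kernel_weight(dx / 301)
  for (degree in 0:3) {
    expect_equal(fit_local_polynomial(dx, y, w, degree)$intensity, 1)
  }
})

test_that("degree-1 fit interpolates exactly linear indicators at the anchor", {
  dx <- seq(-400, 400, by = 200)
  y <- 0.5 + dx / 2000               # linear in dx, value 0.5 at the anchor
  fit <- fit_local_polynomial(dx, y, rep(1, 5), degree = 1)
  expect_equal(fit$intensity, 0.5, tolerance = 1e-12)
})

test_that("missing indicators get zero weight and degenerate fits fall back", {
  dx <- c(-100, 0, 100)
  fit <- fit_local_polynomial(dx, c(NA, 1, NA), rep(1, 3), degree = 1)
  expect_equal(fit$degree_used, 0L)           # only one effective point
  expect_equal(fit$intensity, 1)
  expect_equal(fit$n_effective, 1L)
  fit0 <- fit_local_polynomial(dx, c(NA, NA, NA), rep(1, 3), degree = 1)
  expect_true(is.na(fit0$intensity))
})

test_that("profile equals explicit normal equations on a 200-site fixture", {
  g <- random_genotypes(4, 200, seed = 9)
  spec <- window_spec(b_percent = 5, degree = 1, clamp = FALSE)
  prof <- estimate_profile(g = g, spec = spec)
  ind <- homozygosity_indicator(g)
  maf <- compute_maf(g)
  pos <- g$sites$pos
  win <- build_windows(pos, spec)
  for (wi in c(1, 57, 123, 200)) {
    mem <- win$lo[wi]:win$hi[wi]
    dx <- pos[mem] - pos[win$anchor[wi]]
    w <- kernel_weight(dx / win$h[wi]) * locus_weight(maf[mem])
    for (i in 1:4) {
      oracle <- brute_force_wls(dx, ind[i, mem], w, 1)
      expect_equal(unname(prof$intensity[i, wi]), oracle[1], tolerance = 1e-10)
    }
  }
})

test_that("clamped intensities stay in [0,1] and match clamp-off profile", {
  g <- random_genotypes(6, 150, seed = 21)
  prof <- estimate_profile(g = g, spec = window_spec())
  expect_true(all(prof$intensity >= 0 & prof$intensity <= 1, na.rm = TRUE))
  raw <- estimate_profile(g = g, spec = window_spec(clamp = FALSE))
  expect_equal(prof$intensity, pmin(pmax(raw$intensity, 0), 1))
})

test_that("a fully homozygous individual has intensity identically 1", {
  calls <- rbind(rep(0L, 100), rbinom(100, 2, 0.4))
  g <- toy_genotypes(calls, pos = cumsum(rep(1e5, 100)))
  prof <- estimate_profile(g = g, spec = window_spec(), maf = rep(0.3, 100))
  expect_equal(unname(prof$intensity[1, ]), rep(1, 100), tolerance = 1e-9)
})

test_that("reversing a uniformly spaced chromosome reverses the profile", {
  set.seed(5)
  calls <- matrix(rbinom(300, 2, 0.4), nrow = 3)
  g <- toy_genotypes(calls, pos = seq(1e5, 1e7, length.out = 100))
  prof <- estimate_profile(g = g, spec = window_spec())
  g_rev <- toy_genotypes(calls[, 100:1], pos = g$sites$pos)
  prof_rev <- estimate_profile(g = g_rev, spec = window_spec())
  expect_equal(unname(prof$intensity[, 100:1]), unname(prof_rev$intensity),
               tolerance = 1e-12)
})

test_that("unit locus weights reproduce a single-weight kernel smoother", {
  set.seed(8)
  calls <- matrix(rbinom(200, 2, 0.45), nrow = 2)
  pos <- cumsum(rep(5e4, 100))
  g <- toy_genotypes(calls, pos = pos)
  spec <- window_spec(degree = 1)
  # force every locus weight to 1 by declaring all sites common
  prof <- estimate_profile(g = g, spec = spec, maf = rep(0.3, 100))
  ind <- homozygosity_indicator(g)
  win <- build_windows(pos, spec)
  for (wi in c(10, 50, 90)) {
    mem <- win$lo[wi]:win$hi[wi]
    dx <- pos[mem] - pos[win$anchor[wi]]
    w <- kernel_weight(dx / win$h[wi])        # kernel-only weights
    for (i in 1:2) {
      oracle <- brute_force_wls(dx, ind[i, mem], w, 1)
      expect_equal(unname(prof$intensity[i, wi]),
                   min(max(oracle[1], 0), 1), tolerance = 1e-10)
    }
  }
})

test_that("Bernoulli(0.5) indicators give profiles fluctuating about 0.5", {
  set.seed(31)
  n_sites <- 400
  calls <- matrix(ifelse(runif(5 * n_sites) < 0.5, 0L, 1L), nrow = 5)
  g <- toy_genotypes(calls, pos = cumsum(rep(1e5, n_sites)))
  prof <- estimate_profile(g = g, spec = window_spec(), maf = rep(0.5, n_sites))
  overall <- mean(prof$intensity)
  # k = 20 sites per window; SE of the per-anchor mean ~ sqrt(0.25/20), and
  # averaging anchors within individuals only shrinks it further
  expect_lt(abs(overall - 0.5), 3 * sqrt(0.25 / 20))
})
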