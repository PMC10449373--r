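test_that("percentile-Z maps ranks to normal quantiles and preserves order", {
  z <- percentile_z(c(5, 1, 9))
  expect_equal(z, qnorm(c(2, 1, 3) / 4))
  expect_equal(z[1], 0)
  expect_equal(abs(z[2]), abs(z[3]))
  x <- sort(rnorm(10))
  expect_true(all(diff(percentile_z(x)) > 0))
  expect_warning(z0 <- percentile_z(rep(3, 5)), "constant")
  expect_equal(z0, rep(0, 5))
  expect_error(percentile_z(c(1, 2)), "3 time points")
})

test_that("missing values are filled linearly inside, nearest at the ends", {
  expect_equal(as.numeric(interpolate_missing(c(0, NA, 2))), c(0, 1, 2))
  expect_equal(as.numeric(interpolate_missing(c(NA, 4, 6))), c(4, 4, 6))
  expect_equal(as.numeric(interpolate_missing(c(1, 5, NA))), c(1, 5, 5))
  full <- c(2, 4, 6)
  expect_equal(as.numeric(interpolate_missing(full)), full)
  expect_equal(attr(interpolate_missing(c(0, NA, 2)), "n_interpolated"), 1)
  expect_error(interpolate_missing(c(NA, 1, NA)), "two observed")
})

test_that("local similarity reproduces the hand-worked delayed pair", {
  r <- local_similarity(c(3, 1, -2, 0), c(0, 3, 1, -2), D = 1)
  expect_equal(r$score, 3.5)
  expect_equal(r$sign, "+")
  expect_equal(abs(r$delay), 1)
  # perfect self-match and sign symmetry
  x <- c(1, -1, 1, -1)
  self <- local_similarity(x, x, D = 0)
  expect_equal(self$score, 1)
  expect_equal(self$sign, "+")
  expect_equal(self$delay, 0)
  anti <- local_similarity(x, -x, D = 0)
  expect_equal(anti$score, 1)
  expect_equal(anti$sign, "-")
  expect_error(local_similarity(1:3, 1:4), "lengths")
})

test_that("the dynamic program equals exhaustive window enumeration", {
  set.seed(11)
  for (i in 1:120) {
    n <- sample(4:10, 1)
    D <- sample(0:2, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- local_similarity(x, y, D)
    want <- ls_brute(x, y, D)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$sign, want$sign)
  }
})

test_that("local similarity is symmetric under swap with delay negation", {
  set.seed(12)
  for (i in 1:40) {
    x <- rnorm(10); y <- rnorm(10)
    a <- local_similarity(x, y, D = 2)
    b <- local_similarity(y, x, D = 2)
    expect_equal(a$score, b$score, tolerance = 1e-12)
    expect_equal(a$delay, -b$delay)
    # global sign flip of one series keeps the score, flips the sign
    flip <- local_similarity(x, -y, D = 2)
    expect_equal(flip$score, a$score, tolerance = 1e-12)
    expect_true(flip$sign != a$sign)
  }
})

test_that("permutation p-values are reproducible, floored, and honest on nulls", {
  x <- percentile_z(rnorm(14))
  y <- percentile_z(rnorm(14))
  p1 <- permutation_pvalue(x, y, D = 1, n_perm = 200, seed = 4)
  p2 <- permutation_pvalue(x, y, D = 1, n_perm = 200, seed = 4)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  # constant y: every permutation ties the observed score
  expect_equal(permutation_pvalue(x, rep(0, 14), D = 1, n_perm = 50,
                                  seed = 1), 1)
  # super-uniformity at alpha = 0.05 over a modest null sample
  set.seed(77)
  ps <- replicate(300, {
    a <- percentile_z(rnorm(12)); b <- percentile_z(rnorm(12))
    permutation_pvalue(a, b, D = 1, n_perm = 199,
                       seed = sample.int(1e6, 1))
  })
  rej <- mean(ps < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("shifted Spearman matches cor() on the aligned overlap", {
  x <- c(3, 8, 2, 9, 1, 7, 4, 6)
  expect_equal(spearman_shifted(x, x, 0, n_perm = 19, seed = 1)$rho, 1)
  xr <- rank(x)
  y <- max(xr) + 1 - xr  # reverse-ranked copy
  expect_equal(spearman_shifted(x, y, 0, n_perm = 19, seed = 1)$rho, -1)
  set.seed(6)
  a <- rnorm(10); b <- rnorm(10)
  got <- spearman_shifted(a, b, 1, n_perm = 19, seed = 1)$rho
  expect_equal(got, cor(a[2:10], b[1:9], method = "spearman"))
  expect_error(spearman_shifted(a, b, 7), "overlap")
})

test_that("lag-1 coupled pairs score higher at the matching shift", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    a <- rnorm(14)
    b <- c(rnorm(1), 0.95 * a[1:13] + sqrt(1 - 0.95^2) * rnorm(13))
    # b lags a by one: x=a aligned to y=b at d = -1 in the start_x -
    # start_y convention
    r1 <- abs(spearman_shifted(a, b, -1, n_perm = 9, seed = s)$rho)
    r0 <- abs(spearman_shifted(a, b, 0, n_perm = 9, seed = s)$rho)
    r1 > r0
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("the time-series set interpolates, normalises and drops ineligible series", {
  md <- mk_meta(T_ = 10, missing = c(4, 7),
                seasons = list(spring = 1:3, summer = 4:7, autumn = 8:10))
  set.seed(8)
  m <- matrix(rpois(8 * 5, 40), 8, 5)
  m[, 5] <- 7  # constant series
  rownames(m) <- md$sample_id[!md$missing]
  colnames(m) <- paste0("o", 1:5)
  expect_warning(ts <- timeseries_set(otutab(m), md), "constant")
  expect_equal(length(ts$otu_ids), 4)
  expect_equal(ncol(ts$X), 10)
  expect_equal(ts$n_interpolated, 2)
  expect_false(any(is.na(ts$X)))
  md_short <- mk_meta(T_ = 10, missing = 1:6,
                      seasons = list(spring = 1:3, summer = 4:7,
                                     autumn = 8:10))
  m2 <- m[5:8, , drop = FALSE]
  rownames(m2) <- md_short$sample_id[!md_short$missing]
  expect_error(timeseries_set(otutab(m2), md_short), "observed")
})

test_that("pairwise association tables test every pair with monotone q-values", {
  set.seed(13)
  st <- generate_study(n_lakes = 1, n_times = 14, n_core = 12,
                       n_noncore_per_lake = 0, depth = 2000, n_edges = 3,
                       desiccation = list(), seed = 13)
  ts <- timeseries_set(st$tables[[1]], st$metadata)
  k <- length(ts$otu_ids)
  assoc <- pairwise_associations(ts, D = 1, n_perm = 200, seed = 14)
  expect_equal(nrow(assoc), k * (k - 1) / 2)
  ord <- order(assoc$ls_p)
  expect_true(all(diff(assoc$ls_q[ord]) >= -1e-12))
  ord2 <- order(assoc$sscc_p)
  expect_true(all(diff(assoc$sscc_q[ord2]) >= -1e-12))
  expect_true(all(assoc$network %in% c("synchronous", "time_shifted")))
  expect_true(all((assoc$network == "synchronous") == (assoc$delay == 0)))
  # determinism under the master seed
  assoc2 <- pairwise_associations(ts, D = 1, n_perm = 200, seed = 14)
  expect_identical(assoc, assoc2)
  expect_error(pairwise_associations(list(otu_ids = "one", X = matrix(0, 1, 5))),
               "two eligible")
})

test_that("planted associations are recovered with correct sign and delay class", {
  st <- generate_study(n_lakes = 1, n_times = 14, n_core = 40,
                       n_noncore_per_lake = 0, depth = 5000, n_edges = 10,
                       desiccation = list(), seed = 21)
  ts <- timeseries_set(filter_for_network(st$tables[[1]]), st$metadata)
  assoc <- pairwise_associations(ts, D = 1, alpha = 0.01, n_perm = 9999,
                                 seed = 22)
  truth <- planted_edge_catalogue(st$truth)
  sig <- assoc[assoc$significant, ]
  hit <- paste(truth$otu_a, truth$otu_b) %in% paste(sig$otu_a, sig$otu_b)
  expect_gte(mean(hit), 0.4)
  m <- merge(truth, sig, by = c("otu_a", "otu_b"))
  expect_gte(mean(m$sign == m$ls_sign), 0.9)
  expect_gte(mean((m$delay.x != 0) == (m$delay.y != 0)), 0.9)
})
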