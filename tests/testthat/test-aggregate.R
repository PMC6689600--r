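norm_of <- function(v) normalize_responses(response_matrix(v))

test_that("PCA weights split evenly over identical individuals", {
  x <- c(2, -1, 0, 3, -4)
  m <- norm_of(cbind(a = x, b = x))
  agg <- aggregate_crowd(m, "pca")
  nx <- as.matrix(m[-1])[, 1]
  expect_equal(unname(agg$weights), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(unname(agg$scores), nx * sqrt(2), tolerance = 1e-9)
})

test_that("an adversarial individual gets an opposite-sign PCA weight", {
  x <- c(2, -1, 0, 3, -4, 1)
  m <- norm_of(cbind(a = x, b = -x))
  agg <- aggregate_crowd(m, "pca")
  expect_lt(prod(agg$weights), 0)
  expect_equal(spearman_abs(agg$scores, x), 1, tolerance = 1e-9)
})

test_that("PCA matches a dense eigendecomposition of the covariance", {
  m <- normalize_responses(random_response_matrix(6, 3, seed = 77))
  v <- as.matrix(m[-1])
  expected <- drop(v %*% eigen(crossprod(v), symmetric = TRUE)$vectors[, 1])
  agg <- aggregate_crowd(m, "pca", align = FALSE)
  expect_lt(min(max(abs(agg$scores - expected)),
                max(abs(agg$scores + expected))), 1e-9)
  # invariant: scores = orientation * (matrix %*% weights), unit norm
  expect_equal(sum(agg$weights^2), 1, tolerance = 1e-12)
  expect_equal(unname(agg$scores),
               agg$orientation * drop(v %*% agg$weights), tolerance = 1e-12)
})

test_that("factor analysis recovers a planted factor", {
  set.seed(2)
  x <- rnorm(100)
  w <- runif(6, 0.5, 2)
  dat <- outer(x, w) + matrix(rnorm(600, sd = 0.1), 100, 6)
  agg <- aggregate_crowd(norm_of(dat), "factor_analysis")
  expect_gt(spearman_abs(agg$scores, x), 0.99)
  expect_true(agg$converged)
})

test_that("factor analysis handles duplicate columns and column negation", {
  x <- c(3, 1, 2, 4, 0, 5)
  m <- norm_of(cbind(a = x, b = x))
  agg <- aggregate_crowd(m, "factor_analysis")
  expect_equal(cor(agg$scores, x, method = "spearman"), 1)

  dat <- withr::with_seed(9, outer(rnorm(40), runif(4, 0.5, 2)) +
                            matrix(rnorm(160, sd = 0.3), 40, 4))
  a1 <- aggregate_crowd(norm_of(dat), "factor_analysis")
  dat2 <- dat; dat2[, 2] <- -dat2[, 2]
  a2 <- aggregate_crowd(norm_of(dat2), "factor_analysis")
  expect_gt(abs(cor(a1$scores, a2$scores, method = "spearman")), 1 - 1e-6)
})

test_that("mean cancels an adversarial individual but median sorts rows", {
  m <- response_matrix(tibble::tibble(question = c("q1", "q2"),
                                      a = c(1, -1), b = c(-1, 1)),
                       state = "normalized")
  agg <- aggregate_crowd(m, "mean", align = FALSE)
  expect_equal(unname(agg$scores), c(0, 0))
  expect_equal(unname(agg$weights), c(0.5, 0.5))

  m3 <- normalize_responses(random_response_matrix(12, 3, seed = 3))
  med <- aggregate_crowd(m3, "median", align = FALSE)
  v <- as.matrix(m3[-1])
  expect_equal(unname(med$scores),
               apply(v, 1, function(r) sort(r)[2]))
})

test_that("a single dominant column duplicated k times is its own mean", {
  x <- c(0.3, -1, 2, 0.5)
  m <- norm_of(cbind(a = x, b = x, c = x))
  agg <- aggregate_crowd(m, "mean")
  expect_equal(unname(agg$scores), as.matrix(m[-1])[, 1], ignore_attr = TRUE)
})

test_that("majority alignment orients with the crowd and is involutive", {
  m <- normalize_responses(random_response_matrix(20, 3, seed = 15))
  v <- as.matrix(m[-1])
  base <- aggregate_crowd(m, "pca", align = FALSE)

  pos <- base
  pos$scores <- v[, 1] + 0.01 * v[, 2] + 0.01 * v[, 3]
  al <- align_sign(pos, m)
  if (all(cor(v, al$scores) > 0)) expect_equal(al$orientation, 1)

  neg <- pos
  neg$scores <- -pos$scores
  al2 <- align_sign(neg, m)
  expect_equal(al2$scores, al$scores)

  const <- pos
  const$scores <- rep(1, 20)
  expect_error(align_sign(const, m), "constant")
})

test_that("alignment ties break by the summed correlation sign", {
  # k = 2 with one strongly positive and one weakly negative correlation:
  # the positive count ties at k/2, the correlation sum decides (+1 here)
  s <- withr::with_seed(71, rnorm(50))
  e <- withr::with_seed(72, rnorm(50))
  m <- norm_of(cbind(a = s + 0.2 * e, b = -0.3 * s + e))
  agg <- aggregate_crowd(m, "pca", align = FALSE)
  agg$scores <- s  # evaluate the rule on a known score vector
  al <- align_sign(agg, m)
  r <- drop(cor(as.matrix(m[-1]), s))
  expect_equal(sum(r > 0), 1)  # exactly half of k = 2
  expect_gt(sum(r), 0)
  expect_equal(al$orientation, 1)
  expect_equal(al$scores, s)
})

test_that("negating one column leaves embedding consensus unchanged", {
  sim <- simulate_crowd(n = 80, k = 5, alpha_sd = 0.2, seed = 44)
  m <- sim$responses_normalized
  flipped <- tibble::as_tibble(as.data.frame(m))
  flipped[[3]] <- -flipped[[3]]
  mf <- response_matrix(flipped, state = "normalized")

  for (spec in list(list(method = "pca"), list(method = "factor_analysis"),
                    list(method = "isomap", n_neighbors = 10),
                    list(method = "lle", n_neighbors = 10),
                    list(method = "spectral", n_neighbors = 10))) {
    a <- aggregate_crowd(m, spec$method, n_neighbors = spec$n_neighbors)
    b <- aggregate_crowd(mf, spec$method, n_neighbors = spec$n_neighbors)
    expect_gt(abs(cor(a$scores, b$scores, method = "spearman")), 1 - 1e-6,
              label = spec$method)
  }
  # negative control: mean and median are changed by the flip
  for (mm in c("mean", "median")) {
    a <- aggregate_crowd(m, mm, align = FALSE)
    b <- aggregate_crowd(mf, mm, align = FALSE)
    expect_lt(abs(cor(a$scores, b$scores, method = "spearman")), 1 - 1e-6,
              label = mm)
  }
})

test_that("aggregation is row-permutation equivariant", {
  m <- normalize_responses(random_response_matrix(40, 4, seed = 91))
  perm <- withr::with_seed(92, sample(40))
  mp <- response_matrix(as.data.frame(m)[perm, ], state = "normalized")
  for (spec in list(list(method = "pca"), list(method = "mean"),
                    list(method = "isomap", n_neighbors = 8))) {
    a <- aggregate_crowd(m, spec$method, n_neighbors = spec$n_neighbors)
    b <- aggregate_crowd(mp, spec$method, n_neighbors = spec$n_neighbors)
    expect_equal(unname(b$scores), unname(a$scores[perm]), tolerance = 1e-8,
                 label = spec$method)
  }
})

test_that("consensus accuracy grows with the crowd", {
  meds <- vapply(c(5, 25), function(k) {
    rho <- vapply(1:10, function(i) {
      sim <- simulate_crowd(n = 300, k = k, alpha_mean = 1, alpha_sd = 0.5,
                            seed = 5000 + 100 * k + i)
      agg <- aggregate_crowd(sim$responses_normalized, "pca")
      spearman_abs(agg$scores, sim$class_probs)
    }, numeric(1))
    median(rho)
  }, numeric(1))
  expect_gt(meds[2], meds[1])
})

test_that("tidy, glance and augment expose the fit tabularly", {
  sim <- simulate_crowd(n = 30, k = 4, seed = 55)
  agg <- aggregate_crowd(sim$responses_normalized, "pca")
  td <- tidy(agg)
  expect_named(td, c("question", "score"))
  expect_equal(nrow(td), 30)
  gl <- glance(agg)
  expect_equal(gl$method, "pca")
  expect_equal(abs(gl$orientation), 1)
  au <- augment(agg, sim$responses_normalized)
  expect_true("score" %in% names(au))
})
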