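test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(dt = 0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(max(h), 1)
  expect_gte(t[which.max(h)], 4.5)
  expect_lte(t[which.max(h)], 6)
  # single late negative lobe
  neg <- which(h < -1e-6)
  expect_true(all(t[neg] > 8))
  expect_true(all(diff(neg) == 1))
  # matches the gamma-density difference evaluated directly
  oracle <- dgamma(t, shape = 6, scale = 1) -
    dgamma(t, shape = 16, scale = 1) / 6
  expect_equal(h, oracle / max(oracle), tolerance = 1e-12)
  # refining dt only interpolates
  h2 <- canonical_hrf(dt = 0.05)
  expect_equal(h2[seq(1, length(h2), by = 2)], h, tolerance = 1e-6)
  expect_error(canonical_hrf(dt = 0), "positive")
  expect_error(canonical_hrf(dt = 1, peak_delay = -2), "positive")
})

test_that("convolution is causal, linear and matches the direct sum", {
  k <- canonical_hrf(dt = 2)
  imp <- c(1, rep(0, 30))
  expect_equal(convolve_regressor(imp, k),
               c(k, rep(0, 31 - length(k))), tolerance = 1e-10)
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(convolve_regressor(x + y, k),
               convolve_regressor(x, k) + convolve_regressor(y, k),
               tolerance = 1e-10)
  # brute-force convolution sum on a 20-s boxcar at TR 2
  box <- rep(c(1, 0), c(10, 30))
  direct <- vapply(seq_along(box), function(n) {
    sum(vapply(seq_len(n), function(j) {
      if (n - j + 1 <= length(k)) box[j] * k[n - j + 1] else 0
    }, numeric(1)))
  }, numeric(1))
  expect_equal(convolve_regressor(box, k), direct, tolerance = 1e-12)
  expect_error(convolve_regressor(numeric(0), k), "empty")
})

test_that("design construction counts, standardises and validates columns", {
  d0 <- build_design(drift_order = 0L, n_volumes = 50, tr = 2)
  expect_equal(colnames(d0$matrix), "intercept")
  d <- build_design(list(eff = rnorm(300)), list(conf = rnorm(300)),
                    drift_order = 3L, n_volumes = 300, tr = 2)
  expect_equal(ncol(d$matrix), 6)  # effect + confound + drift 1..3 + intercept
  expect_equal(mean(d$matrix[, "eff"]), 0, tolerance = 1e-12)
  expect_equal(sd(d$matrix[, "eff"]), 1, tolerance = 1e-12)
  x <- rnorm(100)
  expect_error(build_design(list(a = x, b = x), drift_order = 1L,
                            n_volumes = 100, tr = 2), "rank")
  expect_error(build_design(list(a = rnorm(99)), drift_order = 1L,
                            n_volumes = 100, tr = 2), "length")
  expect_error(build_design(list(a = rep(0, 100)), drift_order = 1L,
                            n_volumes = 100, tr = 2), "constant|zero")
})

test_that("OLS fit matches the normal-equations oracle", {
  set.seed(21)
  des <- build_design(list(a = rnorm(60), b = rnorm(60)),
                      drift_order = 2L, n_volumes = 60, tr = 2)
  X <- des$matrix
  Y <- matrix(rnorm(60 * 10), 60, 10)
  fit <- fit_glm(Y, des)
  beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(fit$beta, beta_oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  # noiseless proportional voxel
  y2 <- 2 * X[, "a"]
  fit2 <- fit_glm(matrix(y2), des)
  expect_equal(unname(fit2$beta["a", 1]), 2, tolerance = 1e-10)
  expect_lt(fit2$sigma2[1], 1e-20)
  Ybad <- Y; Ybad[3, 4] <- NA
  expect_error(fit_glm(Ybad, des), "voxel index 4")
})

test_that("F contrasts reduce to t^2 and to the RSS comparison oracle", {
  set.seed(22)
  des <- build_design(list(a = rnorm(80)), list(conf = rnorm(80)),
                      drift_order = 2L, n_volumes = 80, tr = 2)
  X <- des$matrix
  Y <- matrix(X[, "a"] * 0.5 + rnorm(80 * 6, sd = 1), 80, 6)
  fit <- fit_glm(Y, des)
  sm <- f_contrast(fit, "a")
  expect_equal(unname(sm$dof), c(1, 80 - ncol(X)))
  # t^2 identity via lm
  for (v in 1:3) {
    lm_fit <- lm(Y[, v] ~ X - 1)
    tval <- summary(lm_fit)$coefficients["Xa", "t value"]
    expect_equal(sm$f_values[v], tval^2, tolerance = 1e-10)
  }
  # extra-sum-of-squares oracle: refit reduced model
  Z <- X[, colnames(X) != "a"]
  for (v in 1:3) {
    rss_full <- sum(resid(lm(Y[, v] ~ X - 1))^2)
    rss_red <- sum(resid(lm(Y[, v] ~ Z - 1))^2)
    f_or <- (rss_red - rss_full) / (rss_full / (80 - ncol(X)))
    expect_equal(sm$f_values[v], f_or, tolerance = 1e-8)
  }
  # zero-coefficient noiseless voxel has F = 0
  fit0 <- fit_glm(matrix(X[, "conf"] * 3), des)
  expect_equal(f_contrast(fit0, "a")$f_values[1], 0)
  expect_error(f_contrast(fit, matrix(0, 1, ncol(X))), "rank")
})

test_that("FWE thresholding is correct at one voxel and validates alpha", {
  set.seed(23)
  des <- build_design(list(a = rnorm(50)), drift_order = 1L,
                      n_volumes = 50, tr = 2)
  fit <- fit_glm(matrix(rnorm(50)), des)
  sm <- f_contrast(fit, "a")
  m <- fwe_threshold(sm, 0.05, "bonferroni")
  expect_identical(as.logical(m), as.logical(sm$p_values < 0.05))
  expect_error(fwe_threshold(sm, 1.5, "bonferroni"), "alpha")
})

test_that("permutation max-T masks contain the Bonferroni masks on strong signal", {
  set.seed(24)
  n <- 80
  des <- build_design(list(a = rnorm(n)), drift_order = 1L,
                      n_volumes = n, tr = 2)
  X <- des$matrix
  Y <- matrix(rnorm(n * 50), n, 50)
  Y[, 1:5] <- Y[, 1:5] + X[, "a"] %o% rep(1.2, 5)
  fit <- fit_glm(Y, des)
  sm <- f_contrast(fit, "a")
  mb <- fwe_threshold(sm, 0.05, "bonferroni")
  mp <- fwe_threshold(sm, 0.05, "permutation_maxT", fit = fit,
                      n_permutations = 200, seed = 1)
  expect_true(all(mp[mb]))
  expect_true(any(mp))
  expect_error(fwe_threshold(sm, 0.05, "permutation_maxT", fit = fit,
                             n_permutations = 10), "100")
})

test_that("exclusion contrast is exact set arithmetic", {
  set.seed(25)
  dims <- c(5L, 5L, 5L)
  A <- array(runif(125) < 0.3, dims)
  B <- array(runif(125) < 0.3, dims)
  C <- exclusion_contrast(A, B)
  expect_identical(as.logical(C), as.logical(A & !B))
  expect_true(!any(C & B))
  expect_true(all(C[A == FALSE] == FALSE))
  expect_equal(sum(C), sum(A) - sum(A & B))
  expect_identical(exclusion_contrast(A, array(FALSE, dims)), A,
                   ignore_attr = TRUE)
  expect_equal(sum(exclusion_contrast(A, A | B)), 0)
  expect_error(exclusion_contrast(A, B[1:4, , ]), "grids")
})

test_that("cluster tables match an independent connected-components oracle", {
  skip_if_not_installed("igraph")
  igraph_components <- function(mask, connectivity = 26L) {
    vox <- which(mask, arr.ind = TRUE)
    if (nrow(vox) == 0) return(integer(0))
    if (nrow(vox) == 1) return(1L)
    d <- as.matrix(dist(vox, method = "maximum"))
    adj <- d <= 1
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    sort(as.integer(table(igraph::components(g)$membership)),
         decreasing = TRUE)
  }
  set.seed(26)
  dims <- c(8L, 8L, 8L)
  sm <- structure(list(f_values = array(runif(512, 1, 10), dims),
                       p_values = array(runif(512), dims),
                       dof = c(1, 100), dims = dims,
                       affine = diag(c(3, 3, 3, 1)),
                       contrast = matrix(1, 1, 1)), class = "stat_map")
  for (i in 1:5) {
    mask <- array(runif(512) < 0.12, dims)
    tab <- local_maxima_table(sm, mask)
    expect_equal(sum(tab$voxels), sum(mask))
    expect_identical(sort(tab$voxels, decreasing = TRUE),
                     igraph_components(mask))
  }
  # single voxel and face-adjacent pair
  m1 <- array(FALSE, dims); m1[4, 4, 4] <- TRUE
  t1 <- local_maxima_table(sm, m1)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$voxels, 1)
  expect_equal(c(t1$x_mm, t1$y_mm, t1$z_mm), c(3, 3, 3) * 3)
  m2 <- m1; m2[4, 4, 5] <- TRUE
  expect_equal(local_maxima_table(sm, m2)$voxels, 2)
  # empty mask: empty table, not an error
  expect_equal(nrow(local_maxima_table(sm, array(FALSE, dims))), 0)
  # 6-connectivity splits a diagonal pair
  m3 <- m1; m3[5, 5, 5] <- TRUE
  expect_equal(nrow(local_maxima_table(sm, m3, connectivity = 6L)), 2)
  expect_equal(nrow(local_maxima_table(sm, m3, connectivity = 26L)), 1)
})

test_that("peaks lie inside their clusters and carry corrected p-values", {
  set.seed(27)
  dims <- c(6L, 6L, 6L)
  f <- array(rchisq(216, 3), dims)
  sm <- structure(list(f_values = f,
                       p_values = array(pf(f, 1, 50, lower.tail = FALSE),
                                        dims),
                       dof = c(1, 50), dims = dims,
                       affine = diag(c(3, 3, 3, 1)),
                       contrast = matrix(1, 1, 1)), class = "stat_map")
  mask <- array(FALSE, dims); mask[2:4, 2:4, 2:4] <- TRUE
  tab <- local_maxima_table(sm, mask)
  expect_equal(tab$peak_f, max(f[mask]))
  expect_true(all(tab$p_fwe >= sm$p_values[mask][which.max(f[mask])]))
  expect_true(all(tab$p_fwe <= 1))
})
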