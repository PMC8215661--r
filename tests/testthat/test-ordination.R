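test_that("VIF values match the inverse-correlation-matrix oracle", {
  set.seed(7)
  n <- 200
  S <- matrix(0.9, 3, 3); diag(S) <- 1
  X <- matrix(rnorm(n * 3), n) %*% chol(S)
  colnames(X) <- c("a", "b", "c")
  env <- as.data.frame(X)
  # oracle: diagonal of the inverse sample correlation matrix
  oracle <- diag(solve(cor(X)))
  sel <- vif_select(env, c("a", "b", "c"), threshold = 1e9)
  # recompute VIFs the way the selector does, at the full set
  vifs <- vapply(colnames(X), function(v) {
    r2 <- summary(lm(X[, v] ~ X[, setdiff(colnames(X), v)]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(vifs, oracle, tolerance = 1e-9)
  expect_equal(sel$kept, c("a", "b", "c"))  # nothing above 1e9
})

test_that("VIF selection removes collinear variables deterministically", {
  set.seed(9)
  env <- data.frame(a = rnorm(1000), b = rnorm(1000))
  sel <- vif_select(env, c("a", "b"))
  expect_setequal(sel$kept, c("a", "b"))
  # a duplicated column: exactly one of the pair removed (infinite VIF)
  env$a2 <- env$a
  sel2 <- vif_select(env, c("a", "a2", "b"))
  expect_length(intersect(sel2$kept, c("a", "a2")), 1)
  expect_true("b" %in% sel2$kept)
  expect_equal(sel2$trace$vif, Inf)
  # invariance to column order (up to the documented tie-break)
  sel3 <- vif_select(env, c("b", "a2", "a"))
  expect_identical(sel2$kept, sel3$kept)
})

test_that("Hellinger transform has the expected geometry", {
  expect_equal(unname(hellinger(matrix(c(9, 16), 1))),
               matrix(c(0.6, 0.8), 1))
  set.seed(10)
  M <- matrix(rexp(60), 10, 6)
  H <- hellinger(M)
  expect_equal(unname(rowSums(H^2)), rep(1, 10))
  # pairwise distances bounded by sqrt(2)
  expect_true(all(dist(H) <= sqrt(2) + 1e-12))
  # double application differs (guards accidental re-transformation)
  expect_false(isTRUE(all.equal(hellinger(H), H)))
  expect_error(hellinger(matrix(c(-1, 2), 1)), "negative")
  expect_warning(hellinger(rbind(c(1, 1), c(0, 0))), "all-zero")
  # agreement with the community-ecology reference implementation
  skip_if_not_installed("vegan")
  expect_equal(unname(H),
               unname(vegan::decostand(M, method = "hellinger")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA embeds distances faithfully", {
  # collinear points recover spacing on one axis
  d <- dist(c(0, 1, 3))
  p <- pcoa(d)
  expect_equal(dim(p$points)[2], 1)
  expect_equal(dist(p$points[, 1])[c(1, 2, 3)], d[c(1, 2, 3)],
               tolerance = 1e-10, ignore_attr = TRUE)
  # PCoA of Euclidean distances of a Hellinger matrix equals its PCA
  set.seed(11)
  H <- hellinger(matrix(rexp(48), 8, 6))
  pc <- pcoa(dist(H))
  pr <- prcomp(H, center = TRUE)
  k <- ncol(pc$points)
  expect_equal(abs(unname(pc$points)), abs(unname(pr$x[, 1:k])),
               tolerance = 1e-8)
  # identical points embed at the origin
  z <- pcoa(matrix(0, 3, 3))
  expect_equal(ncol(z$points), 0)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("RDA matches the least-squares oracle and vegan", {
  set.seed(12)
  Y <- matrix(rnorm(24), 6, 4)
  env <- data.frame(a = rnorm(6), b = rnorm(6))
  fit <- partial_rda(Y, env, c("a", "b"), n_perm = 0)
  oracle <- rda_oracle(Y, as.matrix(env))
  expect_equal(fit$eigenvalues, oracle$eigenvalues, tolerance = 1e-9)
  expect_equal(fit$constrained_R2, oracle$r2, tolerance = 1e-12)
  skip_if_not_installed("vegan")
  v <- vegan::rda(Y ~ a + b, data = as.data.frame(scale(env)))
  expect_equal(unname(fit$eigenvalues), unname(v$CCA$eig),
               tolerance = 1e-9)
  expect_equal(fit$adjusted_R2, vegan::RsquareAdj(v)$adj.r.squared,
               tolerance = 1e-9)
  # conditioned case agrees with vegan's Condition()
  env$Site <- rep(c("A", "B", "C"), 2)
  fc <- partial_rda(Y, env, c("a", "b"), condition = "Site", n_perm = 0)
  dat <- cbind(as.data.frame(scale(env[c("a", "b")])), Site = env$Site)
  vc <- vegan::rda(Y ~ a + b + Condition(Site), data = dat)
  expect_equal(unname(fc$eigenvalues), unname(vc$CCA$eig),
               tolerance = 1e-9)
})

test_that("RDA recognises exact and absent structure", {
  set.seed(13)
  n <- 20
  env <- data.frame(v = rnorm(n), w = rnorm(n))
  Y <- cbind(2 * env$v, -env$v, 0.5 * env$v)
  fit <- partial_rda(Y, env, "v", n_perm = 99)
  expect_equal(fit$constrained_R2, 1, tolerance = 1e-12)
  expect_equal(fit$perm_p, 0.01)
  # pure noise: adjusted R2 near zero on average
  set.seed(14)
  adjs <- replicate(60, {
    Yn <- matrix(rnorm(50 * 6), 50)
    en <- data.frame(a = rnorm(50), b = rnorm(50))
    partial_rda(Yn, en, c("a", "b"), n_perm = 0)$adjusted_R2
  })
  expect_lt(abs(mean(adjs)), 0.05)
  # eigenvalues sum to the fitted variance (conservation)
  Y2 <- matrix(rnorm(60), 15, 4)
  e2 <- data.frame(a = rnorm(15), b = rnorm(15))
  f2 <- partial_rda(Y2, e2, c("a", "b"), n_perm = 0)
  Yc <- scale(Y2, scale = FALSE)
  H <- qr.fitted(qr(scale(as.matrix(e2))), Yc)
  expect_equal(sum(f2$eigenvalues), sum(H^2) / (15 - 1), tolerance = 1e-9)
  # aliased predictors are named
  e2$a2 <- e2$a
  expect_error(partial_rda(Y2, e2, c("a", "a2"), n_perm = 0), "aliased")
})

test_that("stepwise selection finds true predictors and rejects noise", {
  set.seed(15)
  hits <- 0
  for (i in 1:10) {
    n <- 60
    e <- data.frame(true = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n))
    Y <- cbind(3 * e$true, -2 * e$true, e$true) + matrix(rnorm(n * 3), n)
    s <- stepwise_select(Y, e, c("true", "n1", "n2", "n3"), n_perm = 99)
    if ("true" %in% s$selected) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # all-noise: empty in the large majority of runs (forward selection over
  # three null candidates stops empty with probability 0.95^3 ~ 0.86)
  set.seed(16)
  empties <- 0
  for (i in 1:20) {
    n <- 60
    e <- data.frame(n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    Y <- matrix(rnorm(n * 3), n)
    s <- stepwise_select(Y, e, c("n1", "n2", "n3"), n_perm = 99)
    if (length(s$selected) == 0) empties <- empties + 1
  }
  expect_gte(empties, 14)
  # a perfect single predictor is always selected
  e1 <- data.frame(v = rnorm(30))
  Y1 <- cbind(e1$v, 2 * e1$v)
  set.seed(17)
  expect_equal(stepwise_select(Y1, e1, "v", n_perm = 99)$selected, "v")
})

test_that("variance partitioning recovers constructed fractions", {
  set.seed(18)
  n <- 120
  e <- data.frame(a = rnorm(n), b = rnorm(n))
  # orthogonal predictors with known variance shares
  Y <- cbind(e$a + 0.5 * e$b, e$a - 0.5 * e$b) +
    matrix(rnorm(n * 2, 0, 0.3), n)
  vp <- variance_partition(Y, e, c("a", "b"))
  full <- attr(vp, "full_adj_R2")
  red_a <- partial_rda(Y, e, "b", n_perm = 0)$adjusted_R2
  expect_equal(vp$partial_adj_R2[vp$variable == "a"], full - red_a,
               tolerance = 1e-12)
  # a duplicate of a selected variable has near-zero partial share
  e$a2 <- e$a + rnorm(n, 0, 1e-3)
  vp2 <- variance_partition(Y, e, c("a", "a2", "b"))
  expect_lt(abs(vp2$partial_adj_R2[vp2$variable == "a2"]), 0.01)
  # single predictor: partial equals the global adjusted R2
  vp1 <- variance_partition(Y, e, "a")
  expect_equal(vp1$partial_adj_R2, attr(vp1, "full_adj_R2"))
})

test_that("bisquare IRLS resists outliers and reduces to OLS when clean", {
  # exact line: coefficients recovered to numerical precision, weights 1
  x <- seq(-3, 3, length.out = 25)
  y <- 1.5 - 0.7 * x
  f <- irls_fit(x, y)
  expect_equal(f$intercept, 1.5, tolerance = 1e-10)
  expect_equal(f$slope, -0.7, tolerance = 1e-10)
  expect_equal(f$weights, rep(1, 25))
  # gross outliers barely move the slope and get near-zero weight
  set.seed(19)
  x2 <- runif(20, 0, 10)
  y2 <- 2 + 0.8 * x2 + rnorm(20, 0, 0.05)
  x2 <- c(x2, 5, 6); y2 <- c(y2, 30, -20)
  f2 <- irls_fit(x2, y2)
  expect_lt(abs(f2$slope - 0.8) / 0.8, 0.05)
  expect_true(all(f2$weights[21:22] < 0.05))
  # Gaussian noise only: within one SE of ordinary least squares
  set.seed(20)
  x3 <- rnorm(80); y3 <- 1 + 2 * x3 + rnorm(80)
  f3 <- irls_fit(x3, y3)
  ols <- summary(lm(y3 ~ x3))
  expect_lt(abs(f3$slope - ols$coefficients[2, 1]),
            ols$coefficients[2, 2])
  # cross-check against the reference M-estimator
  skip_if_not_installed("MASS")
  rl <- MASS::rlm(y2 ~ x2, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(f2$slope, unname(coef(rl)[2]), tolerance = 0.05)
  expect_error(irls_fit(1:2, 1:2), "at least 3")
})

test_that("marker-pair frequencies support the robust log-log regression", {
  st <- simulate_study(small_config(seed = 23))
  mp <- marker_pair_frequencies(st, detection_sd = 0.2, seed = 23)
  ok <- mp$freq1 > 0 & mp$freq2 > 0
  f <- irls_fit(log10(mp$freq1[ok]), log10(mp$freq2[ok]))
  expect_gt(f$slope, 0)
  expect_gt(f$r_squared, 0.2)
})
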