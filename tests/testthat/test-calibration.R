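test_that("MML calibration recovers known item parameters", {
  items <- make_items(20, seed = 1)
  u <- generate_responses(stats::rnorm(5000), items, seed = 2)
  fit <- calibrate_2pl(u)
  expect_true(fit$converged)
  expect_lt(mean(abs(fit$est$d - items$d)), 0.1)
  expect_lt(mean(abs(fit$est$a - items$a)), 0.15)
  expect_gt(stats::cor(fit$est$d, items$d), 0.99)
})

test_that("the marginal log-likelihood never decreases across EM cycles", {
  items <- make_items(12, seed = 3)
  u <- generate_responses(stats::rnorm(400), items, seed = 4)
  fit <- calibrate_2pl(u)
  slack <- 1e-8 * (1 + abs(fit$loglik))
  expect_true(all(diff(fit$loglik_trace) > -slack))
})

test_that("estimates respect the bounds even on degenerate items", {
  set.seed(9)
  items <- make_items(6, seed = 5)
  u <- generate_responses(stats::rnorm(150), items, seed = 6)
  u[, 3] <- 1   # answered correctly by everyone
  fit <- calibrate_2pl(u)
  expect_true(all(fit$est$a >= -1 & fit$est$a <= 5))
  expect_true(all(fit$est$d >= -5 & fit$est$d <= 5))
  # an all-correct item is caught by the upper easiness bound
  expect_gt(fit$est$d[3], 4)
})

test_that("anchor items are held exactly and never move", {
  items <- make_items(10, seed = 7)
  u <- generate_responses(stats::rnorm(300), items, seed = 8)
  anchors <- data.frame(id = c("7", "2"), a = c(1.3, 0.9), d = c(0.4, -1))
  fit <- calibrate_2pl(u, fixed = anchors)
  expect_identical(fit$est$a[fit$est$id == "7"], 1.3)
  expect_identical(fit$est$d[fit$est$id == "7"], 0.4)
  expect_equal(fit$vcov[["7"]], matrix(0, 2, 2))
  # adding more data for the free items does not move anchors
  u2 <- rbind(u, generate_responses(stats::rnorm(300), items, seed = 9))
  fit2 <- calibrate_2pl(u2, fixed = anchors)
  expect_identical(fit2$est$a[fit2$est$id == "7"], 1.3)
  expect_identical(fit2$est$d[fit2$est$id == "2"], -1)
  expect_error(calibrate_2pl(u, fixed = data.frame(id = "1", a = 7, d = 0)),
               "bounds")
})

test_that("estimation error shrinks as the sample grows", {
  items <- make_items(10, seed = 10)
  mae <- vapply(c(250, 1000, 4000), function(N) {
    u <- generate_responses(stats::rnorm(N), items, seed = N)
    fit <- calibrate_2pl(u)
    mean(abs(fit$est$d - items$d))
  }, 0)
  expect_true(all(diff(mae) < 0))
})

test_that("MAP ability estimation matches a brute-force grid search", {
  # no responses -> prior mode
  expect_equal(map_ability(NA_real_, data.frame(a = 1, d = 0)), 0)
  # symmetric responses on identical items -> 0
  expect_equal(map_ability(c(1, 0), data.frame(a = c(1, 1), d = c(0, 0))),
               0, tolerance = 1e-8)
  grid <- seq(-6, 6, by = 1e-4)
  set.seed(11)
  for (r in 1:5) {
    n_it <- sample(1:6, 1)
    it <- draw_item_parameters(n_it)
    u <- as.numeric(stats::runif(n_it) < 0.5)
    logpost <- -grid^2 / 2
    for (i in seq_len(n_it)) {
      lin <- it$a[i] * grid + it$d[i]
      logpost <- logpost + u[i] * lin - log1p(exp(lin))
    }
    oracle <- grid[which.max(logpost)]
    expect_equal(map_ability(u, it), oracle, tolerance = 1e-3)
  }
})

test_that("item covariances scale as 1/n and match Monte-Carlo truth", {
  items <- make_items(8, seed = 12)
  u1 <- generate_responses(stats::rnorm(600), items, seed = 13)
  u2 <- rbind(u1, generate_responses(stats::rnorm(600), items, seed = 14))
  v1 <- calibrate_2pl(u1)$vcov
  v2 <- calibrate_2pl(u2)$vcov
  ratio <- rowMeans(vapply(seq_along(v1), function(i)
    diag(v1[[i]]) / diag(v2[[i]]), numeric(2)))
  expect_true(all(ratio > 2 * 0.75 & ratio < 2 * 1.25))

  # asymptotic SE of d-hat vs the empirical SD over replications:
  # one free item at (a = 1, d = 0) among anchored companions, N = 2000
  comp <- make_items(10, seed = 99)
  comp$a[1] <- 1; comp$d[1] <- 0
  anchors <- data.frame(id = as.character(2:10), a = comp$a[-1],
                        d = comp$d[-1])
  reps <- t(vapply(1:100, function(r) {
    u <- generate_responses(stats::rnorm(2000), comp, seed = 500 + r)
    f <- calibrate_2pl(u, fixed = anchors)
    c(f$est$d[1], sqrt(f$vcov[[1]][2, 2]))
  }, numeric(2)))
  ratio <- mean(reps[, 2]) / stats::sd(reps[, 1])
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.4)
})

test_that("concurrent calibration stacks cycles correctly", {
  items <- make_items(6, seed = 15)
  u <- generate_responses(stats::rnorm(200), items, seed = 16)
  f1 <- calibrate_2pl(u)
  f2 <- concurrent_calibrate(list(u))
  expect_equal(f1$est$a, f2$est$a)
  # disjoint item sets across two cycles: converges, estimates in bounds
  itB <- make_items(6, seed = 17); itB$id <- 7:12
  uB <- generate_responses(stats::rnorm(200), itB, seed = 18)
  f3 <- concurrent_calibrate(list(u, uB))
  expect_true(f3$converged)
  expect_equal(nrow(f3$est), 12)
  expect_true(all(f3$est$a >= -1 & f3$est$a <= 5))
  stacked <- stack_responses(list(u, uB))
  expect_equal(dim(stacked), c(400, 12))
  expect_true(all(is.na(stacked[1:200, 7:12])))
})

test_that("fit methods expose the usual modelling surface", {
  items <- make_items(5, seed = 19)
  u <- generate_responses(stats::rnorm(300), items, seed = 20)
  fit <- calibrate_2pl(u)
  expect_s3_class(fit, "cal2pl")
  cf <- coef(fit)
  expect_equal(dim(cf), c(5, 3))
  expect_equal(unname(cf[, "b"]), -fit$est$d / fit$est$a)
  expect_equal(attr(logLik(fit), "df"), 10L)
  p <- predict(fit, theta = c(-1, 0, 1))
  expect_equal(dim(p), c(3, 5))
  expect_true(all(p > 0 & p < 1))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(u))
  s <- summary(fit)
  expect_true(all(s$table$se_a > 0))
  # (a,b) covariance via the delta method stays symmetric PSD
  vab <- vcov(fit, parametrization = "ab")
  expect_true(all(vapply(vab, function(m) m[1, 2] == m[2, 1], FALSE)))
  expect_true(all(vapply(vab, function(m) det(m) >= -1e-12, FALSE)))
})
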