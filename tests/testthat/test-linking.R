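test_that("item parameters transform linearly between scales", {
  id <- transform_items(data.frame(a = 1, b = 0), link_constants(1, 0))
  expect_equal(c(id$a, id$b), c(1, 0))
  tr <- transform_items(data.frame(a = 2, b = 0.5), link_constants(2, 1))
  expect_equal(c(tr$a, tr$b), c(1, 2))
  expect_equal(tr$d, -tr$a * tr$b)
  # inverse map restores the original parameters
  set.seed(30)
  it <- draw_item_parameters(10); it$b <- -it$d / it$a
  cc <- link_constants(1.7, -0.6)
  inv <- link_constants(1 / cc$A, -cc$B / cc$A)
  back <- transform_items(transform_items(it, cc), inv)
  expect_equal(back$a, it$a, tolerance = 1e-12)
  expect_equal(back$b, it$b, tolerance = 1e-12)
  expect_error(link_constants(0, 1), "invalid")
})

test_that("moment methods reproduce hand-computed constants", {
  p <- common_item_pairs(1:2, a_l = c(0.5, 1), d_l = -c(0.5, 1) * c(-1, 1),
                         a_k = c(1, 2), d_k = -c(1, 2) * c(-0.5, 0.5))
  mm <- mean_mean(p)
  expect_equal(c(mm$A, mm$B), c(2, 0))

  p2 <- common_item_pairs(1:3, a_l = rep(1, 3), d_l = -c(-1, 0, 1),
                          a_k = rep(1, 3), d_k = -c(-0.5, 0, 0.5))
  ms <- mean_sigma(p2)
  expect_equal(c(ms$A, ms$B), c(2, 0))

  p3 <- common_item_pairs(1:2, a_l = c(1, 1), d_l = -c(1, 3),
                          a_k = c(1, 1), d_k = -c(0, 1))
  ms3 <- mean_sigma(p3)
  expect_equal(c(ms3$A, ms3$B), c(2, 1))

  # a pure difficulty shift with equal discriminations
  p4 <- common_item_pairs(1:3, a_l = c(0.8, 1, 1.2),
                          d_l = -c(0.8, 1, 1.2) * (c(-1, 0, 1) + 1),
                          a_k = c(0.8, 1, 1.2),
                          d_k = -c(0.8, 1, 1.2) * c(-1, 0, 1))
  mm4 <- mean_mean(p4)
  expect_equal(c(mm4$A, mm4$B), c(1, 1))
  expect_error(mean_mean(p4[1, ]), "at least two")
})

test_that("all four estimators return the identity on a self-link", {
  for (s in 1:5) {
    p <- make_pairs(15, A = 1, B = 0, seed = s)
    p$a_l <- p$a_k; p$b_l <- p$b_k
    for (m in c("mean_mean", "mean_sigma")) {
      cc <- estimate_link(p, m)
      expect_equal(c(cc$A, cc$B), c(1, 0), tolerance = 1e-10)
    }
    for (m in c("haebara", "stocking_lord")) {
      cc <- estimate_link(p, m)
      expect_equal(c(cc$A, cc$B), c(1, 0), tolerance = 1e-6)
      expect_lt(cc$loss, 1e-10)
    }
  }
})

test_that("noise-free pairs recover their generating constants", {
  for (A in c(0.5, 1.3, 2)) for (B in c(-1, 0.5)) {
    p <- make_pairs(15, A = A, B = B, seed = round(10 * A + B))
    for (m in c("mean_mean", "mean_sigma")) {
      cc <- estimate_link(p, m)
      expect_equal(c(cc$A, cc$B), c(A, B), tolerance = 1e-8)
    }
    for (m in c("haebara", "stocking_lord")) {
      cc <- estimate_link(p, m)
      expect_equal(c(cc$A, cc$B), c(A, B), tolerance = 1e-4)
    }
  }
})

test_that("curve methods match a two-stage grid-search oracle", {
  p <- make_pairs(15, A = 1.2, B = 0.4, noise = 0.05, seed = 31)
  grid <- seq(-4, 4, length.out = 61)
  for (crit in c("haebara", "stocking_lord")) {
    loss <- function(A, B) {
      tot <- 0
      for (k in seq_along(grid)) {
        pk <- prob_2pl(grid[k], p$a_k / A, -(p$a_k / A) * (A * p$b_k + B))
        pl <- prob_2pl(grid[k], p$a_l, -p$a_l * p$b_l)
        tot <- tot + if (crit == "haebara") sum((pk - pl)^2)
                     else (sum(pk) - sum(pl))^2
      }
      tot
    }
    coarse <- expand.grid(A = seq(0.25, 4, by = 0.025),
                          B = seq(-2, 2, by = 0.025))
    lv <- mapply(loss, coarse$A, coarse$B)
    best <- coarse[which.min(lv), ]
    fine <- expand.grid(A = seq(best$A - 0.03, best$A + 0.03, by = 1e-3),
                        B = seq(best$B - 0.03, best$B + 0.03, by = 1e-3))
    lv <- mapply(loss, fine$A, fine$B)
    oracle <- fine[which.min(lv), ]
    cc <- characteristic_curve_link(p, crit, grid)
    expect_equal(cc$A, oracle$A, tolerance = 2e-3)
    expect_equal(cc$B, oracle$B, tolerance = 2e-3)
    expect_lte(cc$loss, loss(1, 0))
  }
})

test_that("the Lord chi-squared statistic matches hand values", {
  mk <- function(a_k, b_k, a_l, b_l, cov) {
    p <- data.frame(id = 1L, a_k = a_k, b_k = b_k, a_l = a_l, b_l = b_l)
    p$cov_k <- list(cov); p$cov_l <- list(cov)
    p
  }
  idc <- link_constants(1, 0)
  same <- lord_chi2_test(mk(1.2, 0.3, 1.2, 0.3, diag(2) / 2), idc)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$drifted)

  # delta = (0.1, 0.2), Sigma = I -> 0.05, p = exp(-0.025)
  tst <- lord_chi2_test(mk(1, 0, 1.1, 0.2, diag(2) / 2), idc)
  expect_equal(tst$statistic, 0.05, tolerance = 1e-10)
  expect_equal(tst$p_value, 0.9753099, tolerance = 1e-6)
  expect_false(tst$drifted)

  big <- lord_chi2_test(mk(1, 0, 2, 1, 0.005 * diag(2)), idc)
  expect_equal(big$statistic, 200, tolerance = 1e-8)
  expect_lt(big$p_value, 1e-6)
  expect_true(big$drifted)

  # singular covariance: untestable, treated as retained
  sing <- lord_chi2_test(mk(1, 0, 1.1, 0.2, matrix(0, 2, 2)), idc)
  expect_false(sing$testable)
  expect_false(sing$drifted)
})

test_that("purification removes constructed drift and only that", {
  p <- make_pairs(15, A = 1, B = 0, seed = 32, cov_scale = 1e-4)
  out <- purify(p, "stocking_lord")
  expect_true(out$feasible)
  expect_length(out$retained, 15)
  expect_equal(out$n_iterations, 1L)

  drifted <- p
  drifted$a_l[7] <- drifted$a_l[7] + 1.5
  drifted$b_l[7] <- drifted$b_l[7] + 1.5
  out <- purify(drifted, "stocking_lord")
  expect_true(out$feasible)
  expect_identical(out$drifted$id, 7L)
  expect_setequal(out$retained, setdiff(1:15, 7))

  # gross perturbation of 14 of 15 items forces a breakdown
  broken <- p
  shift <- c(0, 1.5 * (1:14 %% 2 * 2 - 1) * (1 + (1:14) / 7))
  broken$b_l <- broken$b_l + shift
  broken$a_l <- broken$a_l + abs(shift) / 2
  out <- purify(broken, "stocking_lord")
  expect_false(out$feasible)
  expect_lt(length(out$retained), 2)
  expect_error(purify(p[1, , drop = FALSE], "mean_mean"), "at least two")
})

test_that("purification terminates within the common-item count", {
  for (s in 33:36) {
    p <- make_pairs(15, A = 1.1, B = -0.2, noise = 0.2, seed = s,
                    cov_scale = 1e-3)
    out <- purify(p, "haebara")
    expect_lte(out$n_iterations, 15)
    expect_setequal(c(out$retained, out$drifted$id), 1:15)
  }
})
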