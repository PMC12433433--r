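test_that("generating item parameters match the design", {
  cond <- gen_condition("ers_plus_mrs", N = 100, J = 12, D = 1, sigma_RS = 1,
                        r_RS = 0, slope_corr = 1, seed = 1)
  set.seed(1)
  items <- draw_item_parameters(cond)
  A <- attr(items, "slope_matrix")
  C <- attr(items, "intercept_matrix")
  expect_true(all(apply(C, 1, identical, c(-2, -1, 0, -1, -2))))
  expect_identical(A[, 2], A[, 3])   # slope_corr = 1: MRS slope copies ERS
  expect_true(all(A[, 1] > 0))

  cond0 <- gen_condition("ers_plus_mrs", N = 100, J = 500, D = 1, sigma_RS = 1,
                         r_RS = 0, slope_corr = 0, seed = 1)
  set.seed(2)
  A0 <- attr(draw_item_parameters(cond0), "slope_matrix")
  expect_lt(abs(cor(A0[, 2], A0[, 3])), 0.2)  # independent draws
})

test_that("slopes are log-normal with median one", {
  cond <- gen_condition("null", N = 1, J = 10000, D = 1, seed = 1)
  set.seed(3)
  A <- attr(draw_item_parameters(cond), "slope_matrix")
  expect_gt(median(A[, 1]), 0.97)
  expect_lt(median(A[, 1]), 1.03)
  expect_lt(abs(sd(log(A[, 1])) - 0.3), 0.01)
})

test_that("latent traits have the specified scale and correlation", {
  set.seed(4)
  th0 <- draw_latent_traits(gen_condition("null", N = 10000, J = 10, D = 2, seed = 1))
  expect_equal(ncol(th0), 2L)
  expect_lt(max(abs(apply(th0, 2, sd) - 1)), 3 / sqrt(2 * 10000))
  expect_lt(abs(cor(th0[, 1], th0[, 2])), 0.03)

  set.seed(5)
  th1 <- draw_latent_traits(gen_condition("ers_mrs", N = 50000, J = 10, D = 1,
                                          sigma_RS = 1.5, seed = 1))
  expect_lt(abs(sd(th1[, 2]) - 1.5), 0.02)

  set.seed(6)
  th2 <- draw_latent_traits(gen_condition("ers_plus_mrs", N = 50000, J = 10,
                                          D = 1, sigma_RS = 1, r_RS = 0.5,
                                          slope_corr = 0, seed = 1))
  expect_lt(abs(cor(th2[, 2], th2[, 3]) - 0.5), 0.02)
  expect_lt(max(abs(cor(th2[, 1], th2[, 2:3]))), 0.03)  # independent of substantive
})

test_that("response simulation matches its probability model", {
  s <- build_scoring_matrix("null", 5, 1)
  # empty case
  empty <- simulate_responses(list(example_item(c(1), c(-2, -1, 0, -1, -2))),
                              matrix(0, 0, 1), s)
  expect_equal(dim(empty), c(0L, 1L))
  # limiting case: an extreme trait pins the top category
  set.seed(7)
  it <- item_parameters(2, c(-2, -1, 0, -1, -2))
  y <- replicate(1000, simulate_responses(list(it), matrix(8, 1, 1), s)[1, 1])
  expect_gt(mean(y == 4L), 0.99)
})

test_that("empirical category frequencies match quadrature-integrated marginals", {
  # marginal P(Y = k) = int P(k | theta) phi(theta) dtheta, computed by
  # Gauss-Hermite quadrature as an independent oracle
  gh <- pracma::gaussHermite(41)
  th <- sqrt(2) * gh$x; w <- gh$w / sqrt(pi)
  for (kind in c("null", "ers_mrs")) {
    cond <- if (kind == "null")
      gen_condition("null", N = 100000, J = 2, D = 1, seed = 8)
    else
      gen_condition("ers_mrs", N = 100000, J = 2, D = 1, sigma_RS = 1, seed = 8)
    ds <- generate_dataset(cond)
    s <- ds$spec$scoring
    for (j in 1:2) {
      it <- ds$items[[j]]
      if (kind == "null") {
        marg <- rowSums(vapply(seq_along(th), function(q)
          w[q] * category_probabilities(th[q], it, s), numeric(5)))
      } else {
        grid2 <- expand.grid(q1 = seq_along(th), q2 = seq_along(th))
        marg <- rowSums(vapply(seq_len(nrow(grid2)), function(g) {
          q1 <- grid2$q1[g]; q2 <- grid2$q2[g]
          w[q1] * w[q2] *
            category_probabilities(c(th[q1], cond$sigma_RS * th[q2]), it, s)
        }, numeric(5)))
      }
      emp <- tabulate(ds$responses[, j] + 1L, 5) / nrow(ds$responses)
      expect_lt(max(abs(emp - marg)), 0.01)
    }
  }
})

test_that("dataset generation is reproducible and fully covered", {
  cond <- gen_condition("null", N = 1000, J = 10, D = 1, seed = 99)
  d1 <- generate_dataset(cond)
  d2 <- generate_dataset(cond)
  expect_identical(d1$responses, d2$responses)
  expect_equal(dim(d1$responses), c(1000L, 10L))
  expect_true(all(d1$responses %in% 0:4))
  # full-coverage property: every (item, category) pair observed
  expect_true(all(apply(d1$responses, 2, function(y)
    length(unique(y))) == 5L))
})

test_that("weak response styles degenerate to the null distribution", {
  cond_rs <- gen_condition("ers_mrs", N = 60000, J = 5, D = 1,
                           sigma_RS = 1e-6, seed = 12)
  cond_null <- gen_condition("null", N = 60000, J = 5, D = 1, seed = 12)
  d_rs <- generate_dataset(cond_rs)
  d_null <- generate_dataset(cond_null)
  f_rs <- tabulate(d_rs$responses + 1L, 5) / length(d_rs$responses)
  f_null <- tabulate(d_null$responses + 1L, 5) / length(d_null$responses)
  expect_lt(max(abs(f_rs - f_null)), 0.01)
})

test_that("condition validation enforces factor applicability", {
  expect_error(gen_condition("null", N = 100, J = 10, sigma_RS = 1), "apply")
  expect_error(gen_condition("ers_mrs", N = 100, J = 10, D = 1), "sigma_RS")
  expect_error(gen_condition("ers_plus_mrs", N = 100, J = 10, D = 1,
                             sigma_RS = 1, r_RS = 0, slope_corr = 0.5),
               "slope_corr")
  expect_error(gen_condition("ers_mrs", N = 100, J = 10, D = 1, sigma_RS = 1,
                             r_RS = 0.5), "ers_plus_mrs")
})
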