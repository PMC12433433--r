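test_that("hand-evaluated category probabilities are reproduced", {
  s_null <- build_scoring_matrix("null", 5, 1)
  # all slopes and intercepts zero: uniform
  expect_equal(unname(category_probabilities(0, item_parameters(0, rep(0, 5)), s_null)),
               rep(0.2, 5))
  # response-style contribution exactly cancels the symmetric intercepts
  s_bip <- build_scoring_matrix("ers_mrs", 5, 1)
  p <- category_probabilities(c(0, 1), example_item(), s_bip)
  expect_equal(unname(p), rep(0.2, 5), tolerance = 1e-12)
  # zero slopes, intercepts (0,1,2,1,0): plain softmax (frozen from
  # exponentiate-and-normalize by hand)
  p2 <- category_probabilities(0, item_parameters(0, c(0, 1, 2, 1, 0)), s_null)
  expect_equal(unname(p2),
               c(0.06745081, 0.18335030, 0.49839779, 0.18335030, 0.06745081),
               tolerance = 1e-6)
})

test_that("probabilities are a valid distribution for arbitrary finite inputs", {
  set.seed(101)
  for (kind in c("null", "ers_mrs", "ers_plus_mrs")) {
    s <- build_scoring_matrix(kind, 5, 1)
    T_ <- nrow(s)
    for (i in 1:25) {
      it <- item_parameters(rlnorm(T_, 0, 0.5), rnorm(5, 0, 3))
      p <- category_probabilities(rnorm(T_, 0, 2), it, s)
      expect_true(all(p > 0), info = kind)
      expect_true(all(p < 1), info = kind)
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("adding a constant to all intercepts leaves probabilities unchanged", {
  set.seed(102)
  s <- build_scoring_matrix("ers_plus_mrs", 5, 1)
  for (i in 1:10) {
    a <- rlnorm(3, 0, 0.3); cc <- rnorm(5); th <- rnorm(3)
    shift <- runif(1, -5, 5)
    expect_equal(category_probabilities(th, item_parameters(a, cc), s),
                 category_probabilities(th, item_parameters(a, cc + shift), s),
                 tolerance = 1e-12)
  }
  # in particular the generation intercepts (-2,-1,0,-1,-2) and their
  # first-category-zero form (0,1,2,1,0) are observationally identical
  sn <- build_scoring_matrix("null", 5, 1)
  expect_equal(
    category_probabilities(0.7, item_parameters(1.2, c(-2, -1, 0, -1, -2)), sn),
    category_probabilities(0.7, item_parameters(1.2, c(0, 1, 2, 1, 0)), sn),
    tolerance = 1e-12)
})

test_that("the linear-scoring model equals an independently coded GPCM", {
  sn <- build_scoring_matrix("null", 5, 1)
  set.seed(103)
  for (i in 1:10) {
    a <- rlnorm(1, 0, 0.3)
    b <- sort(rnorm(4, 0, 1.5))
    cc <- c(0, cumsum(-a * b))        # c_k = -a * sum_{v<=k} b_v
    for (th in seq(-3, 3, by = 0.75)) {
      expect_equal(
        unname(category_probabilities(th, item_parameters(a, cc), sn)),
        gpcm_prob(th, a, b),
        tolerance = 1e-12)
    }
  }
})

test_that("symmetric intercepts give mirror-symmetric probabilities", {
  sn <- build_scoring_matrix("null", 5, 1)
  it <- item_parameters(1.3, c(-2, -1, 0, -1, -2))
  for (th in c(0.5, 1, 2.5)) {
    p_pos <- category_probabilities(th, it, sn)
    p_neg <- category_probabilities(-th, it, sn)
    expect_equal(unname(p_pos), rev(unname(p_neg)), tolerance = 1e-12)
  }
})

test_that("a bipolar item equals a two-dimensional item at mirrored style scores", {
  s_bip <- build_scoring_matrix("ers_mrs", 5, 1)
  s_sep <- build_scoring_matrix("ers_plus_mrs", 5, 1)
  set.seed(104)
  for (i in 1:10) {
    a_sub <- rlnorm(1, 0, 0.3); a_rs <- rlnorm(1, 0, 0.3)
    cc <- rnorm(5)
    th_sub <- rnorm(1); th_rs <- rnorm(1, 0, 1.5)
    p_bip <- category_probabilities(c(th_sub, th_rs),
                                    item_parameters(c(a_sub, a_rs), cc), s_bip)
    p_sep <- category_probabilities(c(th_sub, th_rs, -th_rs),
                                    item_parameters(c(a_sub, a_rs, a_rs), cc), s_sep)
    expect_equal(p_bip, p_sep, tolerance = 1e-12)
  }
})

test_that("probability curves are consistent, symmetric and style-monotone", {
  sn <- build_scoring_matrix("null", 5, 1)
  it <- item_parameters(1, c(-2, -1, 0, -1, -2))
  pc <- probability_curves(it, sn, grid = 0)
  expect_equal(drop(pc), category_probabilities(0, it, sn))

  pc2 <- probability_curves(it, sn, grid = c(-1, 1))
  expect_equal(unname(pc2[, 1]), rev(unname(pc2[, 2])), tolerance = 1e-12)

  s_bip <- build_scoring_matrix("ers_mrs", 5, 1)
  itb <- example_item()
  pc3 <- probability_curves(itb, s_bip, grid = c(0, 3), varied_dim = 2)
  expect_gt(pc3[1, 2], pc3[1, 1])   # extreme categories rise with theta_RS
  expect_gt(pc3[5, 2], pc3[5, 1])
  expect_lt(pc3[3, 2], pc3[3, 1])   # midpoint falls

  expect_error(probability_curves(it, sn, grid = numeric(0)), "nonempty")
  expect_error(probability_curves(it, sn, grid = 0, varied_dim = 2), "varied_dim")
})

test_that("dimension mismatches are rejected", {
  sn <- build_scoring_matrix("ers_mrs", 5, 1)
  expect_error(category_probabilities(0, example_item(), sn), "theta")
  expect_error(category_probabilities(c(0, 1), item_parameters(1, rep(0, 5)), sn),
               "slopes")
  expect_error(category_probabilities(c(0, Inf), example_item(), sn), "finite")
})
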