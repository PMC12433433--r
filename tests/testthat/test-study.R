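test_that("the default factor grids have 12, 36 and 216 cells", {
  expect_equal(nrow(condition_grid("null")), 12L)
  expect_equal(nrow(condition_grid("ers_mrs")), 36L)
  expect_equal(nrow(condition_grid("ers_plus_mrs")), 216L)
  cfg <- study_config()
  expect_equal(nrow(cfg$grid), 264L)
})

test_that("a replication record is deterministic and carries one selection per rule", {
  grid <- condition_grid("ers_mrs", N = 250, J = 10, D = 1, sigma_RS = 1.5)
  r1 <- run_replication(grid[1, ], rep_index = 3, base_seed = 7, cell_index = 1)
  r2 <- run_replication(grid[1, ], rep_index = 3, base_seed = 7, cell_index = 1)
  expect_identical(r1$seed, r2$seed)
  expect_identical(r1$selected_aic, r2$selected_aic)
  expect_identical(r1[c("selected_bic", "selected_combined")],
                   r2[c("selected_bic", "selected_combined")])
  for (col in c("selected_aic", "selected_bic", "selected_combined"))
    expect_true(r1[[col]] %in% c("null", "ers_mrs", "ers_plus_mrs"))
})

test_that("classification accuracy is the right percentage, per group and overall", {
  rec <- data.frame(
    kind = rep(c("null", "ers_mrs"), each = 4),
    N = rep(c(250, 250, 1000, 1000), 2),
    correct_aic = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    correct_bic = rep(c(TRUE, FALSE), 4))
  acc <- classification_accuracy(rec, group_by = "kind", criterion = "aic")
  expect_equal(acc$accuracy[acc$kind == "null"], 75)
  expect_equal(acc$accuracy[acc$kind == "ers_mrs"], 25)
  overall <- classification_accuracy(rec, criterion = "aic")
  expect_equal(overall$accuracy, 50)
  expect_equal(overall$n_reps, 8L)
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 100))
  expect_error(classification_accuracy(rec, group_by = "sigma_RS"),
               "unknown factor")
})

test_that("factor marginals are count-weighted means over applicable factors", {
  rec <- expand.grid(N = c(250, 1000), J = c(10, 20), rep = 1:5)
  rec$kind <- "null"
  rec$D <- 1
  rec$correct_bic <- rec$N == 1000       # correct iff N = 1000
  m <- factor_marginals(rec, criterion = "bic")
  expect_equal(m$accuracy[m$factor == "N" & m$level == 1000], 100)
  expect_equal(m$accuracy[m$factor == "N" & m$level == 250], 0)
  expect_equal(m$accuracy[m$factor == "J" & m$level == 10], 50)
  # only applicable factors appear for a null-regime record set
  expect_setequal(unique(m$factor), c("N", "J", "D"))
  # marginal = weighted mean of cell accuracies
  cells <- classification_accuracy(rec, group_by = c("N", "J"), criterion = "bic")
  byN <- tapply(cells$accuracy * cells$n_reps, cells$N, sum) /
    tapply(cells$n_reps, cells$N, sum)
  expect_equal(unname(byN["1000"]),
               m$accuracy[m$factor == "N" & m$level == 1000])
})

test_that("a reduced study run produces complete, resumable records and tables", {
  cfg <- study_config(kinds = "null", replications = 3L, base_seed = 5,
                      N = 250, J = 10, D = 1)
  out_dir <- tempfile("study")
  st <- run_study(cfg, out_dir = out_dir)
  expect_equal(nrow(st$records), 3L)
  expect_true(all(st$records$kind == "null"))
  expect_true(file.exists(file.path(out_dir, "records.csv")))
  expect_true(file.exists(file.path(out_dir, "accuracy_bic.csv")))
  expect_true(file.exists(file.path(out_dir, "marginals_aic.csv")))
  # same seed stream prefix: rerunning with more reps preserves early records
  cfg2 <- study_config(kinds = "null", replications = 2L, base_seed = 5,
                       N = 250, J = 10, D = 1)
  st2 <- run_study(cfg2)
  expect_equal(st2$records$selected_bic, st$records$selected_bic[1:2])
  expect_equal(st2$records$seed, st$records$seed[1:2])
})

test_that("slope-correlation table rendering pairs accuracies as 'corr1/corr0'", {
  acc <- data.frame(N = rep(c(250, 500), each = 2),
                    slope_corr = rep(c(1, 0), 2),
                    accuracy = c(61.2, 70.4, 88, 92),
                    n_reps = 40)
  tab <- format_slope_corr_table(acc)
  expect_equal(tab$accuracy[tab$N == 250], "61/70")
  expect_equal(tab$accuracy[tab$N == 500], "88/92")
})

test_that("resampling keeps identifiers unique and degenerates to the full data", {
  cond <- gen_condition("ers_mrs", N = 200, J = 10, D = 1, sigma_RS = 1.5,
                        seed = 61)
  ds <- generate_dataset(cond)
  full <- suppressWarnings(fit_battery(ds$responses, K = 5, D = 1,
                                       options = quick_opts()))
  rs <- suppressWarnings(
    resample_study(ds$responses, n_people = 200, item_subset_size = 10,
                   n_resamples = 2, assumed_true_model = "ers_mrs", D = 1,
                   seed = 3, options = quick_opts()))
  # a full-size resample is a permutation of the data: same selection
  expect_equal(unique(rs$records$selected_bic),
               select_by_criterion(full, "bic"))
  expect_error(resample_study(ds$responses, n_people = 500,
                              item_subset_size = 10), "exceeds")
  expect_error(resample_study(ds$responses, n_people = 100,
                              item_subset_size = 20), "exceeds")
})

test_that("the unendorsed-category repair fills the first missing entry", {
  Y <- rbind(c(0L, 1L), c(1L, NA), c(2L, 0L), c(3L, NA))  # K = 5
  fixed <- suppressMessages(respstyles:::fix_unendorsed(Y, 5L))
  # item 2: categories 2, 3, 4 unendorsed; two missing slots, filled in order
  expect_equal(fixed$Y[2, 2], 2L)
  expect_equal(fixed$Y[4, 2], 3L)
  expect_equal(fixed$n_fixed, 2L)
  # item 1 (category 4) and item 2 (category 4) have no missing slot left
  expect_equal(fixed$n_unfixable, 2L)
})

test_that("derived seeds are stable, distinct and in the valid range", {
  s1 <- respstyles:::derive_seed(1, 1, 1)
  expect_identical(s1, respstyles:::derive_seed(1, 1, 1))
  grid <- expand.grid(cell = 1:50, rep = 1:50)
  seeds <- mapply(function(c, r) respstyles:::derive_seed(123, c, r),
                  grid$cell, grid$rep)
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 1 & seeds < 2^31 - 1))
})
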