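#' Condition grid for one generating regime
#'
#' Crosses the design factors of a generating regime into one condition per
#' row. The default factor levels are the full study grids: 12 cells for the
#' null regime, 36 for the bipolar ERS/MRS regime and 216 for the separate
#' ERS + MRS regime.
#'
#' @param kind generating regime.
#' @param N,J,D,sigma_RS,r_RS,slope_corr factor levels (non-applicable
#'   factors are ignored for the given kind).
#' @return data.frame with one row per cell and a \code{cell} index column.
#' @export
condition_grid <- function(kind = MODEL_KINDS, N = c(250, 500, 1000),
                           J = c(10, 20), D = c(1, 2),
                           sigma_RS = c(0.6, 1, 1.5),
                           r_RS = c(-0.5, 0, 0.5), slope_corr = c(0, 1)) {
  kind <- match.arg(kind)
  fac <- list(N = N, J = J, D = D)
  if (kind != "null") fac$sigma_RS <- sigma_RS
  if (kind == "ers_plus_mrs") {
    fac$r_RS <- r_RS
    fac$slope_corr <- slope_corr
  }
  g <- expand.grid(fac, KEEP.OUT.ATTRS = FALSE)
  g <- cbind(kind = kind, cell = seq_len(nrow(g)), g,
             stringsAsFactors = FALSE)
  g
}

#' Configuration of a simulation study
#'
#' @param kinds generating regimes to run.
#' @param replications replications per cell (the full study uses 250).
#' @param base_seed base seed; every (cell, replication) seed is derived
#'   from it, so any record is re-runnable in isolation.
#' @param N,J,D,sigma_RS,r_RS,slope_corr factor-level overrides (defaults
#'   are the full grids).
#' @param workers parallel workers (forked; scheduling cannot change
#'   results because seeds attach to cell/replication, not to workers).
#' @param options an [fit_options()] list used for every fit.
#' @return list of class \code{"mnrm_study_config"} with the resolved
#'   condition grid in \code{$grid}.
#' @export
study_config <- function(kinds = MODEL_KINDS, replications = 250L,
                         base_seed = 1L, N = c(250, 500, 1000),
                         J = c(10, 20), D = c(1, 2),
                         sigma_RS = c(0.6, 1, 1.5),
                         r_RS = c(-0.5, 0, 0.5), slope_corr = c(0, 1),
                         workers = 1L,
                         options = fit_options(tol_loglik = 1e-4, tol_param = 1e-3)) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  grids <- lapply(kinds, function(k)
    condition_grid(k, N = N, J = J, D = D, sigma_RS = sigma_RS,
                   r_RS = r_RS, slope_corr = slope_corr))
  grid <- do.call(rbind, lapply(grids, function(g) {
    for (col in c("sigma_RS", "r_RS", "slope_corr"))
      if (is.null(g[[col]])) g[[col]] <- NA_real_
    g
  }))
  grid$cell <- seq_len(nrow(grid))
  structure(list(kinds = kinds, replications = as.integer(replications),
                 base_seed = as.integer(base_seed), grid = grid,
                 workers = as.integer(workers), options = options),
            class = "mnrm_study_config")
}

row_to_condition <- function(row, seed) {
  gen_condition(row$kind, N = row$N, J = row$J, D = row$D,
                sigma_RS = if (row$kind == "null") NULL else row$sigma_RS,
                r_RS = if (row$kind == "ers_plus_mrs") row$r_RS else NULL,
                slope_corr = if (row$kind == "ers_plus_mrs") row$slope_corr
                             else NULL,
                seed = seed)
}

#' Run one replication of the simulation study
#'
#' Generates a dataset under the condition, fits the three competing
#' models, and records which model each selection rule picks. Estimation
#' failures are recorded in the result, not raised.
#'
#' @param condition an [gen_condition()] object or one row of a
#'   [condition_grid()].
#' @param rep_index replication index within the cell.
#' @param base_seed study base seed; the replication seed is a stable hash
#'   of (base_seed, cell_index, rep_index).
#' @param cell_index condition index within the study grid.
#' @param options an [fit_options()] list. The study default relaxes the
#'   log-likelihood tolerance to 1e-4 (mirt's default, the estimation
#'   engine conventionally used for this model class) and the parameter
#'   tolerance to 1e-3; model selection is insensitive to log-likelihood
#'   changes far below the criterion penalties.
#' @return one-row data.frame (a study record).
#' @export
run_replication <- function(condition, rep_index = 1L, base_seed = 1L,
                            cell_index = 1L,
                            options = fit_options(tol_loglik = 1e-4, tol_param = 1e-3)) {
  if (is.data.frame(condition)) condition <- row_to_condition(condition, 0L)
  seed <- derive_seed(base_seed, cell_index, rep_index)
  condition$seed <- seed
  t0 <- proc.time()[["elapsed"]]
  ds <- generate_dataset(condition)
  battery <- suppressWarnings(
    fit_battery(ds$responses, K = condition$K, D = condition$D,
                options = options))
  tab <- criterion_table(battery)
  sel <- function(rule) tab$model[tab[[paste0("selected_", rule)]]][1]
  conv <- vapply(battery, function(f) isTRUE(f$converged), logical(1))
  data.frame(
    kind = condition$kind, cell = cell_index, rep = rep_index, seed = seed,
    N = condition$N, J = condition$J, D = condition$D,
    sigma_RS = condition$sigma_RS %||% NA_real_,
    r_RS = condition$r_RS %||% NA_real_,
    slope_corr = condition$slope_corr %||% NA_real_,
    selected_aic = sel("aic"), selected_bic = sel("bic"),
    selected_combined = sel("combined"),
    correct_aic = sel("aic") == condition$kind,
    correct_bic = sel("bic") == condition$kind,
    correct_combined = sel("combined") == condition$kind,
    converged_all = all(conv), redraws = ds$redraws,
    runtime = proc.time()[["elapsed"]] - t0,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulation study
#'
#' Executes every cell of the configured grid for the configured number of
#' replications, each under a derived seed. Partial failures are logged into
#' the records; the study completes.
#'
#' @param config an [study_config()].
#' @param out_dir optional directory; when given, the tidy records, the
#'   per-criterion accuracy tables and the factor marginals are written as
#'   CSV files there.
#' @param progress print per-cell progress messages.
#' @return object of class \code{"mnrm_study"} with \code{records} (one row
#'   per cell x replication) and \code{config}.
#' @export
run_study <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "mnrm_study_config"))
  grid <- config$grid
  jobs <- expand.grid(cell = grid$cell, rep = seq_len(config$replications),
                      KEEP.OUT.ATTRS = FALSE)
  one <- function(i) {
    row <- grid[grid$cell == jobs$cell[i], , drop = FALSE]
    rec <- tryCatch(
      run_replication(row, rep_index = jobs$rep[i],
                      base_seed = config$base_seed,
                      cell_index = jobs$cell[i], options = config$options),
      error = function(e) {
        data.frame(kind = row$kind, cell = jobs$cell[i], rep = jobs$rep[i],
                   seed = NA_integer_, N = row$N, J = row$J, D = row$D,
                   sigma_RS = row$sigma_RS, r_RS = row$r_RS,
                   slope_corr = row$slope_corr,
                   selected_aic = NA_character_,
                   selected_bic = NA_character_,
                   selected_combined = NA_character_,
                   correct_aic = NA, correct_bic = NA, correct_combined = NA,
                   converged_all = FALSE, redraws = NA_integer_,
                   runtime = NA_real_, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
    if (is.null(rec$error)) rec$error <- NA_character_
    if (progress && jobs$rep[i] == config$replications)
      message(sprintf("cell %d/%d (%s) done", jobs$cell[i], nrow(grid),
                      row$kind))
    rec
  }
  recs <- if (config$workers > 1L) {
    parallel::mclapply(seq_len(nrow(jobs)), one, mc.cores = config$workers)
  } else {
    lapply(seq_len(nrow(jobs)), one)
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$cell, records$rep), , drop = FALSE]
  rownames(records) <- NULL
  study <- structure(list(records = records, config = config),
                     class = "mnrm_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
    for (crit in c("aic", "bic", "combined")) {
      acc <- classification_accuracy(records,
                                     group_by = c("kind", "N", "J", "D",
                                                  "sigma_RS", "r_RS",
                                                  "slope_corr"),
                                     criterion = crit)
      write.csv(acc, file.path(out_dir, paste0("accuracy_", crit, ".csv")),
                row.names = FALSE)
      write.csv(factor_marginals(records, criterion = crit),
                file.path(out_dir, paste0("marginals_", crit, ".csv")),
                row.names = FALSE)
    }
  }
  study
}

#' @export
print.mnrm_study <- function(x, ...) {
  cat(sprintf("MNRM simulation study: %d records (%d cells x %d reps)\n",
              nrow(x$records), nrow(x$config$grid),
              x$config$replications))
  print(classification_accuracy(x, group_by = "kind"))
  invisible(x)
}

records_of <- function(x) {
  if (inherits(x, "mnrm_study")) x$records else as.data.frame(x)
}

#' Model classification accuracy
#'
#' Percentage of replications in which the given criterion selects the
#' data-generating model, per group of design factors.
#'
#' @param results an \code{mnrm_study} or its records data.frame.
#' @param group_by character vector of record columns to group by (empty:
#'   one overall percentage).
#' @param criterion \code{"aic"}, \code{"bic"} or \code{"combined"}.
#' @return data.frame with the grouping columns, \code{accuracy} (percent,
#'   0..100) and \code{n_reps}.
#' @export
classification_accuracy <- function(results, group_by = character(),
                                    criterion = c("aic", "bic", "combined")) {
  criterion <- match.arg(criterion)
  rec <- records_of(results)
  if (!nrow(rec)) stop("no records")
  unknown <- setdiff(group_by, names(rec))
  if (length(unknown))
    stop("unknown factor name(s): ", paste(unknown, collapse = ", "))
  correct <- rec[[paste0("correct_", criterion)]]
  if (length(group_by) == 0L) {
    return(data.frame(accuracy = 100 * mean(correct, na.rm = TRUE),
                      n_reps = sum(!is.na(correct))))
  }
  # split by a composed key (type-preserving, NA-safe grouping)
  key <- do.call(paste, c(lapply(rec[group_by], function(v)
    ifelse(is.na(v), "<NA>", as.character(v))), sep = "\r"))
  idx <- split(seq_len(nrow(rec)), key)
  out <- do.call(rbind, lapply(idx, function(ii) {
    cbind(rec[ii[1L], group_by, drop = FALSE],
          data.frame(accuracy = 100 * mean(correct[ii], na.rm = TRUE),
                     n_reps = sum(!is.na(correct[ii]))))
  }))
  rownames(out) <- NULL
  out[do.call(order, out[group_by]), , drop = FALSE]
}

#' Per-factor marginal classification accuracy
#'
#' Classification accuracy marginal to each level of each applicable design
#' factor (weighted by record counts, i.e. the weighted mean of cell
#' accuracies).
#'
#' @inheritParams classification_accuracy
#' @return data.frame with columns \code{factor}, \code{level},
#'   \code{accuracy}, \code{n_reps}.
#' @export
factor_marginals <- function(results, criterion = c("aic", "bic", "combined")) {
  criterion <- match.arg(criterion)
  rec <- records_of(results)
  factors <- c("N", "J", "D", "sigma_RS", "r_RS", "slope_corr")
  factors <- factors[vapply(factors, function(f)
    f %in% names(rec) && any(!is.na(rec[[f]])), logical(1))]
  rows <- lapply(factors, function(f) {
    acc <- classification_accuracy(rec[!is.na(rec[[f]]), , drop = FALSE],
                                   group_by = f, criterion = criterion)
    data.frame(factor = f, level = acc[[f]], accuracy = acc$accuracy,
               n_reps = acc$n_reps, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format an accuracy table with the slope-correlation "/" convention
#'
#' For the separate ERS + MRS regime, accuracies for slope correlation 1 and
#' 0 are conventionally displayed side by side as \code{"x/y"} in one cell.
#'
#' @param accuracy tidy accuracy table from [classification_accuracy()]
#'   that includes a \code{slope_corr} grouping column.
#' @param digits rounding for display.
#' @return data.frame with \code{slope_corr} collapsed into a single
#'   character \code{accuracy} column \code{"<corr 1>/<corr 0>"}.
#' @export
format_slope_corr_table <- function(accuracy, digits = 0) {
  stopifnot("slope_corr" %in% names(accuracy))
  keys <- setdiff(names(accuracy), c("slope_corr", "accuracy", "n_reps"))
  a1 <- accuracy[accuracy$slope_corr == 1, , drop = FALSE]
  a0 <- accuracy[accuracy$slope_corr == 0, , drop = FALSE]
  m <- merge(a1[c(keys, "accuracy")], a0[c(keys, "accuracy")], by = keys,
             suffixes = c("_corr1", "_corr0"))
  m$accuracy <- paste0(round(m$accuracy_corr1, digits), "/",
                       round(m$accuracy_corr0, digits))
  m[c(keys, "accuracy")]
}

#' Resampling study on an applied dataset
#'
#' Emulates smaller studies drawn from one large dataset: in each resample,
#' people and items are sampled without replacement, category coverage is
#' repaired (for every item category never endorsed in the subsample, the
#' item's first missing entry is replaced with that category; items without
#' missing entries are logged and left unchanged), the three competing
#' models are fitted, and each criterion's selection is recorded. Accuracy
#' is the percentage of resamples selecting \code{assumed_true_model}.
#'
#' @param data response matrix with internal codes 0..K-1; may contain NA.
#' @param n_people people per resample (without replacement).
#' @param item_subset_size items per resample (without replacement).
#' @param n_resamples number of resamples.
#' @param assumed_true_model the model counted as the correct choice.
#' @param D substantive dimensions assumed when fitting.
#' @param K number of categories.
#' @param seed base seed.
#' @param options an [fit_options()] list.
#' @return list of class \code{"mnrm_resample_study"} with per-resample
#'   \code{records} and an \code{accuracy} data.frame (percent selecting the
#'   assumed true model per criterion).
#' @export
resample_study <- function(data, n_people, item_subset_size,
                           n_resamples = 100L,
                           assumed_true_model = "ers_plus_mrs", D = 1L,
                           K = 5L, seed = 1L,
                           options = fit_options(tol_loglik = 1e-4, tol_param = 1e-3)) {
  Y <- as_response_matrix(data)
  if (n_people > nrow(Y)) stop("n_people exceeds the number of persons")
  if (item_subset_size > ncol(Y)) stop("item_subset_size exceeds the number of items")
  assumed_true_model <- match.arg(assumed_true_model, MODEL_KINDS)
  one <- function(r) {
    sub <- withr::with_seed(derive_seed(seed, 2L, r), {
      people <- sample.int(nrow(Y), n_people)
      items <- sort(sample.int(ncol(Y), item_subset_size))
      list(Y = Y[people, items, drop = FALSE], items = items)
    })
    fixed <- fix_unendorsed(sub$Y, K)
    battery <- tryCatch(
      suppressWarnings(fit_battery(fixed$Y, K = K, D = D, options = options)),
      error = function(e) NULL)
    if (is.null(battery)) {
      return(data.frame(resample = r, selected_aic = NA_character_,
                        selected_bic = NA_character_,
                        selected_combined = NA_character_,
                        n_fixed = fixed$n_fixed,
                        n_unfixable = fixed$n_unfixable))
    }
    tab <- criterion_table(battery)
    sel <- function(rule) tab$model[tab[[paste0("selected_", rule)]]][1]
    data.frame(resample = r, selected_aic = sel("aic"),
               selected_bic = sel("bic"),
               selected_combined = sel("combined"),
               n_fixed = fixed$n_fixed, n_unfixable = fixed$n_unfixable)
  }
  records <- do.call(rbind, lapply(seq_len(n_resamples), one))
  accuracy <- data.frame(
    criterion = c("aic", "bic", "combined"),
    accuracy = vapply(c("aic", "bic", "combined"), function(cr)
      100 * mean(records[[paste0("selected_", cr)]] == assumed_true_model,
                 na.rm = TRUE), numeric(1)))
  structure(list(records = records, accuracy = accuracy,
                 assumed_true_model = assumed_true_model),
            class = "mnrm_resample_study")
}

#' @export
print.mnrm_resample_study <- function(x, ...) {
  cat("Resampling study (assumed true model:", x$assumed_true_model, ")\n")
  print(x$accuracy)
  invisible(x)
}

# Coverage repair used by the resampling design: for each item category that
# is never endorsed in the subsample, replace the item's first missing entry
# with that category.
fix_unendorsed <- function(Y, K) {
  n_fixed <- 0L; n_unfixable <- 0L
  for (j in seq_len(ncol(Y))) {
    missing_rows <- which(is.na(Y[, j]))
    for (k in 0:(K - 1L)) {
      if (any(Y[, j] == k, na.rm = TRUE)) next
      if (length(missing_rows) == 0L) {
        n_unfixable <- n_unfixable + 1L
        message("item ", j, ": category ", k + 1L,
                " unendorsed and no missing entry to repair")
        next
      }
      Y[missing_rows[1L], j] <- k
      missing_rows <- missing_rows[-1L]
      n_fixed <- n_fixed + 1L
    }
  }
  list(Y = Y, n_fixed = n_fixed, n_unfixable = n_unfixable)
}
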