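#' Information criteria of a fit
#'
#' AIC = -2*loglik + 2p and BIC = -2*loglik + p*log(N); lower is preferred.
#'
#' @param fit an \code{mnrm_fit}, or a list with \code{loglik},
#'   \code{n_params} and \code{N}.
#' @return list of class \code{"criterion_pair"} with \code{model},
#'   \code{loglik}, \code{p}, \code{aic}, \code{bic}.
#' @export
information_criteria <- function(fit) {
  ll <- fit$loglik; p <- fit$n_params; N <- fit$N
  if (is.null(N) || N < 1L) stop("N must be at least 1")
  if (p < 0) stop("parameter count must be nonnegative")
  structure(list(model = if (!is.null(fit$spec)) fit$spec$kind else fit$model,
                 loglik = ll, p = p,
                 aic = -2 * ll + 2 * p,
                 bic = -2 * ll + p * log(N)),
            class = "criterion_pair")
}

# Normalize battery / data.frame / list-of-pairs input to a data.frame with
# columns model, loglik, p, aic, bic (and converged when known).
criteria_frame <- function(x) {
  if (inherits(x, "mnrm_battery")) {
    rows <- lapply(x, function(f) {
      ic <- information_criteria(f)
      data.frame(model = ic$model, loglik = ic$loglik, p = ic$p,
                 aic = ic$aic, bic = ic$bic,
                 converged = isTRUE(f$converged))
    })
    return(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "criterion_pair"))) {
    return(do.call(rbind, lapply(x, function(ic)
      data.frame(model = ic$model, loglik = ic$loglik, p = ic$p,
                 aic = ic$aic, bic = ic$bic))))
  }
  stop("cannot interpret criteria input")
}

#' Criterion table for a model battery
#'
#' @param x an \code{mnrm_battery} (or anything [information_criteria()]
#'   understands as a list).
#' @return data.frame with one row per model: log-likelihood, free parameter
#'   count, AIC, BIC, and logical columns marking the model each selection
#'   rule picks.
#' @export
criterion_table <- function(x) {
  tab <- criteria_frame(x)
  tab$selected_aic <- tab$model == select_by_criterion(tab, "aic")
  tab$selected_bic <- tab$model == select_by_criterion(tab, "bic")
  tab$selected_combined <- tab$model == combined_select(tab)
  tab
}

pick_min <- function(values, models, p) {
  ok <- is.finite(values)
  if (!any(ok)) stop("no finite criterion values to select from")
  if (!all(ok))
    warning("excluding model(s) with non-finite criterion: ",
            paste(models[!ok], collapse = ", "))
  v <- values[ok]; m <- models[ok]; pp <- p[ok]
  best <- which(v == min(v))
  if (length(best) > 1L) best <- best[which.min(pp[best])]  # parsimony tie-break
  m[best]
}

#' Select the preferred model by one criterion
#'
#' Picks the model with the lowest AIC or BIC; exact ties go to the model
#' with fewer free parameters.
#'
#' @param pairs an \code{mnrm_battery}, a criterion data.frame, or a list of
#'   [information_criteria()] results.
#' @param criterion \code{"aic"} or \code{"bic"}.
#' @return the selected model label.
#' @export
select_by_criterion <- function(pairs, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  tab <- criteria_frame(pairs)
  pick_min(tab[[criterion]], tab$model, tab$p)
}

#' Combined BIC-then-AIC selection
#'
#' Two-stage rule: the BIC first decides whether any response style is
#' present (null against the better of the two response-style models); if
#' the gate opens, the AIC decides between the bipolar ERS/MRS and the
#' separate ERS + MRS conceptualizations.
#'
#' @inheritParams select_by_criterion
#' @return the selected model label.
#' @export
combined_select <- function(pairs) {
  tab <- criteria_frame(pairs)
  null_row <- tab[tab$model == "null", , drop = FALSE]
  rs <- tab[tab$model != "null", , drop = FALSE]
  if (nrow(null_row) != 1L || nrow(rs) < 1L)
    stop("combined_select expects the null model plus response-style models")
  rs_bic <- suppressWarnings(min(rs$bic[is.finite(rs$bic)], Inf))
  if (is.finite(null_row$bic) && null_row$bic <= rs_bic) return("null")
  pick_min(rs$aic, rs$model, rs$p)
}
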