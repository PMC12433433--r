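#' One cell of the simulation design
#'
#' A generating condition fixes the data-generating model kind and every
#' design factor: sample size, test length, substantive dimensionality,
#' response-style trait standard deviation, response-style trait correlation
#' and response-style slope correlation. Factors that do not apply to a kind
#' must be left NULL.
#'
#' @param kind generating model kind.
#' @param N persons (the study grid uses 250, 500, 1000).
#' @param J items (10 or 20 in the study grid).
#' @param D substantive dimensions (1 or 2).
#' @param sigma_RS SD of the response-style trait(s) (0.6, 1 or 1.5);
#'   required for both response-style kinds.
#' @param r_RS correlation between the ERS and MRS traits (-0.5, 0 or 0.5);
#'   \code{ers_plus_mrs} only.
#' @param slope_corr correlation between an item's ERS and MRS slopes: 1
#'   means the two slopes are copied (identical), 0 means drawn
#'   independently; \code{ers_plus_mrs} only.
#' @param K response categories (5 in the study).
#' @param seed integer seed making the cell reproducible.
#' @param slope_log_sd log-scale SD of the log-normal slope distribution
#'   (log-mean 0); default 0.3.
#' @return list of class \code{"mnrm_condition"}.
#' @export
gen_condition <- function(kind = MODEL_KINDS, N, J, D = 1L,
                          sigma_RS = NULL, r_RS = NULL, slope_corr = NULL,
                          K = 5L, seed = 1L, slope_log_sd = 0.3) {
  kind <- match.arg(kind)
  N <- as.integer(N); J <- as.integer(J); D <- as.integer(D)
  stopifnot(N >= 0L, J >= 1L, D %in% c(1L, 2L))
  if (kind == "null") {
    if (!is.null(sigma_RS) || !is.null(r_RS) || !is.null(slope_corr))
      stop("sigma_RS, r_RS and slope_corr do not apply to the null kind")
  } else {
    if (is.null(sigma_RS) || sigma_RS <= 0)
      stop("sigma_RS (> 0) is required for kind '", kind, "'")
    if (kind == "ers_mrs") {
      if (!is.null(r_RS) || !is.null(slope_corr))
        stop("r_RS and slope_corr apply only to ers_plus_mrs")
    } else {
      if (is.null(r_RS) || abs(r_RS) >= 1)
        stop("r_RS in (-1, 1) is required for ers_plus_mrs")
      if (is.null(slope_corr) || !slope_corr %in% c(0, 1))
        stop("slope_corr must be 0 (independent draws) or 1 (identical)")
    }
  }
  structure(list(kind = kind, N = N, J = J, D = D, K = as.integer(K),
                 sigma_RS = sigma_RS, r_RS = r_RS, slope_corr = slope_corr,
                 seed = as.integer(seed), slope_log_sd = slope_log_sd),
            class = "mnrm_condition")
}

#' @export
print.mnrm_condition <- function(x, ...) {
  extras <- c(
    if (!is.null(x$sigma_RS)) paste0("sigma_RS=", x$sigma_RS),
    if (!is.null(x$r_RS)) paste0("r_RS=", x$r_RS),
    if (!is.null(x$slope_corr)) paste0("slope_corr=", x$slope_corr))
  cat("Generating condition:", x$kind,
      sprintf("(N=%d, J=%d, D=%d%s, seed=%d)\n", x$N, x$J, x$D,
              if (length(extras)) paste0(", ", paste(extras, collapse = ", "))
              else "", x$seed))
  invisible(x)
}

# Deterministic seed mixing (Lehmer-style), keeps values in 1..2^31-2 so they
# are valid set.seed() inputs. All arithmetic stays below 2^53.
derive_seed <- function(base, ...) {
  m <- 2147483647
  h <- as.numeric(base) %% m
  for (k in c(...)) h <- (h * 48271 + as.numeric(k) + 1) %% m
  as.integer(h %% (m - 2) + 1)
}

spec_for_condition <- function(condition) {
  model_spec(condition$kind, condition$D, condition$K, J = condition$J)
}

#' Draw generating item parameters for a condition
#'
#' Every loaded slope (substantive and response-style) is drawn i.i.d.
#' log-normal with log-mean 0 and log-SD \code{condition$slope_log_sd}
#' (median slope 1); intercepts are the fixed symmetric vector
#' \code{(-2,-1,0,-1,-2)} for K = 5 (its general-K analogue
#' \code{-|k - (K-1)/2|} otherwise). For \code{ers_plus_mrs} with
#' \code{slope_corr = 1}, each item's MRS slope is its ERS slope copied.
#' Uses the current RNG state; seed before calling for reproducibility.
#'
#' @param condition an [gen_condition()] object.
#' @param spec optional precomputed [model_spec()].
#' @return list of J [item_parameters()] objects, with attributes
#'   \code{slope_matrix} (J x T) and \code{intercept_matrix} (J x K).
#' @export
draw_item_parameters <- function(condition, spec = spec_for_condition(condition)) {
  J <- condition$J; K <- condition$K
  T_ <- spec$n_dims
  R <- n_style_dims(condition$kind)
  A <- matrix(0, J, T_)
  sub_slopes <- rlnorm(J, 0, condition$slope_log_sd)
  A[cbind(seq_len(J), spec$item_assignment)] <- sub_slopes
  if (R == 1L) {
    A[, spec$n_substantive + 1L] <- rlnorm(J, 0, condition$slope_log_sd)
  } else if (R == 2L) {
    ers <- rlnorm(J, 0, condition$slope_log_sd)
    mrs <- if (condition$slope_corr == 1) ers
           else rlnorm(J, 0, condition$slope_log_sd)
    A[, spec$n_substantive + 1L] <- ers
    A[, spec$n_substantive + 2L] <- mrs
  }
  intercepts <- -abs(0:(K - 1L) - (K - 1L) / 2)
  C <- matrix(rep(intercepts, each = J), J, K)
  items <- lapply(seq_len(J), function(j) item_parameters(A[j, ], C[j, ]))
  attr(items, "slope_matrix") <- A
  attr(items, "intercept_matrix") <- C
  items
}

#' Draw latent traits for a condition
#'
#' Substantive columns are i.i.d. standard normal and mutually independent;
#' response-style columns are independent of them, with SD
#' \code{condition$sigma_RS}. For \code{ers_plus_mrs} the ERS and MRS
#' columns are bivariate normal with correlation \code{condition$r_RS}.
#' Uses the current RNG state.
#'
#' @inheritParams draw_item_parameters
#' @return N x T matrix (substantive columns first, then style columns).
#' @export
draw_latent_traits <- function(condition, spec = spec_for_condition(condition)) {
  N <- condition$N
  T_ <- spec$n_dims
  R <- n_style_dims(condition$kind)
  theta <- matrix(rnorm(N * condition$D), N, condition$D)
  if (R == 1L) {
    theta <- cbind(theta, rnorm(N, 0, condition$sigma_RS))
  } else if (R == 2L) {
    z1 <- rnorm(N); z2 <- rnorm(N)
    r <- condition$r_RS
    ers <- condition$sigma_RS * z1
    mrs <- condition$sigma_RS * (r * z1 + sqrt(1 - r^2) * z2)
    theta <- cbind(theta, ers, mrs)
  }
  colnames(theta) <- rownames(spec$scoring)
  theta
}

#' Simulate a Likert response matrix
#'
#' Draws each response from the categorical distribution given by
#' [category_probabilities()] at the person's latent scores. Uses the
#' current RNG state.
#'
#' @param items list of [item_parameters()] (length J).
#' @param traits N x T latent trait matrix.
#' @param scoring scoring matrix (T x K).
#' @return N x J integer matrix with entries 0..K-1 and no missing values.
#' @export
simulate_responses <- function(items, traits, scoring) {
  N <- nrow(traits); J <- length(items); K <- ncol(scoring)
  Y <- matrix(0L, N, J, dimnames = list(NULL, paste0("item", seq_len(J))))
  if (N == 0L) return(Y)
  for (j in seq_len(J)) {
    eta <- traits %*% (items[[j]]$slopes * scoring)   # N x K
    eta <- sweep(eta, 2L, items[[j]]$intercepts, "+")
    eta <- eta - apply(eta, 1L, max)
    P <- exp(eta)
    cum <- t(apply(P / rowSums(P), 1L, cumsum))
    u <- runif(N)
    Y[, j] <- as.integer(rowSums(u > cum[, -K, drop = FALSE]))
  }
  Y
}

#' Generate one complete simulated dataset
#'
#' Seeds the RNG from the condition, draws item parameters, latent traits
#' and responses, and enforces full category coverage: if any item has a
#' category that was never endorsed, the whole dataset is redrawn under a
#' derived sub-seed (the draw is counted in the \code{redraws} element).
#' Identical conditions (including seed) give bit-identical output.
#'
#' @param condition an [gen_condition()] object.
#' @param max_redraws abort after this many consecutive redraws (a degenerate
#'   condition, e.g. extreme parameters at tiny N).
#' @return list of class \code{"mnrm_dataset"}: \code{responses} (N x J,
#'   codes 0..K-1), \code{items}, \code{traits}, \code{condition},
#'   \code{spec}, \code{redraws}.
#' @export
generate_dataset <- function(condition, max_redraws = 100L) {
  spec <- spec_for_condition(condition)
  for (attempt in 0:max_redraws) {
    seed <- if (attempt == 0L) condition$seed
            else derive_seed(condition$seed, 1L, attempt)
    out <- withr::with_seed(seed, {
      items <- draw_item_parameters(condition, spec)
      traits <- draw_latent_traits(condition, spec)
      Y <- simulate_responses(items, traits, spec$scoring)
      list(items = items, traits = traits, Y = Y)
    })
    covered <- condition$N > 0L &&
      all(apply(out$Y, 2L, function(y) length(unique(y))) == condition$K)
    if (covered || condition$N == 0L) {
      if (attempt > 0L)
        message("generate_dataset: ", attempt, " redraw(s) needed for full ",
                "category coverage")
      return(structure(list(responses = out$Y, items = out$items,
                            traits = out$traits, condition = condition,
                            spec = spec, redraws = attempt),
                       class = "mnrm_dataset"))
    }
  }
  stop("generate_dataset: no full-category-coverage dataset in ",
       max_redraws, " redraws; the condition looks degenerate")
}

#' @export
print.mnrm_dataset <- function(x, ...) {
  cat(sprintf("MNRM dataset: %d persons x %d items (K=%d), kind %s, %d redraw(s)\n",
              nrow(x$responses), ncol(x$responses), x$condition$K,
              x$condition$kind, x$redraws))
  invisible(x)
}
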