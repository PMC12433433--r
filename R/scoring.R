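#' Build the scoring matrix for a model kind
#'
#' Constructs the fixed per-dimension category scoring functions that
#' structure the MNRM slopes. Rows correspond to latent dimensions
#' (substantive dimensions first, then response-style dimensions), columns to
#' the K response categories (coded internally 0..K-1).
#'
#' For K = 5 the rows are the canonical ones: every substantive row is
#' \code{(0,1,2,3,4)}; the bipolar ERS/MRS row is \code{(2,1,0,1,2)}; the
#' separate ERS and MRS rows are \code{(1,0,0,0,1)} and \code{(0,0,1,0,0)}.
#' For general odd K >= 3 the bipolar row is \code{|k - (K-1)/2|}, the ERS
#' row the indicator of the two end categories, and the MRS row the
#' indicator of the single midpoint. Even K has no single midpoint, so
#' response-style kinds are rejected.
#'
#' @param kind one of \code{"null"}, \code{"ers_mrs"}, \code{"ers_plus_mrs"}.
#' @param K number of response categories (>= 2; odd for response-style kinds).
#' @param n_substantive number of substantive dimensions (1 or 2).
#' @return a numeric matrix of class \code{"mnrm_scoring"} with one row per
#'   latent dimension and \code{K} columns; row names label the dimensions.
#' @examples
#' build_scoring_matrix("ers_mrs", 5, 1)
#' @export
build_scoring_matrix <- function(kind = MODEL_KINDS, K = 5L, n_substantive = 1L) {
  kind <- match.arg(kind)
  K <- as.integer(K)
  n_substantive <- as.integer(n_substantive)
  if (K < 2L) stop("K must be at least 2")
  if (!n_substantive %in% c(1L, 2L)) stop("n_substantive must be 1 or 2")
  if (kind != "null" && K %% 2L == 0L) {
    stop("kind '", kind, "' needs a midpoint category, which requires odd K; ",
         "got K = ", K)
  }
  sub <- 0:(K - 1L)
  rows <- matrix(rep(sub, n_substantive), nrow = n_substantive, byrow = TRUE)
  labels <- if (n_substantive == 1L) "substantive" else
    paste0("substantive", seq_len(n_substantive))
  mid <- (K - 1L) / 2
  if (kind == "ers_mrs") {
    rows <- rbind(rows, abs(sub - mid))
    labels <- c(labels, "ers_mrs")
  } else if (kind == "ers_plus_mrs") {
    rows <- rbind(rows,
                  as.numeric(sub == 0L | sub == K - 1L),
                  as.numeric(sub == mid))
    labels <- c(labels, "ers", "mrs")
  }
  dimnames(rows) <- list(labels, paste0("k", seq_len(K)))
  structure(rows, class = c("mnrm_scoring", "matrix", "array"),
            kind = kind, n_substantive = n_substantive)
}

#' @export
print.mnrm_scoring <- function(x, ...) {
  cat("Scoring matrix (", attr(x, "kind"), ", K = ", ncol(x), ")\n", sep = "")
  m <- unclass(x)
  attr(m, "kind") <- NULL
  attr(m, "n_substantive") <- NULL
  print(m)
  invisible(x)
}

#' Number of response-style dimensions of a model kind
#' @param kind model kind.
#' @return integer: 0, 1 or 2.
#' @export
n_style_dims <- function(kind = MODEL_KINDS) {
  kind <- match.arg(kind)
  switch(kind, null = 0L, ers_mrs = 1L, ers_plus_mrs = 2L)
}

#' Define a model specification
#'
#' Bundles the model kind, dimensionality and item-to-dimension assignment.
#' Items follow between-item multidimensionality: each item loads on exactly
#' one substantive dimension; response-style dimensions apply to all items.
#'
#' @param kind model kind (see [build_scoring_matrix()]).
#' @param n_substantive 1 or 2 substantive dimensions.
#' @param K number of response categories.
#' @param J number of items; ignored when \code{item_assignment} is given.
#' @param item_assignment integer vector of length J giving, for each item,
#'   the substantive dimension (1-based) it measures. Defaults to an even
#'   split: the first J/2 items on dimension 1, the rest on dimension 2.
#' @return a list of class \code{"mnrm_spec"} with elements \code{kind},
#'   \code{n_substantive}, \code{K}, \code{item_assignment}, \code{n_dims}
#'   (total latent dimensions) and \code{scoring}.
#' @export
model_spec <- function(kind = MODEL_KINDS, n_substantive = 1L, K = 5L,
                       J = NULL, item_assignment = NULL) {
  kind <- match.arg(kind)
  n_substantive <- as.integer(n_substantive)
  if (is.null(item_assignment)) {
    if (is.null(J)) stop("give either J or item_assignment")
    J <- as.integer(J)
    if (n_substantive == 2L && J %% 2L != 0L)
      stop("with 2 substantive dimensions J must be even (items split evenly)")
    item_assignment <- rep(seq_len(n_substantive), each = J / n_substantive)
  }
  item_assignment <- as.integer(item_assignment)
  if (any(item_assignment < 1L | item_assignment > n_substantive))
    stop("item_assignment entries must be in 1..n_substantive")
  scoring <- build_scoring_matrix(kind, K, n_substantive)
  structure(list(kind = kind, n_substantive = n_substantive, K = as.integer(K),
                 item_assignment = item_assignment,
                 n_dims = n_substantive + n_style_dims(kind),
                 scoring = scoring),
            class = "mnrm_spec")
}

#' @export
print.mnrm_spec <- function(x, ...) {
  cat("MNRM specification\n")
  cat("  kind:", x$kind, " K:", x$K, "\n")
  cat("  substantive dims:", x$n_substantive,
      " style dims:", n_style_dims(x$kind),
      " items:", length(x$item_assignment), "\n")
  invisible(x)
}

#' Count the free parameters of a fitted MNRM
#'
#' Under the estimation convention every item contributes one substantive
#' slope, one slope per response-style dimension, and K - 1 free intercepts
#' (the first-category intercept is fixed at zero); latent means and
#' variances are fixed (0, 1) and all pairwise latent correlations are free.
#'
#' @param spec an \code{mnrm_spec}.
#' @param J item count; defaults to the spec's own item assignment length.
#' @return integer count \code{J*(1 + R + K - 1) + T*(T-1)/2} with R style
#'   dimensions and T total dimensions.
#' @export
count_free_parameters <- function(spec, J = length(spec$item_assignment)) {
  stopifnot(inherits(spec, "mnrm_spec"), J >= 1L)
  R <- n_style_dims(spec$kind)
  T_ <- spec$n_substantive + R
  as.integer(J * (1L + R + (spec$K - 1L)) + T_ * (T_ - 1L) / 2L)
}
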