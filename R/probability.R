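#' Item parameters for the scoring-matrix MNRM
#'
#' @param slopes numeric vector of length T (one slope per latent dimension;
#'   zero on substantive dimensions the item does not load on), in logits per
#'   scoring unit.
#' @param intercepts numeric vector of K category intercepts (logits). The
#'   generation convention uses \code{(-2,-1,0,-1,-2)}; the estimation
#'   convention fixes the first entry to zero. The two are observationally
#'   identical (softmax location invariance).
#' @return list of class \code{"mnrm_item"}.
#' @export
item_parameters <- function(slopes, intercepts) {
  stopifnot(is.numeric(slopes), is.numeric(intercepts),
            all(is.finite(slopes)), all(is.finite(intercepts)))
  structure(list(slopes = as.numeric(slopes),
                 intercepts = as.numeric(intercepts)),
            class = "mnrm_item")
}

#' Category response probabilities
#'
#' Evaluates the adapted MNRM: the linear predictor of category k is
#' \code{sum_d slopes[d] * scoring[d, k] * theta[d] + intercepts[k]} and
#' probabilities are its softmax over the K categories. The Hadamard product
#' of the item slope vector with the scoring column replaces the free
#' category-specific slopes of the unrestricted nominal response model.
#'
#' @param theta numeric vector of latent scores, length T (rows of
#'   \code{scoring}).
#' @param item an [item_parameters()] object (or any list with
#'   \code{slopes}, \code{intercepts}).
#' @param scoring a scoring matrix from [build_scoring_matrix()] (T x K).
#' @return numeric probability vector of length K summing to one.
#' @examples
#' s <- build_scoring_matrix("ers_mrs", 5, 1)
#' it <- item_parameters(c(1, 1), c(-2, -1, 0, -1, -2))
#' category_probabilities(c(0, 1), it, s)
#' @export
category_probabilities <- function(theta, item, scoring) {
  theta <- as.numeric(theta)
  if (!all(is.finite(theta))) stop("theta must be finite")
  if (length(theta) != nrow(scoring))
    stop("length(theta) must equal nrow(scoring) = ", nrow(scoring))
  if (length(item$slopes) != nrow(scoring))
    stop("length(item$slopes) must equal nrow(scoring)")
  if (length(item$intercepts) != ncol(scoring))
    stop("length(item$intercepts) must equal ncol(scoring) = K")
  eta <- drop((item$slopes * theta) %*% scoring) + item$intercepts
  eta <- eta - max(eta)
  p <- exp(eta)
  p / sum(p)
}

#' Category response probability curves
#'
#' Evaluates category probabilities along a grid of values of one latent
#' dimension, holding all other dimensions at zero. This is the standard
#' category-response-curve display for polytomous IRT models.
#'
#' @param item an [item_parameters()] object.
#' @param scoring scoring matrix (T x K).
#' @param grid numeric vector of latent values (nonempty).
#' @param varied_dim which latent dimension (1..T) varies along the grid.
#' @return K x length(grid) matrix; each column is a probability vector.
#' @export
probability_curves <- function(item, scoring, grid, varied_dim = 1L) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("grid must be nonempty")
  varied_dim <- as.integer(varied_dim)
  if (varied_dim < 1L || varied_dim > nrow(scoring))
    stop("varied_dim must be in 1..", nrow(scoring))
  out <- vapply(grid, function(g) {
    theta <- numeric(nrow(scoring))
    theta[varied_dim] <- g
    category_probabilities(theta, item, scoring)
  }, numeric(ncol(scoring)))
  rownames(out) <- colnames(scoring)
  out
}
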