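#' Read a Likert response table
#'
#' Expects a comma-separated file with a header row of item labels and
#' integer codes 1..K; empty fields are missing. Codes are mapped to the
#' internal 0..K-1 representation.
#'
#' @param path file path.
#' @param K number of categories; inferred as the maximum observed code when
#'   NULL.
#' @return integer matrix (persons x items) with internal codes and NA for
#'   missing, item labels as column names, and attribute \code{K}.
#' @export
read_responses <- function(path, K = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) > 1L)
    stop("ragged table: line ", which(nf != nf[1])[1], " has ",
         nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = "")
  M <- as.matrix(raw)
  num <- suppressWarnings(matrix(as.numeric(M), nrow(M), ncol(M)))
  bad <- which(!is.na(M) & (is.na(num) | num != round(num)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer code '%s' at row %d, column '%s'",
                 M[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(raw)[bad[1, 2]]))
  if (is.null(K)) K <- max(num, na.rm = TRUE)
  out_of_range <- which(!is.na(num) & (num < 1 | num > K), arr.ind = TRUE)
  if (nrow(out_of_range))
    stop(sprintf("code %g at row %d, column '%s' outside 1..%d",
                 num[out_of_range[1, , drop = FALSE]], out_of_range[1, 1],
                 colnames(raw)[out_of_range[1, 2]], K))
  Y <- num - 1
  storage.mode(Y) <- "integer"
  colnames(Y) <- colnames(raw)
  attr(Y, "K") <- as.integer(K)
  Y
}

#' Write a Likert response table
#'
#' Inverse of [read_responses()]: internal codes 0..K-1 are written as
#' 1..K; NA becomes an empty field.
#'
#' @param responses integer matrix with internal codes (or an
#'   [generate_dataset()] result).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_responses <- function(responses, path) {
  Y <- as_response_matrix(responses)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("item", seq_len(ncol(Y)))
  write.csv(as.data.frame(Y + 1L), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize generating parameters alongside a simulated dataset
#'
#' Writes the generating slopes, intercepts, condition and latent-trait
#' summary of a simulated dataset as JSON, for parameter-recovery checks.
#'
#' @param dataset an [generate_dataset()] result.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_generating_parameters <- function(dataset, path) {
  stopifnot(inherits(dataset, "mnrm_dataset"))
  obj <- list(
    condition = dataset$condition[!vapply(dataset$condition, is.null, logical(1))],
    slopes = attr(dataset$items, "slope_matrix"),
    intercepts = attr(dataset$items, "intercept_matrix"),
    scoring = unclass(dataset$spec$scoring),
    redraws = dataset$redraws)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a fit as JSON
#'
#' @param fit an \code{mnrm_fit}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mnrm_fit"))
  obj <- list(kind = fit$spec$kind, slopes = fit$slopes,
              intercepts = fit$intercepts, latent_corr = fit$latent_corr,
              loglik = fit$loglik, n_params = fit$n_params, N = fit$N,
              converged = fit$converged, cycles = fit$cycles,
              trace = fit$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Category-coverage report for a response matrix
#'
#' Model fitting requires every item to show at least two distinct observed
#' categories, and stable estimation prefers every category endorsed at
#' least once. This reports per-item coverage and flags problems without
#' raising errors.
#'
#' @param data response matrix with internal codes 0..K-1 (NA = missing).
#' @param K number of categories.
#' @return list with \code{counts} (K x J endorsement counts),
#'   \code{unendorsed} (list per item of never-endorsed category indices,
#'   1-based), and \code{unfittable} (items with < 2 observed categories).
#' @export
validate_for_fitting <- function(data, K = attr(data, "K")) {
  Y <- as_response_matrix(data)
  if (is.null(K)) stop("K must be given or attached to the data")
  J <- ncol(Y)
  counts <- vapply(seq_len(J), function(j)
    tabulate(Y[, j] + 1L, nbins = K), integer(K))
  labels <- if (is.null(colnames(Y))) as.character(seq_len(J)) else colnames(Y)
  colnames(counts) <- labels
  unendorsed <- apply(counts, 2L, function(ct) which(ct == 0L),
                      simplify = FALSE)
  names(unendorsed) <- labels
  unfittable <- which(colSums(counts > 0L) < 2L)
  flagged <- which(vapply(unendorsed, length, integer(1)) > 0L)
  list(counts = counts,
       unendorsed = unendorsed[flagged],
       unfittable = unfittable,
       ok = length(flagged) == 0L && length(unfittable) == 0L)
}
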