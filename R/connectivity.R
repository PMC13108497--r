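# Connectivity matrices: containers, TSV I/O, and the modality-specific
# weight transforms applied before graph construction.

#' Construct a connectivity matrix
#'
#' One subject x one modality square symmetric weight matrix. Structural
#' matrices hold nonnegative streamline-weight sums; functional matrices
#' hold Pearson correlations (raw) or absolutized Fisher-z values
#' (transformed). The diagonal is always forced to zero.
#'
#' @param weights Square numeric matrix, symmetric to within `tol`.
#' @param subject_id Subject identifier.
#' @param modality `"structural"` or `"functional"`.
#' @param transform_state `"raw"` or `"transformed"`.
#' @param tol Symmetry tolerance; asymmetry up to `tol` is averaged out,
#'   larger asymmetry is an error naming the offending entry.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(weights, subject_id, modality,
                                transform_state = "raw", tol = 1e-8) {
  modality <- match.arg(modality, c("structural", "functional"))
  transform_state <- match.arg(transform_state, c("raw", "transformed"))
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(weights) != ncol(weights)) {
    stop("matrix is not square: ", nrow(weights), " x ", ncol(weights),
         call. = FALSE)
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    bad <- which(!is.finite(weights), arr.ind = TRUE)[1, ]
    stop("non-finite weight at (", bad[1], ", ", bad[2], ")", call. = FALSE)
  }
  asym <- abs(weights - t(weights))
  if (max(asym) > tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetry %.3g at (%d, %d) exceeds tolerance %g",
                 max(asym), bad[1], bad[2], tol), call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (modality == "structural" && transform_state == "raw" &&
      any(weights < 0)) {
    stop("raw structural weights must be nonnegative", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), modality = modality,
         weights = weights, transform_state = transform_state),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("ConnectivityMatrix: subject %s, %s (%s), %d x %d\n",
              x$subject_id, x$modality, x$transform_state,
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' Read a connectivity matrix from TSV
#'
#' Expects an N x N tab-separated numeric table, optionally preceded by a
#' header row of region labels; lines starting with `#` are skipped. The
#' matrix must be symmetric to within 1e-8 (small asymmetry is averaged
#' with the transpose); the diagonal is zeroed on read.
#'
#' @param path Path to the TSV file.
#' @param subject_id Subject identifier to attach.
#' @param modality `"structural"` or `"functional"`.
#' @return A [connectivity_matrix] with `transform_state = "raw"`.
#' @export
read_matrix <- function(path, subject_id, modality) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path, call. = FALSE)
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) lines <- lines[-1]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1) {
    stop("ragged rows in matrix file: ", path, call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(cells))),
              nrow = length(cells), byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric entry at row %d, column %d in %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  out <- connectivity_matrix(m, subject_id, modality)
  if (has_header) out$region_labels <- first
  out
}

#' Write a connectivity matrix to TSV
#'
#' @param x A [connectivity_matrix] or plain numeric matrix.
#' @param path Output path.
#' @param labels Optional region labels written as a header row.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, labels = NULL) {
  m <- if (inherits(x, "connectivity_matrix")) x$weights else x
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(labels)) {
    writeLines(paste(labels, collapse = "\t"), con)
  }
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fisher-z transform and absolutize functional connectivity
#'
#' Implements the standard resting-state transform chain: Pearson
#' correlations between all pairs of regional time series are Fisher
#' z-transformed (atanh) and absolutized, yielding nonnegative functional
#' link weights. Correlations are clipped to `[-1 + 1e-7, 1 - 1e-7]` before
#' atanh so that perfectly (anti)correlated pairs stay finite.
#'
#' @param x One of: a [connectivity_matrix] of raw correlations; a square
#'   symmetric correlation matrix; or a regions x time numeric panel from
#'   which pairwise Pearson correlations are computed first.
#' @param subject_id Subject id (required when `x` is a plain matrix/panel).
#' @param input `"auto"` (square symmetric => correlations, otherwise
#'   panel), `"correlation"`, or `"timeseries"`.
#' @return A [connectivity_matrix], modality functional,
#'   `transform_state = "transformed"`, weights `|atanh(r)|`.
#' @export
preprocess_functional <- function(x, subject_id = NULL,
                                  input = c("auto", "correlation",
                                            "timeseries")) {
  input <- match.arg(input)
  if (inherits(x, "connectivity_matrix")) {
    if (x$modality != "functional") {
      stop("expected a functional matrix, got ", x$modality, call. = FALSE)
    }
    if (x$transform_state == "transformed") return(x)
    r <- x$weights
    subject_id <- x$subject_id
  } else {
    if (is.null(subject_id)) subject_id <- "unknown"
    x <- as.matrix(x)
    is_corr <- nrow(x) == ncol(x) &&
      max(abs(x - t(x))) <= 1e-8 && max(abs(x)) <= 1 + 1e-8
    if (input == "correlation" || (input == "auto" && is_corr)) {
      r <- x
    } else {
      # regions x time panel: correlate rows
      sds <- apply(x, 1, stats::sd)
      if (any(sds == 0)) {
        stop("zero-variance time series for region(s): ",
             paste(which(sds == 0), collapse = ", "), call. = FALSE)
      }
      r <- stats::cor(t(x))
    }
  }
  r <- (r + t(r)) / 2
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  w <- abs(atanh(r))
  diag(w) <- 0
  connectivity_matrix(w, subject_id, "functional",
                      transform_state = "transformed")
}

#' Log-transform structural connectivity
#'
#' Streamline-weight sums span orders of magnitude; a log10 transform makes
#' their distribution comparable to functional weights. Positive weights w
#' become `log10(1 + w)`; zeros stay zero and are treated as absent links.
#' The `1 +` offset keeps weights nonnegative (bare log10 would map weights
#' below 1 to negative values); since the map is strictly increasing it does
#' not change the maximum spanning tree.
#'
#' @param x A [connectivity_matrix] (structural, raw) or a nonnegative
#'   square symmetric matrix.
#' @param subject_id Subject id (required for a plain matrix).
#' @return A structural [connectivity_matrix] with
#'   `transform_state = "transformed"`.
#' @export
preprocess_structural <- function(x, subject_id = NULL) {
  if (inherits(x, "connectivity_matrix")) {
    if (x$modality != "structural") {
      stop("expected a structural matrix, got ", x$modality, call. = FALSE)
    }
    if (x$transform_state == "transformed") return(x)
    w <- x$weights
    subject_id <- x$subject_id
  } else {
    if (is.null(subject_id)) subject_id <- "unknown"
    w <- as.matrix(x)
  }
  if (any(w < 0)) {
    stop("structural weights must be nonnegative", call. = FALSE)
  }
  pos <- w > 0
  w[pos] <- log10(1 + w[pos])
  connectivity_matrix(w, subject_id, "structural",
                      transform_state = "transformed")
}
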