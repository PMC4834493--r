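#' Path collective variables
#'
#' Reference-path machinery for the progress variable S_path and the
#' distance-from-path variable Z_path.  For a configuration `x` and an
#' ordered set of `N` reference frames with squared distances `d_i^2`,
#' \deqn{s = \sum_i i e^{-\lambda d_i^2} / \sum_i e^{-\lambda d_i^2},
#'   \quad z = -(1/\lambda) \log \sum_i e^{-\lambda d_i^2}.}
#' Frames are 1-based so `s` runs over `[1, N]`.  The exponential sums are
#' evaluated with a max-shift (log-sum-exp) so configurations far from the
#' path do not underflow; a configuration genuinely off-path (smallest
#' `lambda * d^2` beyond exp range) raises an "off-path" error.
#'
#' @param frames numeric matrix, one reference frame per row (columns are
#'   CV/coordinate components)
#' @param lambda positive smoothing parameter (inverse squared-distance
#'   units); default from [choose_lambda()]
#' @param metric distance metric identifier (`"euclidean"`)
#' @return a `reference_path`
#' @export
reference_path <- function(frames, lambda = NULL, metric = "euclidean") {
  frames <- as.matrix(frames)
  if (nrow(frames) < 2) stop("a reference path needs at least 2 frames")
  metric <- match.arg(metric, "euclidean")
  d <- sqrt(rowSums((frames[-1, , drop = FALSE] -
    frames[-nrow(frames), , drop = FALSE])^2))
  if (any(d == 0)) stop("degenerate path: coincident adjacent frames")
  if (max(d) > 2 * mean(d) || min(d) < mean(d) / 2) {
    stop("frames are not near-uniformly spaced (adjacent distances must be within a factor 2 of their mean); reparametrize with build_reference_path()")
  }
  p <- structure(
    list(
      frames = frames, metric = metric,
      nframes = nrow(frames)
    ),
    class = "reference_path"
  )
  p$lambda <- if (is.null(lambda)) choose_lambda(p) else lambda
  if (p$lambda <= 0) stop("lambda must be positive")
  p
}

#' @export
print.reference_path <- function(x, ...) {
  cat(sprintf(
    "Reference path: %d frames, %d components, lambda = %.4g (%s metric)\n",
    x$nframes, ncol(x$frames), x$lambda, x$metric
  ))
  invisible(x)
}

#' Compute (S_path, Z_path) for a configuration
#' @param config numeric vector, one configuration in the frame coordinate
#'   space (or a matrix, one configuration per row)
#' @param path a `reference_path`
#' @return list with `s` and `z` (vectors for matrix input)
#' @examples
#' p <- build_reference_path(rbind(c(0, 0), c(3, 0)), nframes = 4)
#' compute_path_cv(c(1, 0.2), p)
#' @export
compute_path_cv <- function(config, path) {
  stopifnot(inherits(path, "reference_path"))
  if (is.null(dim(config))) config <- matrix(config, nrow = 1)
  if (ncol(config) != ncol(path$frames)) {
    stop("configuration dimensionality does not match the path metric space")
  }
  n <- path$nframes
  s <- z <- numeric(nrow(config))
  for (r in seq_len(nrow(config))) {
    d2 <- rowSums((path$frames - matrix(config[r, ], n, ncol(config),
      byrow = TRUE
    ))^2)
    a <- -path$lambda * d2
    m <- max(a)
    if (m < -700) {
      stop("off-path: configuration too far from every reference frame for the exponential sums")
    }
    wts <- exp(a - m)
    S <- sum(wts)
    s[r] <- sum(seq_len(n) * wts) / S
    z[r] <- -(m + log(S)) / path$lambda
  }
  list(s = s, z = z)
}

#' Build a reference path with near-uniform arc-length spacing
#'
#' Reparametrizes an ordered set of source points (two endpoints or a
#' trajectory polyline) to `nframes` frames at equal arc-length fractions.
#'
#' @param points numeric matrix of ordered source points (>= 2 rows); two
#'   rows are treated as straight-line endpoints
#' @param nframes number of output frames
#' @param lambda optional lambda override for the returned path
#' @return a `reference_path`
#' @export
build_reference_path <- function(points, nframes = 30, lambda = NULL) {
  points <- as.matrix(points)
  keep <- c(TRUE, rowSums(abs(diff(points))) > 0)
  points <- points[keep, , drop = FALSE]
  if (nframes < 2) stop("nframes must be at least 2")
  if (nrow(points) < 2) stop("need at least two distinct source points")
  if (nrow(points) == 2 && nframes > 2) {
    fr <- seq(0, 1, length.out = nframes)
    frames <- outer(1 - fr, points[1, ]) + outer(fr, points[2, ])
    return(reference_path(frames, lambda = lambda))
  }
  if (nrow(points) < nframes) {
    stop("fewer distinct source points than requested frames")
  }
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg))
  target <- seq(0, arc[length(arc)], length.out = nframes)
  frames <- apply(points, 2, function(col) approx(arc, col, xout = target)$y)
  reference_path(as.matrix(frames), lambda = lambda)
}

#' Default lambda for a reference path
#'
#' Standard heuristic `lambda = 2.3 / <d^2_adjacent>`, which makes
#' adjacent frames resolvable by the path variables.
#'
#' @param path a `reference_path` (or a frames matrix)
#' @return lambda
#' @export
choose_lambda <- function(path) {
  frames <- if (inherits(path, "reference_path")) path$frames else as.matrix(path)
  d2 <- rowSums((frames[-1, , drop = FALSE] -
    frames[-nrow(frames), , drop = FALSE])^2)
  if (any(d2 == 0)) stop("degenerate (zero) adjacent frame distances")
  2.3 / mean(d2)
}

#' Write / read a reference path as TSV (one frame per row)
#' @param path a `reference_path`
#' @param file file path
#' @export
write_reference_path <- function(path, file) {
  write.table(path$frames, file,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = paste0("x", seq_len(ncol(path$frames)))
  )
  invisible(file)
}

#' @rdname write_reference_path
#' @param lambda optional lambda for the re-read path
#' @export
read_reference_path <- function(file, lambda = NULL) {
  reference_path(as.matrix(read.table(file, header = TRUE, sep = "\t")),
    lambda = lambda
  )
}
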