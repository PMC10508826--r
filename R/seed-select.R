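#' Regular-space clustering of a standardized CV ensemble
#'
#' Single-pass regular-space clustering: frames are visited in order; a
#' frame becomes a new cluster center iff its Euclidean distance to every
#' existing center is at least `dmin` (distance exactly equal to `dmin`
#' opens a new center, so results are bit-reproducible).  The first frame is
#' always a center.  Unlike density-based methods this gives the sparse
#' tails of a predicted ensemble the same footing as its dense core, which
#' is why it is used to pick seeds out of reduced-MSA structure ensembles.
#'
#' The result is order-sensitive by construction; `shuffle = TRUE` permutes
#' the frames (seeded) for sensitivity analysis.  Whatever the order, the
#' post-conditions hold: all pairwise center distances are `>= dmin` and
#' every non-center frame lies strictly within `dmin` of some center.
#'
#' @param x Standardized CV matrix (frames in rows).  A warning (not an
#'   error) is issued if any column's sd deviates from 1 by more than 0.01.
#' @param dmin Minimum center separation in standardized CV space
#'   (dimensionless; default 9).
#' @param shuffle Permute frame order before the pass (default `FALSE`).
#' @param seed Seed for the permutation when `shuffle = TRUE`.
#' @return A `cluster_result`: list with `centers` (frame indices of the
#'   centers, in original indexing), `assignment` (nearest center index per
#'   frame, ties broken toward the lower center index), and `dmin`.
#' @export
regular_space_cluster <- function(x, dmin = 9, shuffle = FALSE, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 1L) stop("need at least one frame")
  stopifnot(dmin > 0)
  sds <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  if (n > 1L && any(abs(sds - 1) > 0.01))
    warning("input does not look standardized (column sd off 1 by > 0.01)")
  ord <- seq_len(n)
  if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    ord <- sample.int(n)
  }
  centers <- integer(0)
  cmat <- matrix(numeric(0), ncol = ncol(x))
  for (i in ord) {
    if (length(centers) == 0L) {
      centers <- i
      cmat <- x[i, , drop = FALSE]
      next
    }
    d2 <- rowSums(sweep(cmat, 2, x[i, ])^2)
    if (min(d2) >= dmin^2) {
      centers <- c(centers, i)
      cmat <- rbind(cmat, x[i, ])
    }
  }
  dall <- outer(rowSums(x^2), rep(1, length(centers))) -
    2 * x %*% t(cmat) + outer(rep(1, n), rowSums(cmat^2))
  assignment <- max.col(-dall, ties.method = "first")
  out <- list(centers = centers, assignment = assignment, dmin = dmin,
              order = ord)
  class(out) <- "cluster_result"
  out
}

#' Select cluster centers as simulation seeds
#'
#' Returns the center frames of a [regular_space_cluster()] result, each
#' tagged with its DFG state when the frames carry the Dunbrack distances.
#'
#' @param result A `cluster_result`.
#' @param frames The CV matrix the clustering was run on, or the
#'   corresponding unstandardized frames (same row order).
#' @param states Optional per-frame state labels; if `NULL` and `frames`
#'   has `d1`/`d2` columns, [classify_dfg()] is applied.
#' @return A list with `frames` (matrix of seed frames), `indices`, and
#'   `states` (factor or `NULL`).
#' @export
select_seeds <- function(result, frames, states = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  frames <- as.matrix(frames)
  idx <- result$centers
  if (length(idx) == 0L)
    return(list(frames = frames[0, , drop = FALSE], indices = integer(0),
                states = NULL))
  sel <- frames[idx, , drop = FALSE]
  if (is.null(states) && all(c("d1", "d2") %in% colnames(frames)))
    states <- classify_dfg(frames[, "d1"], frames[, "d2"])
  list(frames = sel, indices = idx,
       states = if (is.null(states)) NULL else states[idx])
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("regular-space clustering: ", length(x$assignment), " frames, ",
      length(x$centers), " centers (dmin = ", x$dmin, ")\n", sep = "")
  invisible(x)
}
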