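# Binding-site evaluation protocol: clustered binary matching at 5 A,
# precision/recall, MAD statistics, and the discretized Jaccard index.

.xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  if (is.data.frame(x)) return(unname(cbind(x$x, x$y, x$z)))
  if (is.numeric(x) && length(x) == 3) return(matrix(x, 1, 3))
  stop("cannot interpret coordinates; give an n x 3 matrix or a data frame with x/y/z",
       call. = FALSE)
}

#' Match predicted against true metal sites
#'
#' Applies the clustered binary matching rules: a true site with at least
#' one prediction within `radius` counts as one TP (however many
#' predictions hit it); a true site with none is one FN. Predictions not
#' within `radius` of any true site are clustered by average-linkage
#' agglomerative clustering at `radius`, and each cluster counts as a
#' single FP.
#'
#' @param predictions Predicted positions (n x 3 matrix or data frame with
#'   x/y/z columns).
#' @param true_sites True positions, same formats.
#' @param radius Matching radius in Angstrom (default 5).
#' @return A list of class `match_result`: `tp`, `fp`, `fn`,
#'   `matched_pairs` (data frame: prediction, nearest matched true site,
#'   distance), `fp_cluster_centers` (matrix).
#' @export
match_predictions <- function(predictions, true_sites, radius = 5) {
  stopifnot(radius > 0)
  pred <- .xyz_matrix(predictions)
  truth <- .xyz_matrix(true_sites)
  np <- nrow(pred); nt <- nrow(truth)

  if (nt == 0) {
    d <- NULL
    tp <- 0L; fn <- 0L
    unmatched <- seq_len(np)
    pairs <- data.frame(px = numeric(), py = numeric(), pz = numeric(),
                        tx = numeric(), ty = numeric(), tz = numeric(),
                        distance = numeric())
  } else if (np == 0) {
    tp <- 0L; fn <- nt
    unmatched <- integer(0)
    pairs <- data.frame(px = numeric(), py = numeric(), pz = numeric(),
                        tx = numeric(), ty = numeric(), tz = numeric(),
                        distance = numeric())
  } else {
    d <- matrix(0, np, nt)
    for (j in seq_len(nt)) {
      d[, j] <- sqrt((pred[, 1] - truth[j, 1])^2 + (pred[, 2] - truth[j, 2])^2 +
                       (pred[, 3] - truth[j, 3])^2)
    }
    hit_true <- apply(d <= radius, 2, any)
    tp <- sum(hit_true)
    fn <- nt - tp
    matched_pred <- which(apply(d <= radius, 1, any))
    unmatched <- setdiff(seq_len(np), matched_pred)
    if (length(matched_pred)) {
      nearest <- apply(d[matched_pred, , drop = FALSE], 1, which.min)
      dist_near <- d[cbind(matched_pred, nearest)]
      pairs <- data.frame(px = pred[matched_pred, 1], py = pred[matched_pred, 2],
                          pz = pred[matched_pred, 3],
                          tx = truth[nearest, 1], ty = truth[nearest, 2],
                          tz = truth[nearest, 3], distance = dist_near)
    } else {
      pairs <- data.frame(px = numeric(), py = numeric(), pz = numeric(),
                          tx = numeric(), ty = numeric(), tz = numeric(),
                          distance = numeric())
    }
  }

  if (length(unmatched)) {
    um <- pred[unmatched, , drop = FALSE]
    cl <- .threshold_cluster(um, radius)
    fp <- length(unique(cl))
    centers <- t(vapply(sort(unique(cl)), function(ci) {
      colMeans(um[cl == ci, , drop = FALSE])
    }, numeric(3)))
  } else {
    fp <- 0L
    centers <- matrix(numeric(0), 0, 3)
  }

  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 matched_pairs = pairs, fp_cluster_centers = centers),
            class = "match_result")
}

#' Precision and recall from a match result
#'
#' Precision = TP / (TP + FP); recall = TP / (TP + FN). An undefined
#' denominator yields `NA` (an explicit undefined marker, not zero).
#'
#' @param match A `match_result`.
#' @return A list with `precision` and `recall`.
#' @export
precision_recall <- function(match) {
  stopifnot(inherits(match, "match_result"))
  list(
    precision = if (match$tp + match$fp > 0) match$tp / (match$tp + match$fp) else NA_real_,
    recall = if (match$tp + match$fn > 0) match$tp / (match$tp + match$fn) else NA_real_
  )
}

#' Deviation statistics of matched predictions
#'
#' Collects the distance to the nearest true site for *all* predictions
#' within `radius` of any true site (not just the best prediction per
#' site), and returns the mean (MAD), population standard deviation and
#' median.
#'
#' @param predictions,true_sites Positions as in [match_predictions()].
#' @param radius Matching radius (default 5 A).
#' @return A list with `mean`, `std`, `median`, `n`.
#' @export
mad_statistics <- function(predictions, true_sites, radius = 5) {
  m <- match_predictions(predictions, true_sites, radius)
  d <- m$matched_pairs$distance
  if (!length(d)) stop("no prediction within ", radius,
                       " A of a true site; deviation statistics undefined",
                       call. = FALSE)
  list(mean = mean(d), std = sqrt(mean((d - mean(d))^2)),
       median = stats::median(d), n = length(d))
}

#' Discretized Jaccard index of two probability grids
#'
#' Binarizes both grids at `threshold`, optionally zeroes the outer
#' `trim_voxels` shells of both (removing spurious density at the box
#' edges), and returns intersection over union of the resulting voxel
#' sets. An empty union counts as perfect agreement (1.0).
#'
#' @param predicted,expected Arrays (or `voxel_grid`/`density_map`
#'   objects) sharing shape and frame.
#' @param threshold Decision boundary in (0, 1) (default 0.5).
#' @param trim_voxels Number of edge shells to zero out (default 0).
#' @return Jaccard index in `[0, 1]`.
#' @export
discretized_jaccard <- function(predicted, expected, threshold = 0.5,
                                trim_voxels = 0) {
  gv <- function(x) {
    if (inherits(x, "voxel_grid") || inherits(x, "density_map")) x <- x$values
    x <- drop(x)
    stopifnot(is.array(x), length(dim(x)) == 3)
    x
  }
  p <- gv(predicted); e <- gv(expected)
  if (!identical(dim(p), dim(e))) stop("grid shapes differ", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1, trim_voxels >= 0)
  pb <- p > threshold
  eb <- e > threshold
  if (trim_voxels > 0) {
    n <- dim(pb)
    stopifnot(all(2 * trim_voxels < n))
    keep <- lapply(n, function(nk) (trim_voxels + 1):(nk - trim_voxels))
    mask <- array(FALSE, dim = n)
    mask[keep[[1]], keep[[2]], keep[[3]]] <- TRUE
    pb <- pb & mask
    eb <- eb & mask
  }
  uni <- sum(pb | eb)
  if (uni == 0) return(1.0)
  sum(pb & eb) / uni
}

#' Full evaluation report
#'
#' Combines the clustered matching counts, precision/recall, and deviation
#' statistics into one report.
#'
#' @param predictions,true_sites Positions as in [match_predictions()].
#' @param radius Matching radius (default 5 A).
#' @return A list of class `evaluation_report` with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `mad_mean`, `mad_std`, `mad_median`,
#'   `n_distances`.
#' @export
evaluate_predictions <- function(predictions, true_sites, radius = 5) {
  m <- match_predictions(predictions, true_sites, radius)
  pr <- precision_recall(m)
  md <- if (nrow(m$matched_pairs)) {
    mad_statistics(predictions, true_sites, radius)
  } else list(mean = NA_real_, std = NA_real_, median = NA_real_, n = 0L)
  structure(list(tp = m$tp, fp = m$fp, fn = m$fn,
                 precision = pr$precision, recall = pr$recall,
                 mad_mean = md$mean, mad_std = md$std, mad_median = md$median,
                 n_distances = md$n),
            class = "evaluation_report")
}
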