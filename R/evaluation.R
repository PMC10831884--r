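#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table (Hubert-Arabie adjustment): 1 for
#' identical partitions (up to label permutation), about 0 for independent
#' ones.
#'
#' @param labels_a,labels_b vectors of equal length (>= 2); any label type.
#' @return a single number, at most 1.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)) # 1
#' adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)) # -0.5
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_bd("label vectors differ in length (%d vs %d)",
            length(labels_a), length(labels_b))
  }
  n <- length(labels_a)
  if (n < 2L) stop_bd("at least 2 items required")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  cn2 <- choose(n, 2)
  # single division over integer-valued terms, so exact cases stay exact
  num <- 2 * (sum_ij * cn2 - a * b)
  den <- cn2 * (a + b) - 2 * a * b
  if (den == 0) return(ifelse(num == 0, 1, 0))
  num / den
}

#' Cluster-structure agreement between actual and predicted latent vectors
#'
#' Clusters the encoder-derived and fMRI-derived latent vectors
#' independently with multi-restart k-means, for each k in \code{k_values},
#' and reports the adjusted Rand index between the two label vectors per k.
#' High ARI means the fMRI map preserves the latent geometry of the
#' stimulus. The default of 50 restarts makes each clustering reproducible
#' up to genuine structure: with fewer restarts, k-means local optima alone
#' depress the ARI between two clusterings of the same point set.
#'
#' @param actual,predicted \code{\link{latent_sequence}} objects or matrices
#'   with equal row counts.
#' @param k_values integer vector of cluster counts (default 3..20).
#' @param n_restarts k-means restarts per k.
#' @param seed seed controlling the k-means initialisations.
#' @return object of class \code{"cluster_comparison"}: data.frame
#'   \code{ari_per_k} (k, ari) plus the seeds used.
#' @export
compare_cluster_structure <- function(actual, predicted, k_values = 3:20,
                                      n_restarts = 50L, seed = 1L) {
  A <- latent_matrix(actual)
  P <- latent_matrix(predicted)
  if (nrow(A) != nrow(P)) {
    stop_bd("actual and predicted must have equal timepoint counts")
  }
  if (any(k_values > nrow(A))) {
    stop_bd("k = %d exceeds the number of timepoints (%d)",
            max(k_values), nrow(A))
  }
  seeds <- split_seed(seed, length(k_values))
  ari <- vapply(seq_along(k_values), function(i) {
    k <- k_values[i]
    with_seed(seeds[i], {
      ca <- kmeans(A, centers = k, nstart = n_restarts, iter.max = 100)
      cp <- kmeans(P, centers = k, nstart = n_restarts, iter.max = 100)
      adjusted_rand_index(ca$cluster, cp$cluster)
    })
  }, numeric(1))
  structure(list(ari_per_k = data.frame(k = k_values, ari = ari),
                 n_restarts = n_restarts, seed = seed, seeds_used = seeds),
            class = "cluster_comparison")
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat("<cluster_comparison> ARI per k:\n")
  print(x$ari_per_k, row.names = FALSE)
  invisible(x)
}

# Squared Euclidean distances between rows of p (n x d) and rows of a (m x d).
row_dist2 <- function(p, a) {
  outer(rowSums(p^2), rep(1, nrow(a))) +
    outer(rep(1, nrow(p)), rowSums(a^2)) - 2 * tcrossprod(p, a)
}

#' Nearest-neighbour stimulus matching accuracy
#'
#' For each predicted latent vector, finds the k nearest actual latent
#' vectors (Euclidean distance, ties broken toward the lower index) and
#' scores a hit when the vector's own timepoint index is among them. This is
#' the "did we retrieve the right stimulus frame" statistic: with k = 1 it
#' demands an exact match, with k = 3 any of the three closest.
#'
#' @param actual,predicted \code{\link{latent_sequence}} objects or matrices
#'   with equal row counts.
#' @param k neighbourhood size, less than the number of vectors.
#' @return accuracy in [0, 1].
#' @export
knn_match <- function(actual, predicted, k = 1L) {
  A <- latent_matrix(actual)
  P <- latent_matrix(predicted)
  if (nrow(A) != nrow(P)) stop_bd("equal timepoint counts required")
  n <- nrow(A)
  if (k >= n) stop_bd("k (%d) must be smaller than the number of vectors (%d)", k, n)
  d2 <- row_dist2(P, A)
  hits <- vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ], seq_len(n))[seq_len(k)]
    i %in% nb
  }, logical(1))
  mean(hits)
}

#' Closest training frame per predicted latent vector
#'
#' Assigns each predicted latent vector the index of its nearest Euclidean
#' neighbour among the training-frame latent vectors (ties toward the lower
#' index). This is the retrieval step behind object-label prediction: the
#' matched training frame's labels stand in for the decoded stimulus.
#'
#' @param predicted \code{\link{latent_sequence}} or matrix of predicted
#'   vectors.
#' @param train_latents \code{\link{latent_sequence}} or matrix of training
#'   latent vectors (non-empty).
#' @return integer vector of training-frame indices, one per predicted row.
#' @export
nearest_train_frame <- function(predicted, train_latents) {
  P <- latent_matrix(predicted)
  A <- latent_matrix(train_latents)
  if (nrow(A) == 0L) stop_bd("train set must be non-empty")
  d2 <- row_dist2(P, A)
  apply(d2, 1, which.min)
}

ranking_top <- function(ranking, k) {
  stopifnot(is.data.frame(ranking), nrow(ranking) >= 1L)
  as.character(ranking$label[seq_len(min(k, nrow(ranking)))])
}

#' Object-label overlap between test frames and their matched frames
#'
#' Given a label ranking per test frame and per matched (retrieved) frame,
#' scores the fraction of frames whose test top-1 label appears among the
#' matched frame's top-k labels. With a real classifier this is the object
#' prediction accuracy; with ground-truth-backed mocks it validates the
#' retrieval machinery.
#'
#' @param test_rankings,matched_rankings lists of per-frame rankings
#'   (data.frames with \code{label}, \code{score}, scores non-increasing).
#' @param top_k how many of the matched frame's labels count as a hit.
#' @return overlap fraction in [0, 1].
#' @export
label_overlap <- function(test_rankings, matched_rankings, top_k = 1L) {
  stopifnot(length(test_rankings) == length(matched_rankings),
            length(test_rankings) >= 1L)
  hits <- vapply(seq_along(test_rankings), function(i) {
    tr <- test_rankings[[i]]; mr <- matched_rankings[[i]]
    if (nrow(tr) == 0L || nrow(mr) == 0L) stop_bd("empty ranking at frame %d", i)
    ranking_top(tr, 1L) %in% ranking_top(mr, top_k)
  }, logical(1))
  mean(hits)
}

#' Face-detection ROC over a detector threshold sweep
#'
#' Sweeps the detector confidence threshold(s) over a grid and counts, at
#' each operating point, the false positive rate, true positive rate and
#' accuracy of "face present" calls against ground truth. Confidences may be
#' a scalar score per frame or a per-stage confidence triple (a frame is
#' called a face when every stage clears its threshold, the cascade
#' convention).
#'
#' @param confidences numeric vector (one score per frame) or matrix
#'   (frames x 3 stage scores).
#' @param truth logical vector of per-frame face flags.
#' @param threshold_grid numeric vector of scalar thresholds, or matrix
#'   (grid points x 3) of stage-threshold triples (default operating point
#'   c(0.5, 0.6, 0.6) plus a scalar sweep).
#' @return object of class \code{"roc_curve"}: data.frame \code{points} with
#'   threshold(s), \code{fpr}, \code{tpr}, \code{accuracy}. When truth has a
#'   single class, FPR/TPR are NA and only accuracy is reported (with a
#'   warning).
#' @export
face_roc <- function(confidences, truth, threshold_grid = seq(0, 1, 0.05)) {
  conf <- if (is.matrix(confidences)) confidences else
    matrix(confidences, ncol = 1L)
  truth <- as.logical(truth)
  stopifnot(nrow(conf) == length(truth))
  grid <- if (is.matrix(threshold_grid)) threshold_grid else
    matrix(threshold_grid, ncol = 1L)
  if (ncol(grid) != ncol(conf)) {
    stop_bd("threshold grid has %d stages but confidences have %d",
            ncol(grid), ncol(conf))
  }
  single_class <- length(unique(truth)) < 2L
  if (single_class) {
    warning("truth contains a single class; ROC undefined, reporting accuracy only")
  }
  pts <- lapply(seq_len(nrow(grid)), function(g) {
    pred <- rowSums(conf >= rep(grid[g, ], each = nrow(conf))) == ncol(conf)
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    data.frame(fpr = if (single_class) NA_real_ else fp / max(fp + tn, 1L),
               tpr = if (single_class) NA_real_ else tp / max(tp + fn, 1L),
               accuracy = (tp + tn) / length(truth))
  })
  pts <- do.call(rbind, pts)
  thr <- as.data.frame(grid)
  names(thr) <- paste0("threshold", seq_len(ncol(grid)))
  structure(list(points = cbind(thr, pts), n = length(truth)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points over %d frames\n",
              nrow(x$points), x$n))
  print(head(x$points, 10), row.names = FALSE)
  if (nrow(x$points) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  ok <- is.finite(x$points$fpr)
  plot(x$points$fpr[ok], x$points$tpr[ok], type = "b", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "false positive rate",
       ylab = "true positive rate", main = "Face-detection ROC", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}
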