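# Quantitative evaluation of an integration: latent cluster-assignment
# accuracy, k-nearest-neighbour matching accuracy (l1 by default),
# classifier-transfer ROC/AUC, and clustering-robustness co-association.

# all permutations of 1..k (k small) for optimal cluster-to-label matching
permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in permutations_of(k - 1)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Latent cluster-assignment accuracy
#'
#' Clusters the latent points with k-means (fixed seed, multiple restarts),
#' maps clusters to true labels by the assignment maximizing total
#' agreement, and returns the matched accuracy. Invariant to relabelings of
#' the clusters and to isometries of the latent space.
#'
#' @param latents latent matrix.
#' @param labels true labels (one of `n_clusters` values).
#' @param n_clusters number of clusters (must equal the number of distinct
#'   labels; at most 7 for exact matching).
#' @param seed seed for the k-means restarts.
#' @return accuracy in \[0, 1\].
#' @export
cluster_assignment_accuracy <- function(latents, labels, n_clusters,
                                        seed = 1L) {
  latents <- as.matrix(latents)
  lab <- as.integer(factor(labels))
  if (length(unique(lab)) != n_clusters) {
    abort("n_clusters must equal the number of distinct labels")
  }
  if (nrow(latents) < n_clusters) abort("fewer points than clusters")
  if (n_clusters > 7) abort("exact label matching supports up to 7 clusters")
  km <- with_seed(derive_seed(seed, "kmeans"),
                  stats::kmeans(latents, centers = n_clusters, nstart = 10,
                                iter.max = 100))
  cl <- km$cluster
  best <- 0
  for (p in permutations_of(n_clusters)) {
    best <- max(best, mean(p[cl] == lab))
  }
  best
}

#' k-nearest-neighbour matching accuracy between two embeddings
#'
#' For each cell in A, all cells in B are ranked by distance from its latent
#' point; the accuracy is the fraction of cells whose true partner ranks
#' within the closest `k`. Distance ties are broken by sample index.
#'
#' @param latents_a,latents_b latent matrices with equal row counts.
#' @param pairing integer vector: row `i` of A truly corresponds to row
#'   `pairing[i]` of B.
#' @param k neighbourhood size (1 <= k <= n).
#' @param distance `"l1"` (default, as used for latent matching) or `"l2"`.
#' @return a `matching_evaluation`: `k`, `accuracy`, `n`, `distance`.
#' @export
knn_matching_accuracy <- function(latents_a, latents_b, pairing, k,
                                  distance = c("l1", "l2")) {
  distance <- match.arg(distance)
  A <- as.matrix(latents_a); B <- as.matrix(latents_b)
  n <- nrow(A)
  if (nrow(B) != n) abort("embeddings must have equal sample counts")
  if (k < 1 || k > n) abort("k must be in 1..n")
  if (length(pairing) != n || !all(sort(pairing) == seq_len(n))) {
    abort("pairing must be a permutation of 1..n")
  }
  D <- matrix(0, n, n)
  for (d in seq_len(ncol(A))) {
    delta <- outer(A[, d], B[, d], "-")
    D <- D + if (distance == "l1") abs(delta) else delta^2
  }
  hits <- 0L
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))  # ties broken by index
    if (match(pairing[i], ord) <= k) hits <- hits + 1L
  }
  structure(list(k = as.integer(k), accuracy = hits / n, n = as.integer(n),
                 distance = distance),
            class = "matching_evaluation")
}

#' ROC curve and AUC from scores
#'
#' Thresholds are the sorted unique scores plus sentinels; AUC by the
#' trapezoid rule. The curve starts at (0, 0), ends at (1, 1), and both
#' coordinates are nondecreasing.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (the larger value is the positive class).
#' @return a `roc_curve`: `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  lab <- as.integer(factor(labels))
  if (length(unique(lab)) != 2) abort("labels must contain both classes")
  pos <- lab == 2L
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc),
            class = "roc_curve")
}

#' Classifier-transfer ROC
#'
#' Fits the specified classifier (default: random forest with 100 trees of
#' maximum depth 2) on one dataset and scores another — e.g. trained on the
#' observed modality and evaluated on data translated into it — returning
#' the ROC of the transferred scores.
#'
#' @param train_features,train_labels training data (binary labels).
#' @param eval_features,eval_labels evaluation data in the same feature
#'   space.
#' @param classifier_spec list: `ntree` (default 100), `maxnodes` (default 4,
#'   i.e. depth-2 trees), `seed`.
#' @return a `roc_curve` over the evaluation scores.
#' @export
transfer_roc <- function(train_features, train_labels, eval_features,
                         eval_labels,
                         classifier_spec = list(ntree = 100, maxnodes = 4,
                                                seed = 1L)) {
  train_labels <- factor(train_labels)
  if (nlevels(train_labels) != 2) abort("training labels must be binary")
  if (length(unique(eval_labels)) != 2) abort("evaluation labels must be binary")
  if (ncol(as.matrix(train_features)) != ncol(as.matrix(eval_features))) {
    abort("train and eval feature spaces differ")
  }
  ntree <- classifier_spec$ntree %||% 100
  maxnodes <- classifier_spec$maxnodes %||% 4
  seed <- classifier_spec$seed %||% 1L
  Xtr <- as.matrix(train_features)
  Xev <- as.matrix(eval_features)
  colnames(Xtr) <- paste0("f", seq_len(ncol(Xtr)))
  colnames(Xev) <- colnames(Xtr)
  rf <- with_seed(derive_seed(seed, "rf"),
                  randomForest::randomForest(Xtr, train_labels, ntree = ntree,
                                             maxnodes = maxnodes))
  scores <- stats::predict(rf, Xev, type = "prob")[, 2]
  roc_curve(scores, eval_labels)
}

#' Co-association matrix of repeated clusterings
#'
#' Entry (a, b) is the fraction of clusterings in which cells a and b share
#' a cluster; the matrix is symmetric with unit diagonal.
#'
#' @param labelings list of label vectors over the same n cells.
#' @return `n x n` numeric matrix.
#' @export
coassociation_matrix <- function(labelings) {
  if (!length(labelings)) abort("need at least one labeling")
  n <- length(labelings[[1]])
  if (!all(vapply(labelings, length, integer(1)) == n)) {
    abort("labelings have inconsistent lengths")
  }
  M <- matrix(0, n, n)
  for (lab in labelings) {
    M <- M + outer(lab, lab, "==")
  }
  M / length(labelings)
}
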