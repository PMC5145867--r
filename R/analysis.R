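# PCA of calibrated parameter sets with supplementary-variable projection
# and complete-linkage clustering of the individual scores.

#' Principal component analysis (normed, centered)
#'
#' Columns are centered and scaled to unit variance, then decomposed.
#' Variable loadings are scaled to the square root of the eigenvalue, so
#' for standardized data they are the correlations between variables and
#' scores (correlation-circle coordinates).  Component signs are fixed by
#' making the largest-magnitude loading of each component positive.
#'
#' @param X numeric matrix (individuals x variables), no missing values
#' @return list of class `pca_result`: `scores`, `loadings` (scaled),
#'   `explained` (fraction of variance per component), `sdev`, `center`,
#'   `scale`
#' @export
pca_params <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("pca_params: missing values not allowed")
  if (ncol(X) < 2) stop("pca_params: need at least two columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("pca_params: zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(k) {
    v <- p$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(p$rotation, 2, flip, "*")
  scores <- sweep(p$x, 2, flip, "*")
  ev <- p$sdev^2
  structure(list(scores = scores,
                 loadings = sweep(rot, 2, p$sdev, "*"),
                 explained = ev / sum(ev), sdev = p$sdev,
                 center = p$center, scale = p$scale),
            class = "pca_result")
}

#' Project supplementary variables onto the correlation circle
#'
#' The coordinate of a supplementary variable on component k is its
#' Pearson correlation with the individuals' scores on that component.
#'
#' @param pca a [pca_params()] result
#' @param supp numeric matrix with the same individuals (rows)
#' @return matrix (variables x components) of coordinates in `[-1, 1]`
#' @export
project_supplementary <- function(pca, supp) {
  supp <- as.matrix(supp)
  if (nrow(supp) != nrow(pca$scores))
    stop("project_supplementary: row mismatch with the active matrix")
  out <- matrix(0, ncol(supp), ncol(pca$scores),
                dimnames = list(colnames(supp), colnames(pca$scores)))
  for (j in seq_len(ncol(supp))) {
    if (stats::sd(supp[, j]) == 0) {
      warning("zero-variance supplementary variable: coordinate 0")
      next
    }
    out[j, ] <- stats::cor(supp[, j], pca$scores)
  }
  out
}

#' Complete-linkage clustering of PCA scores
#'
#' Euclidean distances over the first `nComponents` score columns,
#' complete-linkage agglomeration, cut into `k` clusters.
#'
#' @param scores score matrix (or a `pca_result`)
#' @param k number of clusters (>= 2)
#' @param nComponents number of leading components used
#' @return list with `labels` (1..k), `hclust` (the dendrogram object)
#' @export
hcluster_scores <- function(scores, k, nComponents = 3) {
  if (inherits(scores, "pca_result")) scores <- scores$scores
  nComponents <- min(nComponents, ncol(scores))
  if (k < 2) stop("hcluster_scores: k must be >= 2")
  if (k > nrow(scores)) stop("hcluster_scores: k exceeds individuals")
  hc <- stats::hclust(stats::dist(scores[, seq_len(nComponents),
                                         drop = FALSE]),
                      method = "complete")
  list(labels = stats::cutree(hc, k = k), hclust = hc)
}

#' Skew-correcting transforms for reporting
#'
#' Optional reporting transform of a calibrated parameter table: log10 of
#' `nuM`, `lp1` and the derived `lx`, `lx1`; reciprocal of `rxp`.
#'
#' @param X matrix/data.frame with named parameter columns
#' @return transformed matrix with renamed columns
#' @export
skew_transform <- function(X) {
  X <- as.matrix(X)
  if (all(c("rxp", "Lp") %in% colnames(X)) && !("lx" %in% colnames(X)))
    X <- cbind(X, lx = X[, "rxp"] * X[, "Lp"])
  if (all(c("rxp", "lp1") %in% colnames(X)) && !("lx1" %in% colnames(X)))
    X <- cbind(X, lx1 = X[, "rxp"] * X[, "lp1"])
  for (nm in intersect(c("nuM", "lp1", "lx", "lx1"), colnames(X))) {
    X[, nm] <- log10(X[, nm])
    colnames(X)[colnames(X) == nm] <- paste0("log10_", nm)
  }
  if ("rxp" %in% colnames(X)) {
    X[, "rxp"] <- 1 / X[, "rxp"]
    colnames(X)[colnames(X) == "rxp"] <- "inv_rxp"
  }
  X
}
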