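#' Principal component analysis of spectra
#'
#' PCA for exploratory analysis of voxel or point spectra. With
#' `pretreat = TRUE` each spectrum is first standard-normal-variate scaled
#' and the decomposition is then performed on the correlation matrix
#' (columns centred and scaled to unit variance), so the eigenvalue > 1
#' retention criterion applies. Component signs are fixed by making the
#' largest-magnitude loading of each PC positive.
#'
#' @param spectra Numeric matrix, one spectrum per row (or a `voxel_table`).
#' @param pretreat Apply SNV + correlation-matrix scaling (default `TRUE`).
#' @param n_components Number of PCs to retain in scores/loadings (default
#'   all).
#' @return Object of class `pca_result` with `scores`, `loadings`,
#'   `eigenvalues` and `pct_variation` (eigenvalue fractions, summing to 1).
#' @export
pca_fit <- function(spectra, pretreat = TRUE, n_components = NULL) {
  X <- if (is.data.frame(spectra)) spectra_matrix(spectra) else as.matrix(spectra)
  if (nrow(X) < 2L) stop_f("need at least 2 spectra")
  if (!is.null(n_components) && n_components > min(dim(X)))
    stop_f("fewer spectra/bands than requested components")
  if (pretreat) {
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0)) stop_f("constant spectrum: SNV undefined")
    X <- (X - rowMeans(X)) / sds
    csd <- apply(X, 2, stats::sd)
    if (any(csd == 0)) stop_f("constant band after SNV; cannot scale")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = pretreat)
  eig <- pc$sdev^2
  # fix sign: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  k <- n_components %||% length(eig)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 eigenvalues = eig,
                 pct_variation = eig / sum(eig)),
            class = "pca_result")
}

#' Choose how many principal components to retain
#'
#' Two standard retention rules: the scree (elbow) test, implemented as the
#' index of the largest second difference of the eigenvalue sequence, and
#' the eigenvalue > 1 criterion, which counts components whose eigenvalue
#' exceeds the variance of one original (standardised) variable and is
#' meaningful for correlation-matrix PCA.
#'
#' @param eigenvalues Eigenvalues sorted in decreasing order.
#' @param rule `"scree"` or `"eigenvalue_gt1"`.
#' @return Integer count of components to retain.
#' @export
select_pc_count <- function(eigenvalues, rule = c("eigenvalue_gt1", "scree")) {
  rule <- match.arg(rule)
  lam <- as.numeric(eigenvalues)
  if (!length(lam)) stop_f("empty eigenvalue list")
  if (is.unsorted(rev(lam))) stop_f("eigenvalues must be sorted descending")
  if (rule == "eigenvalue_gt1") {
    n <- sum(lam > 1)
    if (n == 0L) warning("no eigenvalue exceeds 1; retaining 0 components")
    n
  } else {
    if (length(lam) < 3L) return(1L)
    d2 <- diff(lam, differences = 2) # d2[i] = lam[i] - 2 lam[i+1] + lam[i+2]
    as.integer(which.max(d2) + 1L)   # elbow at the middle index
  }
}

#' Euclidean distance between spectral vectors
#'
#' The distance used throughout the self-organizing-map analysis:
#' `D = sqrt(sum((a - b)^2))`.
#'
#' @param a,b Equal-length numeric vectors.
#' @export
spectral_distance <- function(a, b) {
  if (length(a) != length(b)) stop_f("length mismatch")
  sqrt(sum((a - b)^2))
}

#' Train a self-organizing map on spectra
#'
#' A rectangular-grid batch SOM: codebook vectors are initialised from a
#' random sample of the data, then for a fixed number of epochs every
#' spectrum is assigned to its best-matching unit (nearest codebook under
#' Euclidean distance) and each codebook vector is recomputed as the
#' Gaussian-neighbourhood-weighted mean of the data, with the neighbourhood
#' radius decaying linearly. Batch updates make training deterministic for
#' a given seed.
#'
#' @param spectra Matrix of spectra (rows) or a `voxel_table`.
#' @param grid_rows,grid_cols Node grid size (>= 2 each).
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @return Object of class `som_map`: `codebook` (nodes x bands),
#'   `assignments`, `grid_rows`, `grid_cols`, `node_coords`,
#'   `intra_node_distance` (mean member-to-codebook distance per node) and
#'   `inter_node_distance` (node x node codebook distances).
#' @export
som_fit <- function(spectra, grid_rows = 5L, grid_cols = 5L, epochs = 30L,
                    seed = 1L) {
  X <- if (is.data.frame(spectra)) spectra_matrix(spectra) else as.matrix(spectra)
  if (grid_rows < 2L || grid_cols < 2L) stop_f("grid must be at least 2 x 2")
  n_nodes <- grid_rows * grid_cols
  if (n_nodes > nrow(X))
    warning("more SOM nodes than spectra; some nodes will be empty")
  coords <- as.matrix(expand.grid(row = seq_len(grid_rows),
                                  col = seq_len(grid_cols)))
  grid_d2 <- as.matrix(stats::dist(coords))^2

  with_seed(seed, {
    code <- X[sample.int(nrow(X), n_nodes, replace = n_nodes > nrow(X)), ,
              drop = FALSE]
    r0 <- max(grid_rows, grid_cols) / 2
    for (e in seq_len(epochs)) {
      d2 <- outer(rowSums(X^2), rowSums(code^2), `+`) - 2 * X %*% t(code)
      bmu <- max.col(-d2, ties.method = "first")
      radius <- max(r0 * (1 - (e - 1) / epochs), 0.5)
      h <- exp(-grid_d2 / (2 * radius^2)) # node x node neighbourhood
      W <- h[bmu, , drop = FALSE]         # data x node weights
      denom <- colSums(W)
      nz <- denom > 1e-12
      code[nz, ] <- (t(W) %*% X)[nz, , drop = FALSE] / denom[nz]
    }
    d2 <- outer(rowSums(X^2), rowSums(code^2), `+`) - 2 * X %*% t(code)
    bmu <- max.col(-d2, ties.method = "first")
    intra <- vapply(seq_len(n_nodes), function(k) {
      m <- bmu == k
      if (!any(m)) return(NA_real_)
      mean(sqrt(pmax(d2[m, k], 0)))
    }, numeric(1))
    structure(list(codebook = code, assignments = bmu,
                   grid_rows = grid_rows, grid_cols = grid_cols,
                   node_coords = coords,
                   intra_node_distance = intra,
                   inter_node_distance = as.matrix(stats::dist(code))),
              class = "som_map")
  })
}

#' Cluster SOM codebook vectors into spectral classes
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances) of the codebook vectors, the standard follow-up that turns a
#' trained map into a small number of interpretable spectral classes
#' (default 4: two-peak, major-shoulder, minor-shoulder, single-peak
#' archetypes).
#'
#' @param codebook Node x band matrix (or a `som_map`).
#' @param k Number of classes.
#' @param linkage `stats::hclust` method (default `"ward.D2"`).
#' @return Integer class label per node.
#' @export
hca_classes <- function(codebook, k = 4L, linkage = "ward.D2") {
  if (inherits(codebook, "som_map")) codebook <- codebook$codebook
  if (k < 1L) stop_f("`k` must be >= 1")
  if (k > nrow(codebook)) stop_f("`k` exceeds the node count")
  hc <- stats::hclust(stats::dist(codebook), method = linkage)
  stats::cutree(hc, k = k)
}

#' Nucleotide-degradation freshness indices
#'
#' The simplified K-value and the alternative H-value summarise the
#' catabolite composition: `K = (inosine + Hx) / (IMP + inosine + Hx)` and
#' `H = Hx / (IMP + inosine + Hx)`. Both run from 0 (fresh, all IMP) to 1
#' (fully degraded, all hypoxanthine) and are non-decreasing along the
#' degradation pathway.
#'
#' @param profile A [simulate_catabolites()] profile, or any list with
#'   non-negative `imp`, `inosine`, `hx`.
#' @return Named numeric vector `c(K = ..., H = ...)` (fractions).
#' @export
catabolite_indices <- function(profile) {
  v <- c(profile$imp, profile$inosine, profile$hx)
  if (length(v) != 3L || any(!is.finite(v)) || any(v < -1e-12))
    stop_f("profile must have non-negative imp, inosine, hx")
  tot <- sum(v)
  if (tot <= 0) stop_f("all-zero catabolite profile")
  c(K = (v[2L] + v[3L]) / tot, H = v[3L] / tot)
}

#' Hit Quality Index
#'
#' Goodness-of-fit between two equally scaled spectra: the sum of absolute
#' band-wise differences. Lower values indicate a better match; 0 means
#' identical spectra.
#'
#' @param x,y Equal-length numeric spectra, already on a common scale.
#' @export
hqi <- function(x, y) {
  if (length(x) != length(y)) stop_f("spectra differ in length")
  sum(abs(x - y))
}

#' Calibration curves and day prediction from aging features
#'
#' `calibration_curve()` records the day-to-feature mapping measured on a
#' calibration fillet region for an aging feature (peak separation
#' `"delta_lambda"` or intensity ratio `"ratio"`).
#' `predict_day_from_feature()` assigns a query feature value to the
#' calibration day with the nearest feature value; ties go to the earlier
#' day (the conservative freshness claim) and values outside the curve's
#' range clamp to the nearest endpoint day.
#'
#' @param days Strictly increasing day values.
#' @param values Feature value per day.
#' @param feature_name `"delta_lambda"` or `"ratio"`.
#' @param region Fillet region label.
#' @export
calibration_curve <- function(days, values,
                              feature_name = c("delta_lambda", "ratio"),
                              region = "tail_bottom") {
  feature_name <- match.arg(feature_name)
  if (!length(days)) stop_f("empty calibration curve")
  if (length(days) != length(values)) stop_f("days/values length mismatch")
  if (any(diff(days) <= 0)) stop_f("days must be strictly increasing")
  structure(list(days = as.numeric(days), values = as.numeric(values),
                 feature_name = feature_name, region = region),
            class = "calibration_curve")
}

#' @rdname calibration_curve
#' @param value Query feature value.
#' @param curve A `calibration_curve`.
#' @export
predict_day_from_feature <- function(value, curve) {
  if (!inherits(curve, "calibration_curve")) stop_f("`curve` must be a calibration_curve")
  assert_scalar_number(value, "value")
  d <- abs(curve$values - value)
  curve$days[which.min(d)] # which.min takes the first (earliest day) on ties
}
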