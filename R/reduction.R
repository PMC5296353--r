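# Collinearity analysis, descriptor pruning (23 -> 17), sampling adequacy,
# and range normalization.

descriptor_columns <- function(X) {
  setdiff(names(X), c("stimulus_id"))
}

as_descriptor_matrix <- function(X) {
  if (is.data.frame(X)) {
    ids <- X$stimulus_id
    m <- as.matrix(X[descriptor_columns(X)])
    if (!is.null(ids)) rownames(m) <- ids
    m
  } else {
    as.matrix(X)
  }
}

#' Pairwise Pearson correlations among descriptors
#'
#' @param X descriptor data frame (optionally with a `stimulus_id` column)
#'   or matrix, stimuli in rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(X) {
  m <- as_descriptor_matrix(X)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (nrow(m) < 3) stop("need at least 3 stimuli")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  stats::cor(m)
}

#' Hierarchical clustering of descriptors by correlation
#'
#' Agglomerative average-linkage clustering on the distance `1 - |r|`, so
#' strongly correlated and strongly anticorrelated descriptors both merge
#' early. Merge heights are non-decreasing.
#'
#' @param C correlation matrix.
#' @return an [stats::hclust] tree.
#' @export
cluster_descriptors <- function(C) {
  stats::hclust(stats::as.dist(1 - abs(C)), method = "average")
}

#' Default keep-priority order for collinearity pruning
#'
#' Descriptors earlier in this list are preferred when a collinear pair must
#' lose a member: centroid and skewness medians (and IQRs) outrank their
#' habitual collinear partners — spectral slope, spread median, rolloff
#' median and kurtosis — which sit at the bottom.
#'
#' @return character vector over the 23 canonical names.
#' @export
default_keep_priority <- function() {
  c("spec_centroid_med", "spec_skewness_med", "spec_centroid_iqr",
    "spec_skewness_iqr", "spec_decrease_med", "spec_variation_med",
    "spec_variation_iqr", "spec_flatness_med", "spec_flatness_iqr",
    "spec_crest_med", "spec_crest_iqr", "spec_spread_iqr",
    "spec_rolloff_iqr", "log_attack_time", "attack_slope",
    "temp_centroid", "spec_decrease_iqr",
    "spec_spread_med", "spec_rolloff_med", "spec_slope_med",
    "spec_slope_iqr", "spec_kurtosis_med", "spec_kurtosis_iqr")
}

#' Prune collinear descriptors
#'
#' Repeatedly finds the retained pair with the largest `|r|` above
#' `threshold` and removes its lower-priority member, until no pair exceeds
#' the threshold. Descriptors absent from `keep_priority` rank below all
#' listed ones; ties break alphabetically. Deterministic and idempotent.
#'
#' @param C correlation matrix.
#' @param threshold absolute-correlation cutoff (default 0.905).
#' @param keep_priority character vector, most-preferred first.
#' @return list: `retained` (names), `removed` (data frame with the removed
#'   descriptor, the retained partner and their r).
#' @export
prune_collinear <- function(C, threshold = 0.905,
                            keep_priority = default_keep_priority()) {
  stopifnot(threshold > 0, threshold < 1)
  nms <- colnames(C)
  rank_of <- function(n) {
    i <- match(n, keep_priority)
    ifelse(is.na(i), length(keep_priority) + rank(n), i)
  }
  retained <- nms
  removed <- data.frame(removed = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    sub <- abs(C[retained, retained, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) <= threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- retained[ij[1]]
    b <- retained[ij[2]]
    pr <- rank_of(c(a, b))
    drop_name <- if (pr[1] > pr[2]) a else if (pr[2] > pr[1]) b else
      max(c(a, b))
    keep_name <- setdiff(c(a, b), drop_name)
    removed <- rbind(removed,
                     data.frame(removed = drop_name, partner = keep_name,
                                r = C[drop_name, keep_name],
                                stringsAsFactors = FALSE))
    retained <- setdiff(retained, drop_name)
  }
  list(retained = retained, removed = removed)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal elements,
#' where `q` are the anti-image partial correlations obtained from the
#' inverse correlation matrix. Invariant to column scaling.
#'
#' @param X descriptor data frame or matrix (stimuli in rows).
#' @return scalar in \[0, 1\].
#' @export
kmo_index <- function(X) {
  R <- correlation_matrix(X)
  Ri <- tryCatch(solve(R),
                 error = function(e) stop("correlation matrix is singular"))
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(d, d)
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Range-normalize descriptors to \[0, 1\]
#'
#' Per-column `(x - min) / (max - min)`. The minima and maxima are stored as
#' attributes so held-out data can be mapped with training statistics (in
#' which case values outside \[0, 1\] are allowed).
#'
#' @param X descriptor data frame (optionally with `stimulus_id`) or matrix.
#' @param stats optional list with `min` and `max` named vectors (training
#'   statistics) to apply instead of the column ranges of `X`.
#' @return data frame/matrix of the same shape, with attribute
#'   `"norm_stats"`.
#' @export
range_normalize <- function(X, stats = NULL) {
  m <- as_descriptor_matrix(X)
  if (is.null(stats)) {
    mn <- apply(m, 2, min)
    mx <- apply(m, 2, max)
    if (any(mx == mn)) {
      stop("constant column(s): ", paste(colnames(m)[mx == mn],
                                         collapse = ", "))
    }
  } else {
    mn <- stats$min[colnames(m)]
    mx <- stats$max[colnames(m)]
  }
  norm <- sweep(sweep(m, 2, mn), 2, mx - mn, "/")
  if (is.data.frame(X)) {
    out <- X
    out[colnames(norm)] <- as.data.frame(norm)
  } else {
    out <- norm
  }
  attr(out, "norm_stats") <- list(min = mn, max = mx)
  out
}
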