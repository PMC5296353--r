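# Ratings aggregation, reliability, model metrics and comparison tables.

#' Average ratings across participants
#'
#' @param ratings long data frame from [generate_ratings()] (columns
#'   `participant_id`, `stimulus_id`, `scale`, `rating`).
#' @return data frame: `stimulus_id`, `scale`, `mean_rating` (1-9 scale) and
#'   `mean_norm` (`(mean_rating - 1) / 8`, on \[0, 1\]).
#' @export
aggregate_ratings <- function(ratings) {
  stopifnot(all(c("participant_id", "stimulus_id", "scale", "rating") %in%
                  names(ratings)))
  counts <- table(ratings$stimulus_id, ratings$scale)
  if (any(counts != counts[1])) stop("incomplete rating set (missing cells)")
  agg <- stats::aggregate(rating ~ stimulus_id + scale, data = ratings,
                          FUN = mean)
  names(agg)[names(agg) == "rating"] <- "mean_rating"
  agg$mean_norm <- (agg$mean_rating - 1) / 8
  agg[order(agg$scale, agg$stimulus_id), ]
}

#' Mean ratings in wide form (one column per scale)
#'
#' @param means output of [aggregate_ratings()].
#' @param normalized if `TRUE`, return the \[0, 1\] means.
#' @return data frame with `stimulus_id` and one column per scale.
#' @export
mean_rating_matrix <- function(means, normalized = TRUE) {
  value <- if (normalized) "mean_norm" else "mean_rating"
  out <- stats::reshape(means[c("stimulus_id", "scale", value)],
                        idvar = "stimulus_id", timevar = "scale",
                        direction = "wide")
  names(out) <- sub(paste0("^", value, "\\."), "", names(out))
  rownames(out) <- NULL
  out
}

#' Cronbach's alpha for inter-rater consistency
#'
#' Participants are treated as the items and stimuli as the observations:
#' `alpha = k/(k-1) * (1 - sum of per-participant variances / variance of
#' the per-stimulus participant sum)`, with `k` participants. 1 when all
#' participants give identical (non-constant) ratings.
#'
#' @param mat numeric matrix, participants x stimuli, for one scale.
#' @return scalar alpha (<= 1).
#' @export
cronbach_alpha <- function(mat) {
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  k <- nrow(mat)
  total_var <- stats::var(colSums(mat))
  if (total_var == 0) stop("zero variance in summed ratings")
  k / (k - 1) * (1 - sum(apply(mat, 1, stats::var)) / total_var)
}

#' Ratings of one scale as a participants x stimuli matrix
#'
#' @param ratings long rating data frame.
#' @param scale scale name.
#' @return numeric matrix (participants in rows).
#' @export
rating_matrix <- function(ratings, scale) {
  sub <- ratings[ratings$scale == scale, ]
  if (nrow(sub) == 0) stop("no ratings for scale ", scale)
  wide <- stats::reshape(sub[c("participant_id", "stimulus_id", "rating")],
                         idvar = "participant_id", timevar = "stimulus_id",
                         direction = "wide")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$participant_id
  colnames(m) <- sub("^rating\\.", "", colnames(m))
  m
}

#' Pairwise correlations among scale means
#'
#' Pearson r with two-sided p-values (df = n - 2) for every scale pair.
#'
#' @param means wide data frame from [mean_rating_matrix()].
#' @return list: `r` (correlation matrix), `p` (p-value matrix), `n`.
#' @export
pearson_matrix <- function(means) {
  m <- as.matrix(means[setdiff(names(means), "stimulus_id")])
  if (nrow(m) < 3) stop("need at least 3 stimuli")
  if (any(apply(m, 2, stats::sd) == 0)) stop("constant scale")
  r <- stats::cor(m)
  p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(r))
  for (i in seq_len(ncol(m))) {
    for (j in seq_len(ncol(m))) {
      p[i, j] <- if (i == j) 0 else
        stats::cor.test(m[, i], m[, j])$p.value
    }
  }
  list(r = r, p = p, n = nrow(m))
}

#' Fit metrics between observed and predicted values
#'
#' `R^2 = 1 - SSE/TSS` (TSS about the observed mean) and
#' `RMSE = sqrt(mean((y - yhat)^2))` (population convention, so a
#' mean-only predictor gives RMSE equal to the population SD).
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return named vector: `r2`, `rmse`.
#' @export
model_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  tss <- sum((y_true - mean(y_true))^2)
  if (tss == 0) stop("zero total sum of squares")
  sse <- sum((y_true - y_pred)^2)
  c(r2 = 1 - sse / tss, rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Percent improvement of one model metric over another
#'
#' `round(100 * (new - baseline) / baseline)`, rounding half away from
#' zero; a positive sign means the new model has the higher value.
#'
#' @param baseline baseline metric value (non-zero).
#' @param new comparison metric value.
#' @return signed integer percentage.
#' @export
percent_improvement <- function(baseline, new) {
  if (any(baseline == 0)) stop("zero baseline")
  as.integer(round_half_away(100 * (new - baseline) / baseline))
}

#' Model-comparison table
#'
#' Per emotion dimension and metric, tabulates the linear (PLS) and network
#' values and the integer percent improvement of the network over the PLS
#' model.
#'
#' @param plsr,nn data frames with columns `scale`, `metric`, `value`
#'   (metrics `r2`, `q2`, `rmse`).
#' @return data frame: `scale`, `metric`, `plsr`, `nn`, `improvement_pct`.
#' @export
comparison_table <- function(plsr, nn) {
  merged <- merge(plsr, nn, by = c("scale", "metric"),
                  suffixes = c("_plsr", "_nn"))
  data.frame(scale = merged$scale, metric = merged$metric,
             plsr = merged$value_plsr, nn = merged$value_nn,
             improvement_pct = percent_improvement(merged$value_plsr,
                                                   merged$value_nn))
}

#' Top-k descriptor rank table
#'
#' Ranks descriptors by absolute importance (PLS loadings or network
#' contributions), descending; ties break by canonical descriptor order.
#' Descriptors outside the top `k` get `NA`.
#'
#' @param importance named numeric vector (signed).
#' @param k number of ranked entries (default 6).
#' @return data frame: `descriptor`, `value`, `rank` (NA outside top k).
#' @export
top_k_table <- function(importance, k = 6) {
  stopifnot(length(importance) >= k)
  canon <- match(names(importance), descriptor_names())
  canon[is.na(canon)] <- length(descriptor_names()) +
    seq_len(sum(is.na(canon)))
  ord <- order(-abs(importance), canon)
  rank <- rep(NA_integer_, length(importance))
  nonzero <- abs(importance[ord]) > 0
  top <- ord[seq_len(min(k, sum(nonzero)))]
  rank[top] <- seq_along(top)
  data.frame(descriptor = names(importance), value = unname(importance),
             rank = rank, stringsAsFactors = FALSE)
}
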