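#' Rank-based AUC with midrank tie handling
#'
#' The area under the ROC curve computed as the Mann-Whitney statistic:
#' the probability that a randomly chosen positive outscores a randomly
#' chosen negative, with half credit for ties. With only one class present
#' the AUC is undefined and `NA` is returned (never 0 or 0.5), matching the
#' missing-cell convention of the origin-by-horizon AUC matrix.
#'
#' @param scores Numeric forecast-derived scores.
#' @param labels Binary labels (0/1); pairs with `NA` in either vector are
#'   dropped.
#' @return AUC in \[0, 1\], or `NA` if a class is absent.
#' @export
#' @examples
#' auc_score(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)) # 1
#' auc_score(c(3, 1, 2, 0), c(1, 0, 0, 1))         # 0.5
auc_score <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Downsample the majority class to balance an evaluation set
#'
#' Keeps every crowded (positive) pair and samples the noncrowded ones
#' without replacement down to the same count, removing the positive bias
#' that class imbalance would otherwise impart to AUC estimates.
#' Deterministic given `seed`. In the degenerate case of more positives
#' than negatives the positives are downsampled instead (with a warning).
#'
#' @param pairs A data frame with columns `score` and `label`.
#' @param seed Integer seed for the draw.
#' @return A balanced subset of `pairs`.
#' @export
downsample_balance <- function(pairs, seed) {
  stopifnot(all(c("score", "label") %in% names(pairs)))
  pos <- which(pairs$label == 1); neg <- which(pairs$label == 0)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes required for downsampling", call. = FALSE)
  }
  if (length(pos) > length(neg)) {
    warning("more crowded than noncrowded pairs; downsampling positives")
    pos <- withr::with_seed(seed, sample(pos, length(neg)))
  } else {
    neg <- withr::with_seed(seed, sample(neg, length(pos)))
  }
  pairs[sort(c(pos, neg)), , drop = FALSE]
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Pairs (score, label) are resampled jointly with replacement `B` times;
#' resamples that lose one of the classes are redrawn. The interval is the
#' percentile interval of the resampled AUCs. `B = 250` is the study
#' default.
#'
#' @param pairs Data frame with `score` and `label` columns.
#' @param B Bootstrap iterations (default 250).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A one-row tibble: `auc`, `ci_lo`, `ci_hi`, `n_pos`, `n_neg`, `B`.
#' @export
auc_ci <- function(pairs, B = 250, level = 0.95, seed = 1) {
  est <- auc_score(pairs$score, pairs$label)
  n <- nrow(pairs)
  n_pos <- sum(pairs$label == 1, na.rm = TRUE)
  n_neg <- sum(pairs$label == 0, na.rm = TRUE)
  if (is.na(est)) {
    return(tibble::tibble(auc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          n_pos = n_pos, n_neg = n_neg, B = B))
  }
  boots <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in 1:100) {
        i <- sample.int(n, n, replace = TRUE)
        a <- auc_score(pairs$score[i], pairs$label[i])
        if (!is.na(a)) return(a)
      }
      est # pathological set: fall back to the point estimate
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  tibble::tibble(auc = est, ci_lo = qs[1], ci_hi = qs[2],
                 n_pos = n_pos, n_neg = n_neg, B = B)
}

balanced_auc_ci <- function(pairs, seed, B, level = 0.95, draws = 1) {
  bal <- downsample_balance(pairs, seed)
  out <- auc_ci(bal, B = B, level = level, seed = seed + 1L)
  if (draws > 1) {
    extra <- vapply(seq_len(draws - 1), function(d) {
      b <- downsample_balance(pairs, seed + 1000L * d)
      auc_score(b$score, b$label)
    }, numeric(1))
    out$auc <- mean(c(out$auc, extra))
  }
  out
}

#' Performance per horizon (PPH)
#'
#' For each forecast horizon `h` in 1..24, independently: pairs are the
#' point forecast for `origin + h` (score) against the hourly crowding
#' label at `origin + h`, pooled over all origins, class-balanced by
#' downsampling, and summarised as AUC with a bootstrap confidence
#' interval. Horizons whose pairs lack a crowding event are reported as
#' missing.
#'
#' @param rows Aligned evaluation rows from [align_predictions()].
#' @param target Target series the labels refer to (default `"occupancy"`).
#' @param seed Integer seed controlling downsampling and the bootstrap.
#' @param B Bootstrap iterations.
#' @param level Confidence level.
#' @param draws Downsampling draws averaged for the AUC point estimate
#'   (default 1, a single draw).
#' @return A tibble with one row per model and horizon: `model_id`,
#'   `horizon`, `auc`, `ci_lo`, `ci_hi`, `n_pos`, `n_neg`, `B`.
#' @export
pph <- function(rows, target = "occupancy", seed = 1, B = 250,
                level = 0.95, draws = 1) {
  rows <- dplyr::filter(rows, .data$target == !!target,
                        !is.na(.data$hour_label))
  groups <- rows |>
    dplyr::group_by(.data$model_id, .data$horizon) |>
    dplyr::group_split()
  purrr::map_dfr(groups, function(g) {
    head_cols <- tibble::tibble(model_id = g$model_id[1],
                                horizon = g$horizon[1])
    pairs <- tibble::tibble(score = g$yhat, label = g$hour_label)
    res <- eval_stratum(pairs, seed + 131L * g$horizon[1], B, level, draws)
    dplyr::bind_cols(head_cols, res)
  }) |>
    dplyr::arrange(.data$model_id, .data$horizon)
}

eval_stratum <- function(pairs, seed, B, level, draws) {
  if (sum(pairs$label == 1) == 0 || sum(pairs$label == 0) == 0) {
    tibble::tibble(auc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                   n_pos = sum(pairs$label == 1),
                   n_neg = sum(pairs$label == 0), B = B)
  } else {
    balanced_auc_ci(pairs, seed %% .Machine$integer.max, B, level, draws)
  }
}

#' Window predictions per origin
#'
#' Collapses the 24 hourly rows of each (model, origin) into one binary
#' window prediction problem: the score is the maximum of the 24 point
#' forecasts (the predicted daily-peak analogue) and the label is 1 if any
#' observed hour in the window is crowded, 0 if all 24 hours were observed
#' uncrowded, and missing otherwise.
#'
#' @inheritParams pph
#' @return A tibble with one row per model and origin: `model_id`,
#'   `origin`, `origin_hour`, `score`, `label`.
#' @export
window_predictions <- function(rows, target = "occupancy") {
  rows |>
    dplyr::filter(.data$target == !!target) |>
    dplyr::group_by(.data$model_id, .data$origin, .data$origin_hour) |>
    dplyr::summarise(
      score = max(.data$yhat),
      label = dplyr::case_when(
        any(.data$hour_label == 1, na.rm = TRUE) ~ 1L,
        dplyr::n() == 24L && !anyNA(.data$hour_label) ~ 0L,
        TRUE ~ NA_integer_
      ),
      .groups = "drop"
    )
}

#' Performance per origin (PPO)
#'
#' For each forecast-origin hour of day 0..23: does the model know whether
#' the coming 24 hours will be crowded at all? Pairs are the window
#' predictions from [window_predictions()] restricted to that origin hour,
#' class-balanced and summarised as AUC with a bootstrap interval. Origin
#' hours lacking either class are reported missing.
#'
#' @inheritParams pph
#' @return A tibble with one row per model and origin hour: `model_id`,
#'   `origin_hour`, `auc`, `ci_lo`, `ci_hi`, `n_pos`, `n_neg`, `B`.
#' @export
ppo <- function(rows, target = "occupancy", seed = 1, B = 250,
                level = 0.95, draws = 1) {
  wp <- window_predictions(rows, target) |>
    dplyr::filter(!is.na(.data$label))
  groups <- wp |>
    dplyr::group_by(.data$model_id, .data$origin_hour) |>
    dplyr::group_split()
  purrr::map_dfr(groups, function(g) {
    head_cols <- tibble::tibble(model_id = g$model_id[1],
                                origin_hour = g$origin_hour[1])
    pairs <- tibble::tibble(score = g$score, label = g$label)
    res <- eval_stratum(pairs, seed + 977L * (g$origin_hour[1] + 1L), B,
                        level, draws)
    dplyr::bind_cols(head_cols, res)
  }) |>
    dplyr::arrange(.data$model_id, .data$origin_hour)
}

#' Origin-by-horizon AUC matrix
#'
#' AUC of the hourly crowding prediction restricted to each (origin hour of
#' day, horizon) combination. Cells whose restricted sample contains no
#' crowding event (or no noncrowded hour) are undefined and returned as
#' `NA`.
#'
#' @inheritParams pph
#' @return A tibble with columns `model_id`, `origin_hour`, `horizon`,
#'   `auc`, `n_pos`, `n_neg`.
#' @export
auc_matrix <- function(rows, target = "occupancy") {
  rows |>
    dplyr::filter(.data$target == !!target, !is.na(.data$hour_label)) |>
    dplyr::group_by(.data$model_id, .data$origin_hour, .data$horizon) |>
    dplyr::summarise(
      auc = auc_score(.data$yhat, .data$hour_label),
      n_pos = sum(.data$hour_label == 1),
      n_neg = sum(.data$hour_label == 0),
      .groups = "drop"
    )
}

#' Threshold-based binary classification metrics
#'
#' Confusion-matrix summaries for a fixed decision threshold on the
#' continuous scores (`score >= threshold` predicts crowded): sensitivity
#' (recall), specificity, precision and F1, the unweighted harmonic mean of
#' precision and sensitivity. Ratios with zero denominators are `NA`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold; the natural unadjusted choice for
#'   occupancy forecasts is the crowding threshold itself.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @export
binary_metrics <- function(scores, labels, threshold) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1)
}

#' Aggregated continuous accuracy
#'
#' MAE, MSE and RMSE of the point forecasts per model and target, averaged
#' over all horizons and origins.
#'
#' @param rows Aligned evaluation rows from [align_predictions()].
#' @return A tibble with columns `model_id`, `target`, `n`, `mae`, `mse`,
#'   `rmse`.
#' @export
continuous_metrics <- function(rows) {
  rows |>
    dplyr::group_by(.data$model_id, .data$target) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae = mean(abs(.data$yhat - .data$y_actual)),
      mse = mean((.data$yhat - .data$y_actual)^2),
      rmse = sqrt(mean((.data$yhat - .data$y_actual)^2)),
      .groups = "drop"
    )
}
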