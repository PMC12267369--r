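# Hard-mask evaluation metrics with per-episode aggregation.

check_masks <- function(p, y) {
  if (length(p) != length(y)) stop("masks have different shapes")
  if (!all(p %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("metrics require binary masks")
}

#' Dice coefficient between binary masks
#'
#' `2 |p * y| / (|p| + |y|)`; two empty masks score 1.0 (perfect agreement).
#'
#' @param p,y binary arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(p, y) {
  check_masks(p, y)
  denom <- sum(p) + sum(y)
  if (denom == 0) return(1)
  2 * sum(p * y) / denom
}

#' Intersection over union (Jaccard index) between binary masks
#'
#' `|p * y| / (|p| + |y| - |p * y|)`; two empty masks score 1.0. On binary
#' inputs `IoU = Dice / (2 - Dice)` exactly.
#'
#' @inheritParams dice_coefficient
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(p, y) {
  check_masks(p, y)
  inter <- sum(p * y)
  union <- sum(p) + sum(y) - inter
  if (union == 0) return(1)
  inter / union
}

#' Specificity (true-negative rate) of a predicted mask
#'
#' `TN / (TN + FP)`; when the ground truth has no negatives the convention
#' is 1.0.
#'
#' @inheritParams dice_coefficient
#' @return scalar in `[0, 1]`.
#' @export
specificity <- function(p, y) {
  check_masks(p, y)
  neg <- sum(y == 0)
  if (neg == 0) return(1)
  sum(p == 0 & y == 0) / neg
}

#' Aggregate per-episode metrics into a report
#'
#' Computes the arithmetic mean and standard deviation of Dice, IoU, and
#' specificity over episodes (population SD by default, i.e. divide by n).
#'
#' @param records data frame or list of per-episode records with `dice`,
#'   `iou`, and `specificity` entries.
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1).
#' @return an object of class `metric_report`: list with `mean`, `sd`,
#'   `n_episodes`, and `per_episode`.
#' @export
aggregate_metrics <- function(records, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  if (!is.data.frame(records) || nrow(records) < 1)
    stop("at least one episode record is required")
  cols <- c("dice", "iou", "specificity")
  if (!all(cols %in% names(records))) stop("missing metric columns")
  n <- nrow(records)
  mu <- vapply(records[cols], mean, numeric(1))
  dev <- vapply(cols, function(cl) {
    s2 <- sum((records[[cl]] - mu[[cl]])^2)
    sqrt(s2 / if (sd_type == "population") n else max(1, n - 1))
  }, numeric(1))
  structure(list(mean = mu, sd = dev, n_episodes = n,
                 sd_type = sd_type, per_episode = records),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report over %d episodes (%s SD)\n", x$n_episodes,
              x$sd_type))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %6.2f%% ± %.2f%%\n", m, 100 * x$mean[[m]],
                100 * x$sd[[m]]))
  invisible(x)
}

#' Write a metric report to JSON (and optionally a per-episode CSV)
#'
#' @param report a `metric_report`.
#' @param json_path output JSON path.
#' @param csv_path optional per-episode CSV path.
#' @return invisibly, the JSON path.
#' @export
write_metric_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  jsonlite::write_json(list(mean = as.list(report$mean),
                            sd = as.list(report$sd),
                            n_episodes = report$n_episodes,
                            sd_type = report$sd_type),
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(report$per_episode, csv_path, row.names = FALSE)
  invisible(json_path)
}
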