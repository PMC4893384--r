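# Tracker evaluation: center location error, precision curves with AUC,
# and box-plot statistics, including the two accounting schemes for missed
# detections used in long-term benchmarks (treat a miss as infinite error
# over the whole sequence, or restrict to frames where all compared
# trackers report a detection).

#' Center location error
#'
#' Euclidean distance between estimated and true center, in pixels (or any
#' consistent unit). Vectorized.
#'
#' @param estimate,truth Two-column matrices (or length-2 vectors) of
#'   (u, v) positions.
#' @return Numeric vector of distances.
#' @export
location_error <- function(estimate, truth) {
  e <- matrix(estimate, ncol = 2)
  g <- matrix(truth, ncol = 2)
  sqrt((e[, 1] - g[, 1])^2 + (e[, 2] - g[, 2])^2)
}

#' Precision curve and AUC
#'
#' For each threshold, the fraction of frames whose location error is
#' within it. Two missed-detection accounting modes: `whole_sequence`
#' assigns an infinite error to missed detections (they count against
#' precision at every threshold); `common_frames` restricts the computation
#' to a supplied mask of frames, conventionally the frames where all
#' compared trackers detect. The AUC is the mean precision over the
#' threshold grid.
#'
#' @param errors Per-frame location errors; `NA` marks a missed detection.
#' @param thresholds Monotone threshold grid in pixels.
#' @param mode `"whole_sequence"` or `"common_frames"`.
#' @param common_mask Logical per-frame mask for `common_frames` mode.
#' @return An object of class `ght_precision_curve`: tibble with columns
#'   `threshold`, `precision`, and attributes `auc` and `mode`. An empty
#'   common mask yields `NA` precision and AUC (undefined curve), not an
#'   error.
#' @export
precision_curve <- function(errors, thresholds = 0:50,
                            mode = c("whole_sequence", "common_frames"),
                            common_mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(errors) >= 1L, !is.unsorted(thresholds))
  if (mode == "common_frames") {
    if (is.null(common_mask)) stop("common_frames mode needs a common_mask")
    errors <- errors[common_mask]
    if (length(errors) == 0L || anyNA(errors)) {
      # undefined curve: masked frames must all carry a detection
      curve <- tibble::tibble(threshold = as.numeric(thresholds),
                              precision = NA_real_)
      return(structure(curve, auc = NA_real_, mode = mode,
                       class = c("ght_precision_curve", class(curve))))
    }
  } else {
    errors[is.na(errors)] <- Inf
  }
  prec <- vapply(thresholds, function(th) mean(errors <= th), numeric(1))
  curve <- tibble::tibble(threshold = as.numeric(thresholds),
                          precision = prec)
  structure(curve, auc = mean(prec), mode = mode,
            class = c("ght_precision_curve", class(curve)))
}

#' Area under a precision curve
#'
#' @param curve A `ght_precision_curve`.
#' @return The AUC scalar in `[0, 1]`.
#' @export
auc <- function(curve) attr(curve, "auc")

#' Plot a precision curve
#'
#' @param object A `ght_precision_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ght_precision_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = threshold, y = precision)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "location error threshold (px)",
                  y = "precision",
                  title = sprintf("Precision curve (AUC = %.3f)",
                                  attr(object, "auc")))
}

#' Box-plot statistics of per-frame errors
#'
#' Mean and standard deviation, quartiles, whisker extents (the most
#' extreme values not beyond 1.5 IQR from the box edges), and the outliers
#' beyond the whiskers.
#'
#' @param errors Numeric per-frame errors (`NA` dropped).
#' @return A list of class `ght_error_summary`: `n`, `mean`, `sd`, `q25`,
#'   `median`, `q75`, `whisker_low`, `whisker_high`, `outliers`.
#' @export
summarize_errors <- function(errors) {
  errors <- errors[!is.na(errors)]
  stopifnot(length(errors) >= 1L)
  q <- stats::quantile(errors, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inliers <- errors[errors >= lo_fence & errors <= hi_fence]
  structure(list(
    n = length(errors),
    mean = mean(errors),
    sd = if (length(errors) > 1L) stats::sd(errors) else 0,
    q25 = q[1], median = q[2], q75 = q[3],
    whisker_low = min(inliers), whisker_high = max(inliers),
    outliers = sort(errors[errors < lo_fence | errors > hi_fence])
  ), class = "ght_error_summary")
}

#' @export
print.ght_error_summary <- function(x, ...) {
  cat(sprintf("error summary: mean %.2f +/- %.2f | q25 %.2f median %.2f q75 %.2f | whiskers [%.2f, %.2f] | %d outliers (n = %d)\n",
              x$mean, x$sd, x$q25, x$median, x$q75, x$whisker_low,
              x$whisker_high, length(x$outliers), x$n))
  invisible(x)
}

#' @export
tidy.ght_error_summary <- function(x, ...) {
  tibble::tibble(n = x$n, mean = x$mean, sd = x$sd, q25 = x$q25,
                 median = x$median, q75 = x$q75,
                 whisker_low = x$whisker_low, whisker_high = x$whisker_high,
                 n_outliers = length(x$outliers))
}

#' Evaluate a trajectory against ground truth
#'
#' Joins trajectory and ground truth on `frame`, computes per-frame
#' location errors (missed detections stay `NA`), the precision curve, and
#' the error box statistics.
#'
#' @param traj A `ght_track` or trajectory tibble with `frame`, `u`, `v`.
#' @param truth Ground-truth tibble with `frame`, `u`, `v`.
#' @param thresholds Threshold grid for the precision curve.
#' @param mode Missed-detection accounting mode (see [precision_curve()]).
#' @param common_mask Optional logical mask for `common_frames` mode.
#' @return A list of class `ght_evaluation`: `per_frame` (tibble with
#'   `frame`, `error`, `detected`), `curve`, `auc`, `summary`.
#' @export
evaluate_trajectory <- function(traj, truth, thresholds = 0:50,
                                mode = "whole_sequence",
                                common_mask = NULL) {
  r <- if (inherits(traj, "ght_track")) traj$records else traj
  j <- dplyr::inner_join(
    dplyr::select(r, frame, est_u = u, est_v = v),
    dplyr::select(truth, frame, true_u = u, true_v = v),
    by = "frame")
  err <- location_error(cbind(j$est_u, j$est_v), cbind(j$true_u, j$true_v))
  per_frame <- tibble::tibble(frame = j$frame, error = err,
                              detected = !is.na(j$est_u))
  curve <- precision_curve(err, thresholds, mode, common_mask)
  summ <- if (all(is.na(err))) NULL else summarize_errors(err)
  structure(list(per_frame = per_frame, curve = curve,
                 auc = attr(curve, "auc"), summary = summ),
            class = "ght_evaluation")
}

#' @export
print.ght_evaluation <- function(x, ...) {
  det <- sum(x$per_frame$detected)
  cat(sprintf("<ght_evaluation: %d frames, %d detections, AUC %.3f>\n",
              nrow(x$per_frame), det,
              if (is.na(x$auc)) NA else x$auc))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
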