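#' Score tracked trajectories against ground truth
#'
#' Per ROI, the success rate is the percentage of frames in which the track
#' is both accepted (valid) and within `tolerance_px` (Euclidean) of the
#' true position. Per anatomical region, ROIs are aggregated the way
#' clinical tracking studies report them: a ROI counts as "fitting and
#' tracked" when its success rate reaches `tracked_threshold`, otherwise as
#' misallocated (a false ROI that drifted off its target), and the scoring
#' percentage is `100 * tracked / desired`.
#'
#' @param traj Trajectories data frame from [track_sequence()] (or a
#'   `tracking_result`).
#' @param truth Ground-truth data frame with columns `frame_index`, `roi`,
#'   `x`, `y` (expected top-left positions, e.g. from [roi_truth()]).
#' @param tolerance_px Position-error tolerance in pixels (default 2).
#' @param tracked_threshold Success rate (percent) at or above which a ROI
#'   counts as tracked (default 50).
#'
#' @return An object of class `tracking_report`: list with `per_roi`
#'   (columns `roi`, `label`, `n_frames`, `success_rate`) and `per_region`
#'   (columns `label`, `desired`, `tracked`, `misallocated`,
#'   `scoring_percentage`).
#' @export
evaluate_tracking <- function(traj, truth, tolerance_px = 2,
                              tracked_threshold = 50) {
  if (inherits(traj, "tracking_result")) traj <- traj$trajectories
  req <- c("frame_index", "roi", "x", "y")
  if (!all(req %in% names(traj)) || !all(req %in% names(truth)))
    stop("trajectories and truth need columns frame_index, roi, x, y",
         call. = FALSE)
  m <- merge(traj, truth[, c("frame_index", "roi", "x", "y")],
             by = c("frame_index", "roi"), suffixes = c("", "_true"))
  if (nrow(m) != nrow(traj))
    stop(sprintf(
      "index mismatch: %d trajectory rows but %d matched ground-truth rows",
      nrow(traj), nrow(m)), call. = FALSE)
  m$error_px <- sqrt((m$x - m$x_true)^2 + (m$y - m$y_true)^2)
  m$success <- m$valid & m$error_px <= tolerance_px
  per_roi <- do.call(rbind, lapply(split(m, m$roi), function(d)
    data.frame(roi = d$roi[1], label = d$label[1], n_frames = nrow(d),
               success_rate = 100 * mean(d$success))))
  rownames(per_roi) <- NULL
  per_region <- do.call(rbind, lapply(split(per_roi, per_roi$label),
    function(d) {
      tracked <- sum(d$success_rate >= tracked_threshold)
      data.frame(label = d$label[1], desired = nrow(d), tracked = tracked,
                 misallocated = nrow(d) - tracked,
                 scoring_percentage = 100 * tracked / nrow(d))
    }))
  rownames(per_region) <- NULL
  structure(list(per_roi = per_roi, per_region = per_region,
                 tolerance_px = tolerance_px,
                 tracked_threshold = tracked_threshold,
                 frame_detail = m),
            class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf("<tracking_report> tolerance %g px\n", x$tolerance_px))
  cat("Per ROI:\n")
  print(x$per_roi, row.names = FALSE)
  cat("Per region:\n")
  print(x$per_region, row.names = FALSE)
  invisible(x)
}
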