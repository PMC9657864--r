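#' @include AllClasses.R
NULL

#' Angle of a key point's line to the image origin
#'
#' For a key point at image coordinates (x, y) — origin at the outer left
#' corner, y increasing towards the floor — returns the angle between the
#' line joining the point to the origin and the x-axis:
#' `A = arctan(y / x)`, in radians. When `|x|` falls below `eps` the
#' formula degenerates; the limit value `sign(y) * pi/2` is returned with
#' a warning.
#'
#' @param x,y numeric vectors of coordinates (recycled to common length).
#' @param eps guard threshold on `|x|`.
#' @return Angles in radians.
#' @examples
#' angleToOrigin(1, 1)   # pi/4
#' @export
angleToOrigin <- function(x, y, eps = 1e-9) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  a <- atan(y / x)
  small <- abs(x) < eps
  if (any(small)) {
    .warnf("angleToOrigin: |x| < %g for %d point(s); using limit sign(y)*pi/2",
           eps, sum(small))
    a[small] <- sign(y[small]) * pi / 2
  }
  a
}

#' Angular rate between consecutive frames
#'
#' First difference quotient of a time-ordered angle series:
#' `dw[k] = (A[k] - A[k-1]) / (t[k] - t[k-1])` for `k >= 2`, with
#' `dw[1] = 0` by convention (no earlier frame exists). Time steps come
#' from the real timestamps, which may jitter around the nominal frame
#' period.
#'
#' @param angles radians, one per frame.
#' @param times seconds, strictly increasing, same length as `angles`.
#' @return Radians/second, same length as `angles`.
#' @export
angularRate <- function(angles, times) {
  if (length(angles) != length(times))
    .stopf("angularRate: angles and times must have equal length")
  if (length(angles) == 0L) return(numeric())
  if (length(times) > 1L && any(diff(times) <= 0))
    .stopf("angularRate: times must be strictly increasing")
  c(0, diff(angles) / diff(times))
}

#' Nose-to-hip height ratio
#'
#' `R = N_y / LH_y`, the ratio of the nose's to the left hip's
#' y-coordinate. With image y pointing down towards the floor, `R < 1`
#' while the nose is above the hip (normal upright posture) and `R > 1`
#' once the head is at or below hip height, i.e. as the head nears the
#' floor. A hip y-coordinate of exactly zero makes the ratio undefined;
#' such frames yield `NA` with a warning and should be treated as
#' excluded.
#'
#' @param nY,lhY numeric vectors of nose / left-hip y-coordinates.
#' @return Dimensionless ratios.
#' @export
noseHipRatio <- function(nY, lhY) {
  r <- nY / lhY
  zero <- lhY == 0
  if (any(zero)) {
    .warnf("noseHipRatio: LH_y == 0 for %d frame(s); returning NA", sum(zero))
    r[zero] <- NA_real_
  }
  r
}

#' Compute per-frame kinematic features for one trial
#'
#' For each retained frame, computes the three key-point angles to the
#' image origin (nose, left shoulder, left hip), their angular rates
#' between consecutive frames, and the nose-to-hip height ratio, and
#' attaches the binary class label from the activity map. The sequence is
#' expected to be frame-filtered already (see [applyFrameFilters()]);
#' frames whose hip y-coordinate is exactly zero are dropped with a
#' warning.
#'
#' @param seq a [KeypointSequence-class].
#' @param activityMap named character vector mapping activity codes to
#'   `"fall"`/`"not_fall"` (default [defaultActivityMap()]).
#' @return data.frame with one row per frame: `t`, `subject_id`,
#'   `trial_id`, `activity_id`, `label`, `N_x`, `N_y`, `A_N`, `A_LSh`,
#'   `A_LH`, `dw_N`, `dw_LSh`, `dw_LH`, `R`.
#' @export
computeFeatures <- function(seq, activityMap = defaultActivityMap()) {
  stopifnot(is(seq, "KeypointSequence"))
  fr <- keypointFrames(seq)
  cols <- c("t", "subject_id", "trial_id", "activity_id", "label",
            "N_x", "N_y", "A_N", "A_LSh", "A_LH",
            "dw_N", "dw_LSh", "dw_LH", "R")
  if (!nrow(fr)) {
    out <- data.frame(t = numeric(), subject_id = character(),
                      trial_id = character(), activity_id = integer(),
                      label = character(), N_x = numeric(), N_y = numeric(),
                      A_N = numeric(), A_LSh = numeric(), A_LH = numeric(),
                      dw_N = numeric(), dw_LSh = numeric(), dw_LH = numeric(),
                      R = numeric(), stringsAsFactors = FALSE)
    return(out[cols])
  }
  r <- noseHipRatio(fr$N_y, fr$LH_y)
  if (anyNA(r)) {
    keep <- !is.na(r)
    fr <- fr[keep, , drop = FALSE]
    r <- r[keep]
  }
  lab <- unname(activityMap[as.character(fr$activity_id)])
  if (anyNA(lab))
    .stopf("activity code(s) not in activity map: %s",
           paste(unique(fr$activity_id[is.na(lab)]), collapse = ", "))
  aN <- angleToOrigin(fr$N_x, fr$N_y)
  aLSh <- angleToOrigin(fr$LSh_x, fr$LSh_y)
  aLH <- angleToOrigin(fr$LH_x, fr$LH_y)
  data.frame(t = fr$t, subject_id = subjectId(seq), trial_id = trialId(seq),
             activity_id = fr$activity_id, label = lab,
             N_x = fr$N_x, N_y = fr$N_y,
             A_N = aN, A_LSh = aLSh, A_LH = aLH,
             dw_N = angularRate(aN, fr$t),
             dw_LSh = angularRate(aLSh, fr$t),
             dw_LH = angularRate(aLH, fr$t),
             R = r, stringsAsFactors = FALSE)[cols]
}

#' Select the columns of a named feature set
#'
#' Projects a feature table onto the ordered columns of one of the three
#' model input sets (see [featureSetSpec()]).
#'
#' @param features data.frame from [computeFeatures()] (or several trials'
#'   worth row-bound together).
#' @param spec feature set name ("4p", "5p", "6p") or a
#'   [FeatureSetSpec-class].
#' @return Numeric matrix with `nrow(features)` rows and `m` columns in
#'   the set's fixed order.
#' @export
selectFeatures <- function(features, spec) {
  spec <- featureSetSpec(spec)
  missing <- setdiff(spec@columns, names(features))
  if (length(missing))
    .stopf("feature table lacks column(s): %s", paste(missing, collapse = ", "))
  as.matrix(features[spec@columns])
}

#' Write / read a feature table CSV
#'
#' The on-disk feature table is the superset
#' `t, subject_id, trial_id, activity_id, label, N_x, N_y, dw_N, dw_LSh,
#' dw_LH, R`; model-specific column selection happens downstream via
#' [selectFeatures()].
#'
#' @param features feature data.frame ([computeFeatures()] output).
#' @param path CSV path.
#' @return `path` invisibly (write); the feature data.frame (read).
#' @export
writeFeatures <- function(features, path) {
  cols <- c("t", "subject_id", "trial_id", "activity_id", "label",
            "N_x", "N_y", "dw_N", "dw_LSh", "dw_LH", "R")
  df <- features[intersect(cols, names(features))]
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.9g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  if (!file.exists(path)) .stopf("feature file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       trial_id = "character"))
  need <- c("t", "subject_id", "trial_id", "label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .stopf("feature file %s is missing column(s): %s", path,
           paste(missing, collapse = ", "))
  df
}
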