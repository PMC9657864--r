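#' @include AllClasses.R
NULL

# On-disk column order of the keypoint CSV dialect. `post_impact` is
# optional on read for compatibility with producers that only flag
# unreadable frames.
.KP_CSV_COLS <- c("t", "subject_id", "trial_id", "activity_id", "excluded",
                  "post_impact", .KP_COORD_COLS)
.KP_CSV_REQUIRED <- setdiff(.KP_CSV_COLS, "post_impact")

#' Read a keypoint time-series CSV
#'
#' Reads the keypoint CSV dialect (header `t, subject_id, trial_id,
#' activity_id, excluded, post_impact, N_x, N_y, N_z, LSh_x, LSh_y, LSh_z,
#' LH_x, LH_y, LH_z`; `post_impact` optional) and splits it into one
#' [KeypointSequence-class] per (subject, trial), frames sorted by
#' timestamp. Rows with an unreadable coordinate (empty/NA) are retained
#' with `excluded = TRUE`; use [applyFrameFilters()] to drop them.
#'
#' @param path path to the CSV file.
#' @param nominalFps nominal frame rate recorded on each sequence.
#' @return List of [KeypointSequence-class], in order of first appearance.
#' @seealso [writeKeypoints()], [applyFrameFilters()]
#' @export
readKeypoints <- function(path, nominalFps = 18) {
  if (!file.exists(path)) .stopf("keypoint file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       trial_id = "character"))
  missing <- setdiff(.KP_CSV_REQUIRED, names(df))
  if (length(missing))
    .stopf("keypoint file %s is missing required column(s): %s", path,
           paste(missing, collapse = ", "))
  if (!"post_impact" %in% names(df)) df$post_impact <- FALSE
  df$excluded <- as.logical(df$excluded)
  df$post_impact <- as.logical(df$post_impact)
  key <- paste(df$subject_id, df$trial_id, sep = "\r")
  out <- lapply(unique(key), function(k) {
    fr <- df[key == k, , drop = FALSE]
    if (nrow(fr) > 1L && any(diff(fr$t) <= 0))
      .stopf("non-monotone timestamps in trial '%s' of %s",
             fr$trial_id[1L], path)
    KeypointSequence(fr[setdiff(names(fr), c("subject_id", "trial_id"))],
                     subjectId = fr$subject_id[1L], trialId = fr$trial_id[1L],
                     nominalFps = nominalFps)
  })
  out
}

#' Write keypoint sequences to CSV
#'
#' Inverse of [readKeypoints()]: deterministic column order, floats with 9
#' significant digits, so read/write round-trips are stable byte-for-byte.
#'
#' @param sequences non-empty list of [KeypointSequence-class] (a single
#'   sequence is accepted).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeKeypoints <- function(sequences, path) {
  if (is(sequences, "KeypointSequence")) sequences <- list(sequences)
  if (!length(sequences)) .stopf("no sequences to write")
  tabs <- lapply(sequences, function(s) {
    fr <- keypointFrames(s)
    if (!nrow(fr)) .stopf("sequence '%s' has no frames", trialId(s))
    cbind(data.frame(t = fr$t, subject_id = subjectId(s),
                     trial_id = trialId(s), activity_id = fr$activity_id,
                     excluded = fr$excluded, post_impact = fr$post_impact,
                     stringsAsFactors = FALSE),
          fr[.KP_COORD_COLS])
  })
  df <- do.call(rbind, tabs)[.KP_CSV_COLS]
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.9g", x))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .stopf("cannot write keypoint file %s: %s", path,
                          conditionMessage(ok))
  invisible(path)
}

#' Drop unreadable and post-impact frames
#'
#' Applies the two frame-level preprocessing rules: frames whose key points
#' could not be read (`excluded = TRUE`) are dropped, and every frame at or
#' after the first post-impact frame of the trial is dropped (once the
#' subject has hit the floor the remainder of the trial carries no
#' pre-fall information). Relative order is preserved; the result may be
#' empty. Idempotent.
#'
#' @param seq a [KeypointSequence-class].
#' @return The filtered [KeypointSequence-class].
#' @export
applyFrameFilters <- function(seq) {
  stopifnot(is(seq, "KeypointSequence"))
  fr <- keypointFrames(seq)
  if (nrow(fr)) {
    cut <- which(fr$post_impact)[1L]
    if (!is.na(cut)) fr <- fr[seq_len(cut - 1L), , drop = FALSE]
    fr <- fr[!fr$excluded, , drop = FALSE]
    rownames(fr) <- NULL
  }
  initialize(seq, frames = fr)
}

#' Activity-class maps
#'
#' An activity map assigns each integer activity code to the class `"fall"`
#' or `"not_fall"`. `defaultActivityMap()` follows the UP-Fall convention:
#' codes 1–5 are the five fall activities, 6–11 the six activities of daily
#' living; code 12 is this package's synthetic near-fall (recovered)
#' scenario, a not-fall. `readActivityMap()` loads a custom map from a YAML
#' or JSON file holding a single `id: class` mapping.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` mapping file.
#' @return Named character vector mapping activity code to
#'   `"fall"`/`"not_fall"`.
#' @examples
#' defaultActivityMap()[["1"]]
#' readActivityMap(system.file("extdata", "activity_map.yaml",
#'                             package = "fallsafe"))
#' @export
defaultActivityMap <- function() {
  stats::setNames(c(rep("fall", 5L), rep("not_fall", 7L)),
                  as.character(1:12))
}

#' @rdname defaultActivityMap
#' @export
readActivityMap <- function(path) {
  if (!file.exists(path)) .stopf("activity map file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  map <- unlist(raw)
  bad <- setdiff(unique(map), c("fall", "not_fall"))
  if (length(bad))
    .stopf("activity map %s contains invalid class(es): %s", path,
           paste(bad, collapse = ", "))
  stats::setNames(as.character(map), as.character(names(map)))
}
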