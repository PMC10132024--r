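#' FDA advertising-rule compliance
#'
#' Health warnings on covered tobacco advertising must occupy at least 20%
#' of the advertisement's area and appear on its upper portion. These
#' helpers score detections against the two rules and summarise a corpus.
#'
#' @name compliance
NULL

#' Classify vertical placement of a label box
#'
#' A label is on the upper portion when the vertical center of its bounding
#' box lies strictly above half the image height; a center exactly at
#' height/2 counts as lower (fixed tie rule).
#'
#' @param bbox Half-open `(x0, y0, x1, y1)` in pixels.
#' @param image_height Image height in pixels.
#' @return `"upper"` or `"lower"`.
#' @export
placement_class <- function(bbox, image_height) {
  yc <- (bbox[2] + bbox[4]) / 2
  if (yc < image_height / 2) "upper" else "lower"
}

#' Score one detection against the two FDA rules
#'
#' The area rule is met when `area_fraction >= 0.20` (inclusive, "at least
#' 20%"); the placement rule when the label sits on the upper portion. A
#' post with no detected warning fails every rule by definition.
#'
#' @param detection A `warning_detection` (see [detect_warning()]), or a
#'   one-row detection tibble from [detect_warnings()].
#' @param area_threshold Area-rule threshold (default 0.20).
#' @return A `compliance_result`: list with `has_warning`, `area_fraction`,
#'   `meets_area_rule`, `placement`, `meets_placement_rule`,
#'   `fully_compliant`.
#' @export
evaluate_compliance <- function(detection, area_threshold = 0.20) {
  if (is.data.frame(detection)) {
    stopifnot(nrow(detection) == 1L)
    detection <- list(found = detection$found,
                      area_fraction = detection$area_fraction,
                      placement = detection$placement)
  }
  if (!isTRUE(detection$found)) {
    return(structure(
      list(has_warning = FALSE, area_fraction = NULL, meets_area_rule = FALSE,
           placement = NULL, meets_placement_rule = FALSE, fully_compliant = FALSE),
      class = "compliance_result"
    ))
  }
  af <- detection$area_fraction
  meets_area <- af >= area_threshold
  meets_place <- identical(detection$placement, "upper")
  structure(
    list(has_warning = TRUE, area_fraction = af, meets_area_rule = meets_area,
         placement = detection$placement, meets_placement_rule = meets_place,
         fully_compliant = meets_area && meets_place),
    class = "compliance_result"
  )
}

#' Evaluate compliance over a detection table
#'
#' Adds rule verdict columns to a [detect_warnings()] result.
#'
#' @param detections Tibble with columns `found`, `area_fraction`,
#'   `placement`.
#' @inheritParams evaluate_compliance
#' @return The input tibble with logical columns `meets_area_rule`,
#'   `meets_placement_rule`, `fully_compliant` appended.
#' @export
evaluate_compliance_all <- function(detections, area_threshold = 0.20) {
  detections |>
    mutate(
      meets_area_rule = .data$found & !is.na(.data$area_fraction) &
        .data$area_fraction >= area_threshold,
      meets_placement_rule = .data$found & !is.na(.data$placement) &
        .data$placement == "upper",
      fully_compliant = .data$meets_area_rule & .data$meets_placement_rule
    )
}

#' Summarise compliance over a corpus
#'
#' Counts and percentages follow the reporting convention of compliance
#' audits of advertising corpora: warning prevalence and full compliance are
#' percentages of all posts; the area-rule and placement-rule percentages
#' are among the posts with a detected warning. Percentages are rounded
#' half-up to one decimal.
#'
#' @param results List of `compliance_result` objects, or a tibble from
#'   [evaluate_compliance_all()].
#' @return One-row tibble: `n_posts`, `n_with_warning`, `pct_with_warning`,
#'   `mean_area_fraction_pct` (mean label area as % of post area, among
#'   detected), `n_meeting_area`, `pct_meeting_area`, `n_meeting_placement`,
#'   `pct_meeting_placement`, `n_fully_compliant`, `pct_fully_compliant`.
#' @export
summarize_compliance <- function(results) {
  if (is.data.frame(results)) {
    df <- results
    has <- df$found
    af <- df$area_fraction
    area_ok <- df$meets_area_rule
    place_ok <- df$meets_placement_rule
    full_ok <- df$fully_compliant
  } else {
    if (length(results) == 0L) abort("`results` must contain at least one result")
    has <- map_lgl(results, "has_warning")
    af <- map_dbl(results, function(r) r$area_fraction %||% NA_real_)
    area_ok <- map_lgl(results, "meets_area_rule")
    place_ok <- map_lgl(results, "meets_placement_rule")
    full_ok <- map_lgl(results, "fully_compliant")
  }
  n <- length(has)
  if (n == 0L) abort("`results` must contain at least one result")
  n_warn <- sum(has)
  tibble(
    n_posts = n,
    n_with_warning = n_warn,
    pct_with_warning = round_half_up(100 * n_warn / n, 1),
    mean_area_fraction_pct = if (n_warn > 0)
      round_half_up(100 * mean(af[has], na.rm = TRUE), 1) else NA_real_,
    n_meeting_area = sum(area_ok),
    pct_meeting_area = if (n_warn > 0)
      round_half_up(100 * sum(area_ok) / n_warn, 1) else NA_real_,
    n_meeting_placement = sum(place_ok),
    pct_meeting_placement = if (n_warn > 0)
      round_half_up(100 * sum(place_ok) / n_warn, 1) else NA_real_,
    n_fully_compliant = sum(full_ok),
    pct_fully_compliant = round_half_up(100 * sum(full_ok) / n, 1)
  )
}

#' Presence/absence classification accuracy
#'
#' Percentage of images on which an automated presence verdict agrees with
#' manual coding, rounded half-up to one decimal.
#'
#' @param predicted,truth Equal-length logical vectors.
#' @return Accuracy in percent.
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("`predicted` and `truth` must have equal length")
  if (length(predicted) < 1L) abort("need at least one pair")
  round_half_up(100 * mean(predicted == truth), 1)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here use the
#' conventional half-up rule (e.g. `0.25 -> 0.3` at one decimal).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
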