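#' Audit a directory of post images end to end
#'
#' Runs the full pipeline — detect, score against the FDA rules, summarise —
#' over every readable image under `path`. Unreadable files are skipped with
#' a warning and counted separately, never fatal; zero readable images is an
#' error. Rows are sorted by path, so identical inputs give byte-identical
#' reports.
#'
#' @param path Directory of images, or a character vector of image paths.
#' @param cfg A [detector_config()].
#' @param variants Ordered list of [preprocess_variant()] objects.
#' @param truth Optional truth table (data frame or CSV path) with columns
#'   `path` and `has_warning` (0/1 or logical); when supplied, the summary
#'   gains the presence/absence classification accuracy.
#' @param out_csv,out_json Optional output paths for the per-image CSV and
#'   the corpus summary JSON.
#' @return List with `results` (per-image tibble including rule verdicts),
#'   `summary` (one-row tibble from [summarize_compliance()], plus
#'   `accuracy_pct` when truth was given), and `n_skipped`.
#' @export
run_audit <- function(path, cfg = detector_config(), variants = default_variants(),
                      truth = NULL, out_csv = NULL, out_json = NULL) {
  paths <- expand_image_paths(path)
  if (length(paths) == 0L) abort(sprintf("no images found under '%s'", path[1]))
  rows <- vector("list", length(paths))
  skipped <- character(0)
  for (i in seq_along(paths)) {
    p <- paths[i]
    det <- tryCatch(detect_warning(p, cfg, variants), error = function(e) e)
    if (inherits(det, "error")) {
      if (inherits(det, "warnscan_ocr_unavailable")) stop(det)
      warn(sprintf("skipping unreadable image '%s': %s", p, conditionMessage(det)))
      skipped <- c(skipped, p)
      next
    }
    rows[[i]] <- detection_row(p, det)
  }
  results <- bind_rows(rows)
  if (nrow(results) == 0L) abort("no readable images in input")
  results <- evaluate_compliance_all(results) |> arrange(.data$path)
  summary <- summarize_compliance(results)
  summary$n_skipped <- length(skipped)
  if (!is.null(truth)) {
    truth_df <- if (is.character(truth)) read.csv(truth, stringsAsFactors = FALSE) else as.data.frame(truth)
    joined <- inner_join(results, truth_df, by = "path")
    if (nrow(joined) > 0L) {
      summary$accuracy_pct <- classification_accuracy(joined$found,
                                                      as.logical(joined$has_warning))
    }
  }
  if (!is.null(out_csv)) write.csv(results, out_csv, row.names = FALSE)
  if (!is.null(out_json)) {
    jsonlite::write_json(as.list(summary), out_json, auto_unbox = TRUE, digits = NA)
  }
  list(results = results, summary = summary, n_skipped = length(skipped))
}

#' Join detector output with post metadata
#'
#' Inner join of per-image detection results onto a posts metadata table by
#' a shared key, producing the post records the engagement model consumes,
#' with `has_warning` taken from the detector. Unmatched rows on either side
#' are counted and reported as attributes; duplicate keys are an error
#' naming the offenders.
#'
#' @param detections Tibble from [detect_warnings()] / [run_audit()].
#' @param posts Data frame (or CSV path) of post metadata with the join key
#'   plus `post_id`, `influencer_id`, `brand`, `followers`, `likes`,
#'   `comments`.
#' @param by Join key present in both tables (default `"path"`).
#' @return Tibble of post records with `has_warning` filled from the
#'   detector; attributes `n_unmatched_detections` and `n_unmatched_posts`
#'   report the orphan counts.
#' @export
join_metadata <- function(detections, posts, by = "path") {
  if (is.character(posts)) posts <- read.csv(posts, stringsAsFactors = FALSE)
  posts <- as_tibble(posts)
  detections <- as_tibble(detections)
  for (nm in c("detections", "posts")) {
    tab <- if (nm == "detections") detections else posts
    dup <- tab[[by]][duplicated(tab[[by]])]
    if (length(dup) > 0L) {
      abort(sprintf("duplicate join keys in %s: %s", nm,
                    paste(unique(dup), collapse = ", ")))
    }
  }
  joined <- inner_join(
    detections |> select(all_of(by), found = "found"),
    posts, by = by
  ) |> mutate(has_warning = .data$found) |> select(-"found")
  attr(joined, "n_unmatched_detections") <- nrow(detections) - nrow(joined)
  attr(joined, "n_unmatched_posts") <- nrow(posts) - nrow(joined)
  joined
}
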