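#!/usr/bin/env Rscript
# Thin command-line front end over the warnscan package.
#
#   Rscript scripts/warnscan.R detect  <image|dir> [--min-area N] [--max-area-frac F]
#                                      [--keyword W] [--ocr-backend NAME]
#                                      [--config variants.json] [--out report.csv]
#   Rscript scripts/warnscan.R audit   <dir> [--truth labels.csv] [--out summary.json]
#                                      [--csv per_image.csv]
#   Rscript scripts/warnscan.R fixtures --n N --prevalence P --seed S --out dir/
#   Rscript scripts/warnscan.R engage  <posts.csv> [--outcome likes|comments] [--out fit.json]

suppressPackageStartupMessages(library(warnscan))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("usage: warnscan.R <detect|audit|fixtures|engage> ...", call. = FALSE)
cmd <- args[[1L]]
rest <- args[-1L]

opt <- function(flag, default = NULL) {
  i <- match(flag, rest)
  if (is.na(i)) default else rest[[i + 1L]]
}
positional <- function() {
  drop <- integer(0)
  i <- 1L
  while (i <= length(rest)) {
    if (startsWith(rest[[i]], "--")) { drop <- c(drop, i, i + 1L); i <- i + 2L } else i <- i + 1L
  }
  if (length(drop)) rest[-drop] else rest
}

cfg_from_opts <- function() {
  detector_config(
    min_area = as.numeric(opt("--min-area", 600)),
    max_area_fraction = as.numeric(opt("--max-area-frac", 0.5)),
    keyword = opt("--keyword", "warning"),
    ocr_engine = opt("--ocr-backend", "template")
  )
}
variants_from_opts <- function() {
  cf <- opt("--config")
  if (is.null(cf)) default_variants() else read_variants(cf)
}

if (cmd == "detect") {
  res <- detect_warnings(positional()[[1L]], cfg_from_opts(), variants_from_opts())
  out <- opt("--out")
  if (is.null(out)) {
    print(res)
  } else if (grepl("\\.json$", out)) {
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    write.csv(res, out, row.names = FALSE)
  }
} else if (cmd == "audit") {
  res <- run_audit(positional()[[1L]], cfg_from_opts(), variants_from_opts(),
                   truth = opt("--truth"),
                   out_csv = opt("--csv"), out_json = opt("--out"))
  print(res$summary)
  cat(res$n_skipped, "unreadable file(s) skipped\n")
} else if (cmd == "fixtures") {
  manifest <- generate_corpus(
    n = as.integer(opt("--n", 100)),
    prevalence = as.numeric(opt("--prevalence", 0.1)),
    seed = as.integer(opt("--seed", 1)),
    dir = opt("--out", "fixtures")
  )
  cat("wrote", nrow(manifest), "images to", dirname(manifest$path[[1L]]), "\n")
} else if (cmd == "engage") {
  posts <- read.csv(positional()[[1L]], stringsAsFactors = FALSE)
  fit <- fit_nb_mixed(posts, outcome = opt("--outcome", "likes"))
  print(fit)
  out <- opt("--out")
  if (!is.null(out)) {
    jsonlite::write_json(
      list(tidy = tidy(fit), glance = glance(fit)),
      out, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
} else {
  stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
}
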