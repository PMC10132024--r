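# Bundled 5x7 dot-matrix font used by the fixture renderer and by the
# "template" OCR backend. Pinning the glyph shapes inside the package keeps
# text rendering and template recognition deterministic across systems.
# Each glyph is 7 rows of 5 cells; '#' marks an inked cell.

wl_font_rows <- list(
  "A" = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "B" = c("####.", "#...#", "####.", "#...#", "#...#", "#...#", "####."),
  "C" = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  "D" = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
  "E" = c("#####", "#....", "####.", "#....", "#....", "#....", "#####"),
  "F" = c("#####", "#....", "####.", "#....", "#....", "#....", "#...."),
  "G" = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".####"),
  "H" = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "I" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
  "J" = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
  "K" = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
  "L" = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  "M" = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
  "N" = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "Q" = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
  "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "S" = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "U" = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "V" = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  "W" = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
  "X" = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
  "Y" = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
  "Z" = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
  ":" = c(".....", ".##..", ".##..", ".....", ".##..", ".##..", "....."),
  "," = c(".....", ".....", ".....", ".....", ".##..", "..#..", ".#..."),
  "." = c(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
  "-" = c(".....", ".....", ".....", ".###.", ".....", ".....", "....."),
  "'" = c("..#..", "..#..", ".....", ".....", ".....", ".....", ".....")
)

# 7 x 5 0/1 matrix for one glyph.
wl_glyph_matrix <- function(ch) {
  rows <- wl_font_rows[[ch]]
  if (is.null(rows)) return(NULL)
  do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]] == "#")))
}

wl_font_chars <- function() names(wl_font_rows)

# Advance width (glyph cell width + 1 tracking cell) in font cells.
WL_GLYPH_W <- 5L
WL_GLYPH_H <- 7L
WL_TRACK <- 1L
WL_SPACE_W <- 3L

# Width in font cells of a text line.
wl_line_cells <- function(line) {
  chars <- strsplit(line, "")[[1]]
  w <- 0L
  for (ch in chars) {
    w <- w + if (ch == " ") WL_SPACE_W + WL_TRACK else WL_GLYPH_W + WL_TRACK
  }
  max(w - WL_TRACK, 0L)
}

# Render lines of text into a 0/1 ink matrix at integer scale `scale`.
# Characters outside the font are rendered as blanks of glyph width.
wl_render_text <- function(lines, scale = 2L) {
  scale <- as.integer(scale)
  stopifnot(scale >= 1L)
  lines <- toupper(lines)
  n_lines <- length(lines)
  line_gap <- 3L  # cells between baselines
  h_cells <- n_lines * WL_GLYPH_H + (n_lines - 1L) * line_gap
  w_cells <- max(vapply(lines, wl_line_cells, integer(1)), 1L)
  canvas <- matrix(0L, h_cells, w_cells)
  for (li in seq_len(n_lines)) {
    y0 <- (li - 1L) * (WL_GLYPH_H + line_gap)
    x <- 0L
    for (ch in strsplit(lines[li], "")[[1]]) {
      if (ch == " ") { x <- x + WL_SPACE_W + WL_TRACK; next }
      g <- wl_glyph_matrix(ch)
      if (!is.null(g)) {
        canvas[y0 + seq_len(WL_GLYPH_H), x + seq_len(WL_GLYPH_W)] <-
          pmax(canvas[y0 + seq_len(WL_GLYPH_H), x + seq_len(WL_GLYPH_W)], g)
      }
      x <- x + WL_GLYPH_W + WL_TRACK
    }
  }
  # integer upscale by pixel replication
  if (scale > 1L) canvas <- canvas[rep(seq_len(nrow(canvas)), each = scale),
                                   rep(seq_len(ncol(canvas)), each = scale)]
  canvas
}

# Greedy word wrap: split `text` into lines of at most `max_cells` font cells.
wl_wrap_text <- function(text, max_cells) {
  words <- strsplit(text, " +")[[1]]
  words <- words[nzchar(words)]
  lines <- character(0)
  cur <- ""
  for (w in words) {
    cand <- if (nzchar(cur)) paste(cur, w) else w
    if (wl_line_cells(toupper(cand)) <= max_cells || !nzchar(cur)) {
      cur <- cand
    } else {
      lines <- c(lines, cur)
      cur <- w
    }
  }
  c(lines, cur)
}
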