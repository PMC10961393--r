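#' Render a Navon figure raster
#'
#' Builds the compound stimulus used in the block design: a background matrix
#' of 3 x 5 placeholder elements shaped like '8's (about 2.0 DVA wide and
#' 5.3 DVA high overall), from which line segments are erased to unveil a
#' letter (E or U) at the Global or Local level. A Global letter is drawn by
#' whole '8' placeholders arranged in the letter's shape; a Local letter is a
#' single central placeholder with segments erased to form the letter.
#'
#' @param letter "E" or "U".
#' @param level "Global" or "Local".
#' @param dva_per_pixel raster resolution in degrees of visual angle per pixel.
#'   Must be fine enough that one placeholder spans at least 8 x 12 pixels.
#' @return An object of class \code{"navon_stimulus"} with fields
#'   \code{raster} (binary matrix, rows = y from top, cols = x), \code{letter},
#'   \code{level}, \code{dva_per_pixel} and \code{origin} (visual-field
#'   coordinate of the grid center, degrees).
#' @seealso [navon_background()]
#' @examples
#' s <- render_navon("E", "Global", 0.05)
#' dim(s$raster)
#' @export
render_navon <- function(letter, level, dva_per_pixel) {
  letter <- match.arg(letter, c("E", "U"))
  level <- match.arg(level, c("Global", "Local"))
  geom <- navon_geometry(dva_per_pixel)
  cells <- if (level == "Global") global_cell_pattern(letter) else local_cell_pattern()
  glyph_by_cell <- if (level == "Global") {
    function(r, c) "8"
  } else {
    function(r, c) letter
  }
  raster <- matrix(0L, nrow = geom$ny, ncol = geom$nx)
  for (r in seq_len(5)) {
    for (c in seq_len(3)) {
      if (!cells[r, c]) next
      rows <- ((r - 1L) * geom$ph + 1L):(r * geom$ph)
      cols <- ((c - 1L) * geom$pw + 1L):(c * geom$pw)
      raster[rows, cols] <- glyph_raster(glyph_by_cell(r, c), geom$ph, geom$pw)
    }
  }
  structure(
    list(raster = raster, letter = letter, level = level,
         dva_per_pixel = dva_per_pixel, origin = c(x = 0, y = 0)),
    class = "navon_stimulus")
}

#' Background placeholder matrix of '8's
#'
#' The full 3 x 5 grid of '8' placeholders from which every Navon letter is
#' unveiled by erasing segments; every rendered stimulus raster is a pixelwise
#' subset of this one.
#'
#' @inheritParams render_navon
#' @return A \code{"navon_stimulus"} object with \code{letter = "8"},
#'   \code{level = "Background"}.
#' @export
navon_background <- function(dva_per_pixel) {
  geom <- navon_geometry(dva_per_pixel)
  raster <- matrix(0L, nrow = geom$ny, ncol = geom$nx)
  for (r in seq_len(5)) for (c in seq_len(3)) {
    rows <- ((r - 1L) * geom$ph + 1L):(r * geom$ph)
    cols <- ((c - 1L) * geom$pw + 1L):(c * geom$pw)
    raster[rows, cols] <- glyph_raster("8", geom$ph, geom$pw)
  }
  structure(
    list(raster = raster, letter = "8", level = "Background",
         dva_per_pixel = dva_per_pixel, origin = c(x = 0, y = 0)),
    class = "navon_stimulus")
}

#' @export
print.navon_stimulus <- function(x, ...) {
  cat(sprintf("Navon stimulus: %s / %s, %d x %d px at %g DVA/px (%.2f x %.2f DVA)\n",
              x$letter, x$level, nrow(x$raster), ncol(x$raster), x$dva_per_pixel,
              ncol(x$raster) * x$dva_per_pixel, nrow(x$raster) * x$dva_per_pixel))
  invisible(x)
}

# Overall figure is <= 2.0 DVA wide x 5.3 DVA high: 3 x 5 placeholders of
# ~0.67 x ~1.05 DVA each.
navon_geometry <- function(dva_per_pixel) {
  stopifnot(is.numeric(dva_per_pixel), length(dva_per_pixel) == 1L,
            dva_per_pixel > 0)
  pw <- floor(2.0 / dva_per_pixel / 3)
  ph <- floor(5.3 / dva_per_pixel / 5)
  if (pw < 8L || ph < 12L)
    stop("resolution too coarse: one placeholder must span at least 8 x 12 pixels")
  list(pw = pw, ph = ph, nx = 3L * pw, ny = 5L * ph)
}

# Seven-segment glyphs; every letter's segment set is a subset of '8' = all 7.
glyph_segments <- function(glyph) {
  switch(glyph,
         "8" = c("A", "B", "C", "D", "E", "F", "G"),
         "E" = c("A", "D", "E", "F", "G"),
         "U" = c("B", "C", "D", "E", "F"),
         stop("unknown glyph: ", glyph))
}

glyph_raster <- function(glyph, ph, pw) {
  segs <- glyph_segments(glyph)
  m <- matrix(0L, nrow = ph, ncol = pw)
  th <- max(1L, round(min(ph, pw) * 0.2))
  mid0 <- floor((ph - th) / 2) + 1L
  top <- 1L:ceiling(ph / 2)
  bot <- (floor(ph / 2) + 1L):ph
  put <- function(rows, cols) m[rows, cols] <<- 1L
  if ("A" %in% segs) put(1L:th, seq_len(pw))
  if ("D" %in% segs) put((ph - th + 1L):ph, seq_len(pw))
  if ("G" %in% segs) put(mid0:(mid0 + th - 1L), seq_len(pw))
  if ("F" %in% segs) put(top, 1L:th)
  if ("E" %in% segs) put(bot, 1L:th)
  if ("B" %in% segs) put(top, (pw - th + 1L):pw)
  if ("C" %in% segs) put(bot, (pw - th + 1L):pw)
  m
}

# Cell activation patterns on the 3 x 5 placeholder grid (rows top to bottom).
global_cell_pattern <- function(letter) {
  m <- matrix(FALSE, nrow = 5, ncol = 3)
  if (letter == "E") {
    m[c(1, 3, 5), ] <- TRUE
    m[c(2, 4), 1] <- TRUE
  } else {
    m[, c(1, 3)] <- TRUE
    m[5, ] <- TRUE
  }
  m
}

local_cell_pattern <- function() {
  m <- matrix(FALSE, nrow = 5, ncol = 3)
  m[3, 2] <- TRUE
  m
}
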