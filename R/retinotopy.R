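#' Conditions of the block design
#'
#' The four stimulus conditions: letter E or U presented at the Global or
#' Local level.
#' @export
V1_CONDITIONS <- c("EG", "EL", "UG", "UL")

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Build a synthetic retinotopic map of V1 vertices
#'
#' Places vertices quasi-uniformly (jittered sunflower layout, uniform density
#' in area) on the central visual-field disc of radius \code{max_ecc} degrees,
#' split evenly across hemispheres with the contralateral convention: left
#' hemisphere (L) vertices map the right visual hemifield (vf_x > 0) and vice
#' versa. Visual-field quadrant labels (UL, UR, LL, LR) are derived from the
#' coordinate signs.
#'
#' @param n_vertices total vertex count (even, >= 8); half per hemisphere.
#' @param max_ecc maximum eccentricity in DVA (default 4).
#' @param seed integer seed for the jitter; same seed gives identical maps.
#' @return A data.frame of class \code{"retinotopic_map"} with columns
#'   \code{vertex_id}, \code{hemisphere}, \code{vf_x}, \code{vf_y},
#'   \code{eccentricity}, \code{quadrant}.
#' @examples
#' m <- build_retinotopic_map(40, 4, seed = 1)
#' table(m$hemisphere); max(m$eccentricity)
#' @export
build_retinotopic_map <- function(n_vertices, max_ecc = 4.0, seed = NULL) {
  stopifnot(is.numeric(n_vertices), length(n_vertices) == 1L)
  if (n_vertices < 8 || n_vertices %% 2 != 0)
    stop("n_vertices must be an even integer >= 8")
  m <- n_vertices / 2
  with_seed(seed, {
    half <- function(xsign) {
      i <- seq_len(m)
      r0 <- max_ecc * sqrt((i - 0.5) / m)
      th0 <- pi * (((i * 0.6180339887498949) %% 1) - 0.5) # in (-pi/2, pi/2)
      r <- r0 + stats::runif(m, -1, 1) * 0.4 * max_ecc / sqrt(m)
      th <- th0 + stats::runif(m, -1, 1) * 0.4 * pi / sqrt(m)
      eps <- 1e-3
      r <- pmin(pmax(r, 0.05 * max_ecc), max_ecc)
      th <- pmin(pmax(th, -pi / 2 + eps), pi / 2 - eps)
      th[abs(th) < eps] <- eps # keep off the horizontal meridian
      cbind(x = xsign * r * cos(th), y = r * sin(th))
    }
    left_hemi <- half(+1)   # L hemisphere maps right hemifield
    right_hemi <- half(-1)
    xy <- rbind(left_hemi, right_hemi)
    map <- data.frame(
      vertex_id = seq_len(n_vertices),
      hemisphere = rep(c("L", "R"), each = m),
      vf_x = xy[, "x"], vf_y = xy[, "y"],
      stringsAsFactors = FALSE)
    map$eccentricity <- sqrt(map$vf_x^2 + map$vf_y^2)
    map$quadrant <- vf_quadrant(map$vf_x, map$vf_y)
    class(map) <- c("retinotopic_map", "data.frame")
    attr(map, "max_ecc") <- max_ecc
    map
  })
}

#' Visual-field quadrant from signed coordinates
#'
#' @param x,y visual-field coordinates in DVA (fixation at the origin,
#'   y positive upward).
#' @return Character vector in \{"UL","UR","LL","LR"\}.
#' @export
vf_quadrant <- function(x, y) {
  ifelse(y > 0, ifelse(x < 0, "UL", "UR"), ifelse(x < 0, "LL", "LR"))
}

#' @export
print.retinotopic_map <- function(x, ...) {
  cat(sprintf("Retinotopic map: %d vertices, eccentricity <= %g DVA\n",
              nrow(x), attr(x, "max_ecc")))
  print(table(hemisphere = x$hemisphere, quadrant = x$quadrant))
  invisible(x)
}
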