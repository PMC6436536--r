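#' Generate the geometry of one dot-array stimulus
#'
#' Produces a specification (not an image) of red and black dots of varying
#' sizes intermixed inside the unit disc.  The two colour sets are matched
#' for the size of their biggest and smallest dots; dots never overlap and
#' lie fully inside the disc.  Radii are drawn log-uniformly between
#' `r_min` and `r_max`, then the extreme radii are forced equal across the
#' two sets.
#'
#' @param level One row of [level_table()] or a level index (0..11).
#' @param red_is_larger Logical: does red get the larger count?
#' @param rng_seed Optional integer seed.
#' @param r_min,r_max Radius bounds as fractions of the disc radius.
#' @param max_restarts Full placement restarts before giving up.
#' @return List of class `dot_stimulus_spec`: `level_index`, `ratio_label`,
#'   `red_is_larger`, `dot_radii_red`, `dot_radii_black`, and `dot_centers`
#'   (a matrix of x/y, red dots first).
#' @export
make_stimulus_spec <- function(level, red_is_larger = TRUE, rng_seed = NULL,
                               r_min = 0.02, r_max = 0.08, max_restarts = 50L) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (!is.data.frame(level)) {
    lt <- level_table()
    level <- lt[lt$index == level, ]
    if (nrow(level) != 1L) stop("unknown level index", call. = FALSE)
  }
  n_red <- if (red_is_larger) level$n_large else level$n_small
  n_black <- if (red_is_larger) level$n_small else level$n_large

  draw_radii <- function(n) exp(stats::runif(n, log(r_min), log(r_max)))
  r_red <- draw_radii(n_red)
  r_black <- draw_radii(n_black)
  # force the biggest and smallest dot sizes to match across colour sets
  big <- max(r_red, r_black); small <- min(r_red, r_black)
  r_red[which.max(r_red)] <- big;   r_black[which.max(r_black)] <- big
  r_red[which.min(r_red)] <- small; r_black[which.min(r_black)] <- small

  radii <- c(r_red, r_black)
  ord <- order(radii, decreasing = TRUE)  # place big dots first
  for (restart in seq_len(max_restarts)) {
    centers <- matrix(NA_real_, length(radii), 2)
    failed <- FALSE
    for (j in ord) {
      placed <- FALSE
      for (try in 1:200) {
        # uniform point in the disc of radius 1 - r_j
        u <- sqrt(stats::runif(1)) * (1 - radii[j])
        a <- stats::runif(1, 0, 2 * pi)
        pt <- c(u * cos(a), u * sin(a))
        others <- which(!is.na(centers[, 1]))
        if (!length(others) ||
            all(sqrt((centers[others, 1] - pt[1])^2 +
                     (centers[others, 2] - pt[2])^2) >
                radii[others] + radii[j])) {
          centers[j, ] <- pt; placed <- TRUE; break
        }
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) {
      colnames(centers) <- c("x", "y")
      return(structure(list(
        level_index = level$index, ratio_label = level$ratio_label,
        red_is_larger = red_is_larger,
        dot_radii_red = r_red, dot_radii_black = r_black,
        dot_centers = centers
      ), class = "dot_stimulus_spec"))
    }
  }
  stop("could not place dots without overlap; retry with a different seed",
       call. = FALSE)
}

#' Serialize a stimulus spec to JSON
#'
#' @param spec A `dot_stimulus_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_spec <- function(spec, path) {
  stopifnot(inherits(spec, "dot_stimulus_spec"))
  out <- spec
  out$dot_centers <- as.data.frame(out$dot_centers)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
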