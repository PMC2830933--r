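#' Gestation-length category map
#'
#' Recursive effects between gestation length (GL) and the liabilities to
#' calving difficulty (CD) and stillbirth (SB) are allowed to change across
#' categories of the GL phenotype. The default cutpoints split gestations at
#' 267, 273 and 279 days, giving four categories (<= 267 d, 268-273 d,
#' 274-279 d, >= 280 d); a boundary day belongs to the lower category.
#'
#' @param boundaries strictly increasing integer day cutpoints.
#' @return An object of class \code{"gl_category_map"} with elements
#'   \code{boundaries} and \code{n_categories}.
#' @examples
#' map <- gl_category_map()
#' gl_category(c(265, 267, 268, 291), map)
#' @export
gl_category_map <- function(boundaries = c(267L, 273L, 279L)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1L || anyNA(boundaries))
    stop("'boundaries' must be a non-empty numeric vector")
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("'boundaries' must be strictly increasing")
  structure(list(boundaries = boundaries,
                 n_categories = length(boundaries) + 1L),
            class = "gl_category_map")
}

#' @export
print.gl_category_map <- function(x, ...) {
  cat("GL category map:", x$n_categories, "categories, cutpoints at",
      paste(x$boundaries, collapse = ", "), "days (<= goes down)\n")
  invisible(x)
}

#' Categorize gestation length
#'
#' Assigns each gestation length (in days) to its category under a
#' \code{\link{gl_category_map}}: category 1 is everything at or below the
#' first cutpoint, the last category everything above the last cutpoint.
#'
#' @param gl_days integer vector of gestation lengths in days.
#' @param map a \code{\link{gl_category_map}}.
#' @return integer vector of category indices in \code{1..n_categories}.
#' @export
gl_category <- function(gl_days, map = gl_category_map()) {
  stopifnot(inherits(map, "gl_category_map"))
  if (anyNA(gl_days)) stop("'gl_days' contains missing values")
  findInterval(gl_days, map$boundaries, left.open = TRUE) + 1L
}
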