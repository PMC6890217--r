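#' Construct a 3-D point with an image-space tag
#'
#' A point is a plain numeric vector of length 3 (x, y, z) in millimetres,
#' optionally tagged with the image space it lives in: `"P"` (planned,
#' preoperative), `"R"` (real, postoperative), or `"N"` (the common system
#' both images are mapped into). Every geometry function in the package
#' accepts bare `numeric(3)` vectors as well; the tag, when present on both
#' arguments of an operation, is checked for consistency.
#'
#' @param x,y,z Finite coordinates in millimetres.
#' @param space Optional image-space identifier (a single string).
#' @return A numeric vector of length 3, classed `"point3"`, with a
#'   `"space"` attribute when `space` is given.
#' @examples
#' point3(1, 2, 3, space = "P")
#' @export
point3 <- function(x, y, z, space = NULL) {
  v <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(v))) {
    stop("point3: all coordinates must be finite, got (",
         paste(v, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(space)) {
    stopifnot(is.character(space), length(space) == 1L)
    attr(v, "space") <- space
  }
  class(v) <- c("point3", class(v))
  v
}

#' @export
print.point3 <- function(x, ...) {
  sp <- attr(x, "space")
  cat(sprintf("<point3%s> (%.6g, %.6g, %.6g) mm\n",
              if (is.null(sp)) "" else paste0(" in ", sp),
              x[[1L]], x[[2L]], x[[3L]]))
  invisible(x)
}

# Coerce to a bare numeric(3), validating finiteness.
as_xyz <- function(p, what = "point") {
  v <- unname(as.numeric(p))
  if (length(v) != 3L || !all(is.finite(v))) {
    stop(what, " must be 3 finite coordinates", call. = FALSE)
  }
  v
}

space_of <- function(p) attr(p, "space", exact = TRUE)

# Stop if two tagged points carry conflicting space tags (untagged passes).
check_same_space <- function(a, b, what) {
  sa <- space_of(a); sb <- space_of(b)
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stop(what, ": points are in different image spaces ('", sa, "' vs '",
         sb, "')", call. = FALSE)
  }
  invisible(NULL)
}

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Build the relative coordinate frame from three noncollinear points
#'
#' Constructs the orthonormal, right-handed frame used for tri-point
#' registration. The origin is `A`; the x-axis points along AB; the y-axis
#' is the unit rejection of AC from the x-axis, so it lies in the ABC plane
#' on C's side; the z-axis is the unit normal of the plane, `unit(AB x AC)`.
#' Because both images use the same construction rule, chirality cancels
#' when two congruent triples are mapped into the common system.
#'
#' @param A,B,C Points (`numeric(3)` or [point3()]), all in one image space.
#' @param collinearity_tol Minimum admissible `sin(angle CAB)`. Triples
#'   flatter than this are rejected as degenerate; the default 1e-6 is far
#'   below any anatomically plausible landmark configuration and only guards
#'   against numerical blow-up.
#' @return An object of class `"trip_frame"`: a list with `origin`
#'   (numeric 3) and `axes` (3 x 3 matrix whose rows are the x, y, z unit
#'   vectors), plus the space tag of the input points if any.
#' @seealso [to_frame_coords()], [from_frame_coords()]
#' @examples
#' f <- build_frame(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0))
#' f$axes  # identity: axis-aligned configuration
#' @export
build_frame <- function(A, B, C, collinearity_tol = 1e-6) {
  check_same_space(A, B, "build_frame")
  check_same_space(A, C, "build_frame")
  sp <- space_of(A) %||% space_of(B) %||% space_of(C)
  a <- as_xyz(A, "A"); b <- as_xyz(B, "B"); cc <- as_xyz(C, "C")

  ab <- b - a
  ac <- cc - a
  nab <- vnorm(ab)
  nac <- vnorm(ac)
  if (nab == 0 || nac == 0) {
    stop("build_frame: degenerate geometry, coincident points ",
         "(|AB| = ", nab, ", |AC| = ", nac, ")", call. = FALSE)
  }
  n <- cross3(ab, ac)
  sin_cab <- vnorm(n) / (nab * nac)
  if (sin_cab < collinearity_tol) {
    stop("build_frame: degenerate geometry, points are collinear ",
         "(sin CAB = ", format(sin_cab), " < tol ", collinearity_tol, ")",
         call. = FALSE)
  }

  x_ax <- ab / nab
  rej <- ac - sum(ac * x_ax) * x_ax   # vector rejection of AC from x-axis
  y_ax <- rej / vnorm(rej)
  z_ax <- n / vnorm(n)

  structure(
    list(origin = a,
         axes = rbind(x = x_ax, y = y_ax, z = z_ax),
         space = sp),
    class = "trip_frame")
}

#' @export
print.trip_frame <- function(x, ...) {
  cat("<trip_frame>",
      if (!is.null(x$space)) paste0(" in space ", x$space), "\n", sep = "")
  cat("  origin:", sprintf("(%.6g, %.6g, %.6g) mm", x$origin[1L],
                           x$origin[2L], x$origin[3L]), "\n")
  for (ax in rownames(x$axes)) {
    cat(sprintf("  %s-axis: (% .9f, % .9f, % .9f)\n", ax,
                x$axes[ax, 1L], x$axes[ax, 2L], x$axes[ax, 3L]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Express a point in a relative frame
#'
#' Solves `AG = X' x + Y' y + Z' z` for the coordinates of `G` in the frame;
#' with orthonormal axes this is the projection of `G - origin` onto each
#' axis. The mapping is an isometry: pairwise distances are preserved.
#'
#' @param G A point in the frame's image space.
#' @param frame A [build_frame()] result.
#' @param space Space tag for the result, default `"N"` (the common system).
#' @return A [point3()] in frame coordinates.
#' @examples
#' f <- build_frame(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0))
#' to_frame_coords(c(1, 3, 0), f)  # lies in the XAY plane: z' == 0
#' @export
to_frame_coords <- function(G, frame, space = "N") {
  stopifnot(inherits(frame, "trip_frame"))
  if (!is.null(frame$space)) {
    sg <- space_of(G)
    if (!is.null(sg) && !identical(sg, frame$space)) {
      stop("to_frame_coords: point is in space '", sg,
           "' but the frame was built in '", frame$space, "'", call. = FALSE)
    }
  }
  g <- as_xyz(G, "G")
  v <- as.numeric(frame$axes %*% (g - frame$origin))
  point3(v[1L], v[2L], v[3L], space = space)
}

#' Map frame coordinates back to the original image space
#'
#' Inverse of [to_frame_coords()]: `origin + X' x + Y' y + Z' z`.
#'
#' @param Gp A point in frame coordinates.
#' @param frame A [build_frame()] result.
#' @return A [point3()] in the frame's image space.
#' @export
from_frame_coords <- function(Gp, frame) {
  stopifnot(inherits(frame, "trip_frame"))
  g <- as_xyz(Gp, "G'")
  v <- frame$origin + as.numeric(t(frame$axes) %*% g)
  point3(v[1L], v[2L], v[3L], space = frame$space)
}
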