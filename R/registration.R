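#' Construct an implant pose from its two endpoints
#'
#' An implant is represented by its coronal (platform, crown-facing) and
#' apical (tip, root-facing) endpoints; the implant axis runs coronal to
#' apical.
#'
#' @param coronal,apical Endpoints (`numeric(3)` or [point3()]), mm.
#' @param space Optional image-space tag shared by both endpoints.
#' @return An object of class `"implant_pose"`: list with `coronal`,
#'   `apical`, `length` (mm) and `space`.
#' @export
implant_pose <- function(coronal, apical, space = NULL) {
  check_same_space(coronal, apical, "implant_pose")
  sp <- space %||% space_of(coronal) %||% space_of(apical)
  co <- as_xyz(coronal, "coronal"); ap <- as_xyz(apical, "apical")
  len <- vnorm(ap - co)
  if (len == 0) {
    stop("implant_pose: degenerate implant, coronal and apical endpoints ",
         "coincide", call. = FALSE)
  }
  structure(list(coronal = co, apical = ap, length = len, space = sp),
            class = "implant_pose")
}

#' @export
print.implant_pose <- function(x, ...) {
  cat("<implant_pose>",
      if (!is.null(x$space)) paste0(" in space ", x$space), "\n", sep = "")
  cat(sprintf("  coronal: (%.4f, %.4f, %.4f) mm\n",
              x$coronal[1L], x$coronal[2L], x$coronal[3L]))
  cat(sprintf("  apical : (%.4f, %.4f, %.4f) mm\n",
              x$apical[1L], x$apical[2L], x$apical[3L]))
  cat(sprintf("  length : %.4f mm\n", x$length))
  invisible(x)
}

# Unit axis vector, coronal -> apical.
implant_axis <- function(pose) (pose$apical - pose$coronal) / pose$length

map_pose <- function(pose, frame, space = "N") {
  implant_pose(as_xyz(to_frame_coords(pose$coronal, frame)),
               as_xyz(to_frame_coords(pose$apical, frame)),
               space = space)
}

#' Register a case: map planned and real implants into the common system
#'
#' Selects the basic landmark triple by [rank_landmarks()], builds one frame
#' from the triple's planned-image coordinates and one from its real-image
#' coordinates, and expresses each implant in its own frame. Because the
#' three basic points are anatomically congruent, the two frames realize the
#' same anatomical coordinate system N, making the poses directly
#' comparable. Each mapping is an isometry, so implant lengths are
#' preserved exactly.
#'
#' With at least 4 landmark pairs the registration system error (residual of
#' the held-out 4th-ranked pair, see [system_error()]) is reported;
#' with exactly 3 pairs registration proceeds but the system error is
#' unavailable (`NA`, not zero — no accuracy was measured).
#'
#' @param pairs A [landmark_pairs()] table (>= 3 rows).
#' @param planned An [implant_pose()] in the planned image space P.
#' @param real An [implant_pose()] in the real image space R.
#' @param use_mean_residual Report the mean residual over all non-basic
#'   pairs instead of the 4th pair's (see [system_error()]).
#' @param collinearity_tol Passed to [build_frame()].
#' @return An object of class `"trip_registration"`: list with `ranking`,
#'   `planned_in_N`, `real_in_N`, `system_error_mm` (`NA` when < 4 pairs)
#'   and `residuals`.
#' @export
register_case <- function(pairs, planned, real, use_mean_residual = FALSE,
                          collinearity_tol = 1e-6) {
  pairs <- landmark_pairs(pairs)
  stopifnot(inherits(planned, "implant_pose"), inherits(real, "implant_pose"))
  ranking <- rank_landmarks(pairs, collinearity_tol = collinearity_tol)

  P <- p_coords(pairs); R <- r_coords(pairs)
  bt <- ranking$basic_triple
  fP <- build_frame(P[bt[1L], ], P[bt[2L], ], P[bt[3L], ],
                    collinearity_tol = collinearity_tol)
  fR <- build_frame(R[bt[1L], ], R[bt[2L], ], R[bt[3L], ],
                    collinearity_tol = collinearity_tol)

  planned_in_N <- map_pose(planned, fP)
  real_in_N <- map_pose(real, fR)

  if (nrow(pairs) >= 4L) {
    se <- system_error(pairs, ranking, use_mean = use_mean_residual,
                       collinearity_tol = collinearity_tol)
    system_error_mm <- se$system_error_mm
    residuals <- se$residuals
  } else {
    system_error_mm <- NA_real_
    residuals <- stats::setNames(numeric(0L), character(0L))
  }

  structure(
    list(ranking = ranking,
         planned_in_N = planned_in_N,
         real_in_N = real_in_N,
         system_error_mm = system_error_mm,
         residuals = residuals),
    class = "trip_registration")
}

#' @export
print.trip_registration <- function(x, ...) {
  cat("<trip_registration>\n")
  cat("  basic triple   :", paste(x$ranking$basic_triple, collapse = ", "), "\n")
  if (is.na(x$system_error_mm)) {
    cat("  system error   : unavailable (only 3 landmark pairs)\n")
  } else {
    cat(sprintf("  system error   : %.4f mm (held-out pair '%s')\n",
                x$system_error_mm, x$ranking$fourth_pair))
  }
  cat(sprintf("  implant length : planned %.3f mm, real %.3f mm\n",
              x$planned_in_N$length, x$real_in_N$length))
  invisible(x)
}
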