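#' Correct the digitized coronal point for the cover-screw height
#'
#' On postoperative CBCT the implant platform is often hidden under a cover
#' screw or healing abutment, so the digitized "coronal" point sits HS mm
#' above the true platform. The correction displaces the coronal endpoint
#' by HS along the implant's own coronal-to-apical axis (apically); the
#' apical endpoint is untouched, so the corrected length is the original
#' length minus HS.
#'
#' @param real An [implant_pose()] (normally the real implant in N).
#' @param HS Cover-screw height in mm, `>= 0` and smaller than the implant
#'   length.
#' @return The corrected [implant_pose()].
#' @export
correct_cover_screw <- function(real, HS) {
  stopifnot(inherits(real, "implant_pose"))
  if (!is.numeric(HS) || length(HS) != 1L || !is.finite(HS) || HS < 0) {
    stop("correct_cover_screw: HS must be a single finite number >= 0",
         call. = FALSE)
  }
  if (HS == 0) return(real)
  if (HS >= real$length) {
    stop("correct_cover_screw: HS (", HS, " mm) must be smaller than the ",
         "implant length (", real$length, " mm)", call. = FALSE)
  }
  implant_pose(real$coronal + HS * implant_axis(real), real$apical,
               space = real$space)
}

#' Angular deviation between planned and placed implant axes
#'
#' The angle between the two coronal-to-apical axis vectors, in degrees.
#' The core indicator of guide-template precision: it is unaffected by pure
#' translations of the implant.
#'
#' @param planned,real [implant_pose()] objects in the same space.
#' @return Angle in degrees, in \[0, 180).
#' @export
angular_deviation <- function(planned, real) {
  stopifnot(inherits(planned, "implant_pose"), inherits(real, "implant_pose"))
  d <- sum(implant_axis(planned) * implant_axis(real))
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Endpoint deviations: global, vertical (depth) and lateral components
#'
#' For each endpoint the displacement of the placed implant relative to the
#' plan is decomposed against the *planned* axis direction a (unit,
#' coronal->apical): the global deviation is the 3-D distance, the vertical
#' (depth) deviation its signed component along a — positive means deeper
#' than planned, negative shallower — and the lateral deviation the
#' magnitude of the perpendicular component. By construction
#' `CGD^2 = CVD^2 + CLD^2` and `AGD^2 = AVD^2 + ALD^2`.
#'
#' @param planned,real [implant_pose()] objects in the same space (N).
#' @return Named list: `CGD`, `CVD`, `CLD` (coronal), `AGD`, `AVD`, `ALD`
#'   (apical), all mm; `CVD`/`AVD` signed, the rest nonnegative.
#' @export
endpoint_deviations <- function(planned, real) {
  stopifnot(inherits(planned, "implant_pose"), inherits(real, "implant_pose"))
  a <- implant_axis(planned)
  dev1 <- function(delta) {
    v <- sum(delta * a)
    lat <- vnorm(delta - v * a)
    list(g = vnorm(delta), v = v, l = lat)
  }
  co <- dev1(real$coronal - planned$coronal)
  ap <- dev1(real$apical - planned$apical)
  list(CGD = co$g, CVD = co$v, CLD = co$l,
       AGD = ap$g, AVD = ap$v, ALD = ap$l)
}

#' Rectified deviations: lateral accuracy net of manual depth adjustment
#'
#' CBCT underestimates newly formed bone, so the planned depth is often
#' wrong and the surgeon adjusts insertion depth by eye. That adjustment is
#' a translation of the implant along its own insertion axis and says
#' nothing about the guide template. Rectification undoes it: the placed
#' implant is slid along its *own* axis until its coronal point lies in the
#' plane through the planned coronal point orthogonal to the *planned* axis
#' (equal depth). CRD and ARD are then the residual distances of the
#' rectified coronal and apical points from their planned counterparts.
#'
#' Depth-only deviations give `CRD = ARD = 0`; with parallel axes
#' (`AD = 0`) `CRD` equals the coronal lateral deviation exactly.
#'
#' @param planned,real [implant_pose()] objects in the same space (N).
#' @param tol Rectification is impossible when the placed axis is (near)
#'   perpendicular to the planned axis — the required translation is
#'   unbounded. If `|cos|` of the inter-axis angle falls below `tol`, both
#'   values are returned as `NA` with attribute `rectifiable = FALSE`.
#' @return Named list: `CRD`, `ARD` (mm, nonnegative) and `rectifiable`.
#' @export
rectified_deviations <- function(planned, real, tol = 1e-9) {
  stopifnot(inherits(planned, "implant_pose"), inherits(real, "implant_pose"))
  a <- implant_axis(planned)
  u <- implant_axis(real)
  ua <- sum(u * a)
  if (abs(ua) < tol) {
    return(list(CRD = NA_real_, ARD = NA_real_, rectifiable = FALSE))
  }
  # slide distance s along the placed axis cancelling the depth difference
  s <- -sum((real$coronal - planned$coronal) * a) / ua
  list(CRD = vnorm(real$coronal + s * u - planned$coronal),
       ARD = vnorm(real$apical + s * u - planned$apical),
       rectifiable = TRUE)
}

#' Compute the full accuracy report for one registered case
#'
#' Applies the optional cover-screw correction to the placed implant, then
#' computes all ten indicators. Sign convention (printed in every report):
#' CVD and AVD are positive along the planned coronal-to-apical direction,
#' i.e. positive = deeper than planned, negative = shallower.
#'
#' @param planned,real [implant_pose()] objects in the common system N.
#' @param hs Cover-screw height in mm (default 0 = no correction needed).
#' @param hs_correction Apply [correct_cover_screw()] to the real pose
#'   before computing indicators (default `TRUE`; ignored when `hs = 0`).
#' @param system_error_mm Registration system error to carry into the
#'   report (optional; `NA` = unavailable).
#' @return An object of class `"accuracy_report"`: named list with `HS`,
#'   `AD` (degrees), `CGD`, `CVD`, `CLD`, `CRD`, `AGD`, `AVD`, `ALD`, `ARD`
#'   (mm), `rectifiable`, and `system_error_mm`.
#' @export
accuracy_indicators <- function(planned, real, hs = 0, hs_correction = TRUE,
                                system_error_mm = NA_real_) {
  stopifnot(inherits(planned, "implant_pose"), inherits(real, "implant_pose"))
  real_c <- if (hs_correction && hs > 0) correct_cover_screw(real, hs) else real
  dev <- endpoint_deviations(planned, real_c)
  rect <- rectified_deviations(planned, real_c)
  structure(
    c(list(HS = as.numeric(hs),
           AD = angular_deviation(planned, real_c)),
      dev[c("CGD", "CVD", "CLD")],
      list(CRD = rect$CRD),
      dev[c("AGD", "AVD", "ALD")],
      list(ARD = rect$ARD,
           rectifiable = rect$rectifiable,
           system_error_mm = system_error_mm)),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>  (CVD/AVD sign: + = deeper than planned)\n")
  cat(sprintf("  HS  %7.3f mm   AD  %7.3f deg\n", x$HS, x$AD))
  cat(sprintf("  CGD %7.3f mm   CVD %+7.3f mm   CLD %7.3f mm   CRD %7.3f mm\n",
              x$CGD, x$CVD, x$CLD, x$CRD))
  cat(sprintf("  AGD %7.3f mm   AVD %+7.3f mm   ALD %7.3f mm   ARD %7.3f mm\n",
              x$AGD, x$AVD, x$ALD, x$ARD))
  if (!x$rectifiable) {
    cat("  (rectification impossible: placed axis perpendicular to planned axis)\n")
  }
  if (is.na(x$system_error_mm)) {
    cat("  system error: unavailable\n")
  } else {
    cat(sprintf("  system error: %.4f mm\n", x$system_error_mm))
  }
  invisible(x)
}

#' Full analysis pipeline for one case
#'
#' Ranks the landmarks, registers both implants into the common system N,
#' optionally corrects for the cover-screw height, and computes all
#' indicators.
#'
#' @inheritParams register_case
#' @inheritParams accuracy_indicators
#' @return List with `registration` (a [register_case()] result) and
#'   `report` (an [accuracy_indicators()] result).
#' @export
analyze_case <- function(pairs, planned, real, hs = 0, hs_correction = TRUE,
                         use_mean_residual = FALSE, collinearity_tol = 1e-6) {
  reg <- register_case(pairs, planned, real,
                       use_mean_residual = use_mean_residual,
                       collinearity_tol = collinearity_tol)
  report <- accuracy_indicators(reg$planned_in_N, reg$real_in_N,
                                hs = hs, hs_correction = hs_correction,
                                system_error_mm = reg$system_error_mm)
  list(registration = reg, report = report)
}
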