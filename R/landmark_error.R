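#' Assemble and validate a table of landmark pairs
#'
#' A landmark pair is one anatomical point (pulp angle, crown pit, root
#' tip, ...) digitized in both image spaces: `p*` columns hold its planned
#' (preoperative) coordinates, `r*` columns its real (postoperative)
#' coordinates, all in millimetres.
#'
#' @param df A data.frame with columns `label, px, py, pz, rx, ry, rz`.
#' @return The validated data.frame, classed `"landmark_pairs"`.
#' @export
landmark_pairs <- function(df) {
  need <- c("label", "px", "py", "pz", "rx", "ry", "rz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("landmark_pairs: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$label <- as.character(df$label)
  dup <- df$label[duplicated(df$label)]
  if (length(dup) > 0L) {
    stop("landmark_pairs: duplicate label(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  coords <- as.matrix(df[, need[-1L]])
  if (!is.numeric(coords) || !all(is.finite(coords))) {
    bad <- df$label[!apply(is.finite(coords), 1L, all)]
    stop("landmark_pairs: non-finite coordinate(s) at label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("landmark_pairs", "data.frame")
  df
}

p_coords <- function(pairs) {
  m <- as.matrix(as.data.frame(pairs)[, c("px", "py", "pz")])
  dimnames(m) <- list(pairs$label, c("x", "y", "z")); m
}

r_coords <- function(pairs) {
  m <- as.matrix(as.data.frame(pairs)[, c("rx", "ry", "rz")])
  dimnames(m) <- list(pairs$label, c("x", "y", "z")); m
}

# Pairwise edge-discrepancy matrix over all landmark pairs: entry [i, j] is
# | |PiPj| - |RiRj| | / (0.5 (|PiPj| + |RiRj|)), the symmetric relative
# length difference of edge ij between the two images. Diagonal is 0.
discrepancy_matrix <- function(pairs) {
  dp <- as.matrix(stats::dist(p_coords(pairs)))
  dr <- as.matrix(stats::dist(r_coords(pairs)))
  denom <- 0.5 * (dp + dr)
  off <- row(denom) != col(denom)
  if (any(denom[off] == 0)) {
    bad <- which(denom == 0 & off, arr.ind = TRUE)[1L, ]
    stop("degenerate edge: landmarks '", pairs$label[bad[1L]], "' and '",
         pairs$label[bad[2L]],
         "' coincide in both images (zero-length edge)", call. = FALSE)
  }
  D <- abs(dp - dr) / denom
  diag(D) <- 0
  dimnames(D) <- list(pairs$label, pairs$label)
  D
}

#' Relative length discrepancy of one landmark edge between the two images
#'
#' For the segment joining landmarks i and j, returns the absolute length
#' difference between the planned and real images divided by the mean
#' length: `||P| - |R|| / (0.5 (|P| + |R|))`. Dimensionless, in \[0, 2);
#' zero iff the edge has identical length in both images, and symmetric in
#' the roles of the two images.
#'
#' @param pairs A [landmark_pairs()] table.
#' @param i,j Labels (or integer indices) of the two landmarks.
#' @return A single nonnegative number.
#' @export
edge_discrepancy <- function(pairs, i, j) {
  pairs <- landmark_pairs(pairs)
  ii <- resolve_label(pairs, i); jj <- resolve_label(pairs, j)
  if (ii == jj) stop("edge_discrepancy: i and j must differ", call. = FALSE)
  P <- p_coords(pairs); R <- r_coords(pairs)
  dp <- vnorm(P[ii, ] - P[jj, ])
  dr <- vnorm(R[ii, ] - R[jj, ])
  if (dp + dr == 0) {
    stop("degenerate edge: landmarks '", pairs$label[ii], "' and '",
         pairs$label[jj], "' coincide in both images", call. = FALSE)
  }
  abs(dp - dr) / (0.5 * (dp + dr))
}

resolve_label <- function(pairs, i) {
  if (is.numeric(i)) {
    i <- as.integer(i)
    if (i < 1L || i > nrow(pairs)) stop("index out of range: ", i, call. = FALSE)
    return(i)
  }
  k <- match(as.character(i), pairs$label)
  if (is.na(k)) stop("unknown landmark label: '", i, "'", call. = FALSE)
  k
}

# Triangle error from a precomputed discrepancy matrix.
triangle_error_from_D <- function(D, a, b, c) {
  e <- c(D[a, b], D[a, c], D[b, c])
  sum(e) + max(e) - min(e)
}

#' Triangle-congruence error of three landmark pairs
#'
#' By the side-side-side congruence rule, if the triangles formed by the
#' same three landmarks in the two images are congruent, those landmarks
#' carry no relative digitization error. The metric is the sum of the three
#' edge discrepancies plus a similarity term `t = max - min` over them, so
#' three edges that differ *proportionally* (a global scale difference) are
#' penalized less than three edges that differ unevenly. Zero iff the two
#' triangles are exactly congruent; permutation-invariant in a, b, c.
#'
#' @param pairs A [landmark_pairs()] table.
#' @param a,b,c Labels (or indices) of three distinct landmarks.
#' @return A single nonnegative number (dimensionless).
#' @export
triangle_error <- function(pairs, a, b, c) {
  pairs <- landmark_pairs(pairs)
  idx <- vapply(list(a, b, c), resolve_label, integer(1L), pairs = pairs)
  if (anyDuplicated(idx)) {
    stop("triangle_error: the three landmarks must be distinct", call. = FALSE)
  }
  D <- discrepancy_matrix(pairs[idx, , drop = FALSE])
  triangle_error_from_D(D, 1L, 2L, 3L)
}

point_error_from_D <- function(D, i, pool) {
  others <- setdiff(pool, i)
  uv <- utils::combn(others, 2L)
  s <- 0
  for (k in seq_len(ncol(uv))) {
    s <- s + triangle_error_from_D(D, i, uv[1L, k], uv[2L, k])
  }
  s
}

#' Cumulative triangle error attributed to one landmark pair
#'
#' Sums the triangle error of every triangle that landmark i forms with two
#' other landmarks of the pool. A landmark whose digitization is off in one
#' image inflates every triangle it participates in, so its error dominates.
#'
#' @param pairs A [landmark_pairs()] table (the pool; at least 3 rows).
#' @param i Label (or index) of the landmark to score.
#' @return A single nonnegative number.
#' @export
point_error <- function(pairs, i) {
  pairs <- landmark_pairs(pairs)
  if (nrow(pairs) < 3L) {
    stop("point_error: need at least 3 landmark pairs, got ", nrow(pairs),
         call. = FALSE)
  }
  D <- discrepancy_matrix(pairs)
  point_error_from_D(D, resolve_label(pairs, i), seq_len(nrow(pairs)))
}

#' Rank landmark pairs by iterative worst-point elimination
#'
#' While more than three pairs remain, the per-point error [point_error()]
#' is recomputed over the *remaining* pool and the pair with the maximal
#' error is eliminated (a corrupted pair inflates the scores of good pairs,
#' so removal must relieve the survivors). The three survivors are the
#' "basic triple" used to build the registration frames; the last
#' eliminated pair (the best of the rejected, i.e. 4th-ranked overall) is
#' held out to measure the registration system error.
#'
#' Ties on the maximal error are broken by the larger total edge
#' discrepancy to all remaining pairs, then by the later position in input
#' order, making the output deterministic for a given input order.
#'
#' @param pairs A [landmark_pairs()] table with at least 3 rows.
#' @param collinearity_tol Passed to [build_frame()] when checking that the
#'   selected triple is usable.
#' @return An object of class `"landmark_ranking"`: list with
#'   `elimination_order` (labels, worst first), `basic_triple` (3 labels in
#'   input order), `fourth_pair` (label or `NA` when only 3 pairs were
#'   given), and `point_errors` (named; each eliminated pair's error at the
#'   round of its elimination).
#' @export
rank_landmarks <- function(pairs, collinearity_tol = 1e-6) {
  pairs <- landmark_pairs(pairs)
  m <- nrow(pairs)
  if (m < 3L) {
    stop("rank_landmarks: need at least 3 landmark pairs, got ", m,
         call. = FALSE)
  }
  D <- discrepancy_matrix(pairs)

  remaining <- seq_len(m)
  elim <- integer(0L)
  errs <- numeric(0L)
  while (length(remaining) > 3L) {
    E <- vapply(remaining, function(i) point_error_from_D(D, i, remaining),
                numeric(1L))
    worst <- which(E == max(E))
    if (length(worst) > 1L) {
      rowsum_D <- vapply(remaining[worst],
                         function(i) sum(D[i, remaining]), numeric(1L))
      worst <- worst[rowsum_D == max(rowsum_D)]
      worst <- worst[length(worst)]  # later input position
    }
    out <- remaining[worst]
    elim <- c(elim, out)
    errs <- c(errs, E[worst])
    remaining <- setdiff(remaining, out)
  }

  ranking <- structure(
    list(elimination_order = pairs$label[elim],
         basic_triple = pairs$label[remaining],
         fourth_pair = if (length(elim) > 0L) pairs$label[elim[length(elim)]]
                       else NA_character_,
         point_errors = stats::setNames(errs, pairs$label[elim])),
    class = "landmark_ranking")

  # selected triple must support frame construction in both images
  P <- p_coords(pairs); R <- r_coords(pairs)
  tryCatch({
    build_frame(P[remaining[1L], ], P[remaining[2L], ], P[remaining[3L], ],
                collinearity_tol = collinearity_tol)
    build_frame(R[remaining[1L], ], R[remaining[2L], ], R[remaining[3L], ],
                collinearity_tol = collinearity_tol)
  }, error = function(e) {
    stop("rank_landmarks: selected basic triple (",
         paste(pairs$label[remaining], collapse = ", "),
         ") is degenerate: ", conditionMessage(e), call. = FALSE)
  })
  ranking
}

#' @export
print.landmark_ranking <- function(x, ...) {
  cat("<landmark_ranking>\n")
  cat("  basic triple :", paste(x$basic_triple, collapse = ", "), "\n")
  cat("  fourth pair  :", x$fourth_pair, "\n")
  if (length(x$elimination_order) > 0L) {
    cat("  eliminated (worst first):\n")
    for (l in x$elimination_order) {
      cat(sprintf("    %-10s E = %.6g\n", l, x$point_errors[[l]]))
    }
  }
  invisible(x)
}

#' Registration system error from the held-out landmark pair
#'
#' Builds the registration frames from the basic triple in each image,
#' maps both digitizations of every non-basic landmark into the common
#' system N, and reports the Euclidean distance between the two images of
#' the 4th-ranked pair as the per-case system error. Residuals of all
#' remaining non-basic pairs are returned as diagnostics; their mean can be
#' reported instead via `use_mean`.
#'
#' @param pairs A [landmark_pairs()] table with at least 4 rows.
#' @param ranking A [rank_landmarks()] result computed on `pairs`.
#' @param use_mean If `TRUE`, report the mean residual over all non-basic
#'   pairs instead of the 4th pair's residual (the default single-pair
#'   reading).
#' @param collinearity_tol Passed to [build_frame()].
#' @return List with `system_error_mm` and `residuals` (named, mm, one per
#'   non-basic pair).
#' @export
system_error <- function(pairs, ranking = rank_landmarks(pairs),
                         use_mean = FALSE, collinearity_tol = 1e-6) {
  pairs <- landmark_pairs(pairs)
  stopifnot(inherits(ranking, "landmark_ranking"))
  if (nrow(pairs) < 4L) {
    stop("system_error: need at least 4 landmark pairs to hold one out, got ",
         nrow(pairs), call. = FALSE)
  }
  if (!all(c(ranking$basic_triple, ranking$elimination_order) %in% pairs$label)) {
    stop("system_error: ranking does not match the given landmark pairs",
         call. = FALSE)
  }

  P <- p_coords(pairs); R <- r_coords(pairs)
  bt <- ranking$basic_triple
  fP <- build_frame(P[bt[1L], ], P[bt[2L], ], P[bt[3L], ],
                    collinearity_tol = collinearity_tol)
  fR <- build_frame(R[bt[1L], ], R[bt[2L], ], R[bt[3L], ],
                    collinearity_tol = collinearity_tol)

  held_out <- setdiff(pairs$label, bt)
  residuals <- vapply(held_out, function(l) {
    vnorm(as_xyz(to_frame_coords(P[l, ], fP)) -
          as_xyz(to_frame_coords(R[l, ], fR)))
  }, numeric(1L))

  se <- if (use_mean) mean(residuals) else residuals[[ranking$fourth_pair]]
  list(system_error_mm = se, residuals = residuals)
}
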