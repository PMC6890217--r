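# Rotation matrix from extrinsic XYZ Euler angles in degrees.
euler_rotation <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1L]); sx <- sin(r[1L])
  cy <- cos(r[2L]); sy <- sin(r[2L])
  cz <- cos(r[3L]); sz <- sin(r[3L])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Uniform random rotation (QR of a Gaussian matrix, sign-fixed, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Configuration of a synthetic guided-implantation case
#'
#' Describes everything needed to fabricate a case with known ground truth:
#' the landmark cloud, the digitization noise, the rigid motion relating the
#' planned (P) and real (R) image spaces, and the true deviation of the
#' placed implant from the plan.
#'
#' Defaults emulate the clinical setting: 16 landmark pairs (the number
#' digitized per case in practice) scattered over a jaw-scale
#' 60 x 40 x 20 mm region with at least 5 mm separation; 0.1 mm isotropic
#' digitization noise per coordinate in *both* images (landmark-selection
#' error arises in preoperative and postoperative CBCT alike); a 10 mm
#' implant; and a true deviation of 5 degrees angular, 0.5 mm coronal
#' lateral, 1 mm depth — the order of magnitude reported for guided
#' implantation.
#'
#' @param n_landmarks Number of landmark pairs (>= 3).
#' @param region Bounding box of the landmark cloud, mm (length 3).
#' @param min_separation Minimum pairwise landmark distance, mm.
#' @param noise_sigma SD of the per-coordinate Gaussian digitization noise,
#'   mm, applied independently in both images.
#' @param true_rotation Euler angles (degrees, length 3) of the rigid
#'   motion from P to R (patient repositioning between scans).
#' @param true_translation Translation of the rigid motion, mm (length 3).
#' @param implant_length Planned implant length, mm.
#' @param true_deviation List with `angular` (degrees), `lateral` (mm,
#'   coronal lateral offset) and `depth` (mm, signed; positive = deeper).
#' @param seed Integer seed; the whole case is deterministic given it.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_landmarks = 16L,
                             region = c(60, 40, 20),
                             min_separation = 5,
                             noise_sigma = 0.1,
                             true_rotation = c(5, 10, -7),
                             true_translation = c(20, -10, 5),
                             implant_length = 10,
                             true_deviation = list(angular = 5,
                                                   lateral = 0.5,
                                                   depth = 1),
                             seed = 1L) {
  stopifnot(n_landmarks >= 3L, length(region) == 3L, all(region > 0),
            min_separation >= 0, noise_sigma >= 0, implant_length > 0,
            length(true_rotation) == 3L, length(true_translation) == 3L,
            is.list(true_deviation),
            all(c("angular", "lateral", "depth") %in% names(true_deviation)),
            true_deviation$lateral >= 0)
  structure(
    list(n_landmarks = as.integer(n_landmarks), region = region,
         min_separation = min_separation, noise_sigma = noise_sigma,
         true_rotation = true_rotation, true_translation = true_translation,
         implant_length = implant_length, true_deviation = true_deviation,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

# Rejection-sample n points in the box with minimum pairwise separation.
sample_landmark_cloud <- function(n, region, min_sep, max_tries = 2000L * n) {
  pts <- matrix(NA_real_, n, 3L)
  k <- 0L
  for (try in seq_len(max_tries)) {
    cand <- stats::runif(3L) * region
    if (k == 0L ||
        min(sqrt(colSums((t(pts[seq_len(k), , drop = FALSE]) - cand)^2))) >=
          min_sep) {
      k <- k + 1L
      pts[k, ] <- cand
      if (k == n) return(pts)
    }
  }
  stop("sample_landmark_cloud: region ", paste(region, collapse = "x"),
       " mm too small for ", n, " landmarks at ", min_sep,
       " mm minimum separation", call. = FALSE)
}

#' Generate a synthetic case with analytic ground truth
#'
#' Fabricates a complete case: landmark pairs, planned and real implant
#' poses, and the ground-truth accuracy indicators implied by the
#' configured deviation, computed in closed form independently of the
#' registration pipeline.
#'
#' Construction: true landmark positions are sampled in the planned space;
#' the real space is a rigid motion of the planned space; digitized
#' coordinates add i.i.d. Gaussian noise in *both* images. The real implant
#' is derived from the planned one *in planned space* — coronal offset
#' `lateral` mm in a random direction orthogonal to the planned axis plus
#' `depth` mm along it, axis tilted by `angular` degrees in a second random
#' orthogonal direction — and then carried into the real space by the same
#' rigid motion. Implant endpoints carry no digitization noise, so with
#' `noise_sigma = 0` the pipeline must recover the ground truth exactly.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `landmarks` ([landmark_pairs()]), `planned` and `real`
#'   ([implant_pose()] in P and R), `truth` (named list of ground-truth
#'   indicator values `AD`, `CGD`, `CVD`, `CLD`, `CRD`, `AGD`, `AVD`,
#'   `ALD`, `ARD`), and `config`.
#' @export
generate_case <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)

  Pm <- sample_landmark_cloud(cfg$n_landmarks, cfg$region, cfg$min_separation)

  # planned implant: centered in the region, drilling "down" (-z)
  a_hat <- c(0, 0, -1)
  L <- cfg$implant_length
  p_ic <- cfg$region / 2
  p_ia <- p_ic + L * a_hat

  # true deviation in planned space, in random orthogonal directions
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)   # orthonormal complement of a_hat
  phi_lat <- stats::runif(1L, 0, 2 * pi)
  phi_tilt <- stats::runif(1L, 0, 2 * pi)
  e_lat <- cos(phi_lat) * e1 + sin(phi_lat) * e2
  e_tilt <- cos(phi_tilt) * e1 + sin(phi_tilt) * e2
  alpha <- cfg$true_deviation$angular * pi / 180
  lam <- cfg$true_deviation$lateral
  dep <- cfg$true_deviation$depth
  r_ic_p <- p_ic + lam * e_lat + dep * a_hat
  u_real <- cos(alpha) * a_hat + sin(alpha) * e_tilt
  r_ia_p <- r_ic_p + L * u_real

  # analytic ground-truth indicators (vector algebra, no registration)
  d_cor <- r_ic_p - p_ic
  d_api <- r_ia_p - p_ia
  gt_cvd <- sum(d_cor * a_hat)
  gt_cld <- vnorm(d_cor - gt_cvd * a_hat)
  gt_avd <- sum(d_api * a_hat)
  gt_ald <- vnorm(d_api - gt_avd * a_hat)
  ca <- sum(u_real * a_hat)
  if (abs(ca) > 1e-9) {
    s <- -gt_cvd / ca
    gt_crd <- vnorm(d_cor + s * u_real)
    gt_ard <- vnorm(d_api + s * u_real)
  } else {
    gt_crd <- NA_real_; gt_ard <- NA_real_
  }
  truth <- list(
    AD = cfg$true_deviation$angular,
    CGD = vnorm(d_cor), CVD = gt_cvd, CLD = gt_cld, CRD = gt_crd,
    AGD = vnorm(d_api), AVD = gt_avd, ALD = gt_ald, ARD = gt_ard)

  # carry the real space away by the configured rigid motion
  R0 <- euler_rotation(cfg$true_rotation)
  tr <- cfg$true_translation
  Rm_true <- t(R0 %*% t(Pm)) + matrix(tr, cfg$n_landmarks, 3L, byrow = TRUE)
  r_ic <- as.numeric(R0 %*% r_ic_p + tr)
  r_ia <- as.numeric(R0 %*% r_ia_p + tr)

  # digitization noise in BOTH images
  sg <- cfg$noise_sigma
  Pd <- Pm + matrix(stats::rnorm(3L * cfg$n_landmarks, sd = sg),
                    cfg$n_landmarks, 3L)
  Rd <- Rm_true + matrix(stats::rnorm(3L * cfg$n_landmarks, sd = sg),
                         cfg$n_landmarks, 3L)

  landmarks <- landmark_pairs(data.frame(
    label = sprintf("L%02d", seq_len(cfg$n_landmarks)),
    px = Pd[, 1L], py = Pd[, 2L], pz = Pd[, 3L],
    rx = Rd[, 1L], ry = Rd[, 2L], rz = Rd[, 3L]))

  list(landmarks = landmarks,
       planned = implant_pose(p_ic, p_ia, space = "P"),
       real = implant_pose(r_ic, r_ia, space = "R"),
       truth = truth,
       config = cfg)
}

#' Sweep the number of provided landmark pairs
#'
#' For each replicate one case with `max(counts)` landmark pairs is
#' generated; each count then uses the first `count` pairs of that same
#' case, so values are paired across counts (the same digitizations, just
#' fewer offered), mirroring the clinical protocol of offering 4 to 16
#' landmarks in the same cases. For each subset the landmarks are ranked
#' and the held-out-pair system error computed.
#'
#' @param cfg A [synthetic_config()]; `n_landmarks` is overridden.
#' @param counts Integer vector of landmark counts to test (each >= 4).
#' @param replicates Number of replicate cases (>= 2).
#' @return List with `per_replicate` (data.frame: `count`, `replicate`,
#'   `system_error_mm`) and `summary` (data.frame: `count`, `mean_mm`,
#'   `sd_mm`).
#' @export
sweep_landmark_count <- function(cfg = synthetic_config(),
                                 counts = 4:16, replicates = 15L) {
  stopifnot(inherits(cfg, "synthetic_config"), all(counts >= 4L),
            replicates >= 2L)
  counts <- sort(unique(as.integer(counts)))
  rows <- vector("list", replicates * length(counts))
  k <- 0L
  for (j in seq_len(replicates)) {
    cfg_j <- cfg
    cfg_j$n_landmarks <- max(counts)
    cfg_j$seed <- (cfg$seed + 7919L * j) %% .Machine$integer.max
    case <- generate_case(cfg_j)
    for (ct in counts) {
      sub <- landmark_pairs(case$landmarks[seq_len(ct), , drop = FALSE])
      se <- system_error(sub, rank_landmarks(sub))
      k <- k + 1L
      rows[[k]] <- data.frame(count = ct, replicate = j,
                              system_error_mm = se$system_error_mm)
    }
  }
  per_replicate <- do.call(rbind, rows)
  agg <- stats::aggregate(system_error_mm ~ count, per_replicate,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  summary <- data.frame(count = agg$count,
                        mean_mm = agg$system_error_mm[, "mean"],
                        sd_mm = agg$system_error_mm[, "sd"])
  list(per_replicate = per_replicate, summary = summary)
}

#' Sweep the spatial spread of the basic triple
#'
#' Quantifies how landmark spread controls registration quality: for each
#' requested minimum edge length an equilateral landmark triangle of that
#' side is placed with random orientation, digitized with noise in both
#' images, and the tri-point frames are built. Reported per replicate are
#' the orientation error of the estimated P-to-R rotation against the true
#' rigid motion and the registration error at a probe point offset 20 mm
#' from the triangle centroid along its normal (a landmark far from the
#' fiducials, where angular error hurts most).
#'
#' @param cfg A [synthetic_config()] (noise, rigid motion and seed used).
#' @param min_edges Edge lengths (mm) to test.
#' @param replicates Replicates per edge length (>= 2).
#' @param probe_offset_mm Distance of the probe point from the triangle
#'   centroid, mm.
#' @return List with `per_replicate` (data.frame: `min_edge_mm`,
#'   `replicate`, `orientation_error_deg`, `probe_error_mm`) and `summary`
#'   (means per edge length).
#' @export
sweep_landmark_spread <- function(cfg = synthetic_config(),
                                  min_edges = c(5, 10, 20, 30),
                                  replicates = 200L,
                                  probe_offset_mm = 20) {
  stopifnot(inherits(cfg, "synthetic_config"), all(min_edges > 0),
            replicates >= 2L)
  set.seed(cfg$seed)
  R0 <- euler_rotation(cfg$true_rotation)
  tr <- cfg$true_translation
  center <- cfg$region / 2
  sg <- cfg$noise_sigma

  rows <- vector("list", length(min_edges) * replicates)
  k <- 0L
  for (s in min_edges) {
    # equilateral triangle of side s in the xy-plane, centroid at origin
    h <- s / sqrt(3)
    base_tri <- rbind(c(h, 0, 0),
                      c(-h / 2, s / 2, 0),
                      c(-h / 2, -s / 2, 0))
    for (j in seq_len(replicates)) {
      Q <- random_rotation()
      tri_p <- t(Q %*% t(base_tri)) +
        matrix(center, 3L, 3L, byrow = TRUE)
      normal <- as.numeric(Q %*% c(0, 0, 1))
      probe_p <- center + probe_offset_mm * normal
      tri_r <- t(R0 %*% t(tri_p)) + matrix(tr, 3L, 3L, byrow = TRUE)
      probe_r <- as.numeric(R0 %*% probe_p + tr)

      tri_p_d <- tri_p + matrix(stats::rnorm(9L, sd = sg), 3L, 3L)
      tri_r_d <- tri_r + matrix(stats::rnorm(9L, sd = sg), 3L, 3L)

      fP <- build_frame(tri_p_d[1L, ], tri_p_d[2L, ], tri_p_d[3L, ])
      fR <- build_frame(tri_r_d[1L, ], tri_r_d[2L, ], tri_r_d[3L, ])

      # estimated P->R rotation vs the true one
      M <- t(fR$axes) %*% fP$axes
      E <- M %*% t(R0)
      ang <- acos(min(1, max(-1, (sum(diag(E)) - 1) / 2))) * 180 / pi

      probe_err <- vnorm(as_xyz(to_frame_coords(probe_p, fP)) -
                         as_xyz(to_frame_coords(probe_r, fR)))
      k <- k + 1L
      rows[[k]] <- data.frame(min_edge_mm = s, replicate = j,
                              orientation_error_deg = ang,
                              probe_error_mm = probe_err)
    }
  }
  per_replicate <- do.call(rbind, rows)
  ag1 <- stats::aggregate(orientation_error_deg ~ min_edge_mm,
                          per_replicate, mean)
  ag2 <- stats::aggregate(probe_error_mm ~ min_edge_mm, per_replicate, mean)
  summary <- merge(ag1, ag2, by = "min_edge_mm")
  names(summary) <- c("min_edge_mm", "mean_orientation_error_deg",
                      "mean_probe_error_mm")
  list(per_replicate = per_replicate, summary = summary)
}
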