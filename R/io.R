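# File formats
# ------------
# Landmarks: CSV, header `label,px,py,pz,rx,ry,rz`; one row per landmark
# pair; p* = planned image, r* = real image; coordinates unitless-in-file,
# interpreted as millimetres (convention flagged by a `# units=mm` comment).
# Implants: CSV, header `role,end,x,y,z`; role in {planned, real}, end in
# {coronal, apical}; exactly one row per (role, end).
# Lines starting with `#` are comments; fields are never quoted.

split_csv_line <- function(line) trimws(strsplit(line, ",", fixed = TRUE)[[1L]])

# Read a simple CSV, keeping original line numbers; returns list(header,
# rows = list of character vectors, lines = integer vector).
read_simple_csv <- function(path, expected_header, what) {
  if (!file.exists(path)) {
    stop(what, ": file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) {
    stop(what, ": ", path, ": no content lines", call. = FALSE)
  }
  header <- split_csv_line(raw[keep[1L]])
  if (!identical(tolower(header), expected_header)) {
    stop(what, ": ", path, ": line ", keep[1L], ": expected header '",
         paste(expected_header, collapse = ","), "', got '",
         paste(header, collapse = ","), "'", call. = FALSE)
  }
  data_idx <- keep[-1L]
  list(rows = lapply(raw[data_idx], split_csv_line), lines = data_idx)
}

parse_num_fields <- function(fields, path, line, what) {
  v <- suppressWarnings(as.numeric(fields))
  if (anyNA(v) || !all(is.finite(v))) {
    stop(what, ": ", path, ": line ", line,
         ": non-numeric or non-finite coordinate in '",
         paste(fields, collapse = ","), "'", call. = FALSE)
  }
  v
}

#' Read landmark pairs from a CSV file
#'
#' Expects header `label,px,py,pz,rx,ry,rz` (planned coordinates then real
#' coordinates, mm). `#` lines are comments. Parse failures report the file
#' and line number; duplicate labels and non-finite coordinates are
#' rejected.
#'
#' @param path Path to the CSV file.
#' @return A [landmark_pairs()] table.
#' @export
read_landmarks <- function(path) {
  spec <- c("label", "px", "py", "pz", "rx", "ry", "rz")
  parsed <- read_simple_csv(path, spec, "read_landmarks")
  n <- length(parsed$rows)
  if (n == 0L) {
    stop("read_landmarks: ", path, ": no landmark rows", call. = FALSE)
  }
  labels <- character(n); coords <- matrix(NA_real_, n, 6L)
  for (k in seq_len(n)) {
    f <- parsed$rows[[k]]
    if (length(f) != 7L) {
      stop("read_landmarks: ", path, ": line ", parsed$lines[k],
           ": expected 7 fields, got ", length(f), call. = FALSE)
    }
    if (f[1L] == "") {
      stop("read_landmarks: ", path, ": line ", parsed$lines[k],
           ": empty label", call. = FALSE)
    }
    labels[k] <- f[1L]
    coords[k, ] <- parse_num_fields(f[-1L], path, parsed$lines[k],
                                    "read_landmarks")
  }
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0L) {
    stop("read_landmarks: ", path, ": duplicate label(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  landmark_pairs(data.frame(label = labels,
                            px = coords[, 1L], py = coords[, 2L],
                            pz = coords[, 3L], rx = coords[, 4L],
                            ry = coords[, 5L], rz = coords[, 6L]))
}

#' Write landmark pairs to CSV
#'
#' Inverse of [read_landmarks()]; coordinates are written with enough
#' digits for a lossless round trip (well under 1e-9 mm).
#'
#' @param pairs A [landmark_pairs()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(pairs, path) {
  pairs <- landmark_pairs(pairs)
  lines <- c("# units=mm",
             "label,px,py,pz,rx,ry,rz",
             vapply(seq_len(nrow(pairs)), function(k) {
               paste(c(pairs$label[k],
                       sprintf("%.12g", as.numeric(pairs[k, -1L]))),
                     collapse = ",")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read planned and real implant poses from a CSV file
#'
#' Expects header `role,end,x,y,z` with exactly one row for each of
#' planned/coronal, planned/apical, real/coronal, real/apical (mm).
#'
#' @param path Path to the CSV file.
#' @return List with `planned` and `real` [implant_pose()] objects.
#' @export
read_implants <- function(path) {
  parsed <- read_simple_csv(path, c("role", "end", "x", "y", "z"),
                            "read_implants")
  pts <- list()
  for (k in seq_along(parsed$rows)) {
    f <- parsed$rows[[k]]
    if (length(f) != 5L) {
      stop("read_implants: ", path, ": line ", parsed$lines[k],
           ": expected 5 fields, got ", length(f), call. = FALSE)
    }
    role <- tolower(f[1L]); end <- tolower(f[2L])
    if (!role %in% c("planned", "real") ||
        !end %in% c("coronal", "apical")) {
      stop("read_implants: ", path, ": line ", parsed$lines[k],
           ": role must be planned|real and end coronal|apical, got '",
           f[1L], ",", f[2L], "'", call. = FALSE)
    }
    key <- paste(role, end, sep = ".")
    if (!is.null(pts[[key]])) {
      stop("read_implants: ", path, ": line ", parsed$lines[k],
           ": duplicate row for ", role, " ", end, call. = FALSE)
    }
    pts[[key]] <- parse_num_fields(f[3:5], path, parsed$lines[k],
                                   "read_implants")
  }
  need <- c("planned.coronal", "planned.apical", "real.coronal", "real.apical")
  absent <- setdiff(need, names(pts))
  if (length(absent) > 0L) {
    stop("read_implants: ", path, ": missing row(s): ",
         paste(gsub(".", " ", absent, fixed = TRUE), collapse = "; "),
         call. = FALSE)
  }
  list(planned = implant_pose(pts$planned.coronal, pts$planned.apical,
                              space = "P"),
       real = implant_pose(pts$real.coronal, pts$real.apical, space = "R"))
}

#' Write planned and real implant poses to CSV
#'
#' @param planned,real [implant_pose()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_implants <- function(planned, real, path) {
  stopifnot(inherits(planned, "implant_pose"), inherits(real, "implant_pose"))
  fmt <- function(role, end, v) {
    paste(c(role, end, sprintf("%.12g", v)), collapse = ",")
  }
  writeLines(c("# units=mm",
               "role,end,x,y,z",
               fmt("planned", "coronal", planned$coronal),
               fmt("planned", "apical", planned$apical),
               fmt("real", "coronal", real$coronal),
               fmt("real", "apical", real$apical)),
             path)
  invisible(path)
}

REPORT_SCHEMA_VERSION <- "1.0"
SIGN_CONVENTION <- "CVD/AVD positive = deeper than planned (along planned coronal->apical axis)"

report_to_list <- function(result) {
  reg <- result$registration; rep <- result$report
  list(
    schema_version = REPORT_SCHEMA_VERSION,
    tool = "tripoint",
    tool_version = as.character(utils::packageVersion("tripoint")),
    sign_convention = SIGN_CONVENTION,
    registration = list(
      basic_triple = reg$ranking$basic_triple,
      elimination_order = reg$ranking$elimination_order,
      fourth_pair = reg$ranking$fourth_pair,
      point_errors = as.list(reg$ranking$point_errors),
      residuals_mm = as.list(reg$residuals),
      system_error_mm = if (is.na(reg$system_error_mm)) NULL
                        else reg$system_error_mm,
      system_error_available = !is.na(reg$system_error_mm)),
    indicators = list(
      HS_mm = rep$HS, AD_deg = rep$AD,
      CGD_mm = rep$CGD, CVD_mm = rep$CVD, CLD_mm = rep$CLD,
      CRD_mm = if (is.na(rep$CRD)) NULL else rep$CRD,
      AGD_mm = rep$AGD, AVD_mm = rep$AVD, ALD_mm = rep$ALD,
      ARD_mm = if (is.na(rep$ARD)) NULL else rep$ARD,
      rectifiable = rep$rectifiable))
}

#' Analyze one case from its input files
#'
#' Reads the landmark and implant CSVs, runs the full pipeline
#' ([analyze_case()]) and optionally writes a versioned JSON report and/or
#' a one-row CSV of the indicators.
#'
#' @param landmarks_path,implants_path Input CSV paths (see
#'   [read_landmarks()], [read_implants()]).
#' @param hs Cover-screw height, mm.
#' @param hs_correction Apply the cover-screw correction.
#' @param use_mean_residual See [register_case()].
#' @param out_json,out_csv Optional output paths.
#' @return The [analyze_case()] result, invisibly when writing output.
#' @export
run_analyze <- function(landmarks_path, implants_path, hs = 0,
                        hs_correction = TRUE, use_mean_residual = FALSE,
                        out_json = NULL, out_csv = NULL) {
  pairs <- read_landmarks(landmarks_path)
  imp <- read_implants(implants_path)
  result <- analyze_case(pairs, imp$planned, imp$real, hs = hs,
                         hs_correction = hs_correction,
                         use_mean_residual = use_mean_residual)
  if (!is.null(out_json)) {
    jsonlite::write_json(report_to_list(result), out_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(out_csv)) {
    utils::write.csv(report_row(result$report), out_csv, row.names = FALSE)
  }
  if (is.null(out_json) && is.null(out_csv)) result else invisible(result)
}

report_row <- function(report) {
  data.frame(HS = report$HS, AD = report$AD, CGD = report$CGD,
             CVD = report$CVD, CLD = report$CLD, CRD = report$CRD,
             AGD = report$AGD, AVD = report$AVD, ALD = report$ALD,
             ARD = report$ARD, system_error_mm = report$system_error_mm)
}

#' Summarize a cohort of accuracy reports
#'
#' Aggregates per-case reports into the per-indicator mean and SD layout
#' used for cohort accuracy tables.
#'
#' @param reports A list of [accuracy_indicators()] results.
#' @return data.frame with columns `indicator`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_reports <- function(reports) {
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, logical(1L), "accuracy_report")))
  tab <- do.call(rbind, lapply(reports, report_row))
  data.frame(
    indicator = names(tab),
    mean = vapply(tab, function(x) mean(x, na.rm = TRUE), numeric(1L)),
    sd = vapply(tab, function(x) stats::sd(x, na.rm = TRUE), numeric(1L)),
    min = vapply(tab, function(x) suppressWarnings(min(x, na.rm = TRUE)),
                 numeric(1L)),
    max = vapply(tab, function(x) suppressWarnings(max(x, na.rm = TRUE)),
                 numeric(1L)),
    row.names = NULL)
}
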