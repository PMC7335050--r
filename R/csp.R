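# Chemical-shift-perturbation analysis: peak matching across a titration,
# the combined-CSP formula, the mean + 1 SD threshold, and classification of
# residues into dose-responsive shifts vs. intensity loss to noise.

#' Combined amide chemical shift perturbation
#'
#' The weighted combination of proton and nitrogen shift changes,
#' `sqrt((ddH^2 + ddN^2 / 25) / 2)`, down-weighting the nitrogen dimension
#' by its ~5-fold wider ppm scale.  Symmetric in the sign of both inputs.
#'
#' @param delta_dH Amide proton shift change (ppm).
#' @param delta_dN Amide nitrogen shift change (ppm).
#' @return CSP in ppm (vectorised).
#' @export
compute_csp <- function(delta_dH, delta_dN) {
  sqrt((delta_dH^2 + delta_dN^2 / 25) / 2)
}

#' Read a Sparky-style peak list
#'
#' Expects whitespace-separated rows of `assignment  w1(15N)  w2(1H)
#' [height]`, e.g. `G82N-H 115.30 8.21 1.0e6`.  The residue number is parsed
#' from the first integer in the assignment token; rows without one are
#' collected separately as unassigned.  Header lines (starting with
#' `Assignment` or non-numeric w1) are skipped.
#'
#' @param path Path to the peak-list text file.
#' @return A data frame (`residue_id`, `dH`, `dN`, `intensity`) of assigned
#'   peaks, with unassigned rows in attribute `unassigned`.  `intensity` is
#'   `NA` when the height column is absent.
#' @export
read_peak_list <- function(path) {
  if (!file.exists(path)) stopf("peak list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stopf("empty peak list: %s", path)

  parse_row <- function(line) {
    tok <- strsplit(line, "\\s+")[[1L]]
    if (length(tok) < 3L) return(NULL)
    w1 <- suppressWarnings(as.numeric(tok[2L]))
    w2 <- suppressWarnings(as.numeric(tok[3L]))
    if (is.na(w1) || is.na(w2)) return(NULL)  # header or malformed
    height <- if (length(tok) >= 4L) suppressWarnings(as.numeric(tok[4L]))
              else NA_real_
    num <- regmatches(tok[1L], regexpr("[0-9]+", tok[1L]))
    rid <- if (length(num)) as.integer(num) else NA_integer_
    data.frame(residue_id = rid, dN = w1, dH = w2, intensity = height,
               assignment = tok[1L])
  }
  rows <- do.call(rbind, lapply(lines, parse_row))
  if (is.null(rows) || !nrow(rows)) stopf("no valid peak rows in %s", path)
  assigned <- rows[!is.na(rows$residue_id), , drop = FALSE]
  unassigned <- rows[is.na(rows$residue_id), , drop = FALSE]
  if (anyDuplicated(assigned$residue_id)) {
    stopf("duplicate residue assignment in %s", path)
  }
  if (all(is.na(assigned$intensity)) && nrow(assigned)) {
    warnf("%s has no height column; intensity-based classification disabled",
          path)
  }
  out <- assigned[, c("residue_id", "dH", "dN", "intensity")]
  rownames(out) <- NULL
  structure(out, unassigned = unassigned)
}

#' Write a Sparky-style peak list
#'
#' @param peaks Peak data frame (`residue_id`, `dH`, `dN`, `intensity`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  hdr <- sprintf("%12s %10s %10s %14s", "Assignment", "w1", "w2",
                 "Data Height")
  rows <- sprintf("%12s %10.4f %10.4f %14.6g",
                  sprintf("X%dN-H", peaks$residue_id),
                  peaks$dN, peaks$dH, peaks$intensity)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write every peak list of a titration series
#'
#' @param series A `gm_titration` from [gen_peak_titration()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths (`apo`, then one per
#'   ratio), invisibly.
#' @export
write_titration <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(apo = file.path(dir, "apo.list"))
  write_peak_list(series$apo, paths[["apo"]])
  for (pt in series$points) {
    p <- file.path(dir, sprintf("ratio_%g.list", pt$ratio))
    write_peak_list(pt$peaks, p)
    paths[sprintf("ratio_%g", pt$ratio)] <- p
  }
  invisible(paths)
}

#' Pair peaks of two lists
#'
#' When both lists carry residue assignments the pairing is by
#' `residue_id`.  Otherwise peaks are matched greedily by the scaled
#' distance `sqrt(ddH^2 + (ddN/5)^2)`, closest pairs first, each peak used
#' at most once, within the stated tolerances; among equidistant candidates
#' the lower `residue_id` (or row index) wins.
#'
#' @param reference Reference peak data frame (e.g. apo).
#' @param titrated Titrated peak data frame.
#' @param tol_H,tol_N Matching tolerances in ppm (positive).
#' @param by_assignment Pair by residue id when both lists have them
#'   (default); set `FALSE` to force positional matching.
#' @return Data frame `ref_idx`, `tit_idx`, `residue_id`, `dist` (scaled
#'   ppm); unmatched reference peaks appear with `tit_idx = NA` and are
#'   flagged `missing = TRUE`.
#' @export
match_peaks <- function(reference, titrated, tol_H = 0.05, tol_N = 0.25,
                        by_assignment = TRUE) {
  if (tol_H <= 0 || tol_N <= 0) stopf("tolerances must be positive")
  has_ids <- by_assignment &&
    !anyNA(reference$residue_id) && !anyNA(titrated$residue_id)
  if (has_ids) {
    tit_idx <- match(reference$residue_id, titrated$residue_id)
    d <- sqrt((reference$dH - titrated$dH[tit_idx])^2 +
                ((reference$dN - titrated$dN[tit_idx]) / 5)^2)
    return(data.frame(ref_idx = seq_len(nrow(reference)), tit_idx = tit_idx,
                      residue_id = reference$residue_id, dist = d,
                      missing = is.na(tit_idx)))
  }
  # positional fallback: greedy nearest-neighbour under the scaled metric
  nr <- nrow(reference); nt <- nrow(titrated)
  tol <- sqrt(tol_H^2 + (tol_N / 5)^2)
  dd <- outer(reference$dH, titrated$dH, `-`)^2 +
    (outer(reference$dN, titrated$dN, `-`) / 5)^2
  dd <- sqrt(dd)
  dH_ok <- abs(outer(reference$dH, titrated$dH, `-`)) <= tol_H
  dN_ok <- abs(outer(reference$dN, titrated$dN, `-`)) <= tol_N
  dd[!(dH_ok & dN_ok) | dd > tol] <- NA_real_
  tit_of <- rep(NA_integer_, nr)
  dist_of <- rep(NA_real_, nr)
  repeat {
    if (all(is.na(dd))) break
    # smallest distance; ties resolved by lowest (ref, tit) index pair
    best <- which(dd == min(dd, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    tit_of[best[1L]] <- best[2L]
    dist_of[best[1L]] <- dd[best[1L], best[2L]]
    dd[best[1L], ] <- NA_real_
    dd[, best[2L]] <- NA_real_
  }
  data.frame(ref_idx = seq_len(nr), tit_idx = tit_of,
             residue_id = reference$residue_id, dist = dist_of,
             missing = is.na(tit_of))
}

#' Profile a titration series: per-residue CSP, intensity ratio, threshold
#'
#' CSPs are computed between the apo point and the highest titration ratio;
#' intermediate ratios feed a dose-response monotonicity flag.  The
#' significance threshold is the mean CSP plus one sample standard
#' deviation, computed over all assigned residues with a measurable CSP.
#' Residues present in apo but unmatched at the highest ratio receive
#' `intensity_ratio = 0` and an `NA` CSP.
#'
#' @param series A `gm_titration`, or a list with elements `apo` (peak data
#'   frame) and `points` (list of `list(ratio, peaks)`).
#' @param noise_floor Intensity fraction (of apo) regarded as the spectral
#'   noise level, in (0, 1).  Required: the analysis does not guess it.
#' @param tol_H,tol_N Peak-matching tolerances (ppm).
#' @return A `gm_csp_profile` data frame (`residue_id`, `delta_dH`,
#'   `delta_dN`, `csp`, `intensity_ratio`, `monotone`, `class`) with
#'   attributes `mean_csp`, `sd_csp`, `threshold`, `noise_floor`.  Classes
#'   are filled by [classify_residues()], which is applied automatically.
#' @export
profile_titration <- function(series, noise_floor, tol_H = 0.05,
                              tol_N = 0.25) {
  if (missing(noise_floor) || !is.numeric(noise_floor) ||
      noise_floor <= 0 || noise_floor >= 1) {
    stopf("`noise_floor` must be given, in (0, 1)")
  }
  if (is.null(series$apo)) stopf("titration series lacks an apo point")
  if (!length(series$points)) stopf("titration series has no titrated points")
  ratios <- vapply(series$points, function(p) p$ratio, numeric(1))
  if (any(diff(ratios) <= 0)) stopf("titration ratios must be increasing")
  apo <- series$apo
  top <- series$points[[which.max(ratios)]]$peaks

  pair_to <- function(peaks) {
    m <- match_peaks(apo, peaks, tol_H = tol_H, tol_N = tol_N)
    csp <- rep(NA_real_, nrow(apo))
    ok <- !m$missing
    csp[ok] <- compute_csp(apo$dH[ok] - peaks$dH[m$tit_idx[ok]],
                           apo$dN[ok] - peaks$dN[m$tit_idx[ok]])
    csp
  }

  m <- match_peaks(apo, top, tol_H = tol_H, tol_N = tol_N)
  ok <- !m$missing
  delta_dH <- delta_dN <- rep(NA_real_, nrow(apo))
  delta_dH[ok] <- top$dH[m$tit_idx[ok]] - apo$dH[ok]
  delta_dN[ok] <- top$dN[m$tit_idx[ok]] - apo$dN[ok]
  csp <- compute_csp(delta_dH, delta_dN)
  have_int <- !all(is.na(apo$intensity)) && !all(is.na(top$intensity))
  int_ratio <- rep(NA_real_, nrow(apo))
  if (have_int) {
    int_ratio[] <- 0  # unmatched at the top ratio: peak lost to noise
    int_ratio[ok] <- top$intensity[m$tit_idx[ok]] / apo$intensity[ok]
  }

  # dose-response check: csp non-decreasing across ratios within tolerance
  csp_by_ratio <- vapply(series$points,
                         function(p) pair_to(p$peaks), numeric(nrow(apo)))
  csp_by_ratio <- matrix(csp_by_ratio, nrow = nrow(apo))
  tol_mono <- 2 * sqrt(2) * tol_H  # generous: two positional tolerances
  monotone <- apply(csp_by_ratio, 1L, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2L || all(diff(v) >= -tol_mono)
  })

  mean_csp <- mean(csp, na.rm = TRUE)
  sd_csp <- if (sum(!is.na(csp)) > 1L) sd(csp, na.rm = TRUE) else 0
  prof <- data.frame(residue_id = apo$residue_id, delta_dH = delta_dH,
                     delta_dN = delta_dN, csp = csp,
                     intensity_ratio = int_ratio, monotone = monotone,
                     class = "unperturbed", stringsAsFactors = FALSE)
  prof <- structure(prof, mean_csp = mean_csp, sd_csp = sd_csp,
                    threshold = mean_csp + sd_csp,
                    noise_floor = noise_floor,
                    class = c("gm_csp_profile", "data.frame"))
  classify_residues(prof)
}

#' Classify residues into perturbation classes
#'
#' Attenuation takes precedence: a residue whose intensity ratio is at or
#' below the noise floor is `attenuated` regardless of its CSP.  Otherwise
#' a residue is `shifted` when its CSP strictly exceeds the threshold
#' (mean + 1 SD), else `unperturbed`.  Residues with no measurable CSP and
#' no intensity information are `unassigned`.
#'
#' @param profile A `gm_csp_profile` from [profile_titration()].
#' @return The profile with its `class` column filled.
#' @export
classify_residues <- function(profile) {
  thr <- attr(profile, "threshold")
  floor_ <- attr(profile, "noise_floor")
  if (is.null(thr)) stopf("profile lacks a threshold; run profile_titration()")
  cls <- rep("unperturbed", nrow(profile))
  cls[!is.na(profile$csp) & profile$csp > thr] <- "shifted"
  att <- !is.na(profile$intensity_ratio) & profile$intensity_ratio <= floor_
  cls[att] <- "attenuated"
  cls[is.na(profile$csp) & (is.na(profile$intensity_ratio))] <- "unassigned"
  profile$class <- cls
  profile
}

#' Write a CSP profile as CSV plus a JSON summary
#'
#' @param profile A `gm_csp_profile`.
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_csp_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "csp_profile.csv")
  write.csv(as.data.frame(profile), csv, row.names = FALSE)
  summ <- list(mean_csp = attr(profile, "mean_csp"),
               sd_csp = attr(profile, "sd_csp"),
               threshold = attr(profile, "threshold"),
               noise_floor = attr(profile, "noise_floor"),
               counts = as.list(table(profile$class)))
  js <- file.path(dir, "csp_summary.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
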