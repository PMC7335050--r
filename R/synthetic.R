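# Synthetic-data generators.  Every input the analysis stages consume can be
# generated here with known ground truth: HSQC titration peak lists, conformer
# ensembles drawn from rigid-body-displaced cluster centers, steady-state
# binding isotherms and dye-release fluorescence traces.

#' Describe how one residue responds to peptide titration
#'
#' A perturbation spec encodes the two response classes seen in HSQC
#' titrations: `"shift"` residues show focal, dose-responsive chemical shift
#' changes that grow with the peptide:protein ratio, while `"attenuate"`
#' residues lose peak intensity toward the noise level (intermediate-exchange
#' broadening).  `"none"` leaves the residue untouched.
#'
#' @param residue_id Integer residue number the spec applies to.
#' @param kind One of `"shift"`, `"attenuate"`, `"none"`.
#' @param max_dH Maximal amide proton shift (ppm) reached at the highest
#'   titration ratio. Must be non-negative.
#' @param max_dN Maximal amide nitrogen shift (ppm) at the highest ratio.
#' @param intensity_floor Fraction of the apo peak intensity retained at the
#'   highest ratio, in `[0, 1]`.  For `kind = "attenuate"` this should lie
#'   below the noise floor used at analysis time.
#' @return A `gm_perturbation` list.
#' @export
perturbation_spec <- function(residue_id,
                              kind = c("shift", "attenuate", "none"),
                              max_dH = 0, max_dN = 0,
                              intensity_floor = 1) {
  kind <- match.arg(kind)
  if (!is_count(residue_id)) stopf("`residue_id` must be a positive integer")
  if (max_dH < 0 || max_dN < 0) stopf("`max_dH` and `max_dN` must be >= 0")
  if (intensity_floor < 0 || intensity_floor > 1) {
    stopf("`intensity_floor` must be in [0, 1]")
  }
  structure(list(residue_id = as.integer(residue_id), kind = kind,
                 max_dH = max_dH, max_dN = max_dN,
                 intensity_floor = intensity_floor),
            class = "gm_perturbation")
}

# Saturation-like dose-response fraction: r/(r+1), rescaled so the highest
# ratio reaches exactly 1.  Mimics fast-exchange titration behaviour without
# modelling exchange kinetics.
dose_fraction <- function(ratio, max_ratio) {
  (ratio / (ratio + 1)) / (max_ratio / (max_ratio + 1))
}

#' Generate a synthetic HSQC titration series
#'
#' Draws apo amide peaks in realistic ppm windows (1H in 6-10 ppm, 15N in
#' 100-135 ppm), then builds one peak list per titration point.  A residue
#' with a `"shift"` spec moves along `(max_dH, max_dN)` by the saturation
#' fraction `r/(r+1)` (normalised to reach the full displacement at the
#' highest ratio); an `"attenuate"` residue decays geometrically toward
#' `intensity_floor`.  Gaussian position noise of sd `noise_sd` (ppm) is
#' added to every coordinate of every titration point, and multiplicative
#' intensity noise of sd `intensity_noise` to every height; the apo list is
#' the clean assigned reference against which displacements are measured.
#'
#' @param n_residues Number of assigned residues (ids `1:n_residues`).
#' @param specs List of [perturbation_spec()] objects; residues not listed
#'   are unperturbed.
#' @param ratios Peptide:protein molar ratios, strictly increasing, first 0
#'   (the apo point).
#' @param noise_sd Positional noise sd in ppm, applied to both dimensions.
#' @param intensity_noise Relative (multiplicative) intensity noise sd.
#' @param noise_floor Intensity fraction regarded as the spectral noise
#'   level; `"attenuate"` specs must floor below it.
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @return A `gm_titration` list with elements `apo` (peak data frame:
#'   `residue_id`, `dH`, `dN`, `intensity`) and `points` (list of
#'   `list(ratio, peaks)`), plus a `truth` attribute with the per-residue
#'   generating class and true final CSP.
#' @export
gen_peak_titration <- function(n_residues, specs = list(),
                               ratios = c(0, 1, 2, 4),
                               noise_sd = 0.003, intensity_noise = 0.02,
                               noise_floor = 0.1, seed) {
  if (!is_count(n_residues)) stopf("`n_residues` must be a positive integer")
  if (length(ratios) < 2L || ratios[1L] != 0 || any(diff(ratios) <= 0)) {
    stopf("`ratios` must be strictly increasing and start at 0 (apo)")
  }
  ids <- vapply(specs, function(s) s$residue_id, integer(1))
  if (anyDuplicated(ids)) stopf("duplicate residue_id in `specs`")
  if (length(ids) && (any(ids < 1L) || any(ids > n_residues))) {
    stopf("spec residue_id outside 1..n_residues")
  }
  for (s in specs) {
    if (s$kind == "attenuate" && s$intensity_floor >= noise_floor) {
      stopf("attenuate spec for residue %d has intensity_floor %.3g >= noise floor %.3g",
            s$residue_id, s$intensity_floor, noise_floor)
    }
  }
  max_ratio <- ratios[length(ratios)]

  with_seed(seed, {
    true_dH <- runif(n_residues, 6, 10)
    true_dN <- runif(n_residues, 100, 135)
    true_int <- exp(rnorm(n_residues, log(1e6), 0.3))

    kind <- rep("none", n_residues)
    mdH <- mdN <- numeric(n_residues)
    floor_ <- rep(1, n_residues)
    for (s in specs) {
      kind[s$residue_id] <- s$kind
      if (s$kind == "shift") {
        mdH[s$residue_id] <- s$max_dH
        mdN[s$residue_id] <- s$max_dN
      }
      if (s$kind == "attenuate") floor_[s$residue_id] <- s$intensity_floor
    }

    make_point <- function(ratio) {
      apo_ref <- ratio == 0  # clean assigned reference, no measurement noise
      f <- if (apo_ref) 0 else dose_fraction(ratio, max_ratio)
      eH <- eN <- 0
      eI <- 1
      if (!apo_ref) {
        eH <- rnorm(n_residues, 0, noise_sd)
        eN <- rnorm(n_residues, 0, noise_sd)
        eI <- pmax(0, 1 + rnorm(n_residues, 0, intensity_noise))
      }
      data.frame(residue_id = seq_len(n_residues),
                 dH = true_dH + f * mdH + eH,
                 dN = true_dN + f * mdN + eN,
                 intensity = true_int * floor_^f * eI)
    }

    apo <- make_point(0)
    points <- lapply(ratios[-1L], function(r) list(ratio = r,
                                                   peaks = make_point(r)))
    truth <- data.frame(residue_id = seq_len(n_residues), kind = kind,
                        true_csp = compute_csp(mdH, mdN),
                        intensity_floor = floor_)
    structure(list(apo = apo, points = points, ratios = ratios),
              truth = truth, noise_sd = noise_sd, seed = seed,
              class = "gm_titration")
  })
}

# Random proper rotation (det +1) via QR decomposition.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Generate well-separated conformer cluster centers
#'
#' Builds a smooth random Calpha chain (3.8 A virtual bonds) and derives the
#' remaining centers by adding independent smooth deformations, rescaled so
#' every pair of centers sits at least `separation` Angstrom apart in
#' best-fit RMSD.
#'
#' @param n_atoms Atoms per conformer.
#' @param n_centers Number of centers.
#' @param separation Minimal pairwise best-fit RMSD between centers (A).
#' @param seed Integer seed.
#' @return List of `n_centers` coordinate matrices (`n_atoms` x 3).
#' @export
gen_conformer_centers <- function(n_atoms, n_centers = 2, separation = 5,
                                  seed) {
  if (!is_count(n_atoms) || n_atoms < 4L) stopf("`n_atoms` must be >= 4")
  if (!is_count(n_centers)) stopf("`n_centers` must be a positive integer")
  with_seed(seed, {
    # smooth self-avoiding-ish chain: random walk with persistent direction
    steps <- matrix(rnorm(3 * n_atoms), n_atoms, 3)
    for (i in 2:n_atoms) steps[i, ] <- 0.7 * steps[i - 1L, ] + 0.3 * steps[i, ]
    steps <- steps / sqrt(rowSums(steps^2)) * 3.8
    base <- apply(steps, 2, cumsum)
    centers <- vector("list", n_centers)
    centers[[1L]] <- base
    if (n_centers > 1L) {
      for (k in 2:n_centers) {
        disp <- matrix(rnorm(3 * n_atoms), n_atoms, 3)
        for (i in 2:n_atoms) disp[i, ] <- 0.6 * disp[i - 1L, ] + 0.4 * disp[i, ]
        cand <- base + disp
        # rescale deformation until the best-fit RMSD to every earlier
        # center reaches the target separation (refit absorbs some of it)
        for (iter in 1:6) {
          dmin <- min(vapply(centers[seq_len(k - 1L)], function(cc)
            kabsch_superpose(cc, cand)$rmsd, numeric(1)))
          if (dmin >= separation) break
          scale <- if (dmin < 1e-8) 2 else 1.15 * separation / dmin
          disp <- disp * scale
          cand <- base + disp
        }
        centers[[k]] <- cand
      }
    }
    centers
  })
}

#' Generate a synthetic conformer ensemble with known cluster labels
#'
#' Frames are assigned to centers by the population vector, jittered with
#' isotropic Gaussian displacement, and optionally given a random rigid
#' rotation and translation (which best-fit superposition removes).  The
#' generating labels are retained for evaluation only.
#'
#' @param centers List of coordinate matrices (`n_atoms` x 3), all the same
#'   shape.
#' @param populations Probability vector over centers (sums to 1).
#' @param n_frames Number of frames to draw.
#' @param jitter_sd Isotropic per-atom displacement sd (A).
#' @param rigid_transform Apply a random rotation and translation per frame.
#' @param seed Integer seed.
#' @return A `gm_ensemble` with `frames` (array `n_atoms` x 3 x `n_frames`),
#'   `frame_ids`, and attribute `true_labels`.
#' @export
gen_ensemble <- function(centers, populations, n_frames, jitter_sd = 0.3,
                         rigid_transform = FALSE, seed) {
  if (!length(centers)) stopf("`centers` must be a non-empty list")
  shapes <- vapply(centers, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) stopf("centers have mismatched shapes")
  if (length(populations) != length(centers)) {
    stopf("`populations` must have one entry per center")
  }
  if (any(populations < 0) || abs(sum(populations) - 1) > 1e-8) {
    stopf("`populations` must be non-negative and sum to 1")
  }
  if (!is_count(n_frames)) stopf("`n_frames` must be a positive integer")
  if (jitter_sd < 0) stopf("`jitter_sd` must be >= 0")
  n_atoms <- nrow(centers[[1L]])

  with_seed(seed, {
    labels <- sample.int(length(centers), n_frames, replace = TRUE,
                         prob = populations)
    frames <- array(NA_real_, c(n_atoms, 3L, n_frames))
    for (i in seq_len(n_frames)) {
      x <- centers[[labels[i]]]
      if (jitter_sd > 0) x <- x + matrix(rnorm(3 * n_atoms, 0, jitter_sd),
                                         n_atoms, 3)
      if (rigid_transform) {
        x <- x %*% t(random_rotation())
        x <- sweep(x, 2, runif(3, -20, 20), `+`)
      }
      frames[, , i] <- x
    }
    structure(list(frames = frames, frame_ids = seq_len(n_frames),
                   mask = NULL, interval_ps = 100),
              true_labels = labels, seed = seed, class = "gm_ensemble")
  })
}

#' Generate a steady-state binding isotherm
#'
#' Equilibrium responses follow the 1:1 Langmuir model
#' `R_eq(C) = rmax * C / (kd + C)` with additive Gaussian noise of sd
#' `noise_frac * rmax`.
#'
#' @param kd True dissociation constant (nM).
#' @param rmax True maximal response (RU).
#' @param concentrations Analyte concentrations (nM), all positive.
#' @param noise_frac Noise sd as a fraction of `rmax`.
#' @param seed Integer seed.
#' @return A `gm_isotherm` data frame with columns `conc_nM`, `response_RU`.
#' @export
gen_isotherm <- function(kd, rmax, concentrations, noise_frac = 0.02, seed) {
  if (kd <= 0 || rmax <= 0) stopf("`kd` and `rmax` must be positive")
  if (!length(concentrations)) stopf("`concentrations` must be non-empty")
  if (any(concentrations <= 0)) stopf("concentrations must be positive")
  with_seed(seed, {
    r <- rmax * concentrations / (kd + concentrations) +
      rnorm(length(concentrations), 0, noise_frac * rmax)
    structure(data.frame(conc_nM = concentrations, response_RU = r),
              true_kd = kd, true_rmax = rmax, seed = seed,
              class = c("gm_isotherm", "data.frame"))
  })
}

#' Generate liposome dye-release fluorescence traces
#'
#' The sample trace rises exponentially from the blank level to a plateau at
#' `f_blank + true_release * (f_triton - f_blank)`; the blank trace stays at
#' `f_blank` and the Triton (full-lysis) trace rises rapidly to `f_triton`.
#' Readings are spaced 10 s apart, matching a plate-reader dequenching assay.
#'
#' @param true_release True released fraction in `[0, 1]`.
#' @param f_blank Blank (buffer-treated) fluorescence plateau (AU).
#' @param f_triton Full-lysis fluorescence plateau (AU); must exceed
#'   `f_blank`.
#' @param n_points Number of time points.
#' @param noise_sd Additive Gaussian noise sd (AU) on every reading.
#' @param rise_frac Rise time constant of the sample trace, as a fraction of
#'   the total trace duration.
#' @param seed Integer seed.
#' @return A `gm_release_trace` data frame with columns `time_s`,
#'   `F_sample`, `F_blank`, `F_triton`.
#' @export
gen_release_traces <- function(true_release, f_blank = 50, f_triton = 400,
                               n_points = 180, noise_sd = 1,
                               rise_frac = 0.1, seed) {
  if (f_triton <= f_blank) stopf("`f_triton` must exceed `f_blank`")
  if (true_release < 0 || true_release > 1) {
    stopf("`true_release` must be in [0, 1]")
  }
  if (!is_count(n_points)) stopf("`n_points` must be a positive integer")
  with_seed(seed, {
    t_s <- (seq_len(n_points) - 1L) * 10
    total <- max(t_s[length(t_s)], 10)
    plateau <- f_blank + true_release * (f_triton - f_blank)
    rise <- 1 - exp(-t_s / (rise_frac * total))
    f_sample <- f_blank + (plateau - f_blank) * rise +
      rnorm(n_points, 0, noise_sd)
    f_blank_tr <- f_blank + rnorm(n_points, 0, noise_sd)
    f_triton_tr <- f_blank + (f_triton - f_blank) *
      (1 - exp(-t_s / (0.02 * total))) + rnorm(n_points, 0, noise_sd)
    structure(data.frame(time_s = t_s, F_sample = f_sample,
                         F_blank = f_blank_tr, F_triton = f_triton_tr),
              true_release = true_release, seed = seed,
              class = c("gm_release_trace", "data.frame"))
  })
}
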