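# Small fixture builders shared across test files; everything is generated
# in code, nothing is stored on disk.

# A classified CSP profile with the given residues marked perturbed.
make_profile <- function(residues, perturbed, class = "shifted") {
  prof <- data.frame(residue_id = residues,
                     delta_dH = 0, delta_dN = 0,
                     csp = ifelse(residues %in% perturbed, 0.1, 0.001),
                     intensity_ratio = 1, monotone = TRUE,
                     class = ifelse(residues %in% perturbed, class,
                                    "unperturbed"),
                     stringsAsFactors = FALSE)
  structure(prof, mean_csp = mean(prof$csp), sd_csp = sd(prof$csp),
            threshold = mean(prof$csp) + sd(prof$csp), noise_floor = 0.1,
            class = c("gm_csp_profile", "data.frame"))
}

# Deterministic standard titration used by several CSP recovery tests:
# 15 shifted residues (true CSP = 3 x positional noise sd) and 10
# attenuated residues out of 200.
standard_titration <- function(seed, n_residues = 200, sigma = 0.003) {
  eff <- 3 * sigma
  specs <- c(
    lapply(1:15, function(r)
      perturbation_spec(r, "shift", max_dH = eff, max_dN = 5 * eff)),
    lapply(16:25, function(r)
      perturbation_spec(r, "attenuate", intensity_floor = 0.05)))
  gen_peak_titration(n_residues, specs, noise_sd = sigma, seed = seed)
}

# Full synthetic fixture set for the end-to-end pipeline tests: a
# titration with a noncanonical-groove signature on BAK numbering, a
# synthetic Calpha structure, two conformer ensembles of distinct
# stability, one isotherm and one release trace.  Everything is generated
# in code with known ground truth; nothing is stored on disk.
make_fixture_set <- function(dir, seed = 20) {
  noncan <- c(96, 98, 99, 113, 114, 118, 157, 161, 162, 163, 165, 166, 168)
  specs <- lapply(noncan, function(r)
    perturbation_spec(r, "shift", max_dH = 0.03, max_dN = 0.15))
  series <- gen_peak_titration(186, specs, noise_sd = 0.002,
                               seed = derive_seed_t(seed, 1))
  # keep only residues 15..186 (folded-domain construct numbering)
  keep <- function(df) df[df$residue_id >= 15, ]
  series$apo <- keep(series$apo)
  series$points <- lapply(series$points, function(p) {
    p$peaks <- keep(p$peaks); p
  })
  tdir <- file.path(dir, "titration")
  write_titration(series, tdir)

  coords <- matrix(rnorm(172 * 3, sd = 8), ncol = 3)
  pdb <- file.path(dir, "bak_ca_synthetic.pdb")
  write_multimodel_pdb(coords, pdb, residue_ids = 15:186, chain = "A")

  cen <- gen_conformer_centers(12, 3, separation = 5,
                               seed = derive_seed_t(seed, 2))
  e_hi <- gen_ensemble(cen[1:2], c(0.75, 0.25), 120, jitter_sd = 0.2,
                       seed = derive_seed_t(seed, 3))
  e_lo <- gen_ensemble(cen, c(0.35, 0.33, 0.32), 120, jitter_sd = 0.2,
                       seed = derive_seed_t(seed, 4))
  p_hi <- file.path(dir, "site_hi.pdb")
  p_lo <- file.path(dir, "site_lo.pdb")
  write_multimodel_pdb(e_hi$frames, p_hi, residue_ids = 1:12, chain = "A")
  write_multimodel_pdb(e_lo$frames, p_lo, residue_ids = 1:12, chain = "A")

  iso <- gen_isotherm(1000, 100, 3200 / 2^(0:7), 0.02,
                      seed = derive_seed_t(seed, 5))
  iso_p <- file.path(dir, "isotherm.csv")
  write.csv(as.data.frame(iso), iso_p, row.names = FALSE)
  tr <- gen_release_traces(0.46, noise_sd = 0.5,
                           seed = derive_seed_t(seed, 6))
  tr_p <- file.path(dir, "release_bmf.csv")
  write.csv(as.data.frame(tr), tr_p, row.names = FALSE)

  list(apo = file.path(tdir, "apo.list"),
       points = list("1" = file.path(tdir, "ratio_1.list"),
                     "2" = file.path(tdir, "ratio_2.list"),
                     "4" = file.path(tdir, "ratio_4.list")),
       pdb = pdb, ens = c(hi = p_hi, lo = p_lo), iso = iso_p, tr = tr_p,
       noncan = noncan)
}

# local seed derivation for fixture building (independent of the package's)
derive_seed_t <- function(seed, k) seed * 1000L + k

fixture_config <- function(fx, outdir, seed = 1) {
  list(seed = seed, outdir = outdir,
       csp = list(apo = fx$apo, points = fx$points, noise_floor = 0.1),
       map = list(pdb = fx$pdb, chain = "A", permutations = 999),
       cluster = list(ensembles = as.list(fx$ens),
                      receptor_range = "1-12", peptide_range = "",
                      epsilon = 2.0),
       fit = list(isotherms = list(BMF = fx$iso)),
       release = list(traces = list(BMF = fx$tr)))
}

# Tiny multi-model PDB on disk; returns its path.
write_tiny_ensemble_pdb <- function(frames, dir = withr::local_tempdir(),
                                    ...) {
  path <- file.path(dir, "ens.pdb")
  write_multimodel_pdb(frames, path, ...)
  path
}
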