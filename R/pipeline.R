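# Config-driven orchestration: CSP -> groove mapping -> enrichment;
# ensembles -> populations -> site ranking; isotherms -> K_D table;
# release traces -> release summary.  One YAML config, one reproducible
# report.

config_schema <- list(
  top = c("seed", "outdir", "csp", "map", "cluster", "fit", "release"),
  csp = c("apo", "points", "noise_floor", "tol_h", "tol_n"),
  map = c("pdb", "chain", "model_index", "grooves", "permutations"),
  cluster = c("ensembles", "format", "epsilon", "receptor_range",
              "peptide_range", "receptor_chain", "peptide_chain"),
  fit = c("isotherms", "cmax", "offset"),
  release = c("traces", "window")
)

check_keys <- function(keys, valid, where) {
  bad <- setdiff(keys, valid)
  if (length(bad)) {
    near <- vapply(bad, function(k) {
      d <- utils::adist(k, valid)
      valid[which.min(d)]
    }, character(1))
    stopf("unknown config key(s) in %s: %s (did you mean: %s?)", where,
          paste(bad, collapse = ", "), paste(near, collapse = ", "))
  }
}

check_files <- function(paths, where) {
  paths <- unlist(paths)
  miss <- paths[!file.exists(paths)]
  if (length(miss)) {
    stopf("missing input file(s) for %s: %s", where,
          paste(miss, collapse = ", "))
  }
}

#' Validate a pipeline YAML config
#'
#' Schema-checks the config (unknown keys are rejected, with the nearest
#' valid key suggested), verifies that referenced input files exist, and
#' injects defaults: clustering `epsilon` 2.0 A, the BAK/BH3 atom mask
#' (receptor 102-125 and 147-177, peptide 4-23), 9999 permutations, the
#' threefold saturation QC, and a 10\% plateau window.
#'
#' @param path YAML file, or an equivalent named list.
#' @return A `gm_config` list with stage blocks `csp`, `map`, `cluster`,
#'   `fit`, `release` (absent stages are `NULL`), `seed` and `outdir`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg) || !length(cfg)) stopf("config is empty")
  check_keys(names(cfg), config_schema$top, "config")
  stages <- intersect(names(cfg), c("csp", "map", "cluster", "fit",
                                    "release"))
  if (!length(stages)) stopf("config defines no stages")
  for (st in stages) check_keys(names(cfg[[st]]), config_schema[[st]],
                                sprintf("stage '%s'", st))

  if (!is.null(cfg$csp)) {
    b <- cfg$csp
    if (is.null(b$apo) || is.null(b$points)) {
      stopf("csp stage needs `apo` and `points`")
    }
    if (is.null(b$noise_floor)) stopf("csp stage needs `noise_floor`")
    check_files(c(b$apo, unlist(b$points)), "csp")
    b$tol_h <- b$tol_h %||% 0.05
    b$tol_n <- b$tol_n %||% 0.25
    cfg$csp <- b
  }
  if (!is.null(cfg$map)) {
    b <- cfg$map
    if (is.null(cfg$csp)) stopf("map stage requires a csp stage")
    if (!is.null(b$pdb)) check_files(b$pdb, "map")
    if (!is.null(b$grooves)) check_files(b$grooves, "map")
    b$permutations <- b$permutations %||% 9999
    b$model_index <- b$model_index %||% 1
    cfg$map <- b
  }
  if (!is.null(cfg$cluster)) {
    b <- cfg$cluster
    if (is.null(b$ensembles)) stopf("cluster stage needs `ensembles`")
    check_files(b$ensembles, "cluster")
    b$epsilon <- b$epsilon %||% 2.0
    b$receptor_range <- b$receptor_range %||% "102-125,147-177"
    b$peptide_range <- b$peptide_range %||% "4-23"
    b$receptor_chain <- b$receptor_chain %||% "A"
    b$peptide_chain <- b$peptide_chain %||% "B"
    b$format <- b$format %||% "auto"
    cfg$cluster <- b
  }
  if (!is.null(cfg$fit)) {
    b <- cfg$fit
    if (is.null(b$isotherms)) stopf("fit stage needs `isotherms`")
    check_files(b$isotherms, "fit")
    b$offset <- isTRUE(b$offset)
    cfg$fit <- b
  }
  if (!is.null(cfg$release)) {
    b <- cfg$release
    if (is.null(b$traces)) stopf("release stage needs `traces`")
    check_files(b$traces, "release")
    b$window <- b$window %||% 0.1
    cfg$release <- b
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% "groovemapper_run"
  structure(cfg, class = "gm_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline from a validated config
#'
#' Stages execute in dependency order (csp, map, cluster, fit, release);
#' a stage failure aborts the run naming the stage, retaining partial
#' outputs.  All stage randomness derives from the single global seed, so
#' an identical config, inputs and seed reproduce an identical report
#' hash (timestamps are excluded from the hash).
#'
#' @param config A `gm_config` from [validate_config()], or a path to a
#'   YAML config.
#' @return A `gm_report` list (per-stage summaries, provenance, warnings)
#'   with attribute `hash`; also written to `outdir/report.json` and
#'   `outdir/report.md`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) || !inherits(config, "gm_config")) {
    config <- validate_config(config)
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  report <- list(package = "groovemapper",
                 version = as.character(utils::packageVersion("groovemapper")),
                 seed = seed, stages = list(), warnings = character())
  profile <- NULL

  if (!is.null(config$csp)) {
    b <- config$csp
    report$stages$csp <- run_stage("csp", {
      apo <- read_peak_list(b$apo)
      ratios <- as.numeric(names(b$points))
      if (anyNA(ratios)) stopf("csp point names must be numeric ratios")
      ord <- order(ratios)
      points <- lapply(ord, function(i) {
        list(ratio = ratios[i], peaks = read_peak_list(b$points[[i]]))
      })
      profile <- profile_titration(list(apo = apo, points = points),
                                   noise_floor = b$noise_floor,
                                   tol_H = b$tol_h, tol_N = b$tol_n)
      write_csp_profile(profile, outdir)
      list(inputs = c(apo = b$apo, unlist(b$points)),
           params = list(noise_floor = b$noise_floor, tol_h = b$tol_h,
                         tol_n = b$tol_n),
           mean_csp = attr(profile, "mean_csp"),
           sd_csp = attr(profile, "sd_csp"),
           threshold = attr(profile, "threshold"),
           counts = as.list(table(profile$class)),
           profile = profile)
    })
    profile <- report$stages$csp$profile
    report$stages$csp$profile <- NULL
  }

  if (!is.null(config$map)) {
    b <- config$map
    report$stages$map <- run_stage("map", {
      structure_ <- if (!is.null(b$pdb)) {
        load_structure(b$pdb, chain = b$chain, model_index = b$model_index)
      } else NULL
      grooves <- if (!is.null(b$grooves)) read_grooves_yaml(b$grooves)
                 else default_grooves()
      mapping <- map_perturbations(profile, structure_, grooves)
      enr <- groove_enrichment(mapping, n_permutations = b$permutations,
                               seed = derive_seed(seed, 2L))
      write.csv(enr$per_groove, file.path(outdir, "groove_mapping.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(per_groove = enr$per_groove,
             n_perturbed_total = enr$n_perturbed_total,
             n_assigned_total = enr$n_assigned_total,
             n_permutations = enr$n_permutations, seed = enr$seed),
        file.path(outdir, "enrichment.json"), auto_unbox = TRUE,
        digits = NA, dataframe = "rows")
      if (!is.null(structure_)) {
        paint_perturbations(structure_, mapping$perturbed,
                            file.path(outdir, "perturbed.pdb"))
      }
      list(params = list(permutations = b$permutations, pdb = b$pdb),
           per_groove = enr$per_groove,
           n_perturbed_total = enr$n_perturbed_total,
           n_assigned_total = enr$n_assigned_total)
    })
  }

  if (!is.null(config$cluster)) {
    b <- config$cluster
    report$stages$cluster <- run_stage("cluster", {
      mask <- atom_mask(b$receptor_range, b$peptide_range)
      paths <- b$ensembles
      if (is.null(names(paths))) {
        names(paths) <- tools::file_path_sans_ext(basename(unlist(paths)))
      }
      ensembles <- lapply(paths, function(p)
        read_ensemble(p, mask, receptor_chain = b$receptor_chain,
                      peptide_chain = b$peptide_chain, format = b$format))
      if (length(ensembles) >= 2L) {
        cmp <- compare_sites(ensembles, epsilon = b$epsilon,
                             seed = derive_seed(seed, 3L))
        write.csv(cmp$ranking, file.path(outdir, "site_ranking.csv"),
                  row.names = FALSE)
        labs <- lapply(cmp$clusters, `[[`, "labels")
        for (nm in names(labs)) {
          write.csv(data.frame(frame = seq_along(labs[[nm]]),
                               cluster = labs[[nm]]),
                    file.path(outdir, sprintf("clusters_%s.csv", nm)),
                    row.names = FALSE)
        }
        list(params = list(epsilon = b$epsilon,
                           receptor_range = b$receptor_range,
                           peptide_range = b$peptide_range),
             ranking = cmp$ranking, conclusive = cmp$conclusive)
      } else {
        cl <- average_linkage_cluster(pairwise_rmsd(ensembles[[1L]]),
                                      b$epsilon)
        write.csv(data.frame(frame = seq_along(cl$labels),
                             cluster = cl$labels),
                  file.path(outdir, "clusters.csv"), row.names = FALSE)
        list(params = list(epsilon = b$epsilon,
                           receptor_range = b$receptor_range,
                           peptide_range = b$peptide_range),
             populations = cl$populations,
             top_population = top_population(cl)$population)
      }
    })
    if (isFALSE(report$stages$cluster$conclusive)) {
      report$warnings <- c(report$warnings,
                           "cluster: site ranking inconclusive (bootstrap intervals overlap)")
    }
  }

  if (!is.null(config$fit)) {
    b <- config$fit
    report$stages$fit <- run_stage("fit", {
      paths <- b$isotherms
      if (is.null(names(paths))) {
        names(paths) <- tools::file_path_sans_ext(basename(unlist(paths)))
      }
      fits <- lapply(names(paths), function(nm) {
        iso <- read_isotherm_csv(paths[[nm]])
        fit <- fit_steady_state(iso, offset = b$offset)
        if (!is.null(b$cmax)) {
          qc <- check_saturation(fit, b$cmax)
          fit$cmax_over_kd <- qc$ratio
          fit$saturation_ok <- qc$ok
          fit$caveat <- qc$caveat
        }
        data.frame(analyte = nm, kd_nM = fit$kd, rmax_RU = fit$rmax,
                   se_kd_nM = fit$se_kd, cmax_over_kd = fit$cmax_over_kd,
                   saturation_ok = fit$saturation_ok)
      })
      tab <- do.call(rbind, fits)
      jsonlite::write_json(tab, file.path(outdir, "kd_fits.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      list(params = list(offset = b$offset, cmax = b$cmax), fits = tab)
    })
    bad <- report$stages$fit$fits
    bad <- bad[!bad$saturation_ok, , drop = FALSE]
    if (nrow(bad)) {
      report$warnings <- c(report$warnings, sprintf(
        "fit '%s': saturation criterion not met (cmax/K_D = %.2f < 3)",
        bad$analyte, bad$cmax_over_kd))
    }
  }

  if (!is.null(config$release)) {
    b <- config$release
    report$stages$release <- run_stage("release", {
      conds <- lapply(b$traces, function(ps)
        lapply(as.character(unlist(ps)), read_release_csv))
      summ <- summarize_release(conds, window = b$window)
      write.csv(summ, file.path(outdir, "release_summary.csv"),
                row.names = FALSE)
      list(params = list(window = b$window), summary = summ)
    })
  }

  hash <- digest::digest(report)
  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  md <- c(sprintf("# groovemapper run (seed %d)", seed),
          sprintf("- version: %s", report$version),
          sprintf("- stages: %s", paste(names(report$stages),
                                        collapse = ", ")),
          sprintf("- report hash: %s", hash),
          if (length(report$warnings)) c("", "## Warnings",
                                         paste("-", report$warnings)))
  writeLines(md, file.path(outdir, "report.md"))
  structure(report, hash = hash, class = "gm_report")
}
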