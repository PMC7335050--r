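# Minimal fixed-column PDB reading/writing for Calpha traces and
# multi-model conformer ensembles.  Only the ATOM fields this package needs
# are handled; author residue numbering is kept verbatim.

parse_pdb_models <- function(path) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur <- character()
  in_model <- FALSE
  for (ln in lines) {
    rec <- substr(ln, 1L, 6L)
    if (startsWith(rec, "MODEL")) {
      in_model <- TRUE
      cur <- character()
    } else if (startsWith(rec, "ENDMDL")) {
      models[[length(models) + 1L]] <- cur
      cur <- character()
      in_model <- FALSE
    } else if (rec == "ATOM  " || rec == "HETATM") {
      cur <- c(cur, ln)
    }
  }
  if (length(cur)) models[[length(models) + 1L]] <- cur
  if (!length(models) || !length(models[[1L]])) {
    stopf("no ATOM records in %s", path)
  }
  lapply(models, function(ls) {
    occ <- suppressWarnings(as.numeric(substr(ls, 55L, 60L)))
    occ[is.na(occ)] <- 1
    data.frame(
      name = trimws(substr(ls, 13L, 16L)),
      altloc = substr(ls, 17L, 17L),
      resname = trimws(substr(ls, 18L, 20L)),
      chain = substr(ls, 22L, 22L),
      resid = as.integer(substr(ls, 23L, 26L)),
      x = as.numeric(substr(ls, 31L, 38L)),
      y = as.numeric(substr(ls, 39L, 46L)),
      z = as.numeric(substr(ls, 47L, 54L)),
      occ = occ,
      stringsAsFactors = FALSE)
  })
}

#' Load a Calpha trace from a PDB file
#'
#' Extracts one Calpha coordinate per residue from the requested chain and
#' model.  Altloc duplicates keep the highest-occupancy record (first on
#' ties); residues without a Calpha atom are skipped with a warning.
#' Residue numbering is taken verbatim from the file.
#'
#' @param path PDB file.
#' @param chain Chain identifier; default the first chain present.
#' @param model_index Model to read from a multi-model file (default 1).
#' @return A `gm_structure` data frame (`residue_id`, `x`, `y`, `z`) with
#'   attributes `chain` and `source`.
#' @export
load_structure <- function(path, chain = NULL, model_index = 1L) {
  models <- parse_pdb_models(path)
  if (model_index < 1L || model_index > length(models)) {
    stopf("model_index %d out of range (file has %d model(s))",
          model_index, length(models))
  }
  atoms <- models[[model_index]]
  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains) {
    stopf("chain '%s' not in %s (available: %s)", chain, path,
          paste(chains, collapse = ", "))
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  all_res <- unique(atoms$resid)
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  if (!nrow(ca)) stopf("no Calpha atoms in chain '%s' of %s", chain, path)
  # altloc: highest occupancy wins, first record on ties
  ca <- ca[order(ca$resid, -ca$occ), , drop = FALSE]
  ca <- ca[!duplicated(ca$resid), , drop = FALSE]
  missing_ca <- setdiff(all_res, ca$resid)
  if (length(missing_ca)) {
    warnf("skipping %d residue(s) without Calpha in chain '%s': %s",
          length(missing_ca), chain,
          paste(utils::head(missing_ca, 10L), collapse = ", "))
  }
  if (any(!is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z))) {
    stopf("non-finite coordinates in %s", path)
  }
  out <- data.frame(residue_id = ca$resid, x = ca$x, y = ca$y, z = ca$z)
  rownames(out) <- NULL
  structure(out, chain = chain, source = path,
            class = c("gm_structure", "data.frame"))
}

format_atom_line <- function(serial, name, resname, chain, resid,
                             x, y, z, occ = 1, bfac = 0) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, resname, chain, resid, x, y, z, occ, bfac)
}

#' Write coordinates as a (multi-model) PDB file
#'
#' @param coords A `n_atoms` x 3 matrix, a list of such matrices, or a
#'   `n_atoms` x 3 x `n_frames` array; each matrix/slice becomes one MODEL.
#' @param path Output path.
#' @param residue_ids Residue numbers per atom (default `1:n_atoms`).
#' @param chain Chain id per atom (recycled; default `"A"`).
#' @param bfac B-factor per atom (recycled; default 0).
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(coords, path, residue_ids = NULL,
                                 chain = "A", bfac = 0) {
  frames <- if (is.array(coords) && length(dim(coords)) == 3L) {
    lapply(seq_len(dim(coords)[3L]), function(i) coords[, , i])
  } else if (is.matrix(coords)) list(coords) else coords
  n_atoms <- nrow(frames[[1L]])
  residue_ids <- residue_ids %||% seq_len(n_atoms)
  chain <- rep_len(chain, n_atoms)
  bfac <- rep_len(bfac, n_atoms)
  multi <- length(frames) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    m <- frames[[k]]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(format_atom_line(seq_len(n_atoms), "CA", "ALA", chain,
                                residue_ids, m[, 1L], m[, 2L], m[, 3L],
                                1, bfac), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
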