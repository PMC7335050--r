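# Mapping classified residues onto structure-defined binding grooves and
# quantifying per-groove enrichment of perturbations by permutation.

#' Define a named binding groove by its member residues
#'
#' @param name Groove name, e.g. `"canonical"` or `"noncanonical"`.
#' @param residue_ids Integer residue numbers (author/PDB numbering).
#' @param helix_labels Free-text helix annotation.
#' @param provenance Free-text note on where the residue list comes from.
#' @return A `gm_groove` list.
#' @export
groove_definition <- function(name, residue_ids, helix_labels = "",
                              provenance = "") {
  if (!length(residue_ids)) stopf("groove '%s' has an empty residue set", name)
  structure(list(name = name,
                 residue_ids = sort(unique(as.integer(residue_ids))),
                 helix_labels = helix_labels, provenance = provenance),
            class = "gm_groove")
}

#' Default BAK groove definitions
#'
#' The canonical BH3-binding groove (helices alpha3/alpha4/alpha5) and the
#' noncanonical alpha4/alpha6/alpha7 groove, each defined by the BAK
#' residues whose HSQC signals respond to BH3-peptide titration
#' (author/PDB 2IMS numbering).  The two sets share the alpha3/alpha4
#' residues {96, 98, 99, 113, 114, 118}; shared residues count toward both
#' grooves.
#'
#' @return A named list of two `gm_groove` objects.
#' @export
default_grooves <- function() {
  canonical <- c(82, 83, 85, 89, 90, 91, 93, 94, 95, 96, 97, 98, 99,
                 108, 113, 114, 118, 126, 130, 131, 132, 133, 134)
  noncanonical <- c(96, 98, 99, 113, 114, 118,
                    157, 161, 162, 163, 164, 165, 166, 168)
  list(
    canonical = groove_definition(
      "canonical", canonical,
      helix_labels = "alpha3/alpha4/alpha5",
      provenance = paste("PUMA-responsive residues of the canonical groove:",
                         "alpha3 G82,D83,I85,Y89,D90,S91,F93,Q94,T95,M96,",
                         "L97,Q98,H99; alpha4 K113,I114,L118; alpha5",
                         "G126,A130,L131,L132,G133,F134; plus Y108")),
    noncanonical = groove_definition(
      "noncanonical", noncanonical,
      helix_labels = "alpha4/alpha6/alpha7",
      provenance = paste("BMF/HRK-responsive residues: alpha3 M96,Q98,H99;",
                         "alpha4 K113,I114,L118; alpha6 F157,F161,M162,",
                         "L163,H164,H165,C166; alpha7 A168")))
}

#' Read groove definitions from a YAML file
#'
#' The file maps groove names to residue-number lists, e.g.
#' `canonical: [82, 83, 85]`.
#'
#' @param path YAML file.
#' @return Named list of `gm_groove` objects.
#' @export
read_grooves_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stopf("no grooves in %s", path)
  out <- lapply(names(raw), function(nm)
    groove_definition(nm, unlist(raw[[nm]]), provenance = path))
  setNames(out, names(raw))
}

#' Map classified perturbations onto grooves
#'
#' A residue counts as perturbed when its class is `shifted` or
#' `attenuated`.  Counts are restricted to residues both assigned in the
#' profile (class not `unassigned`) and present in the structure; an empty
#' intersection signals a numbering mismatch and is an error.  Each
#' groove's `fraction` is the perturbed share of its assigned members;
#' residues shared between grooves count toward both.
#'
#' @param profile A classified `gm_csp_profile`.
#' @param structure A `gm_structure` from [load_structure()], or `NULL` to
#'   use the profile residues as-is.
#' @param grooves Named list of `gm_groove` (default [default_grooves()]).
#' @return A `gm_groove_mapping` list: `per_groove` data frame (`groove`,
#'   `n_groove`, `n_perturbed_in_groove`, `fraction`), `assigned`,
#'   `perturbed`, `grooves`.
#' @export
map_perturbations <- function(profile, structure = NULL,
                              grooves = default_grooves()) {
  if (!"class" %in% names(profile)) stopf("profile is not classified")
  assigned <- profile$residue_id[profile$class != "unassigned"]
  if (!is.null(structure)) {
    keep <- intersect(assigned, structure$residue_id)
    if (!length(keep)) {
      stopf(paste("no overlap between profile residues and structure",
                  "numbering; check residue numbering"))
    }
    assigned <- keep
  }
  perturbed <- profile$residue_id[profile$class %in%
                                    c("shifted", "attenuated")]
  perturbed <- intersect(perturbed, assigned)
  per <- do.call(rbind, lapply(grooves, function(g) {
    members <- intersect(g$residue_ids, assigned)
    hit <- intersect(members, perturbed)
    data.frame(groove = g$name, n_groove = length(members),
               n_perturbed_in_groove = length(hit),
               fraction = if (length(members)) length(hit) / length(members)
                          else NA_real_)
  }))
  rownames(per) <- NULL
  structure(list(per_groove = per, assigned = sort(assigned),
                 perturbed = sort(perturbed), grooves = grooves),
            class = "gm_groove_mapping")
}

#' Permutation test of per-groove perturbation enrichment
#'
#' The null distribution draws `|perturbed|` residues uniformly without
#' replacement from the assigned residues and counts how many land in each
#' groove.  The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`, so it is always
#' in (0, 1].  With zero perturbed residues every p is 1.
#'
#' @param mapping A `gm_groove_mapping` from [map_perturbations()].
#' @param n_permutations Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A `gm_enrichment` list: `per_groove` data frame with
#'   `permutation_p` added, plus `n_perturbed_total`, `n_assigned_total`,
#'   `n_permutations`, `seed`, and the raw `null_counts` matrix (one row
#'   per permutation) for diagnostics.
#' @export
groove_enrichment <- function(mapping, n_permutations = 9999, seed = 1L) {
  if (n_permutations < 99) stopf("`n_permutations` must be >= 99")
  assigned <- mapping$assigned
  k <- length(mapping$perturbed)
  if (k > length(assigned)) stopf("more perturbed than assigned residues")
  per <- mapping$per_groove
  obs <- per$n_perturbed_in_groove
  ge <- NULL
  if (k == 0L) {
    per$permutation_p <- rep(1, nrow(per))
  } else {
    groove_sets <- lapply(mapping$grooves, function(g)
      intersect(g$residue_ids, assigned))
    ge <- with_seed(seed, {
      counts <- matrix(0L, n_permutations, nrow(per))
      for (b in seq_len(n_permutations)) {
        draw <- sample(assigned, k)
        counts[b, ] <- vapply(groove_sets, function(s)
          sum(draw %in% s), integer(1))
      }
      counts
    })
    per$permutation_p <- vapply(seq_len(nrow(per)), function(j)
      (1 + sum(ge[, j] >= obs[j])) / (1 + n_permutations), numeric(1))
  }
  structure(list(per_groove = per, n_perturbed_total = k,
                 n_assigned_total = length(assigned),
                 n_permutations = n_permutations, seed = seed,
                 null_counts = ge),
            class = "gm_enrichment")
}

#' Paint perturbation calls into PDB B-factors for visualisation
#'
#' Writes a Calpha-trace PDB in which perturbed residues carry B-factor 1
#' and all others 0.
#'
#' @param structure A `gm_structure`.
#' @param perturbed Integer residue ids to mark.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
paint_perturbations <- function(structure, perturbed, path) {
  bfac <- as.numeric(structure$residue_id %in% perturbed)
  write_multimodel_pdb(as.matrix(structure[, c("x", "y", "z")]), path,
                       residue_ids = structure$residue_id,
                       chain = attr(structure, "chain") %||% "A",
                       bfac = bfac)
}
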