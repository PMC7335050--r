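# Conformer-population analysis: atom masks, ensemble input, best-fit Kabsch
# superposition, pairwise Calpha RMSD, epsilon-terminated average-linkage
# clustering and the top-population statistic.

MAX_FRAMES <- 20000L

#' Define a Calpha atom mask
#'
#' Residue ranges per chain role; the masked atom order is fixed: receptor
#' segments in sequence order, then the peptide segments.
#'
#' @param receptor Receptor residue ranges, as a string `"102-125,147-177"`
#'   or a list of `c(lo, hi)` pairs.
#' @param peptide Peptide residue ranges, same formats, or `NULL`.
#' @return A `gm_mask` list with integer vectors `receptor` and `peptide`.
#' @export
atom_mask <- function(receptor, peptide = NULL) {
  parse_ranges <- function(r) {
    if (is.null(r)) return(integer())
    if (is.character(r)) {
      parts <- strsplit(r, ",")[[1L]]
      r <- lapply(parts, function(p) {
        lo_hi <- as.integer(strsplit(trimws(p), "-")[[1L]])
        if (length(lo_hi) == 1L) rep(lo_hi, 2L) else lo_hi
      })
    }
    if (is.numeric(r)) r <- list(r)
    out <- unlist(lapply(r, function(lh) {
      if (length(lh) != 2L || lh[2L] < lh[1L]) stopf("bad residue range")
      seq.int(lh[1L], lh[2L])
    }))
    if (anyDuplicated(out)) stopf("overlapping residue ranges in mask")
    out
  }
  structure(list(receptor = parse_ranges(receptor),
                 peptide = parse_ranges(peptide), atom_name = "CA"),
            class = "gm_mask")
}

#' Default BAK/BH3-peptide clustering mask
#'
#' Calpha atoms of receptor residues 102-125 and 147-177 plus peptide
#' residues 4-23 — the region flanking both binding grooves and the bound
#' BH3 helix.
#'
#' @return A `gm_mask`.
#' @export
default_mask <- function() atom_mask("102-125,147-177", "4-23")

#' Read a conformer ensemble
#'
#' Accepts a multi-model PDB (mask applied per model: receptor-chain
#' Calphas in sequence order, then peptide-chain) or a plain whitespace
#' table with columns `frame atom x y z` (already masked).
#'
#' @param path Input file.
#' @param mask A `gm_mask`; required for PDB input.
#' @param receptor_chain,peptide_chain Chain ids for the two roles in PDB
#'   input.
#' @param format `"auto"` (by extension), `"pdb"` or `"table"`.
#' @return A `gm_ensemble` (frames array `n_atoms` x 3 x `n_frames`).
#' @export
read_ensemble <- function(path, mask = default_mask(),
                          receptor_chain = "A", peptide_chain = "B",
                          format = c("auto", "pdb", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb"
              else "table"
  }
  if (format == "pdb") {
    models <- parse_pdb_models(path)
    pick <- function(atoms, chain, resids, frame) {
      ca <- atoms[atoms$name == "CA" & atoms$chain == chain, , drop = FALSE]
      idx <- match(resids, ca$resid)
      if (anyNA(idx)) {
        stopf("frame %d: missing masked Calpha for residue(s) %s (chain %s)",
              frame, paste(resids[is.na(idx)], collapse = ", "), chain)
      }
      as.matrix(ca[idx, c("x", "y", "z")])
    }
    frames_list <- lapply(seq_along(models), function(k) {
      m <- models[[k]]
      rec <- if (length(mask$receptor)) {
        pick(m, receptor_chain, mask$receptor, k)
      } else NULL
      pep <- if (length(mask$peptide)) {
        pick(m, peptide_chain, mask$peptide, k)
      } else NULL
      rbind(rec, pep)
    })
  } else {
    tab <- read.table(path, header = TRUE)
    need <- c("frame", "atom", "x", "y", "z")
    if (!all(need %in% names(tab))) {
      stopf("coordinate table needs columns: %s", paste(need, collapse = " "))
    }
    frames_list <- lapply(split(tab, tab$frame), function(d) {
      as.matrix(d[order(d$atom), c("x", "y", "z")])
    })
  }
  n_atoms <- unique(vapply(frames_list, nrow, integer(1)))
  if (length(n_atoms) != 1L) stopf("frames have differing atom counts")
  if (length(frames_list) > MAX_FRAMES) {
    stopf("ensemble exceeds the %d-frame cap", MAX_FRAMES)
  }
  frames <- array(unlist(frames_list), c(n_atoms, 3L, length(frames_list)))
  if (any(!is.finite(frames))) stopf("non-finite coordinates in %s", path)
  structure(list(frames = frames, frame_ids = seq_along(frames_list),
                 mask = mask, interval_ps = NA_real_),
            class = "gm_ensemble")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1; reflections excluded) and
#' translation minimising the RMSD of `X` onto `Y`.
#'
#' @param X,Y Coordinate matrices (`n` x 3, `n >= 3`, non-collinear).
#' @return List with `rotation` (3 x 3), `translation` (length 3; the fit
#'   maps `x` to `x %*% t(rotation) + translation`), and `rmsd` (A).
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L) {
    stopf("X and Y must be n x 3 matrices of equal shape")
  }
  n <- nrow(X)
  if (n < 3L) stopf("need at least 3 atoms to superpose")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv_x <- svd(Xc)$d; sv_y <- svd(Yc)$d
  if (sv_x[2L] < 1e-9 * max(sv_x[1L], 1) ||
      sv_y[2L] < 1e-9 * max(sv_y[1L], 1)) {
    stopf("degenerate (collinear or coincident) coordinates")
  }
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(sum((fitted - Yc)^2) / n)
  list(rotation = R, translation = as.numeric(cy - R %*% cx), rmsd = rmsd)
}

#' Pairwise best-fit RMSD matrix of an ensemble
#'
#' Each entry (i, j) is the minimum RMSD over proper rotations and
#' translations of frames i and j over the masked atoms, fitted
#' independently per pair (so the matrix need not obey the triangle
#' inequality).
#'
#' @param ensemble A `gm_ensemble`, or a bare `n_atoms` x 3 x `n_frames`
#'   array.
#' @return Symmetric matrix (A) with zero diagonal.
#' @export
pairwise_rmsd <- function(ensemble) {
  frames <- if (is.list(ensemble)) ensemble$frames else ensemble
  if (length(dim(frames)) != 3L) stopf("expected an n_atoms x 3 x n_frames array")
  if (dim(frames)[3L] < 2L) stopf("need at least 2 frames")
  if (dim(frames)[3L] > MAX_FRAMES) {
    stopf("ensemble exceeds the %d-frame cap", MAX_FRAMES)
  }
  pairwise_rmsd_cpp(frames)
}

#' Fraction of triples violating the triangle inequality
#'
#' Best-fit RMSD under independent pairwise superposition is not a metric;
#' occasional triangle-inequality violations are expected and permitted.
#' This diagnostic counts them (within a numerical slack) so that
#' pathological inputs — more than ~10\% of triples violating — can be
#' flagged.  Exhaustive over all triples: small matrices only.
#'
#' @param dist Symmetric distance matrix (n <= 200).
#' @param slack Additive tolerance before a triple counts as violating.
#' @return Fraction of violating triples.
#' @export
triangle_violations <- function(dist, slack = 1e-9) {
  n <- nrow(dist)
  if (n > 200L) stopf("exhaustive triple check is limited to n <= 200")
  if (n < 3L) return(0)
  trip <- utils::combn(n, 3L)
  viol <- apply(trip, 2L, function(t3) {
    d <- c(dist[t3[1L], t3[2L]], dist[t3[1L], t3[3L]], dist[t3[2L], t3[3L]])
    max(d) > sum(d) - max(d) + slack
  })
  mean(viol)
}

#' Average-linkage clustering terminated at epsilon
#'
#' Agglomerative merging of the closest cluster pair under unweighted
#' average linkage (mean of all cross-pair distances), proceeding while the
#' minimum inter-cluster average distance is at most `epsilon`; at
#' termination every remaining inter-cluster distance strictly exceeds
#' `epsilon`.  Ties are broken toward the lowest (i, j) cluster-index pair,
#' clusters being indexed by their smallest member frame.
#'
#' @param dist Symmetric non-negative distance matrix with zero diagonal.
#' @param epsilon Termination distance (A), positive; the field default for
#'   Calpha-RMSD trajectory clustering is 2.0.
#' @return A `gm_clusters` list: `labels` (cluster index per frame, 1 =
#'   most populated), `populations` (descending fractions), `sizes`,
#'   `representative_frames` (per-cluster medoid frame ids), `epsilon`,
#'   `linkage`.
#' @export
average_linkage_cluster <- function(dist, epsilon = 2.0) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n != ncol(dist) || n < 1L) stopf("`dist` must be square")
  if (epsilon <= 0) stopf("`epsilon` must be positive")
  if (any(dist < 0) || any(abs(dist - t(dist)) > 1e-9) ||
      any(abs(diag(dist)) > 1e-9)) {
    stopf("`dist` must be symmetric, non-negative, with zero diagonal")
  }
  slots <- avg_linkage_cpp(dist, epsilon)
  # order clusters by size (descending), ties by smallest member index
  tab <- table(slots)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  slot_ids <- as.integer(names(tab))[ord]
  labels <- match(slots, slot_ids)
  sizes <- as.integer(tab)[ord]
  medoid <- vapply(seq_along(slot_ids), function(k) {
    members <- which(labels == k)
    if (length(members) == 1L) return(members)
    within <- dist[members, members, drop = FALSE]
    members[which.min(rowSums(within))]
  }, integer(1))
  structure(list(labels = labels, populations = sizes / n, sizes = sizes,
                 representative_frames = medoid, epsilon = epsilon,
                 linkage = "average", n_frames = n),
            class = "gm_clusters")
}

#' Population of the most populated conformer
#'
#' @param result A `gm_clusters`.
#' @return List with `population` (fraction of frames in the largest
#'   cluster) and `representative_frame` (its medoid frame id).
#' @export
top_population <- function(result) {
  list(population = result$populations[1L],
       representative_frame = result$representative_frames[1L])
}

#' Compare binding sites by conformer-population stability
#'
#' Clusters each ensemble, reports its top population with a
#' frame-resampling bootstrap confidence interval (labels fixed, frames
#' resampled with replacement), and ranks the ensembles.  Rankings whose
#' neighbouring intervals overlap are flagged inconclusive.
#'
#' @param ensembles Named list of `gm_ensemble` objects (>= 2), or of
#'   precomputed distance matrices.
#' @param epsilon Clustering cutoff (A).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return A `gm_site_ranking` list: `ranking` data frame (`site`,
#'   `top_population`, `lower`, `upper`, `n_frames`), `conclusive` flag,
#'   `epsilon`, `seed`, and the per-site `gm_clusters` in `clusters`.
#' @export
compare_sites <- function(ensembles, epsilon = 2.0, n_boot = 200,
                          conf = 0.95, seed = 1L) {
  if (length(ensembles) < 2L) stopf("need at least two ensembles")
  if (is.null(names(ensembles)) || any(!nzchar(names(ensembles)))) {
    stopf("`ensembles` must be a named list")
  }
  alpha <- (1 - conf) / 2
  res <- lapply(seq_along(ensembles), function(i) {
    e <- ensembles[[i]]
    d <- if (is.matrix(e)) e else pairwise_rmsd(e)
    cl <- average_linkage_cluster(d, epsilon)
    boots <- with_seed(derive_seed(seed, i), {
      vapply(seq_len(n_boot), function(b) {
        lb <- cl$labels[sample.int(cl$n_frames, replace = TRUE)]
        max(tabulate(lb)) / cl$n_frames
      }, numeric(1))
    })
    ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
    list(cl = cl, top = cl$populations[1L], lower = ci[1L], upper = ci[2L])
  })
  rank_df <- data.frame(site = names(ensembles),
                        top_population = vapply(res, `[[`, numeric(1), "top"),
                        lower = vapply(res, `[[`, numeric(1), "lower"),
                        upper = vapply(res, `[[`, numeric(1), "upper"),
                        n_frames = vapply(res, function(r) r$cl$n_frames,
                                          integer(1)))
  rank_df <- rank_df[order(-rank_df$top_population), ]
  rownames(rank_df) <- NULL
  overlap <- if (nrow(rank_df) > 1L) {
    any(rank_df$lower[-nrow(rank_df)] <= rank_df$upper[-1L])
  } else FALSE
  structure(list(ranking = rank_df, conclusive = !overlap,
                 epsilon = epsilon, conf = conf, seed = seed,
                 clusters = setNames(lapply(res, `[[`, "cl"),
                                     names(ensembles))),
            class = "gm_site_ranking")
}
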