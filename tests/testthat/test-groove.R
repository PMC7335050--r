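# Structure loading, the default groove definitions, perturbation mapping
# and the permutation enrichment test (checked against the hypergeometric
# law on small toys).

make_ca_pdb <- function(path, resids, chain = "A", altloc_dup = FALSE) {
  coords <- matrix(seq_len(3 * length(resids)), ncol = 3) * 1.0
  write_multimodel_pdb(coords, path, residue_ids = resids, chain = chain)
  if (altloc_dup) {
    # append an altloc B copy of the first residue with higher occupancy
    ln <- readLines(path)
    dup <- sub("^(ATOM  .{10})(.)(.{39})1\\.00", "\\1B\\32.00", ln[1])
    writeLines(c(ln[1], dup, ln[-1]), path)
  }
  path
}

test_that("load_structure extracts one Calpha per residue", {
  d <- withr::local_tempdir()
  p <- make_ca_pdb(file.path(d, "s.pdb"), 15:186)
  s <- load_structure(p, chain = "A")
  expect_s3_class(s, "gm_structure")
  expect_equal(nrow(s), 172)
  expect_equal(s$residue_id, 15:186)
  expect_error(load_structure(p, chain = "Z"), "available: A")
})

test_that("altloc duplicates keep the highest-occupancy record", {
  d <- withr::local_tempdir()
  p <- make_ca_pdb(file.path(d, "alt.pdb"), 1:4, altloc_dup = TRUE)
  s <- load_structure(p)
  expect_equal(nrow(s), 4L)
  # the altloc B record (occupancy 2.00) shares coordinates with row 1 in
  # this fixture; build a conflicting one to check selection
  ln <- readLines(p)
  ln[2] <- sub("   1\\.000", "  99.000", ln[2])  # x of the occ-2 record
  writeLines(ln, p)
  s2 <- load_structure(p)
  expect_equal(s2$x[1], 99)
})

test_that("default grooves reproduce the published residue sets", {
  g <- default_grooves()
  expect_equal(g$canonical$residue_ids,
               c(82, 83, 85, 89, 90, 91, 93, 94, 95, 96, 97, 98, 99, 108,
                 113, 114, 118, 126, 130, 131, 132, 133, 134))
  expect_equal(g$noncanonical$residue_ids,
               c(96, 98, 99, 113, 114, 118, 157, 161, 162, 163, 164, 165,
                 166, 168))
  expect_true(126 %in% g$canonical$residue_ids)
  expect_false(126 %in% g$noncanonical$residue_ids)
  expect_true(all(c(161, 168) %in% g$noncanonical$residue_ids))
  expect_equal(intersect(g$canonical$residue_ids, g$noncanonical$residue_ids),
               c(96, 98, 99, 113, 114, 118))
})

test_that("shipped extdata matches the in-code defaults", {
  yml <- system.file("extdata", "grooves_bak.yaml", package = "groovemapper")
  g <- read_grooves_yaml(yml)
  d <- default_grooves()
  expect_equal(g$canonical$residue_ids, d$canonical$residue_ids)
  expect_equal(g$noncanonical$residue_ids, d$noncanonical$residue_ids)

  pl <- read_peak_list(system.file("extdata", "example_peaks.list",
                                   package = "groovemapper"))
  expect_equal(pl$residue_id, c(82, 83, 85, 89, 90))
  expect_equal(nrow(attr(pl, "unassigned")), 1L)
})

test_that("groove YAML override round-trips", {
  d <- withr::local_tempdir()
  p <- file.path(d, "g.yaml")
  writeLines(c("canonical: [82, 83, 85]", "other: [10, 11]"), p)
  g <- read_grooves_yaml(p)
  expect_equal(names(g), c("canonical", "other"))
  expect_equal(g$other$residue_ids, c(10, 11))
})

test_that("map_perturbations does set arithmetic per groove", {
  g <- default_grooves()
  resids <- 15:186
  prof <- make_profile(resids, perturbed = g$noncanonical$residue_ids)
  m <- map_perturbations(prof, NULL, g)
  per <- m$per_groove
  expect_equal(per$fraction[per$groove == "noncanonical"], 1.0)
  overlap <- intersect(g$canonical$residue_ids, g$noncanonical$residue_ids)
  expect_equal(per$fraction[per$groove == "canonical"],
               length(overlap) / length(g$canonical$residue_ids))

  none <- map_perturbations(make_profile(resids, integer()), NULL, g)
  expect_equal(none$per_groove$fraction, c(0, 0))

  # numbering mismatch: profile residues absent from the structure
  d <- withr::local_tempdir()
  p <- make_ca_pdb(file.path(d, "s.pdb"), 1000:1010)
  s <- load_structure(p)
  expect_error(map_perturbations(prof, s, g), "numbering")

  # residues absent from both structure and profile do not change counts
  prof_small <- make_profile(80:170, perturbed = g$noncanonical$residue_ids)
  p2 <- make_ca_pdb(file.path(d, "s2.pdb"), 80:170)
  m2 <- map_perturbations(prof_small, load_structure(p2), g)
  m2b <- map_perturbations(make_profile(c(80:170, 300:310),
                                        g$noncanonical$residue_ids),
                           load_structure(p2), g)
  expect_equal(m2$per_groove, m2b$per_groove)
})

test_that("a BMF/HRK-style profile prefers the noncanonical groove", {
  bmf_residues <- c(96, 98, 99, 113, 114, 118, 157, 161, 162, 163, 165,
                    166, 168)
  prof <- make_profile(15:186, perturbed = bmf_residues)
  m <- map_perturbations(prof, NULL, default_grooves())
  per <- m$per_groove
  expect_gt(per$fraction[per$groove == "noncanonical"],
            per$fraction[per$groove == "canonical"])
})

test_that("permutation p agrees with the exhaustive hypergeometric null", {
  # 10-residue toy: groove = residues 1:4, perturbed = 3 of them, all in
  # the groove.  Exact tail p = P(X >= 3), X ~ Hypergeom(4, 6, 3).
  g <- list(g1 = groove_definition("g1", 1:4))
  prof <- make_profile(1:10, perturbed = 1:3)
  m <- map_perturbations(prof, NULL, g)
  e <- groove_enrichment(m, n_permutations = 9999, seed = 21)
  p_exact <- hyper_tail_p(3, 4, 10, 3)
  expect_equal(p_exact, choose(4, 3) / choose(10, 3))
  expect_lt(abs(e$per_groove$permutation_p - p_exact),
            4 * sqrt(p_exact * (1 - p_exact) / 9999) + 2e-4)
  expect_lte(e$per_groove$permutation_p, 0.15)
  expect_gt(e$per_groove$permutation_p, 0)

  # strong enrichment in a big background: p <= 0.01
  g2 <- list(g1 = groove_definition("g1", 1:6))
  prof2 <- make_profile(1:100, perturbed = 1:6)
  m2 <- map_perturbations(prof2, NULL, g2)
  e2 <- groove_enrichment(m2, n_permutations = 9999, seed = 22)
  expect_lte(e2$per_groove$permutation_p, 0.01)
})

test_that("null permutation p-values are uniform on (0, 1]", {
  # The in-groove count is discrete, so the raw p-values sit on a lattice;
  # uniformity is checked on the randomized PIT, the standard continuity
  # correction for discrete test statistics.
  g <- list(g1 = groove_definition("g1", 1:30))
  pit <- vapply(1:150, function(seed) {
    set.seed(seed + 5000)
    perturbed <- sample(1:100, 12)
    m <- map_perturbations(make_profile(1:100, perturbed), NULL, g)
    e <- groove_enrichment(m, n_permutations = 499, seed = seed)
    obs <- e$per_groove$n_perturbed_in_groove
    p_ge <- e$per_groove$permutation_p
    p_gt <- (1 + sum(e$null_counts[, 1] > obs)) / (1 + e$n_permutations)
    p_gt + runif(1) * (p_ge - p_gt)
  }, numeric(1))
  expect_true(all(pit > 0 & pit <= 1 + 1e-12))
  ks <- suppressWarnings(ks.test(pit, "punif"))
  expect_gt(ks$p.value, 0.05)
})

test_that("zero perturbed residues give fraction 0 and p = 1", {
  m <- map_perturbations(make_profile(1:20, integer()), NULL,
                         list(g = groove_definition("g", 1:5)))
  e <- groove_enrichment(m, 999, seed = 1)
  expect_equal(e$per_groove$fraction, 0)
  expect_equal(e$per_groove$permutation_p, 1)
})

test_that("B-factor painting marks perturbed residues", {
  d <- withr::local_tempdir()
  p <- make_ca_pdb(file.path(d, "s.pdb"), 1:6)
  s <- load_structure(p)
  out <- file.path(d, "painted.pdb")
  paint_perturbations(s, c(2, 5), out)
  b <- as.numeric(substr(grep("^ATOM", readLines(out), value = TRUE),
                         61, 66))
  expect_equal(b, c(0, 1, 0, 0, 1, 0))
})
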