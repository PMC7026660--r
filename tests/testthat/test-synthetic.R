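test_that("noise-free maps follow the exact power-law decay", {
  spec <- synth_spec(10, noise_level = 0, intra_tad_boost = 1,
                     decay_exponent = 1, scale = 100, seed = 1)
  M <- generate_contact_map(spec)$matrix
  lag <- abs(outer(1:10, 1:10, "-"))
  off <- upper.tri(M)
  expect_equal(M[off], 100 / lag[off])
  expect_equal(diag(M), rep(0, 10))
  ## determinism under a fixed seed, with noise
  spec2 <- synth_spec(10, noise_level = 0.2, seed = 42)
  expect_identical(generate_contact_map(spec2)$matrix,
                   generate_contact_map(spec2)$matrix)
  expect_error(synth_spec(4, n_chromosomes = 2), "3 loci")
  expect_error(synth_spec(10, tad_boundaries = c(5, 5)), "increasing")
})

test_that("intra-TAD boost enriches same-block contacts by the stated factor", {
  spec <- synth_spec(10, tad_boundaries = 5, noise_level = 0,
                     intra_tad_boost = 4, seed = 1)
  M <- generate_contact_map(spec)$matrix
  ## oracle from the generator's construction: lag-2 pairs inside a
  ## block vs the lag-2 pairs crossing the boundary
  intra <- c(M[1, 3], M[2, 4], M[3, 5], M[6, 8], M[7, 9], M[8, 10])
  cross <- c(M[4, 6], M[5, 7])
  expect_equal(mean(intra) / mean(cross), 4, tolerance = 1e-12)
})

test_that("generated maps pass contact-map validation and connectivity", {
  for (seed in 1:3) {
    spec <- synth_spec(45, n_chromosomes = 3, tad_boundaries = c(5, 20, 37),
                       noise_level = 0.3, seed = seed)
    m <- generate_contact_map(spec)
    expect_s3_class(m, "contact_map")       # symmetry/sign enforced there
    f <- filter_bins(m, scope = "chromosome")
    expect_equal(nrow(f$matrix), 45)        # connected per chromosome
  }
})

test_that("identity perturbation at zero strength reproduces the base", {
  base <- filter_bins(generate_contact_map(synth_spec(30, noise_level = 0.1,
                                                      seed = 4)))
  fam <- generate_cell_family(base,
                              list(planted_perturbation(1:5, integer(), "id")),
                              strength = 0, seed = 1)
  expect_equal(fam$id$matrix, base$matrix, tolerance = 1e-8)
})

test_that("a planted mode swap is recovered by Hungarian matching", {
  base <- filter_bins(generate_contact_map(
    synth_spec(60, tad_boundaries = c(20, 40), noise_level = 0.05,
               seed = 6)))
  fam <- generate_cell_family(base,
                              list(planted_perturbation(c(2, 1, 3, 4, 5),
                                                        integer(), "swap")),
                              strength = 0.1, seed = 2)
  f0 <- gnm(base, n_modes = 20)
  f1 <- gnm(fam$swap, n_modes = 20)
  mm <- match_modes(f0, f1, m = 5)
  expect_equal(mm$assignment, c(2L, 1L, 3L, 4L, 5L))
})

test_that("identity-permuted families share mobility profiles", {
  base <- filter_bins(generate_contact_map(
    synth_spec(50, tad_boundaries = c(15, 32), noise_level = 0.05, seed = 8)))
  perts <- lapply(1:3, function(i)
    planted_perturbation(integer(), integer(), paste0("c", i)))
  fam <- generate_cell_family(base, perts, strength = 0.05, seed = 3)
  profs <- lapply(fam, function(m)
    fluctuations(gnm(m, n_modes = 25), normalized = TRUE))
  expect_gt(profile_correlation(profs[[1]], profs[[2]]), 0.99)
  expect_gt(profile_correlation(profs[[1]], profs[[3]]), 0.99)
})

test_that("planted highly mobile loci top the relative-mobility ranking", {
  base <- filter_bins(generate_contact_map(
    synth_spec(80, tad_boundaries = c(25, 55), noise_level = 0.05,
               seed = 10)))
  perts <- list(planted_perturbation(integer(), c(40L), "hm"),
                planted_perturbation(integer(), integer(), "c1"),
                planted_perturbation(integer(), integer(), "c2"))
  fam <- generate_cell_family(base, perts, strength = 0.05, seed = 4)
  profs <- lapply(fam, function(m)
    fluctuations(gnm(m, n_modes = 40), normalized = TRUE))
  rel <- relative_mobility(profs)
  expect_equal(which.max(as.numeric(rel$hm)), 40L)
  expect_true(40L %in% call_hm_loci(rel$hm, 0.10))
})

test_that("gene annotations tile the bins deterministically", {
  ann <- generate_gene_annotation(10, bin_size = 1000, genes_per_bin = 1,
                                  seed = 5)
  expect_equal(nrow(ann), 10)
  expect_true(all(ann$start < ann$end))
  expect_false(any(duplicated(ann$gene)))
  ## byte-identical BED under a fixed seed
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_bed(generate_gene_annotation(10, 1000, 2, seed = 9), t1)
  write_bed(generate_gene_annotation(10, 1000, 2, seed = 9), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("HEG collections embed the true sets at the stated contamination", {
  hmgs <- list(cellA = paste0("G", 1:20), cellB = paste0("G", 21:40))
  universe <- paste0("G", 1:200)
  ## no contamination, no decoys: self-overlap dominates the collection
  coll0 <- generate_heg_collection(hmgs, universe, n_decoy_sets = 0,
                                   contamination = 0, seed = 1)
  res <- screen(hmgs$cellA, coll0, query_label = "cellA")
  expect_equal(res$self_rank, 1L)
  expect_equal(res$ranking$jaccard[1], 1)
  ## deterministic GMT output
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_gmt(generate_heg_collection(hmgs, universe, 5, 0.2, seed = 7), t1)
  write_gmt(generate_heg_collection(hmgs, universe, 5, 0.2, seed = 7), t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_error(generate_heg_collection(hmgs, universe, contamination = 0.6),
               "contamination")
})

test_that("decoy-only collections score at the hypergeometric baseline", {
  set.seed(15)
  universe <- paste0("G", 1:400)
  query <- sample(universe, 40)
  only_decoys <- generate_heg_collection(list(), universe,
                                         n_decoy_sets = 5, seed = 2)
  expect_length(only_decoys, 5)
  decoys <- lapply(1:50, function(i) sample(universe, 40))
  names(decoys) <- sprintf("d%02d", 1:50)
  J <- vapply(decoys, jaccard, 0, a = query)
  ## oracle: |intersection| ~ Hypergeometric(400, 40, 40)
  k <- stats::qhyper(c(0.001, 0.999)^(1 / 50), 40, 360, 40)
  bounds <- k / (80 - k)
  expect_gte(max(J), bounds[1])
  expect_lte(max(J), bounds[2])
  e_k <- 40 * 40 / 400
  expect_lt(abs(mean(J) - e_k / (80 - e_k)), 0.05)
})

test_that("structure embedding respects the contact geometry", {
  ## equal pairwise contacts -> equilateral triangle
  eq <- contact_map(matrix(1, 3, 3) - diag(3))
  s <- generate_structure(eq, k_const = 2, min_rho = -1)
  d <- as.matrix(dist(s$coords))
  off <- d[upper.tri(d)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-8)
  ## round trip preserves contact rank order on a structured map
  m <- generate_contact_map(synth_spec(40, tad_boundaries = c(12, 26),
                                       noise_level = 0, seed = 3))
  s2 <- generate_structure(m, k_const = 1)
  back <- structure_to_contacts(s2)$matrix
  up <- upper.tri(m$matrix) & m$matrix > 0
  expect_gt(cor(back[up], m$matrix[up], method = "spearman"), 0.8)
  ## deterministic coordinates
  s3 <- generate_structure(m, k_const = 1)
  expect_identical(s2$coords, s3$coords)
})
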