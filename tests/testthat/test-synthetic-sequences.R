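test_that("zero divergence yields identical clade members", {
  spec <- default_spec()
  tpl <- list(clade_template("CyR", "DTD", divergence = 0))
  refs <- gen_scaffold_refs(spec, tpl, n_refs_per_clade = 4, seed = 7)
  expect_length(unique(unname(refs$sequences)), 1L)
})

test_that("planted motifs round-trip through extract_motif against the truth table", {
  spec <- default_spec()
  tpl <- list(clade_template("CyR", "DTD"), clade_template("CyHR", "TSD"))
  refs <- gen_scaffold_refs(spec, tpl, n_refs_per_clade = 3, seed = 3)
  expect_equal(nrow(refs$truth), 6L)
  anchor <- refs$sequences[[1]]
  rmap <- reference_map(names(refs$sequences)[1], spec$site_map, spec$length)
  for (id in names(refs$sequences)) {
    mc <- extract_motif(refs$sequences[[id]], anchor, rmap)
    expect_identical(mc$motif_triplet,
                     refs$truth$motif_triplet[refs$truth$protein_id == id])
    expect_true(mc$schiff_lysine_present)
  }
})

test_that("within-clade p-distance is below between-clade p-distance", {
  spec <- default_spec()
  tpl <- list(clade_template("CyR", "DTD", divergence = 0.1),
              clade_template("XeR", "DTA", divergence = 0.1))
  within <- c(); between <- c()
  for (s in 1:20) {
    refs <- gen_scaffold_refs(spec, tpl, n_refs_per_clade = 2, seed = s)
    sq <- refs$sequences
    lab <- refs$truth$clade_label
    for (i in 1:3) for (j in (i + 1):4) {
      p <- hamming_p(sq[[i]], sq[[j]])
      if (lab[i] == lab[j]) within <- c(within, p) else between <- c(between, p)
    }
  }
  expect_lt(mean(within), mean(between))
})

test_that("generators are deterministic in the seed", {
  spec <- default_spec()
  tpl <- default_clade_templates()
  a <- gen_scaffold_refs(spec, tpl, 2, seed = 9)
  b <- gen_scaffold_refs(spec, tpl, 2, seed = 9)
  expect_identical(a, b)
  ga <- gen_genome_set(spec, tpl, n_genomes = 3, seed = 5)
  gb <- gen_genome_set(spec, tpl, n_genomes = 3, seed = 5)
  expect_identical(ga, gb)
  # and byte-identical FASTA on re-run
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(a$sequences, f1); write_fasta(b$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("genome-set truth table covers every protein exactly once", {
  spec <- default_spec()
  gs <- gen_genome_set(spec, default_clade_templates(), n_genomes = 4,
                       genes_per_genome = 2, decoys_per_genome = 3, seed = 2)
  all_ids <- unlist(lapply(gs$proteomes, names), use.names = FALSE)
  expect_setequal(gs$truth$protein_id, all_ids)
  expect_equal(anyDuplicated(gs$truth$protein_id), 0L)
  expect_equal(sum(gs$truth$is_rhodopsin), 8L)
  # decoys carry no Schiff-site lysine
  sm <- spec$site_map[["schiff_lysine"]]
  for (i in which(!gs$truth$is_rhodopsin)) {
    s <- gs$proteomes[[gs$truth$genome_id[i]]][[gs$truth$protein_id[i]]]
    expect_false(substr(s, sm, sm) == "K")
  }
})

test_that("habitat labels follow the template weights' support", {
  spec <- default_spec()
  tpl <- list(clade_template("CyR", "DTD",
                             habitat_weights = c(freshwater = 1)))
  gs <- gen_genome_set(spec, tpl, n_genomes = 8, seed = 4)
  expect_true(all(gs$genomes$habitat == "freshwater"))
})

test_that("flash-dataset noise has the declared variance and zero-noise is exact", {
  m <- photocycle_model()
  clean <- synth_difference_spectra(m)
  d0 <- gen_flash_dataset(m, noise_sigma = 0, seed = 1)
  expect_identical(d0$dA, clean$dA)
  sigma <- 0.003
  dn <- gen_flash_dataset(m, noise_sigma = sigma, seed = 8,
                          t = default_time_grid(n = 160))
  cleann <- synth_difference_spectra(m, t = default_time_grid(n = 160))
  resid <- dn$dA - cleann$dA
  expect_gte(length(resid), 1e4)
  expect_lt(abs(var(as.vector(resid)) - sigma^2) / sigma^2, 0.2)
  expect_identical(gen_flash_dataset(m, sigma, seed = 8)$dA,
                   gen_flash_dataset(m, sigma, seed = 8)$dA)
})

test_that("configuration errors are caught", {
  expect_error(scaffold_spec(site_map = c(acceptor = 74, hbond_partner = 74,
                                          donor = 85, counterion = 200,
                                          release1 = 182, release2 = 192,
                                          schiff_lysine = 204)),
               "distinct")
  expect_error(clade_template("CyR", "DTD", divergence = 0.8), "divergence")
  expect_error(gen_genome_set(default_spec(), list(), n_genomes = 2),
               "non-empty")
  expect_error(gen_titration_dataset(7, TRUE, ph_grid = c(3, 4, 5)),
               "at least 4")
})
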