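test_that("generators are deterministic under a fixed seed", {
  f1 <- generate_family(family_spec(seed = 3, members_per_class = 2,
                                    ancestor_length = 120))
  f2 <- generate_family(family_spec(seed = 3, members_per_class = 2,
                                    ancestor_length = 120))
  expect_identical(f1$records, f2$records)
  t1 <- generate_tree(3, seed = 8); t2 <- generate_tree(3, seed = 8)
  expect_identical(t1$newick, t2$newick)
  g1 <- generate_cds(make_records("MGLWHK"), seed = 2)
  g2 <- generate_cds(make_records("MGLWHK"), seed = 2)
  expect_identical(g1$record, g2$record)
})

test_that("family generator realizes its identity targets", {
  # 1 class, 2 members, 0.99 target: realized identity at least 0.96
  fam <- generate_family(family_spec(n_classes = 2, members_per_class = 2,
                                     ancestor_length = 300,
                                     within_identity = 0.99, seed = 21))
  cls1 <- fam$records[fam$records$class_label == "class1", ]
  expect_gte(hamming_identity(cls1$sequence[1], cls1$sequence[2]), 0.96)

  # realized within/between identities near the designed matrix
  fam2 <- generate_family(family_spec(n_classes = 3, members_per_class = 3,
                                      ancestor_length = 400, seed = 33))
  recs <- fam2$records
  for (pair in list(c(1, 2), c(1, 4), c(1, 7))) {
    got <- hamming_identity(recs$sequence[pair[1]], recs$sequence[pair[2]])
    i <- match(recs$class_label[pair[1]], paste0("class", 1:3))
    j <- match(recs$class_label[pair[2]], paste0("class", 1:3))
    # realized pairwise identity within 3 percentage points of design
    expect_lt(abs(got - fam2$truth$identity_matrix[i, j]), 0.03)
  }
})

test_that("feature-negative twins differ at exactly the ablated positions", {
  gs <- generate_cdh_set(1, plan = tibble::tibble(
    signal_peptide = TRUE, rossmann = TRUE, catalytic_his = TRUE,
    heme_ligands = TRUE, ydy = TRUE, cterm_extension = FALSE), seed = 66)
  pos <- gs$records[1, ]

  ab <- ablate_features(pos, "catalytic_his", gs$ref)
  diffs <- which(strsplit(pos$sequence, "")[[1]] !=
                   strsplit(ab$record$sequence, "")[[1]])
  expect_equal(diffs, 689)
  expect_equal(ab$positions, 689L)
  expect_equal(evaluate_record(ab$record, gs$ref)$verdict, "excluded")

  ab2 <- ablate_features(pos, c("signal_peptide", "heme_ligands"), gs$ref)
  expect_setequal(ab2$positions, c(7, 9, 11, 13, 15, 65))
  r2 <- evaluate_record(ab2$record, gs$ref)
  expect_false(r2$has_signal_peptide)
  expect_false(r2$has_heme_ligands)
})

test_that("generated CDS carries planted sites and survives the pipeline", {
  prot <- paste0("M", strrep("GLED", 60))
  g <- generate_cds(make_records(prot),
                    tibble::tibble(enzyme = "BsaI", codon_start = 50),
                    seed = 4)
  expect_equal(translate_cds(g$record$sequence), prot)
  planted <- g$truth$planted
  expect_equal(planted$codon_start, 50)
  found <- scan_restriction_sites(g$record)
  expect_true(planted$start %in% found$start)
  # every chance site is logged in the truth
  g0 <- generate_cds(make_records(prot), seed = 10)
  expect_identical(g0$truth$all_sites,
                   scan_restriction_sites(g0$record))
  # domestication of the output is clean and translation-preserving
  dom <- domesticate_cds(g$record)
  expect_equal(nrow(scan_restriction_sites(dom$cds)), 0)
  expect_equal(dom$protein, prot)
  # unrealizable planting errors out
  expect_error(generate_cds(make_records("MWWWWWWWWW"),
                            tibble::tibble(enzyme = "BsaI"), seed = 1),
               "not realizable")
})

test_that("assay simulation inverts through the activity calculator", {
  cfg <- assay_config("cytc550")
  sim <- simulate_assay(0.25, cfg, noise_sd = 0, seed = 9)
  expect_equal(volumetric_activity(sim$trace, cfg)$activity, 0.25,
               tolerance = 1e-12)
  # Monte-Carlo: mean recovered activity within 1% of truth
  acts <- vapply(1:100, function(k) {
    s <- simulate_assay(0.1, cfg, noise_sd = 0.002, n_points = 19,
                        duration_min = 3, seed = k)
    volumetric_activity(s$trace, cfg)$activity
  }, numeric(1))
  expect_equal(mean(acts), 0.1, tolerance = 0.01)
})

test_that("spectrum simulation plants recoverable band structure", {
  ox <- simulate_spectrum(state = "oxidized", seed = 1)
  expect_equal(ox$truth$soret_center, 420)
  red <- simulate_spectrum(state = "reduced", seed = 1)
  expect_equal(red$truth$soret_center, 429)
  sf <- spectral_features(ox$spectrum, red$spectrum)
  expect_equal(sf$soret$peak_nm[1], 420, tolerance = 1.5)
  expect_equal(sf$soret$peak_nm[2], 429, tolerance = 1.5)
})
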