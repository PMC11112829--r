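test_that("site scanning finds planted sites on both strands", {
  filler <- strrep("AC", 50)
  dna <- paste0(substr(filler, 1, 10), "GGTCTC", substr(filler, 17, 100))
  hits <- scan_restriction_sites(dna)
  bsa <- hits[hits$enzyme == "BsaI", ]
  expect_equal(nrow(bsa), 1)
  expect_equal(bsa$strand, "+")
  expect_equal(bsa$start0, 10)

  dna2 <- paste0(substr(filler, 1, 10), "GAGACC", substr(filler, 17, 100))
  bsa2 <- scan_restriction_sites(dna2)
  expect_equal(bsa2$enzyme, "BsaI")
  expect_equal(bsa2$strand, "-")

  # palindromic sites reported once
  dna3 <- paste0("AAAA", "GAGCTC", "TTTT")
  sac <- scan_restriction_sites(dna3)
  expect_equal(nrow(sac), 1)
  expect_equal(sac$strand, "+")

  # 50 planted sites at known offsets in a ~5 kb synthetic CDS
  prot <- paste(rep("GLELED", 300), collapse = "")
  plant <- tibble::tibble(enzyme = rep(c("BsaI", "SacI"), 25))
  g <- generate_cds(make_records(prot), plant, seed = 6)
  found <- scan_restriction_sites(g$record)
  planted <- g$truth$planted
  expect_true(all(planted$start %in% found$start))
  expect_gte(nrow(found), 50)
})

test_that("domestication removes sites synonymously and strips the stop", {
  # in-frame GGT CTC (Gly-Leu): one synonymous edit removes the BsaI site
  cds <- paste0("ATG", "GGTCTC", "TGGCACTAA")
  out <- domesticate_cds(cds)
  expect_equal(nrow(out$edits), 1)
  expect_equal(nrow(scan_restriction_sites(out$cds)), 0)
  expect_equal(translate_cds(out$cds), "MGLWH")
  expect_true(out$stop_removed)

  # site-free CDS returned unchanged except stop removal
  clean <- "ATGTGGCACCACTAA"
  out2 <- domesticate_cds(clean)
  expect_equal(out2$cds, "ATGTGGCACCAC")
  expect_equal(nrow(out2$edits), 0)

  # idempotence
  expect_equal(domesticate_cds(out$cds)$cds, out$cds)

  expect_error(domesticate_cds("ATGTAATGGTAA"), "internal stop")
  expect_error(domesticate_cds("ATGCC"), "divisible")

  # 20 seeded synthetic CDS with planted sites: always site-free,
  # translation preserved
  for (k in 1:20) {
    prot <- protein_with_cassette(300, seed = 8000 + k)
    n_sites <- (k %% 5) + 1
    enz <- sample(restriction_enzymes()$name, n_sites)
    g <- generate_cds(make_records(prot), cassette_sites(prot, enz),
                      seed = k)
    dom <- domesticate_cds(g$record)
    expect_equal(nrow(scan_restriction_sites(dom$cds)), 0)
    expect_equal(translate_cds(dom$cds), prot)
  }
})

test_that("fragment plans respect length limits and round-trip assembly", {
  gs <- generate_cdh_set(1, plan = tibble::tibble(
    signal_peptide = TRUE, rossmann = TRUE, catalytic_his = TRUE,
    heme_ligands = TRUE, ydy = TRUE, cterm_extension = FALSE), seed = 44)
  sp <- split_domains(gs$records[1, ], gs$ref)
  g <- generate_cds(gs$records[1, ],
                    tibble::tibble(enzyme = c("BsaI", "BbsI")), seed = 15)
  dom <- domesticate_cds(g$record)
  plan <- plan_fragments(dom$cds, sp_end = 23, dh_start = sp$dh_start)

  expect_true(all(plan$synth_length >= 300 & plan$synth_length <= 900))
  # short SP module is padded with a spacer
  expect_true(plan$spacer[plan$module == "SP"])
  expect_equal(plan$synth_length[plan$module == "SP"], 300)
  # the long DH module was subdivided at codon boundaries
  dh_rows <- plan[grepl("^DH", plan$module), ]
  expect_gte(nrow(dh_rows), 2)
  expect_true(all((dh_rows$cds_from - 1) %% 3 == 0))
  # overhang uniqueness and non-palindromicity
  oh <- c(plan$overhang5, plan$overhang3[nrow(plan)])
  expect_equal(anyDuplicated(oh), 0)

  va <- validate_assembly(plan)
  expect_true(va$valid)
  expect_equal(va$message, "assembly valid")
  expect_true(startsWith(va$product, paste0(dom$cds, "TAA")))
  orf <- substr(va$product, 1, nchar(dom$cds) + 3)
  expect_true(endsWith(translate_cds(orf), "*"))

  # shuffled fragment order gives the identical unique product
  set.seed(99)
  va2 <- validate_assembly(plan[sample(nrow(plan)), ])
  expect_equal(va2$product, va$product)

  # duplicate overhangs make ligation ambiguous
  bad <- plan
  bad$synth_sequence[2] <- bad$synth_sequence[1]
  expect_error(validate_assembly(bad), "[Aa]mbiguous")
})

test_that("fragment planning guards degenerate domain coordinates", {
  prot <- protein_with_cassette(250, seed = 5)
  g <- generate_cds(make_records(prot), seed = 77)
  dom <- domesticate_cds(g$record)
  expect_error(plan_fragments(dom$cds, sp_end = 0, dh_start = 50),
               "at least one codon")
  expect_error(plan_fragments(dom$cds, sp_end = 20, dh_start = 21),
               "at least one codon")
  expect_error(plan_fragments(paste0(dom$cds, "GGTCTC"), 20, 50),
               "forbidden|divisible")
})
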