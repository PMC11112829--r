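test_that("anchoring maps reference positions through indels", {
  # self-anchoring is the identity map
  a <- anchor_to_reference(REF$record, REF)
  expect_true(a$anchorable)
  expect_equal(a$identity, 1)
  expect_equal(a$landmarks$query_pos, c(65, 163, 689))

  # deleting 10 residues before the heme Met shifts its mapping to 55
  s <- REF$record$sequence[[1]]
  del <- paste0(substr(s, 1, 30), substr(s, 41, nchar(s)))
  q <- tibble::tibble(accession = "del10", sequence = del)
  ad <- anchor_to_reference(q, REF)
  expect_equal(ad$landmarks$query_pos[ad$landmarks$landmark == "heme_met"], 55)
  expect_equal(ad$landmarks$query_residue, c("M", "H", "H"))

  # random sequences are unanchorable
  for (k in 1:10) {
    r <- make_records(random_aa(810, seed = 900 + k))
    expect_false(anchor_to_reference(r, REF)$anchorable)
  }
})

test_that("signal peptide heuristic recovers planted SPs and rejects ablations", {
  gs <- generate_cdh_set(200, identity_to_ref = 0.85, seed = 77)
  calls <- vapply(seq_len(nrow(gs$records)), function(i) {
    predict_signal_peptide(gs$records[i, ])$pass
  }, logical(1))
  pos <- gs$truth$signal_peptide
  expect_gte(mean(calls[pos]), 0.95)        # recall on planted SPs
  expect_true(all(!calls[!pos]))            # ablated SPs always fail

  # poly-D N-terminus lacks a hydrophobic core
  polyD <- make_records(paste0("MK", strrep("D", 30), random_aa(100, 3)))
  expect_false(predict_signal_peptide(polyD)$pass)
  short <- make_records("MKFLSLVAVL")
  res <- predict_signal_peptide(short)
  expect_false(res$pass)
  expect_equal(res$reason, "too short")
})

test_that("criterion evaluation matches the planted ground truth", {
  gs <- generate_cdh_set(25, seed = 31)
  cur <- curate_dataset(gs$records, gs$ref)
  cmp <- dplyr::inner_join(cur$report, gs$truth, by = "accession")
  expect_equal(cmp$has_signal_peptide, cmp$signal_peptide)
  expect_equal(cmp$has_rossmann, cmp$rossmann)
  expect_equal(cmp$has_catalytic_his, cmp$catalytic_his)
  expect_equal(cmp$has_heme_ligands, cmp$heme_ligands)
  expect_true(all(cmp$has_cyt_domain))
  all_pass <- cmp$signal_peptide & cmp$rossmann & cmp$catalytic_his &
    cmp$heme_ligands
  expect_equal(cmp$verdict == "kept", all_pass)
  expect_true(all(nzchar(cmp$reasons[cmp$verdict == "excluded"])))

  # single planted violation: catalytic His -> Ala
  full <- gs$records[which(rowSums(!gs$truth[-1]) == 0)[1], ]
  mut <- full
  substr(mut$sequence, 689, 689) <- "A"
  rep1 <- evaluate_record(mut, gs$ref)
  expect_equal(rep1$verdict, "excluded")
  expect_match(rep1$reasons, "has_catalytic_his")

  # truncation to the DH domain loses Cyt evidence
  dh_only <- tibble::tibble(
    accession = "dhonly",
    sequence = substr(full$sequence, 256, nchar(full$sequence)))
  rep2 <- evaluate_record(dh_only, gs$ref)
  expect_equal(rep2$verdict, "excluded")
  expect_match(rep2$reasons, "has_cyt_domain")
  expect_match(rep2$reasons, "has_heme_ligands")
})

test_that("curation handles empty input and verdicts are order-independent", {
  empty <- tibble::tibble(accession = character(), sequence = character())
  out <- curate_dataset(empty, REF)
  expect_equal(nrow(out$kept), 0)

  gs <- generate_cdh_set(8, seed = 55)
  fwd <- curate_dataset(gs$records, gs$ref)$report
  rev <- curate_dataset(gs$records[nrow(gs$records):1, ], gs$ref)$report
  expect_equal(dplyr::arrange(fwd, accession), dplyr::arrange(rev, accession))
})

test_that("redundancy reduction returns the planted cluster count", {
  # two identical sequences -> one representative
  dup <- make_records(rep(random_aa(120, 8), 2))
  rr <- reduce_redundancy(dup, 0.99)
  expect_equal(nrow(rr$representatives), 1)
  expect_equal(rr$clusters$representative, c("R1", "R1"))

  # threshold 1.0 keeps every distinct sequence
  fam0 <- generate_family(family_spec(n_classes = 2, members_per_class = 3,
                                      ancestor_length = 150, seed = 3))
  expect_equal(nrow(reduce_redundancy(fam0$records, 1.0)$representatives),
               nrow(fam0$records))

  # 10 planted clusters of 5 at >= 99% within, far below across
  fam <- generate_family(family_spec(n_classes = 10, members_per_class = 5,
                                     ancestor_length = 300,
                                     within_identity = 0.992,
                                     sibling_branch = 0.3,
                                     backbone_step = 0.08, seed = 19))
  rr10 <- reduce_redundancy(fam$records, 0.99)
  expect_equal(nrow(rr10$representatives), 10)
  # no two representatives reach the threshold (brute-force all pairs)
  reps <- rr10$representatives
  for (i in 1:(nrow(reps) - 1)) for (j in (i + 1):nrow(reps)) {
    p <- Biostrings::pid(Biostrings::pairwiseAlignment(
      reps$sequence[i], reps$sequence[j], type = "global",
      substitutionMatrix = blosum62,
      gapOpening = 11, gapExtension = 1), type = "PID1") / 100
    expect_lt(p, 0.99)
  }
})

test_that("column trimming matches a brute-force recount", {
  aln <- c(paste0("AC-", "DEF"), paste0("AC-", "D-F"), paste0("A--", "DEF"))
  # column 3 gap fraction 1.0 -> removed; others kept
  out <- trim_alignment_columns(aln, 0.9)
  expect_equal(out$removed_columns, 3)

  # inclusive bound: a column at exactly the threshold is removed
  rows <- c(rep("A-A", 9), "AAA")  # column 2: 9/10 gaps
  expect_equal(trim_alignment_columns(rows, 0.9)$removed_columns, 2)
  # gap-free alignment unchanged
  clean <- c("ACD", "ACD")
  expect_equal(trim_alignment_columns(clean, 0.9)$alignment, clean)
  expect_error(trim_alignment_columns(c("AC", "A"), 0.9), "ragged")

  # random gapped alignment vs per-column recount
  set.seed(42)
  mat <- matrix(sample(c("A", "C", "-"), 20 * 50, replace = TRUE,
                       prob = c(0.3, 0.3, 0.4)), nrow = 20)
  aln2 <- apply(mat, 1, paste, collapse = "")
  out2 <- trim_alignment_columns(aln2, 0.9)
  manual <- which(colMeans(mat == "-") >= 0.9)
  expect_equal(out2$removed_columns, manual)
})

test_that("logo frequencies and information content match brute force", {
  # perfectly conserved region of identical records
  recs <- make_records(rep(REF$record$sequence, 3))
  logo <- build_logo(recs, REF, region = c(686, 692))
  cols <- tidy(logo)
  expect_true(all(cols$freq == 1))
  expect_equal(unique(cols$info), log2(20), tolerance = 1e-12)

  # planted 50/50 split at the catalytic column
  half <- REF$record$sequence[[1]]
  substr(half, 689, 689) <- "D"
  mix <- make_records(c(rep(REF$record$sequence, 3), rep(half, 3)))
  lg <- build_logo(mix, REF, region = c(689, 689))
  d <- tidy(lg)
  expect_setequal(d$residue, c("D", "H"))
  expect_equal(d$freq, c(0.5, 0.5))
  expect_equal(unique(d$info), log2(20) - 1, tolerance = 1e-12)

  # brute-force frequency recount on a mutated set
  gs <- generate_cdh_set(6, seed = 91)
  region <- c(260, 275)
  lg2 <- build_logo(gs$records, gs$ref, region)
  cols2 <- tidy(lg2)
  for (p in region[1]:region[2]) {
    res <- vapply(gs$records$sequence, function(s) substr(s, p, p),
                  character(1), USE.NAMES = FALSE)
    tab <- table(res) / length(res)
    sub <- cols2[cols2$position == p, ]
    expect_setequal(sub$residue, names(tab))
    expect_equal(sub$freq[match(names(tab), sub$residue)],
                 as.numeric(tab), tolerance = 1e-12)
  }
  expect_true(all(abs(tapply(cols2$freq, cols2$position, sum) - 1) < 1e-9))
})
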