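test_that("raw pair scores equal the exhaustive DP oracle on short inputs", {
  set.seed(11)
  for (k in 1:12) {
    a <- random_aa(sample(8:15, 1), seed = 300 + k)
    b <- random_aa(sample(8:15, 1), seed = 400 + k)
    got <- score_pair(make_records(a), make_records(b))
    want <- oracle_local_score(a, b, blosum62)
    expect_equal(got$raw_score, want, info = paste(a, b))
  }
})

test_that("pair scoring is symmetric, self-similar and rejects degenerate input", {
  x <- make_records(random_aa(300, seed = 1), "x")
  y <- make_records(random_aa(300, seed = 2), "y")
  xy <- score_pair(x, y); yx <- score_pair(y, x)
  expect_equal(xy$score, yx$score)
  expect_equal(xy$percent_identity, yx$percent_identity)

  self <- score_pair(x, x)
  expect_equal(self$percent_identity, 1.0)
  expect_lt(self$score, 1e-160)

  # unrelated random 300-mers never reach the loosest sweep cut-off
  for (k in 1:20) {
    p <- make_records(random_aa(300, seed = 500 + k), "p")
    q <- make_records(random_aa(300, seed = 600 + k), "q")
    expect_gt(score_pair(p, q)$score, 1e-40)
  }

  expect_error(score_pair(make_records("XXXX"), x), "unknown residues")
})

test_that("network construction keeps isolated nodes and thresholds edges", {
  s <- random_aa(100, seed = 9)  # below the 150-residue window: warns
  trip <- make_records(rep(s, 3))
  expect_warning(net <- build_network(trip, threshold = 1e-30), "150-1100")
  expect_equal(nrow(net$edges), 3)  # clique of duplicates

  two <- make_records(c(random_aa(300, seed = 21), random_aa(300, seed = 22)))
  net2 <- suppressWarnings(build_network(two, threshold = 1e-30))
  expect_equal(nrow(net2$nodes), 2)
  expect_equal(nrow(net2$edges), 0)
  expect_error(build_network(two[1, ]), "at least 2")

  # within-family edges match brute-force pairwise recomputation
  fam <- generate_family(family_spec(n_classes = 3, members_per_class = 4,
                                     ancestor_length = 200, seed = 5))
  net3 <- suppressWarnings(build_network(fam$records, threshold = 1e-20))
  recs <- fam$records
  for (i in 1:(nrow(recs) - 1)) for (j in (i + 1):nrow(recs)) {
    sc <- score_pair(recs[i, ], recs[j, ])$score
    in_edges <- any((net3$edges$a == recs$accession[i] &
                       net3$edges$b == recs$accession[j]) |
                      (net3$edges$a == recs$accession[j] &
                         net3$edges$b == recs$accession[i]))
    expect_equal(in_edges, sc <= 1e-20)
  }
})

test_that("sweep components split monotonically and report separation", {
  fam <- generate_family(family_spec(n_classes = 3, members_per_class = 4,
                                     ancestor_length = 250, seed = 13))
  net <- suppressWarnings(build_network(fam$records, threshold = 1e-5))
  cutoffs <- 10^seq(-10, -150, by = -20)
  groups <- split(fam$records$accession, fam$records$class_label)
  sw <- sweep_components(net, cutoffs, seed_groups = groups)

  counts <- glance(sw)$n_components
  expect_true(all(diff(counts) >= 0))  # ordered loosest -> strictest
  per_cut <- split(sw$components, sw$components$cutoff)
  for (pc in per_cut) {
    expect_equal(sort(pc$accession), sort(fam$records$accession))
    expect_equal(anyDuplicated(pc$accession), 0)
  }
  # the most distant class separates no later than the sibling classes
  sep <- sw$separation
  last <- fam$truth$separation_order[1]
  expect_true(sep$separation_cutoff[sep$group == last] >=
                max(sep$separation_cutoff[sep$group != last]))

  expect_error(sweep_components(net, c(1e-40, 1e-20)), "decreasing")
  expect_error(sweep_components(net, 1e-3), "build threshold")
})

test_that("sweep on an edgeless network yields singletons everywhere", {
  recs <- make_records(vapply(1:4, function(i) random_aa(300, 700 + i),
                              character(1)))
  net <- suppressWarnings(build_network(recs, threshold = 1e-60))
  sw <- sweep_components(net, c(1e-70, 1e-80))
  expect_true(all(glance(sw)$n_components == 4))
})

test_that("cluster extraction is seed-driven, closed and label-exact", {
  fam <- generate_family(family_spec(n_classes = 3, members_per_class = 4,
                                     ancestor_length = 250, seed = 23))
  net <- suppressWarnings(build_network(fam$records, threshold = 1e-5))
  co <- fam$truth$designed_cutoff
  seedsB <- fam$records$accession[fam$records$class_label == "class2"][1]
  got <- extract_cluster(net, co, seedsB)
  expect_setequal(got$accession,
                  fam$records$accession[fam$records$class_label == "class2"])
  # closure: no edge at the cutoff leaves the extracted set
  e <- net$edges[net$edges$score <= co, ]
  inside <- e$a %in% got$accession | e$b %in% got$accession
  expect_true(all(e$a[inside] %in% got$accession &
                    e$b[inside] %in% got$accession))

  # isolated seed -> singleton
  iso <- extract_cluster(net, 1e-300, seedsB)
  expect_true(nrow(iso) >= 1)
  expect_error(extract_cluster(net, co, "nope"), "nope")
})
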