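# Synthetic-data generators. Every generator is deterministic under its
# seed and returns the planted ground truth alongside the artifact, so the
# analysis modules can be validated against known answers.

mutate_sequence <- function(seq, divergence, protected = integer(0),
                            alphabet = AA_CANONICAL) {
  ch <- seq_chars(seq)
  eligible <- setdiff(seq_along(ch), protected)
  n_mut <- round(divergence * length(ch))
  n_mut <- min(n_mut, length(eligible))
  if (n_mut > 0) {
    pos <- sample(eligible, n_mut)
    ch[pos] <- vapply(ch[pos], function(r) sample(setdiff(alphabet, r), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

random_protein <- function(len) {
  paste(sample(AA_CANONICAL, len, replace = TRUE), collapse = "")
}

# Expected-score model for the designed separation cut-offs: the expected
# raw local-alignment score between homologs of fractional identity p and
# length L is approximately L (p m_diag + (1 - p) m_off) under the scoring
# matrix; converting through the bit-score gives the predicted AS.
predicted_as <- function(identity, len, params = scoring_params()) {
  m <- get_submat(params$matrix)
  aa <- AA_CANONICAL
  m <- m[aa, aa]
  m_diag <- mean(diag(m))
  m_off <- mean(m[upper.tri(m)])
  raw <- len * (identity * m_diag + (1 - identity) * m_off)
  bits_to_as(raw_to_bits(raw, params), len, len, params)
}

#' Specification for a planted-partition protein family
#'
#' Describes a synthetic dataset of several sequence classes diverged from
#' a common root along a caterpillar topology, emulating the nested
#' divergence of the four CDH classes: the last class in the list is the
#' most distant (splits at the root), the first two are sibling classes
#' splitting last. Pairwise identities are controlled by per-branch
#' divergences; the designed separation cut-offs for a similarity-network
#' sweep are derived a priori from the identity targets through the
#' expected-score model.
#'
#' @param n_classes Number of classes (>= 2).
#' @param members_per_class Sequences per class.
#' @param ancestor_length Root sequence length (residues).
#' @param within_identity Target pairwise identity inside a class.
#' @param sibling_branch Divergence of each terminal class branch.
#' @param backbone_step Divergence of each backbone step between
#'   successive class splits.
#' @param seed Random seed; all randomness flows from it.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_classes = 4, members_per_class = 5,
                        ancestor_length = 300, within_identity = 0.85,
                        sibling_branch = 0.25, backbone_step = 0.15,
                        seed = 1) {
  stopifnot(n_classes >= 2, members_per_class >= 1,
            within_identity > 0, within_identity < 1)
  structure(list(n_classes = n_classes,
                 members_per_class = members_per_class,
                 ancestor_length = ancestor_length,
                 within_identity = within_identity,
                 sibling_branch = sibling_branch,
                 backbone_step = backbone_step,
                 seed = seed),
            class = "family_spec")
}

#' Generate a planted-partition protein family
#'
#' Realizes a [family_spec()]: class ancestors are produced by point
#' mutations along the caterpillar topology, members by further mutations
#' below each ancestor so that realized within-class identities land near
#' `within_identity` (each member diverges `1 - sqrt(within_identity)`
#' from its ancestor). No indels are introduced, so planted coordinates
#' stay exact.
#'
#' @param spec A [family_spec()].
#' @return A list: `records` (tibble `accession`, `sequence`,
#'   `class_label`) and `truth` with the class labels, the class-ancestor
#'   identity matrix (designed), the predicted between/within AS and the
#'   `designed_cutoff` at which the partition should be exactly
#'   recoverable, plus the designed separation order (most distant class
#'   first).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    C <- spec$n_classes
    root <- random_protein(spec$ancestor_length)
    # caterpillar: class C splits at the root, C-1 one step later, ...,
    # classes 1 and 2 are siblings at the last backbone node
    n_backbone <- C - 1
    backbone <- vector("list", n_backbone)
    backbone[[1]] <- root
    if (n_backbone > 1) {
      for (k in 2:n_backbone) {
        backbone[[k]] <- mutate_sequence(backbone[[k - 1]], spec$backbone_step)
      }
    }
    anc_node <- c(n_backbone, n_backbone, rev(seq_len(n_backbone))[-1])[1:C]
    # classes splitting earlier also get longer terminal branches, so the
    # distance order (last class most distant) is strict
    extra_branch <- spec$sibling_branch +
      spec$backbone_step * (n_backbone - anc_node)
    ancestors <- lapply(seq_len(C), function(cl) {
      mutate_sequence(backbone[[anc_node[cl]]], extra_branch[cl])
    })
    member_div <- 1 - sqrt(spec$within_identity)
    records <- purrr::map_dfr(seq_len(C), function(cl) {
      tibble::tibble(
        accession = sprintf("C%02d_M%02d", cl, seq_len(spec$members_per_class)),
        sequence = vapply(seq_len(spec$members_per_class), function(i) {
          mutate_sequence(ancestors[[cl]], member_div)
        }, character(1)),
        class_label = sprintf("class%d", cl))
    })
    # designed identity between class ancestors from the branch structure
    depth_from <- function(cl) anc_node[cl]
    id_anc <- matrix(1, C, C)
    for (i in seq_len(C)) for (j in seq_len(C)) {
      if (i == j) next
      shared <- min(depth_from(i), depth_from(j))
      steps <- abs(depth_from(i) - depth_from(j))
      id_anc[i, j] <- (1 - spec$backbone_step)^steps *
        (1 - extra_branch[i]) * (1 - extra_branch[j])
    }
    id_members <- id_anc * spec$within_identity
    diag(id_members) <- spec$within_identity
    # coincidence correction: diverged positions still match 1/19 of the
    # time under uniform replacement
    id_members <- id_members + (1 - id_members) / 19
    closest_between <- max(id_members[upper.tri(id_members)])
    as_within <- predicted_as(spec$within_identity, spec$ancestor_length)
    as_between <- predicted_as(closest_between, spec$ancestor_length)
    designed_cutoff <- exp(mean(log(c(as_within, as_between))))
    # separation order: most distant (lowest max identity to others) first
    max_id_to_others <- vapply(seq_len(C), function(i) {
      max(id_members[i, -i])
    }, numeric(1))
    truth <- list(
      class_labels = stats::setNames(records$class_label, records$accession),
      identity_matrix = id_members,
      predicted_as_within = as_within,
      predicted_as_between = as_between,
      designed_cutoff = designed_cutoff,
      separation_order = sprintf("class%d", order(max_id_to_others)))
    list(records = records, truth = truth)
  })
}

FEATURE_NAMES <- c("signal_peptide", "rossmann", "catalytic_his",
                   "heme_ligands", "ydy", "cterm_extension")

#' Generate a curated-feature CDH-like sequence set
#'
#' Derives `n` sequences from the synthetic reference root by background
#' point mutations (never touching the landmark coordinates), then applies
#' targeted single-point ablations according to the feature plan:
#' poisoning the signal-peptide h-region with aspartates, mutating a
#' required Rossmann glycine, the catalytic His, the heme Met, or the YDY
#' anchor; members with `cterm_extension` get extra random residues
#' appended. A feature-negative member differs from its feature-positive
#' form only at the ablated positions. When `rossmann` or `ydy` is
#' ablated, accidental motif re-occurrences near the landmark are also
#' scrubbed so that the planted truth is unambiguous.
#'
#' @param n Number of sequences.
#' @param plan Optional tibble with logical columns from
#'   `signal_peptide`, `rossmann`, `catalytic_his`, `heme_ligands`,
#'   `ydy`, `cterm_extension` (recycled/defaulted to TRUE); by default
#'   each feature is ablated independently with probability
#'   `ablation_rate`.
#' @param identity_to_ref Background identity target to the reference.
#' @param ablation_rate Per-feature ablation probability for the default
#'   plan.
#' @param cterm_len Length of the C-terminal extension when planted.
#' @param ref A `cdh_reference` whose record is the root (default
#'   [synthetic_reference()]).
#' @param seed Random seed.
#' @return A list: `records`, `truth` (tibble `accession` + one logical
#'   column per feature), `ref`.
#' @export
generate_cdh_set <- function(n, plan = NULL, identity_to_ref = 0.85,
                             ablation_rate = 0.15, cterm_len = 50,
                             ref = synthetic_reference(), seed = 1) {
  with_seed(seed, {
    root <- ref$record$sequence[[1]]
    rlen <- nchar(root)
    ross <- ref$rossmann_start
    ydy <- regexpr(ref$linker_anchor_motif, root, fixed = TRUE)[[1]]
    protected <- c(1:23, ref$heme_met_pos, ref$heme_his_pos,
                   ref$catalytic_his_pos, ydy:(ydy + 2), ross:(ross + 5))
    if (is.null(plan)) {
      plan <- tibble::as_tibble(stats::setNames(
        lapply(FEATURE_NAMES, function(f) stats::runif(n) > ablation_rate),
        FEATURE_NAMES))
      plan$cterm_extension <- stats::runif(n) < 0.3
    } else {
      plan <- tibble::as_tibble(plan)
      for (f in FEATURE_NAMES) if (!f %in% names(plan)) plan[[f]] <- TRUE
      stopifnot(nrow(plan) == n)
    }
    div <- 1 - identity_to_ref
    sp_poison <- c(7L, 9L, 11L, 13L, 15L)
    records <- purrr::map_dfr(seq_len(n), function(i) {
      s <- mutate_sequence(root, div, protected = protected)
      ch <- seq_chars(s)
      if (!plan$signal_peptide[i]) ch[sp_poison] <- "D"
      if (!plan$rossmann[i]) ch[ross + 2] <- "A"
      if (!plan$catalytic_his[i]) ch[ref$catalytic_his_pos] <- "A"
      if (!plan$heme_ligands[i]) ch[ref$heme_met_pos] <- "A"
      if (!plan$ydy[i]) ch[ydy + 1] <- "A"
      s <- paste(ch, collapse = "")
      if (!plan$rossmann[i]) {
        # scrub chance GxGxxG occurrences in the searched neighborhood
        win <- max(1, ross - 20):min(rlen, ross + 25)
        repeat {
          sub <- substr(s, win[1], win[length(win)])
          m <- regexpr("G.G..G", sub)[[1]]
          if (m < 0) break
          hit <- win[1] + m - 1
          substr(s, hit, hit) <- sample(setdiff(AA_CANONICAL, "G"), 1)
        }
      }
      if (!plan$ydy[i]) {
        win_lo <- max(1, ydy - 30); win_hi <- min(rlen - 2, ydy + 30)
        repeat {
          sub <- substr(s, win_lo, win_hi + 2)
          m <- regexpr("YDY", sub, fixed = TRUE)[[1]]
          if (m < 0) break
          hit <- win_lo + m - 1
          substr(s, hit + 1, hit + 1) <- sample(setdiff(AA_CANONICAL, "D"), 1)
        }
      }
      if (plan$cterm_extension[i]) s <- paste0(s, random_protein(cterm_len))
      tibble::tibble(accession = sprintf("SYN%04d", i), sequence = s)
    })
    truth <- dplyr::bind_cols(tibble::tibble(accession = records$accession),
                              plan)
    list(records = records, truth = truth, ref = ref)
  })
}

#' Ablate planted features in a CDH-like sequence
#'
#' Applies the targeted single-point ablations used by
#' [generate_cdh_set()] to an existing sequence, producing the
#' feature-negative twin of a feature-positive record: the two differ at
#' exactly the returned positions. For `rossmann` and `ydy` the scrub of
#' chance motif re-occurrences near the landmark may add a few recorded
#' single-point changes.
#'
#' @param record One-row record tibble.
#' @param features Character vector of features to ablate (subset of
#'   `signal_peptide`, `rossmann`, `catalytic_his`, `heme_ligands`,
#'   `ydy`).
#' @param ref The `cdh_reference` the coordinates refer to.
#' @param seed Seed for the scrub replacements.
#' @return A list: `record` (ablated) and `positions` (integer vector of
#'   changed positions).
#' @export
ablate_features <- function(record, features, ref = synthetic_reference(),
                            seed = 1) {
  stopifnot(all(features %in% FEATURE_NAMES))
  s <- record$sequence[[1]]
  ross <- ref$rossmann_start
  ydy <- regexpr(ref$linker_anchor_motif, ref$record$sequence[[1]],
                 fixed = TRUE)[[1]]
  with_seed(seed, {
    ch <- seq_chars(s)
    if ("signal_peptide" %in% features) ch[c(7, 9, 11, 13, 15)] <- "D"
    if ("rossmann" %in% features) ch[ross + 2] <- "A"
    if ("catalytic_his" %in% features) ch[ref$catalytic_his_pos] <- "A"
    if ("heme_ligands" %in% features) ch[ref$heme_met_pos] <- "A"
    if ("ydy" %in% features) ch[ydy + 1] <- "A"
    out <- paste(ch, collapse = "")
    if ("rossmann" %in% features) {
      win <- max(1, ross - 20):min(nchar(out), ross + 25)
      repeat {
        sub <- substr(out, win[1], win[length(win)])
        m <- regexpr("G.G..G", sub)[[1]]
        if (m < 0) break
        hit <- win[1] + m - 1
        substr(out, hit, hit) <- sample(setdiff(AA_CANONICAL, "G"), 1)
      }
    }
    if ("ydy" %in% features) {
      lo <- max(1, ydy - 30); hi <- min(nchar(out) - 2, ydy + 30)
      repeat {
        sub <- substr(out, lo, hi + 2)
        m <- regexpr("YDY", sub, fixed = TRUE)[[1]]
        if (m < 0) break
        substr(out, lo + m, lo + m) <- sample(setdiff(AA_CANONICAL, "D"), 1)
      }
    }
    changed <- which(seq_chars(s) != seq_chars(out))
    rec <- record
    rec$sequence <- out
    list(record = rec, positions = changed)
  })
}

#' Generate a clade-structured random tree
#'
#' Builds a tree of `n_clades` subtrees whose internal nodes sit beyond
#' `threshold + margin` from the root while leaves stay within
#' `within_depth` of their clade node — so a distance cut at `threshold`
#' recovers exactly the planted clades. With a single clade the tree is a
#' shallow star and the cut returns one clade.
#'
#' @param n_clades Number of planted clades.
#' @param leaves_per_clade Leaves per clade (recycled).
#' @param threshold Distance threshold the tree is designed around.
#' @param margin How far beyond the threshold each clade node sits.
#' @param within_depth Maximum leaf depth below its clade node.
#' @param seed Random seed.
#' @return A list: `newick` (string), `tree` (`phylo`), `truth` (tibble
#'   `accession`, `clade`).
#' @export
generate_tree <- function(n_clades, leaves_per_clade = 4, threshold = 0.4,
                          margin = 0.2, within_depth = 0.05, seed = 1) {
  stopifnot(n_clades >= 1)
  leaves_per_clade <- rep_len(leaves_per_clade, n_clades)
  with_seed(seed, {
    subtree <- function(k) {
      leaves <- sprintf("clade%02d_t%02d", k, seq_len(leaves_per_clade[k]))
      bl <- stats::runif(length(leaves), within_depth / 5, within_depth)
      inner <- paste(sprintf("%s:%.5f", leaves, bl), collapse = ",")
      if (n_clades == 1) {
        sprintf("(%s);", inner)
      } else {
        sprintf("(%s):%.5f", inner, threshold + margin)
      }
    }
    newick <- if (n_clades == 1) subtree(1) else
      sprintf("(%s);", paste(vapply(seq_len(n_clades), subtree, character(1)),
                             collapse = ","))
    tree <- ape::read.tree(text = newick)
    truth <- purrr::map_dfr(seq_len(n_clades), function(k) {
      tibble::tibble(
        accession = sprintf("clade%02d_t%02d", k, seq_len(leaves_per_clade[k])),
        clade = k)
    })
    list(newick = newick, tree = tree, truth = truth)
  })
}

#' Reverse-translate a protein with planted restriction sites
#'
#' Samples a codon uniformly for every residue, then plants each requested
#' recognition site by synonymous codon rewrites at a feasible,
#' codon-compatible position (a stated `codon_start` is honored when
#' feasible; otherwise a seeded random feasible position is chosen).
#' Translation always equals the input protein; chance occurrences of any
#' recognition site are logged in the truth alongside the planted ones.
#'
#' @param protein One-row record tibble (or string) to reverse-translate.
#' @param planted_sites Tibble with column `enzyme` and optional
#'   `codon_start` (1-based codon index, NA for automatic placement);
#'   `NULL` plants nothing.
#' @param enzymes Enzyme tibble (see [restriction_enzymes()]).
#' @param seed Random seed.
#' @return A list: `record` (tibble `accession`, `sequence`), `truth`
#'   (list with `planted` tibble `enzyme`, `start` (1-based nt),
#'   `codon_start` and `all_sites`, the full scan of the output).
#' @export
generate_cds <- function(protein, planted_sites = NULL,
                         enzymes = restriction_enzymes(), seed = 1) {
  prot <- if (is.data.frame(protein)) protein$sequence[[1]] else protein
  acc <- if (is.data.frame(protein)) protein$accession[[1]] else "cds1"
  prot <- toupper(prot)
  gc <- genetic_code()
  with_seed(seed, {
    codons <- vapply(seq_chars(prot), function(aa) {
      cands <- names(gc)[gc == aa]
      if (length(cands) == 0) abort_param(sprintf("no codon for residue %s", aa))
      sample(cands, 1)
    }, character(1), USE.NAMES = FALSE)

    planted <- tibble::tibble(enzyme = character(), start = integer(),
                              codon_start = integer())
    occupied <- integer(0)
    if (!is.null(planted_sites) && nrow(planted_sites) > 0) {
      if (!"codon_start" %in% names(planted_sites)) {
        planted_sites$codon_start <- NA_integer_
      }
      for (r in seq_len(nrow(planted_sites))) {
        enz <- planted_sites$enzyme[r]
        recog <- enzymes$recognition[match(enz, enzymes$name)]
        if (is.na(recog)) abort_param(sprintf("unknown enzyme %s", enz))
        want_codon <- planted_sites$codon_start[r]
        nt_offsets <- if (!is.na(want_codon)) {
          (want_codon - 1L) * 3L + 1:3
        } else {
          sample(seq_len(nchar(prot) * 3 - nchar(recog)))
        }
        res <- NULL
        for (o in nt_offsets) {
          span <- o:(o + nchar(recog) - 1L)
          if (any(span %in% occupied) || max(span) > length(codons) * 3) next
          res <- try_plant(codons, gc, recog, o)
          if (!is.null(res)) {
            codons <- res
            occupied <- c(occupied, span)
            planted <- dplyr::bind_rows(planted, tibble::tibble(
              enzyme = enz, start = o,
              codon_start = (o - 1L) %/% 3L + 1L))
            break
          }
        }
        if (is.null(res)) {
          abort_param(sprintf(
            "site %s not realizable by synonymous choice%s", enz,
            if (is.na(want_codon)) "" else sprintf(" at codon %d", want_codon)))
        }
      }
    }
    cds <- paste(codons, collapse = "")
    stopifnot(translate_cds(cds) == prot)
    record <- tibble::tibble(accession = acc, sequence = cds)
    list(record = record,
         truth = list(planted = planted,
                      all_sites = scan_restriction_sites(cds, enzymes)))
  })
}

# attempt to realize `recog` at nt offset `o` purely by synonymous codon
# substitutions; returns the modified codon vector or NULL
try_plant <- function(codons, gc, recog, o) {
  span <- o:(o + nchar(recog) - 1L)
  cidx <- unique((span - 1L) %/% 3L + 1L)
  if (length(cidx) > 4) return(NULL)
  syns <- lapply(cidx, function(ci) sort(names(gc)[gc == gc[[codons[ci]]]]))
  grid <- expand.grid(syns, stringsAsFactors = FALSE)
  region_start <- (cidx[1] - 1L) * 3L + 1L
  rel <- o - region_start + 1L
  for (g in seq_len(nrow(grid))) {
    combo <- as.character(grid[g, ])
    region <- paste(combo, collapse = "")
    if (substr(region, rel, rel + nchar(recog) - 1L) == recog) {
      out <- codons
      out[cidx] <- combo
      return(out)
    }
  }
  NULL
}

#' Simulate a linear assay trace
#'
#' Inverts the volumetric-activity model: the true slope is
#' `activity * extinction * path * sample_fraction / dilution` and the
#' trace is that line plus Gaussian noise.
#'
#' @param true_activity True volumetric activity (U mL^-1, >= 0).
#' @param cfg An [assay_config()].
#' @param noise_sd Gaussian noise on each absorbance point (AU).
#' @param n_points Number of trace points.
#' @param duration_min Trace duration (minutes; the standard runs cover
#'   3 min).
#' @param dilution,sample_fraction Sample handling factors, as in
#'   [volumetric_activity()].
#' @param a0 Starting absorbance.
#' @param seed Random seed.
#' @return A list: `trace` (tibble `time_min`, `absorbance`), `truth`
#'   (list `slope`, `activity`).
#' @export
simulate_assay <- function(true_activity, cfg = assay_config(),
                           noise_sd = 0, n_points = 19, duration_min = 3,
                           dilution = 1, sample_fraction = 1, a0 = 0.1,
                           seed = 1) {
  if (true_activity < 0) abort_param("true activity must be non-negative")
  if (noise_sd < 0) abort_param("noise_sd must be non-negative")
  slope <- true_activity * cfg$extinction * cfg$path * sample_fraction / dilution
  with_seed(seed, {
    t <- seq(0, duration_min, length.out = n_points)
    abs_ <- a0 + slope * t + stats::rnorm(n_points, 0, noise_sd)
    list(trace = tibble::tibble(time_min = t, absorbance = abs_),
         truth = list(slope = slope, activity = true_activity))
  })
}

gaussian_band <- function(wl, center, sd, amp) {
  amp * exp(-((wl - center)^2) / (2 * sd^2))
}

#' Simulate an enzyme UV-Vis spectrum
#'
#' Sum of Gaussian bands: aromatic protein band at 280 nm, heme b Soret
#' band at 420 nm (oxidized) or 429 nm (reduced) scaled by `heme`, flavin
#' band at 450 nm scaled by `occupancy`, and alpha/beta bands (562/530 nm)
#' added in the reduced state.
#'
#' @param a280 Protein band amplitude (AU).
#' @param occupancy FAD occupancy in \[0, 1\].
#' @param heme Heme content in \[0, 1\] (0 for an isolated DH domain).
#' @param state `"oxidized"` or `"reduced"`.
#' @param noise_sd Gaussian noise (AU).
#' @param seed Random seed.
#' @return A list: `spectrum` (tibble `wavelength`, `absorbance`,
#'   250-700 nm at 1 nm), `truth` (band centers and amplitudes).
#' @export
simulate_spectrum <- function(a280 = 1.5, occupancy = 1, heme = 1,
                              state = c("oxidized", "reduced"),
                              noise_sd = 0, seed = 1) {
  state <- match.arg(state)
  stopifnot(occupancy >= 0, occupancy <= 1, heme >= 0, heme <= 1)
  soret_center <- if (state == "oxidized") 420 else 429
  with_seed(seed, {
    wl <- 250:700
    soret_amp <- 0.45 * heme * a280 / 1.5
    flavin_amp <- 0.12 * occupancy * a280 / 1.5
    y <- gaussian_band(wl, 280, 22, a280) +
      gaussian_band(wl, soret_center, 11, soret_amp) +
      gaussian_band(wl, 450, 28, flavin_amp)
    if (state == "reduced") {
      y <- y + gaussian_band(wl, 562, 7, 0.22 * heme * a280 / 1.5) +
        gaussian_band(wl, 530, 9, 0.15 * heme * a280 / 1.5)
    }
    if (noise_sd > 0) y <- y + stats::rnorm(length(wl), 0, noise_sd)
    list(spectrum = tibble::tibble(wavelength = wl, absorbance = y),
         truth = list(soret_center = if (heme > 0) soret_center else NA_real_,
                      soret_amp = soret_amp, flavin_amp = flavin_amp,
                      a280 = a280, state = state))
  })
}

#' Simulate a multi-step purification scenario
#'
#' Builds a step table with known true yields and purification factors:
#' step k keeps `recoveries[k]` of the previous step's total activity and
#' its specific activity is `purities[k]` times the supernatant's.
#' Assays listed in `bdl_assays` report `"b.d.l."` after the supernatant.
#'
#' @param recoveries Per-step activity recoveries in (0, 1\], one per
#'   post-supernatant step.
#' @param purities Per-step purification factors (non-decreasing, >= 1).
#' @param reference_totals Named vector of supernatant total activities
#'   per assay (U), e.g. `c(dcip = 946, cytc = 47)`.
#' @param total_protein_ref Supernatant total protein (mg).
#' @param volume_ref Supernatant volume (mL).
#' @param bdl_assays Assays below detection limit after the supernatant.
#' @param noise_sd Multiplicative lognormal noise on measured totals.
#' @param seed Random seed.
#' @return A list: `steps` (tibble for [purification_table()]), `truth`
#'   (tibble `step`, `assay`, `yield_pct`, `purification_factor`,
#'   `specific_activity`, `total_protein`).
#' @export
simulate_purification <- function(recoveries, purities,
                                  reference_totals = c(dcip = 946),
                                  total_protein_ref = 1310,
                                  volume_ref = 4500,
                                  bdl_assays = character(),
                                  noise_sd = 0, seed = 1) {
  stopifnot(all(recoveries > 0), all(recoveries <= 1),
            length(purities) == length(recoveries),
            !is.unsorted(purities), all(purities >= 1))
  n_steps <- length(recoveries)
  assays <- names(reference_totals)
  with_seed(seed, {
    labels <- c("Supernatant", sprintf("Step%d", seq_len(n_steps)))
    cum_rec <- cumprod(recoveries)
    spec_ref <- reference_totals / total_protein_ref
    total_act <- lapply(assays, function(a) {
      c(reference_totals[[a]], reference_totals[[a]] * cum_rec)
    })
    names(total_act) <- assays
    # protein follows the dcip-equivalent first assay's totals and purity
    lead <- assays[1]
    total_protein <- c(total_protein_ref,
                       total_act[[lead]][-1] / (spec_ref[[lead]] * purities))
    volume <- volume_ref / 3^(0:n_steps)
    steps <- tibble::tibble(step = labels, volume = volume,
                            conc = total_protein / volume,
                            total_protein = total_protein)
    truth_rows <- list()
    for (a in assays) {
      vals <- total_act[[a]]
      if (noise_sd > 0) {
        vals[-1] <- vals[-1] * exp(stats::rnorm(n_steps, 0, noise_sd))
      }
      col <- as.character(signif(vals, 12))
      if (a %in% bdl_assays && n_steps > 0) col[-1] <- "b.d.l."
      steps[[paste0("total_activity_", a)]] <- col
      truth_rows[[a]] <- tibble::tibble(
        step = labels, assay = a,
        yield_pct = 100 * c(1, cum_rec),
        purification_factor = c(1, purities),
        specific_activity = total_act[[a]] / total_protein,
        total_protein = total_protein)
    }
    list(steps = steps, truth = dplyr::bind_rows(truth_rows))
  })
}
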