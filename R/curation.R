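#' Anchor a query sequence to the annotated reference
#'
#' Global (Needleman-Wunsch, affine-gap) alignment of the query to the
#' reference, returning a per-position map from reference coordinates to
#' query coordinates (NA where the reference position aligns to a gap).
#' Queries whose alignment identity falls below the reference's
#' `identity_floor` are flagged unanchorable; criteria that rely on the map
#' then report unknown.
#'
#' @param query One-row record tibble.
#' @param ref A `cdh_reference` (see [reference_annotation()]).
#' @param params A [scoring_params()] configuration.
#' @return A list of class `cdh_anchor`: `accession`, `identity`,
#'   `anchorable`, `map` (integer vector over reference positions),
#'   `landmarks` (tibble of annotated positions with mapped query positions
#'   and query residues), and the two aligned strings.
#' @export
anchor_to_reference <- function(query, ref, params = scoring_params()) {
  stopifnot(inherits(ref, "cdh_reference"))
  qs <- toupper(query$sequence[[1]])
  if (nchar(qs) < 100) abort_param("query shorter than 100 residues")
  aln <- global_align(qs, ref$record$sequence[[1]], params)
  anchorable <- aln$identity >= ref$identity_floor
  map <- if (anchorable) alignment_position_map(aln$query, aln$ref) else NULL
  landmarks <- NULL
  if (anchorable) {
    pos <- c(heme_met = ref$heme_met_pos, heme_his = ref$heme_his_pos,
             catalytic_his = ref$catalytic_his_pos)
    qpos <- map[pos]
    landmarks <- tibble::tibble(
      landmark = names(pos), ref_pos = unname(pos),
      query_pos = unname(qpos),
      query_residue = ifelse(is.na(qpos), NA_character_,
                             substring(qs, qpos, qpos)))
  }
  structure(list(accession = query$accession[[1]], identity = aln$identity,
                 anchorable = anchorable, map = map, landmarks = landmarks,
                 query_aln = aln$query, ref_aln = aln$ref, query_seq = qs),
            class = "cdh_anchor")
}

# query positions aligned to a reference interval (non-NA map entries)
mapped_positions <- function(anchor, ref_from, ref_to) {
  idx <- ref_from:min(ref_to, length(anchor$map))
  p <- anchor$map[idx]
  p[!is.na(p)]
}

#' Evaluate the functional-candidate criteria for one sequence
#'
#' Applies the five curation criteria used to triage putative class III
#' CDHs: (i) a predicted signal peptide, (ii) the FAD-binding Rossmann
#' consensus `GxGxxG` in the query region aligned to the reference Rossmann
#' neighborhood, (iii) a His at the query position mapped from the
#' reference catalytic His, (iv) an N-terminal cytochrome domain (at least
#' `cyt_min_coverage` of the reference Cyt region aligned, without gaps, to
#' query positions preceding the DH start), and (v) Met/His at the mapped
#' heme-ligand positions. The verdict is `kept` only when all five pass;
#' unanchorable queries report unknown (NA) for the alignment-based flags
#' and are excluded with reason `unanchorable`.
#'
#' @param query One-row record tibble.
#' @param ref A `cdh_reference`.
#' @param signalp Optional external prediction tibble (`accession`,
#'   `has_signal_peptide`) overriding the built-in heuristic.
#' @param rossmann_window Columns around the reference Rossmann start
#'   searched for the motif.
#' @param cyt_min_coverage Minimum aligned fraction of the reference Cyt
#'   region for criterion (iv).
#' @param params A [scoring_params()] configuration.
#' @return A one-row curation-report tibble.
#' @export
evaluate_record <- function(query, ref, signalp = NULL, rossmann_window = 15,
                            cyt_min_coverage = 0.6,
                            params = scoring_params()) {
  acc <- query$accession[[1]]
  sp_flag <- if (!is.null(signalp) && acc %in% signalp$accession) {
    signalp$has_signal_peptide[match(acc, signalp$accession)]
  } else {
    predict_signal_peptide(query)$pass
  }
  anchor <- anchor_to_reference(query, ref, params)
  if (!anchor$anchorable) {
    flags <- c(has_signal_peptide = sp_flag, has_rossmann = NA,
               has_catalytic_his = NA, has_cyt_domain = NA,
               has_heme_ligands = NA)
    return(report_row(acc, anchor$identity, FALSE, flags,
                      extra_reason = "unanchorable"))
  }
  qs <- anchor$query_seq
  lm <- anchor$landmarks
  res_at <- function(landmark) {
    lm$query_residue[lm$landmark == landmark]
  }
  has_catalytic_his <- identical(res_at("catalytic_his"), "H")
  has_heme_ligands <- identical(res_at("heme_met"), "M") &&
    identical(res_at("heme_his"), "H")

  ross_lo <- max(1, ref$rossmann_start - rossmann_window)
  ross_hi <- ref$rossmann_start + 5 + rossmann_window
  qpos <- mapped_positions(anchor, ross_lo, ross_hi)
  has_rossmann <- length(qpos) >= 6 &&
    grepl("G.G..G", substring(qs, min(qpos), max(qpos)))

  dh_start_q <- anchor$map[ref$dh_region[1]]
  if (is.na(dh_start_q)) {
    after <- anchor$map[ref$dh_region[1]:length(anchor$map)]
    dh_start_q <- if (any(!is.na(after))) min(after, na.rm = TRUE) else nchar(qs) + 1
  }
  cyt_idx <- ref$cyt_region[1]:ref$cyt_region[2]
  cyt_map <- anchor$map[cyt_idx]
  cyt_cov <- mean(!is.na(cyt_map) & cyt_map < dh_start_q)
  has_cyt_domain <- cyt_cov >= cyt_min_coverage

  flags <- c(has_signal_peptide = sp_flag, has_rossmann = has_rossmann,
             has_catalytic_his = has_catalytic_his,
             has_cyt_domain = has_cyt_domain,
             has_heme_ligands = has_heme_ligands)
  report_row(acc, anchor$identity, TRUE, flags)
}

report_row <- function(accession, identity, anchorable, flags,
                       extra_reason = NULL) {
  reasons <- c(extra_reason, names(flags)[!is.na(flags) & !flags])
  verdict <- if (anchorable && all(!is.na(flags)) && all(flags)) "kept" else "excluded"
  tibble::tibble(
    accession = accession, identity = identity, anchorable = anchorable,
    has_signal_peptide = flags[["has_signal_peptide"]],
    has_rossmann = flags[["has_rossmann"]],
    has_catalytic_his = flags[["has_catalytic_his"]],
    has_cyt_domain = flags[["has_cyt_domain"]],
    has_heme_ligands = flags[["has_heme_ligands"]],
    verdict = verdict,
    reasons = paste(reasons, collapse = ";"))
}

#' Curate a dataset against the reference
#'
#' Applies [evaluate_record()] to every record (records should already be
#' length-filtered to the full-length window, 700-1000 residues) and
#' tallies exclusions per criterion.
#'
#' @inheritParams evaluate_record
#' @param records Record tibble.
#' @return A list: `kept` (record tibble), `report` (one row per record),
#'   `tally` (per-criterion exclusion counts).
#' @export
curate_dataset <- function(records, ref, signalp = NULL, ...) {
  assert_records(records)
  if (nrow(records) == 0) {
    return(list(kept = records,
                report = tibble::tibble(accession = character()),
                tally = tibble::tibble(criterion = character(), n_failed = integer())))
  }
  report <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    evaluate_record(records[i, , drop = FALSE], ref, signalp = signalp, ...)
  })
  crits <- c("has_signal_peptide", "has_rossmann", "has_catalytic_his",
             "has_cyt_domain", "has_heme_ligands")
  tally <- tibble::tibble(
    criterion = c(crits, "unanchorable"),
    n_failed = c(vapply(crits, function(cr) sum(!report[[cr]], na.rm = TRUE),
                        integer(1)),
                 sum(!report$anchorable)))
  list(kept = records[records$accession %in%
                        report$accession[report$verdict == "kept"], ,
                      drop = FALSE],
       report = report, tally = tally)
}

#' Reduce sequence redundancy by greedy identity clustering
#'
#' Greedy first-fit clustering in input order: each record joins the first
#' existing representative to which its pairwise global-alignment identity
#' (matches over aligned columns) is at or above `identity_threshold`;
#' otherwise it founds a new cluster. Representatives are returned in
#' founding order. The pipeline default, 0.99, keeps a single
#' representative per group of >= 99%-identical sequences.
#'
#' @param records Record tibble.
#' @param identity_threshold Fraction in (0, 1].
#' @param params A [scoring_params()] configuration.
#' @return A list: `representatives` (record tibble) and `clusters`
#'   (tibble `accession`, `representative`).
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.99,
                              params = scoring_params()) {
  assert_records(records)
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  reps <- integer(0)
  assignment <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    placed <- FALSE
    for (r in reps) {
      idt <- global_align(records$sequence[[i]], records$sequence[[r]],
                          params)$identity
      if (idt >= identity_threshold) {
        assignment[i] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); assignment[i] <- i }
  }
  list(representatives = records[reps, , drop = FALSE],
       clusters = tibble::tibble(
         accession = records$accession,
         representative = records$accession[assignment]))
}

#' Trim high-gap columns from an alignment
#'
#' Removes alignment columns whose gap fraction is at or above
#' `max_gap_fraction` (inclusive bound; the pipeline default removes
#' columns with >= 90% gaps).
#'
#' @param alignment Character vector of equal-length gapped sequences
#'   (gaps as `-`), optionally named.
#' @param max_gap_fraction Gap-fraction bound in (0, 1].
#' @return A list: `alignment` (trimmed, names preserved) and
#'   `removed_columns` (1-based indices).
#' @export
trim_alignment_columns <- function(alignment, max_gap_fraction = 0.9) {
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) abort_param("ragged alignment: rows differ in length")
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  drop <- which(gap_frac >= max_gap_fraction)
  keep <- setdiff(seq_len(ncol(mat)), drop)
  trimmed <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(trimmed) <- names(alignment)
  list(alignment = trimmed, removed_columns = drop)
}

#' Build a sequence logo over reference-defined columns
#'
#' Star alignment through [anchor_to_reference()]: each record is aligned
#' to the reference and its residues are collected at the reference
#' positions of `region`. Per column, residue frequencies are computed over
#' non-gap characters and the information content is
#' `R = log2(20) - H(column)` bits (no small-sample correction by default).
#'
#' @param records Record tibble (>= 2 anchorable records required).
#' @param ref A `cdh_reference`.
#' @param region Integer `c(from, to)` in reference coordinates.
#' @param small_sample_correction Subtract the Basharin small-sample bias
#'   `(20 - 1) / (2 n ln 2)` from each column's information content.
#' @param params A [scoring_params()] configuration.
#' @return A `cdh_logo` object: tibble `position`, `residue`, `freq`,
#'   `info`, `coverage` (fraction of anchorable records contributing).
#' @export
build_logo <- function(records, ref, region, small_sample_correction = FALSE,
                       params = scoring_params()) {
  assert_records(records)
  stopifnot(length(region) == 2,
            region[1] >= 1,
            region[2] <= nchar(ref$record$sequence[[1]]))
  anchors <- lapply(seq_len(nrow(records)), function(i) {
    anchor_to_reference(records[i, , drop = FALSE], ref, params)
  })
  ok <- vapply(anchors, function(a) a$anchorable, logical(1))
  if (sum(ok) < 2) abort_param("fewer than 2 anchorable records")
  if (mean(ok) < 0.5) {
    warning("fewer than 50% of records anchor to the reference", call. = FALSE)
  }
  anchors <- anchors[ok]
  positions <- region[1]:region[2]
  rows <- purrr::map_dfr(positions, function(p) {
    res <- vapply(anchors, function(a) {
      qp <- a$map[p]
      if (is.na(qp)) NA_character_ else substring(a$query_seq, qp, qp)
    }, character(1))
    res <- res[!is.na(res)]
    n <- length(res)
    if (n == 0) {
      return(tibble::tibble(position = p, residue = NA_character_,
                            freq = NA_real_, info = 0, coverage = 0))
    }
    tab <- table(res) / n
    h <- -sum(tab * log2(tab))
    info <- log2(20) - h
    if (small_sample_correction) info <- max(0, info - 19 / (2 * n * log(2)))
    tibble::tibble(position = p, residue = names(tab),
                   freq = as.numeric(tab), info = info,
                   coverage = n / length(anchors))
  })
  structure(list(columns = rows, region = region,
                 n_records = length(anchors)),
            class = "cdh_logo")
}

#' @export
print.cdh_logo <- function(x, ...) {
  cat(sprintf("Sequence logo over reference columns %d-%d (%d records)\n",
              x$region[1], x$region[2], x$n_records))
  print(x$columns)
  invisible(x)
}
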