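#' Split a sequence into SP / Cyt / linker / DH segments
#'
#' The dehydrogenase domain is taken to start `linker_offset` (default 8)
#' residues before the conserved `YDY` motif near the start of the Rossmann
#' fold — the split point used to partition genes into synthesis modules.
#' The query's YDY occurrence is accepted when it lies within
#' `anchor_slack` residues of the position mapped from the reference's YDY;
#' when no such occurrence exists the split falls back to the query
#' position aligned to the reference DH start and the result is flagged
#' `fallback`.
#'
#' @param query One-row record tibble.
#' @param ref A `cdh_reference`.
#' @param sp_end Last residue of the signal peptide; when `NULL` it is
#'   taken from [predict_signal_peptide()] (0 when prediction fails).
#' @param anchor_slack Maximum distance (residues) between a query YDY and
#'   its expected mapped position.
#' @param params A [scoring_params()] configuration.
#' @return A list with `segments` (tibble `part`, `start`, `end`; 1-based
#'   inclusive, empty parts have `start > end`), `dh_start`, `ydy_pos`
#'   (NA under fallback) and `fallback`.
#' @export
split_domains <- function(query, ref, sp_end = NULL, anchor_slack = 30,
                          params = scoring_params()) {
  anchor <- anchor_to_reference(query, ref, params)
  qs <- anchor$query_seq
  qlen <- nchar(qs)
  ref_ydy <- regexpr(ref$linker_anchor_motif,
                     ref$record$sequence[[1]], fixed = TRUE)[[1]]

  ydy_pos <- NA_integer_
  if (anchor$anchorable) {
    expect_q <- anchor$map[ref_ydy]
    if (is.na(expect_q)) expect_q <- anchor$map[ref$rossmann_start]
    hits <- gregexpr(ref$linker_anchor_motif, qs, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(hits) > 0 && !is.na(expect_q)) {
      near <- hits[abs(hits - expect_q) <= anchor_slack]
      if (length(near) > 0) ydy_pos <- near[1]
    } else if (length(hits) > 0 && is.na(expect_q)) {
      ydy_pos <- hits[1]
    }
  } else {
    hits <- gregexpr(ref$linker_anchor_motif, qs, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(hits) == 0) abort_param("no YDY anchor and query unanchorable")
    ydy_pos <- hits[1]
  }

  fallback <- is.na(ydy_pos)
  if (fallback) {
    dh_start <- anchor$map[ref$dh_region[1]]
    if (is.na(dh_start)) abort_param("no YDY anchor and DH start unmappable")
  } else {
    dh_start <- ydy_pos - ref$linker_offset
  }
  if (dh_start < 2) abort_param("DH start collides with the N-terminus")

  if (is.null(sp_end)) {
    sp <- predict_signal_peptide(query)
    sp_end <- if (isTRUE(sp$pass)) sp$cleavage_pos else 0L
  }
  cyt_end_ref <- ref$cyt_region[2]
  cyt_end <- if (anchor$anchorable && !is.na(anchor$map[cyt_end_ref])) {
    min(anchor$map[cyt_end_ref], dh_start - 1)
  } else dh_start - 1
  dh_end_ref <- ref$dh_region[2]
  dh_end <- if (anchor$anchorable && !is.na(anchor$map[dh_end_ref])) {
    anchor$map[dh_end_ref]
  } else qlen

  segments <- tibble::tibble(
    part = c("SP", "Cyt", "linker", "DH", "Cterm"),
    start = c(1L, sp_end + 1L, cyt_end + 1L, dh_start, dh_end + 1L),
    end = c(sp_end, cyt_end, dh_start - 1L, dh_end, qlen))
  list(segments = segments, dh_start = dh_start,
       ydy_pos = if (fallback) NA_integer_ else ydy_pos,
       fallback = fallback)
}
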