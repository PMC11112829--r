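# Pairwise alignment scoring shared by the ssn and curation modules.
# Local alignments (Smith-Waterman) feed the similarity network; global
# alignments (Needleman-Wunsch) feed reference anchoring and redundancy
# reduction. Both run through Biostrings with a BLOSUM62 / affine-gap
# configuration.

#' Scoring configuration for pairwise alignment
#'
#' The similarity network converts raw local-alignment scores to bit scores
#' with Karlin-Altschul statistics and then to an expectation-style
#' alignment score AS = m n 2^(-bits), where m and n are the sequence
#' lengths scaled by `eff_scale` (an effective search-space multiplier).
#' Lower AS means stronger similarity. `lambda` and `K` default to the
#' standard gapped BLOSUM62 (gap open 11, extend 1) constants.
#'
#' @param matrix Substitution matrix name (shipped with Biostrings).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul parameters for the bit-score conversion.
#' @param eff_scale Effective search-space multiplier applied to `m * n`.
#' @return A list of class `cdh_scoring` used by [score_pair()] and
#'   [build_network()].
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, eff_scale = 1) {
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 eff_scale = eff_scale),
            class = "cdh_scoring")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

raw_to_bits <- function(raw, params) {
  (params$lambda * raw - log(params$K)) / log(2)
}

bits_to_as <- function(bits, m, n, params) {
  params$eff_scale * m * n * 2^(-bits)
}

# Vectorized local alignment of many patterns against one subject.
# Returns tibble(raw, width, nmatch).
local_align_many <- function(patterns, subject, params) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = subject,
    type = "local",
    substitutionMatrix = get_submat(params$matrix),
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  tibble::tibble(raw = Biostrings::score(aln),
                 width = Biostrings::nchar(aln),
                 nmatch = Biostrings::nmatch(aln))
}

#' Score a sequence pair for the similarity network
#'
#' Computes an optimal local alignment under the configured substitution
#' matrix and affine gap penalties, converts the raw score to bits and to an
#' expectation-style alignment score `AS = m n 2^(-bits)`. The score is
#' symmetric in its arguments.
#'
#' @param x,y One-row record tibbles (or lists with `accession` and
#'   `sequence`).
#' @param params A [scoring_params()] configuration.
#' @return A one-row tibble with `a`, `b`, `raw_score`, `bitscore`, `score`
#'   (the AS) and `percent_identity` (fraction of identities over aligned
#'   columns).
#' @export
score_pair <- function(x, y, params = scoring_params()) {
  xs <- toupper(x$sequence[[1]]); ys <- toupper(y$sequence[[1]])
  if (nchar(xs) == 0 || nchar(ys) == 0) abort_param("empty sequence")
  if (grepl("^X+$", xs) || grepl("^X+$", ys)) {
    abort_param("undefined score: sequence consists only of unknown residues")
  }
  # canonical orientation so both argument orders give the identical
  # alignment (the DP tie-break depends on which sequence is the pattern)
  if (xs <= ys) res <- local_align_many(xs, ys, params) else
    res <- local_align_many(ys, xs, params)
  bits <- raw_to_bits(res$raw, params)
  tibble::tibble(
    a = x$accession[[1]], b = y$accession[[1]],
    raw_score = res$raw, bitscore = bits,
    score = bits_to_as(bits, nchar(xs), nchar(ys), params),
    percent_identity = res$nmatch / res$width)
}

# Global (Needleman-Wunsch) alignment of one pair; returns the two aligned
# strings (with '-' gaps) plus identity over aligned columns.
global_align <- function(xs, ys, params = scoring_params()) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = xs, subject = ys, type = "global",
    substitutionMatrix = get_submat(params$matrix),
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  list(query = unname(pat), ref = unname(sub),
       score = Biostrings::score(aln),
       identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln))
}

# Map annotated positions of sequence B (ref) to positions of sequence A
# (query) through a global alignment. Returns an integer vector over ref
# positions: query position or NA where the ref position aligns to a gap.
alignment_position_map <- function(query_aln, ref_aln) {
  q <- seq_chars(query_aln)
  r <- seq_chars(ref_aln)
  stopifnot(length(q) == length(r))
  qpos <- cumsum(q != "-")
  rpos <- cumsum(r != "-")
  out <- rep(NA_integer_, max(rpos))
  sel <- r != "-" & q != "-"
  out[rpos[sel]] <- qpos[sel]
  out
}
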