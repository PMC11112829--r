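# Internal helpers shared across modules.

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy scale, used by the signal-peptide heuristic.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_param <- function(msg) stop(msg, call. = FALSE)

assert_records <- function(records, what = "records") {
  stopifnot(is.data.frame(records))
  needed <- c("accession", "sequence")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort_param(sprintf("%s must have columns %s (missing: %s)",
                        what, paste(needed, collapse = ", "),
                        paste(missing, collapse = ", ")))
  }
  dup <- records$accession[duplicated(records$accession)]
  if (length(dup) > 0) {
    abort_param(sprintf("duplicate accession(s): %s",
                        paste(unique(dup), collapse = ", ")))
  }
  invisible(records)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp <- function(dna) {
  chartr("ACGT", "TGCA", vapply(dna, function(s) {
    paste(rev(seq_chars(s)), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Rand index between two partitions
#'
#' Agreement between two labelings of the same items: the fraction of item
#' pairs on which the partitions agree (together in both, or apart in both).
#' Used to compare network clusters against planted family labels.
#'
#' @param labels_a,labels_b Vectors of cluster labels, same length and order.
#' @return A number in \[0, 1\]; 1 means identical partitions.
#' @export
rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 2)
  n <- length(labels_a)
  same_a <- outer(labels_a, labels_a, "==")
  same_b <- outer(labels_b, labels_b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}

# Deterministic child seed derived from a user seed, kept inside 32-bit range.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + as.integer(k)) %% 2147483581L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
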