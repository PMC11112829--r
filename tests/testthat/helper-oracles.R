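# Shared fixtures and independent oracles.

REF <- synthetic_reference()

# Exhaustive affine-gap local-alignment DP (Gotoh), the independent oracle
# for raw pairwise scores on short inputs. A gap of length k costs
# gap_open + k * gap_ext, matching the package's scoring convention.
oracle_local_score <- function(a, b, submat, gap_open = 11, gap_ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + s)
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}

# brute-force identity between two equal-length ungapped strings
hamming_identity <- function(x, y) {
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  mean(xs == ys)
}

# protein with a cassette making every default enzyme plantable by
# synonymous choice (G-L for BsaI, E-L for SacI, E-D for BbsI,
# V-F-K-L for PmeI, G-A-P for AscI)
protein_with_cassette <- function(len, seed) {
  set.seed(seed)
  body <- random_aa(len, seed)
  at <- sample(10:(len - 20), 1)
  paste0(substr(body, 1, at), "GLELEDVFKLGAP",
         substr(body, at + 1, len))
}

# explicit, non-overlapping planting positions inside the cassette
cassette_sites <- function(prot, enzymes) {
  cas <- regexpr("GLELEDVFKLGAP", prot)[[1]]
  offset <- c(BsaI = 0, SacI = 2, BbsI = 4, PmeI = 6, AscI = 10)
  tibble::tibble(enzyme = enzymes,
                 codon_start = cas + unname(offset[enzymes]))
}

make_records <- function(seqs, prefix = "R") {
  tibble::tibble(accession = paste0(prefix, seq_along(seqs)),
                 sequence = seqs)
}
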