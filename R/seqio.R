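#' Read a FASTA file into a record tibble
#'
#' Parses a protein or DNA FASTA file into one row per entry. The header
#' token before the first whitespace becomes the accession; the remainder
#' becomes the description. Sequences are uppercased and validated against
#' the declared alphabet.
#'
#' Non-canonical protein residues (B, Z, U, J, O, `*`) are rejected by
#' default because downstream curation removes sequences with
#' non-proteinogenic characters; set `coerce_x = TRUE` to convert them to X
#' instead.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @param coerce_x For protein input, coerce non-canonical residues to `X`
#'   instead of erroring.
#' @return A tibble with columns `accession`, `description`, `sequence`,
#'   `length`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), coerce_x = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort_param(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble::tibble(accession = character(), description = character(),
                          sequence = character(), length = integer()))
  }
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- unname(toupper(as.character(set)))
  records <- tibble::tibble(accession = accession,
                            description = description,
                            sequence = sequence,
                            length = nchar(sequence))
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0) {
    abort_param(sprintf("duplicate accession(s) in %s: %s", path,
                        paste(dup, collapse = ", ")))
  }
  validate_alphabet(records, alphabet, coerce_x = coerce_x)
}

validate_alphabet <- function(records, alphabet, coerce_x = FALSE) {
  allowed <- if (alphabet == "dna") c("A", "C", "G", "T") else
    c(AA_CANONICAL, "X")
  bad_of <- function(s) {
    ch <- unique(seq_chars(s))
    setdiff(ch, allowed)
  }
  bad <- lapply(records$sequence, bad_of)
  has_bad <- lengths(bad) > 0
  if (any(has_bad)) {
    if (alphabet == "protein" && coerce_x) {
      noncanon <- c("B", "Z", "U", "J", "O", "*")
      fixable <- vapply(bad, function(b) all(b %in% noncanon), logical(1))
      if (all(fixable | !has_bad)) {
        records$sequence[has_bad] <- vapply(
          records$sequence[has_bad],
          function(s) gsub("[BZUJO*]", "X", s),
          character(1), USE.NAMES = FALSE)
        return(records)
      }
    }
    msgs <- vapply(which(has_bad), function(i) {
      sprintf("%s: illegal %s character(s) %s", records$accession[i],
              alphabet, paste(bad[[i]], collapse = ""))
    }, character(1))
    abort_param(paste(msgs, collapse = "; "))
  }
  records
}

#' Write records to FASTA
#'
#' @param records A record tibble (`accession`, optional `description`,
#'   `sequence`).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  assert_records(records)
  desc <- records$description %||% NULL
  header <- if (!is.null(desc) && any(nzchar(desc))) {
    ifelse(nzchar(desc), paste(records$accession, desc), records$accession)
  } else records$accession
  wrap <- function(s) {
    paste(substring(s, seq(1, nchar(s), width),
                    pmin(seq(1, nchar(s), width) + width - 1, nchar(s))),
          collapse = "\n")
  }
  lines <- unlist(Map(function(h, s) c(paste0(">", h), wrap(s)),
                      header, records$sequence), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Merge record sets, removing duplicate accessions
#'
#' Union of several record tibbles keeping the first occurrence of each
#' accession, in first-seen order. A conflict (same accession, different
#' sequence across sources) keeps the first occurrence and is reported.
#'
#' @param ... Record tibbles, or a single list of them.
#' @return The merged tibble, with attributes `merge_report` (per-source and
#'   merged counts) and `conflicts` (tibble of conflicting accessions).
#' @export
merge_dedup <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1)
  lapply(sets, assert_records)
  src_names <- names(sets) %||% paste0("set", seq_along(sets))
  if (is.null(names(sets))) names(sets) <- src_names
  all <- dplyr::bind_rows(sets, .id = "source")
  first <- !duplicated(all$accession)
  merged <- dplyr::select(all[first, , drop = FALSE], -"source")
  dup_rows <- all[!first, , drop = FALSE]
  conflicts <- tibble::tibble(accession = character(), source = character())
  if (nrow(dup_rows) > 0) {
    kept_seq <- stats::setNames(merged$sequence, merged$accession)
    is_conflict <- dup_rows$sequence != kept_seq[dup_rows$accession]
    if (any(is_conflict)) {
      conflicts <- tibble::tibble(accession = dup_rows$accession[is_conflict],
                                  source = dup_rows$source[is_conflict])
      warning(sprintf("%d accession(s) with conflicting sequences; first occurrence kept: %s",
                      nrow(conflicts),
                      paste(unique(conflicts$accession), collapse = ", ")),
              call. = FALSE)
    }
  }
  report <- tibble::tibble(
    source = c(src_names, "merged"),
    n = c(vapply(sets, nrow, integer(1)), nrow(merged)))
  attr(merged, "merge_report") <- report
  attr(merged, "duplicates_removed") <- nrow(dup_rows)
  attr(merged, "conflicts") <- conflicts
  merged
}

#' Filter records by sequence length
#'
#' Keeps records whose length lies in `[min_len, max_len]` (both bounds
#' inclusive). The network-building stage of the pipeline uses the window
#' 150–1100 residues; full-length CDH curation uses 700–1000.
#'
#' @param records A record tibble.
#' @param min_len,max_len Inclusive residue bounds.
#' @return A list with tibbles `kept` and `removed`, both in input order.
#' @export
filter_by_length <- function(records, min_len, max_len) {
  assert_records(records)
  if (min_len < 0 || max_len < 0) abort_param("length bounds must be non-negative")
  if (min_len > max_len) abort_param("min_len must be <= max_len")
  len <- nchar(records$sequence)
  keep <- len >= min_len & len <= max_len
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}
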