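#' Heuristic signal-peptide prediction
#'
#' A built-in approximation of secretion-signal architecture used when no
#' external predictor output is available: within the N-terminus the
#' sequence must show (1) a positively charged n-region (at least one K/R in
#' the first `n_region_len` residues), (2) a hydrophobic h-region — a window
#' of at least `h_window` consecutive residues drawn from the apolar set
#' with mean Kyte-Doolittle hydropathy at or above `h_min_kd`, starting no
#' later than `h_start_max` and ending by `h_end_max` — and (3) a
#' small-residue cleavage context (A/G/S) within `cleavage_reach` residues
#' after the h-region. Sequences shorter than 25 residues fail with reason
#' "too short".
#'
#' This heuristic is calibrated for triage, not as a SignalP replacement;
#' external predictor calls override it wherever supplied (see the
#' `signalp` argument of [curate_dataset()]).
#'
#' @param query One-row record tibble (or list with `sequence`).
#' @param n_region_len,h_window,h_min_kd,h_start_max,h_end_max,cleavage_reach
#'   Heuristic parameters (residue counts and hydropathy threshold).
#' @return One-row tibble: `pass`, `score` (mean hydropathy of the best
#'   h-window, NA when none), `cleavage_pos` (last SP residue, NA when
#'   failing), `reason`.
#' @export
predict_signal_peptide <- function(query, n_region_len = 8, h_window = 7,
                                   h_min_kd = 1.5, h_start_max = 12,
                                   h_end_max = 25, cleavage_reach = 6) {
  s <- toupper(query$sequence[[1]])
  if (nchar(s) < 25) {
    return(tibble::tibble(pass = FALSE, score = NA_real_,
                          cleavage_pos = NA_integer_, reason = "too short"))
  }
  ch <- seq_chars(substr(s, 1, 40))
  fail <- function(reason) tibble::tibble(pass = FALSE, score = NA_real_,
                                          cleavage_pos = NA_integer_,
                                          reason = reason)
  if (!any(ch[seq_len(n_region_len)] %in% c("K", "R"))) {
    return(fail("no positively charged n-region"))
  }
  apolar <- c("A", "C", "F", "G", "I", "L", "M", "S", "T", "V", "W")
  kd <- KYTE_DOOLITTLE[ch]
  ok_res <- ch %in% apolar
  best <- NULL
  for (start in 2:h_start_max) {
    # extend the window as far as the apolar run allows
    end <- start + h_window - 1
    if (end > length(ch) || end > h_end_max) break
    if (!all(ok_res[start:end])) next
    while (end + 1 <= min(length(ch), h_end_max) && ok_res[end + 1]) {
      end <- end + 1
    }
    m <- mean(kd[start:end])
    if (m >= h_min_kd && (is.null(best) || m > best$score)) {
      best <- list(start = start, end = end, score = m)
    }
  }
  if (is.null(best)) return(fail("no hydrophobic h-region"))
  cleave_zone <- seq(best$end + 1,
                     min(length(ch), best$end + cleavage_reach))
  small <- which(ch[cleave_zone] %in% c("A", "G", "S"))
  if (length(small) == 0) return(fail("no small-residue cleavage context"))
  tibble::tibble(pass = TRUE, score = best$score,
                 cleavage_pos = as.integer(cleave_zone[max(small)]),
                 reason = NA_character_)
}

#' Read external signal-peptide predictions
#'
#' Adapter for tabular output in the SignalP 5 short format: a
#' `#`-commented header followed by rows whose first column is the sequence
#' ID and second column the prediction class (`SP(Sec/SPI)` or `OTHER`). A
#' third numeric column, when present, is kept as the score.
#'
#' @param path Path to the prediction table.
#' @return Tibble `accession`, `has_signal_peptide`, `score`, suitable for
#'   the `signalp` argument of [evaluate_record()] / [curate_dataset()].
#' @export
read_signalp_summary <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(accession = character(),
                          has_signal_peptide = logical(), score = numeric()))
  }
  parts <- strsplit(lines, "\t|\\s+")
  tibble::tibble(
    accession = vapply(parts, `[`, character(1), 1),
    has_signal_peptide = vapply(parts, `[`, character(1), 2) != "OTHER",
    score = vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[3])); if (length(v) == 0) NA_real_ else v
    }, numeric(1)))
}
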