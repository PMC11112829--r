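# Golden-gate construct design: domestication of the CDS (synonymous
# removal of forbidden restriction sites), partition into SP/Cyt/DH
# synthesis modules of 300-900 bp with 4-nt fusion overhangs, and
# simulation of the Type IIS digestion/ligation to validate the assembly.

#' Default restriction enzymes for domestication
#'
#' The five enzymes whose sites must be absent from synthesized fragments:
#' SacI, PmeI, AscI (cloning sites) and the Type IIS enzymes BbsI and BsaI
#' used for the golden-gate reactions. `cut_offset` is the distance from
#' the recognition site to the top-strand cut (Type IIS only).
#'
#' @return Tibble `name`, `recognition`, `cut_offset`, `overhang_length`.
#' @export
restriction_enzymes <- function() {
  tibble::tibble(
    name = c("SacI", "PmeI", "AscI", "BbsI", "BsaI"),
    recognition = c("GAGCTC", "GTTTAAAC", "GGCGCGCC", "GAAGAC", "GGTCTC"),
    cut_offset = c(NA, NA, NA, 2L, 1L),
    overhang_length = c(NA, NA, NA, 4L, 4L))
}

as_dna_string <- function(dna) {
  s <- if (is.data.frame(dna)) dna$sequence[[1]] else as.character(dna)[[1]]
  s <- toupper(s)
  bad <- setdiff(unique(seq_chars(s)), c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    abort_param(sprintf("illegal DNA character(s): %s", paste(bad, collapse = "")))
  }
  s
}

find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  as.integer(hits[hits > 0])
}

#' Scan a sequence for restriction sites on both strands
#'
#' Reports every occurrence of each enzyme's recognition sequence on the
#' plus strand and of its reverse complement (a minus-strand site).
#' Palindromic sites are reported once, on the plus strand.
#'
#' @param dna A nucleotide record tibble or DNA string.
#' @param enzymes Enzyme tibble (see [restriction_enzymes()]).
#' @return Tibble `enzyme`, `strand`, `start0` (0-based), `start`
#'   (1-based), `end` (1-based inclusive), sorted by position.
#' @export
scan_restriction_sites <- function(dna, enzymes = restriction_enzymes()) {
  s <- as_dna_string(dna)
  out <- purrr::map_dfr(seq_len(nrow(enzymes)), function(i) {
    recog <- enzymes$recognition[i]
    rc <- revcomp(recog)
    fwd <- find_all(recog, s)
    rows <- tibble::tibble(enzyme = enzymes$name[i], strand = "+",
                           start = fwd)
    if (rc != recog) {
      rev <- find_all(rc, s)
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        enzyme = enzymes$name[i], strand = "-", start = rev))
    }
    rows$width <- nchar(recog)
    rows
  })
  out <- dplyr::arrange(out, .data$start, .data$enzyme)
  tibble::tibble(enzyme = out$enzyme, strand = out$strand,
                 start0 = out$start - 1L, start = out$start,
                 end = out$start + out$width - 1L)
}

GENETIC_CODE_TABLE <- NULL

genetic_code <- function() Biostrings::GENETIC_CODE

codons_of <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Translate a coding sequence
#'
#' @param cds DNA string or nucleotide record, length divisible by 3.
#' @return Amino-acid string (`*` for stop codons).
#' @export
translate_cds <- function(cds) {
  s <- as_dna_string(cds)
  if (nchar(s) %% 3 != 0) abort_param("CDS length not divisible by 3")
  paste(genetic_code()[codons_of(s)], collapse = "")
}

synonymous_codons <- function(codon) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  sort(names(gc)[gc == aa])
}

#' Domesticate a CDS for golden-gate synthesis
#'
#' Destroys every forbidden restriction site by synonymous single-codon
#' edits and removes the terminal stop codon. The translation of the output
#' (plus stop) always equals the translation of the input; a rescan of the
#' output finds zero sites. When several synonymous codons destroy a site,
#' the most frequent codon in `codon_usage` wins (uniform by default, then
#' alphabetical order).
#'
#' @param cds Nucleotide record tibble or DNA string; length divisible by
#'   3, no internal stop codons.
#' @param enzymes Enzyme tibble (see [restriction_enzymes()]).
#' @param codon_usage Optional named numeric vector of codon frequencies.
#' @return A list: `cds` (edited, stop removed), `edits` (tibble `enzyme`,
#'   `site_start`, `codon_index`, `from`, `to`), `protein`.
#' @export
domesticate_cds <- function(cds, enzymes = restriction_enzymes(),
                            codon_usage = NULL) {
  s <- as_dna_string(cds)
  if (nchar(s) %% 3 != 0) abort_param("CDS length not divisible by 3")
  prot <- translate_cds(s)
  aa <- seq_chars(prot)
  if (any(aa[-length(aa)] == "*")) abort_param("CDS contains internal stop codons")
  had_stop <- aa[length(aa)] == "*"
  if (had_stop) s <- substr(s, 1, nchar(s) - 3)
  protein <- translate_cds(s)

  usage_of <- function(codon) {
    if (is.null(codon_usage) || !codon %in% names(codon_usage)) 1 else
      codon_usage[[codon]]
  }
  edits <- tibble::tibble(enzyme = character(), site_start = integer(),
                          codon_index = integer(), from = character(),
                          to = character())
  max_recog <- max(nchar(enzymes$recognition))
  guard <- 0
  repeat {
    sites <- scan_restriction_sites(s, enzymes)
    if (nrow(sites) == 0) break
    guard <- guard + 1
    if (guard > 10 * (nrow(sites) + 10)) {
      abort_param("domestication did not converge")
    }
    site <- sites[1, ]
    codon_idx <- unique(((site$start:site$end) - 1L) %/% 3L + 1L)
    codons <- codons_of(s)
    lo <- max(1, site$start - max_recog)
    hi <- min(nchar(s), site$end + max_recog)
    before <- scan_restriction_sites(substr(s, lo, hi), enzymes)
    before_keys <- setdiff(paste(before$enzyme, before$strand, before$start),
                           paste(site$enzyme, site$strand, site$start - lo + 1L))
    candidates <- list()
    for (ci in codon_idx) {
      for (alt in setdiff(synonymous_codons(codons[ci]), codons[ci])) {
        cand <- codons
        cand[ci] <- alt
        news <- paste(cand, collapse = "")
        after <- scan_restriction_sites(substr(news, lo, hi), enzymes)
        after_keys <- paste(after$enzyme, after$strand, after$start)
        target_key <- paste(site$enzyme, site$strand, site$start - lo + 1L)
        # the target site must be gone and no site may appear that was
        # not already present (pre-existing neighbors are fixed later)
        if (!target_key %in% after_keys &&
            all(after_keys %in% before_keys)) {
          candidates[[length(candidates) + 1]] <-
            list(ci = ci, from = codons[ci], to = alt, seq = news,
                 usage = usage_of(alt))
        }
      }
    }
    if (length(candidates) == 0) {
      abort_param(sprintf(
        "site %s at %d cannot be destroyed by a synonymous single-codon edit",
        site$enzyme, site$start))
    }
    usages <- vapply(candidates, function(x) x$usage, numeric(1))
    best <- candidates[[which.max(usages)]]
    edits <- dplyr::bind_rows(edits, tibble::tibble(
      enzyme = site$enzyme, site_start = site$start,
      codon_index = best$ci, from = best$from, to = best$to))
    s <- best$seq
  }
  stopifnot(translate_cds(s) == protein)
  list(cds = s, edits = edits, protein = protein, stop_removed = had_stop)
}

# Spacer alphabet restricted to A/C/T so no forbidden recognition sequence
# (all contain G) can form inside the spacer or across its boundary beyond
# the few context positions that are screened explicitly.
NEUTRAL_SPACER_UNIT <- "CTATCACTATCCATACATTACTCATACCTA"

neutral_spacer <- function(n) {
  if (n <= 0) return("")
  substr(strrep(NEUTRAL_SPACER_UNIT, ceiling(n / nchar(NEUTRAL_SPACER_UNIT))),
         1, n)
}

ADAPTER5 <- "TGGTCTCA"   # BsaI recognition, cut 1 nt downstream
ADAPTER3 <- "AGAGACCT"   # minus-strand BsaI recognition

is_palindromic <- function(oh) oh == revcomp(oh)

build_synth <- function(payload, min_len = 300) {
  core <- paste0(ADAPTER5, payload, ADAPTER3)
  pad <- max(0, min_len - nchar(core))
  list(seq = paste0(core, neutral_spacer(pad)), spacer = pad > 0)
}

#' Plan golden-gate synthesis fragments for a domesticated CDS
#'
#' Cuts the CDS at the codon boundaries mapped from the domain split (end
#' of the signal peptide, start of the dehydrogenase domain), subdivides
#' any module exceeding the synthesis limit at codon boundaries, appends
#' the C-terminal stop module (TAA), and assigns each junction a 4-nt
#' fusion overhang taken from the CDS itself. Junctions whose overhang
#' would collide with another (identical, palindromic, or
#' reverse-complementary to one in use) are shifted by whole codons until a
#' valid overhang is found. Fragments shorter than `min_len` after
#' adapter addition are padded with a neutral A/C/T spacer placed 3' of the
#' reverse recognition site, outside the assembled product. Every
#' synthesized fragment is between `min_len` and `max_len` bp.
#'
#' @param cds Domesticated CDS (string or nucleotide record; no forbidden
#'   sites, stop codon removed).
#' @param sp_end Last signal-peptide residue (protein coordinates).
#' @param dh_start First DH-domain residue (protein coordinates), e.g.
#'   from [split_domains()].
#' @param min_len,max_len Synthesized-fragment length limits in bp.
#' @param enzymes Enzyme tibble used to verify the fragments stay clean.
#' @return A `cdh_fragment_plan`: tibble `module`, `fragment`, `cds_from`,
#'   `cds_to`, `payload`, `overhang5`, `overhang3`, `spacer`,
#'   `synth_sequence`, `synth_length`, with the CDS as attribute.
#' @export
plan_fragments <- function(cds, sp_end, dh_start, min_len = 300,
                           max_len = 900, enzymes = restriction_enzymes()) {
  s <- as_dna_string(cds)
  if (nchar(s) %% 3 != 0) abort_param("CDS length not divisible by 3")
  if (nrow(scan_restriction_sites(s, enzymes)) > 0) {
    abort_param("CDS still contains forbidden sites; domesticate first")
  }
  n_codon <- nchar(s) / 3
  sp_end <- as.integer(sp_end); dh_start <- as.integer(dh_start)
  if (sp_end < 1 || dh_start <= sp_end + 1 || dh_start > n_codon) {
    abort_param("every domain must span at least one codon")
  }
  overhead <- nchar(ADAPTER5) + nchar(ADAPTER3)
  max_payload <- max_len - overhead

  # domain junctions in bp (end of module, codon boundaries)
  domain_ends <- c(SP = sp_end * 3L, Cyt = (dh_start - 1L) * 3L,
                   DH = nchar(s))

  # subdivide long modules at codon boundaries
  junctions <- integer(0)
  prev <- 0L
  modules <- character(0)
  for (m in names(domain_ends)) {
    end <- domain_ends[[m]]
    span <- end - prev
    n_chunks <- ceiling(span / (max_payload - 4L))
    sizes <- rep(span %/% n_chunks, n_chunks)
    sizes <- sizes - sizes %% 3L
    sizes[n_chunks] <- span - sum(sizes[-n_chunks])
    bounds <- prev + cumsum(sizes)
    junctions <- c(junctions, bounds)
    modules <- c(modules, if (n_chunks == 1) m else
      paste0(m, ".", seq_len(n_chunks)))
    prev <- end
  }

  # overhangs: CDS 4-mers at each junction (and the CDS termini); shift
  # internal junctions by codons until all are mutually compatible
  oh_at <- function(j) substr(s, j + 1L, j + 4L)
  used <- c(substr(s, 1, 4))  # 5' terminal overhang
  internal <- junctions[-length(junctions)]
  shifted <- internal
  for (k in seq_along(internal)) {
    j <- internal[k]
    ok_oh <- function(oh) {
      nchar(oh) == 4 && !is_palindromic(oh) &&
        !(oh %in% used) && !(revcomp(oh) %in% used)
    }
    found <- FALSE
    for (delta in c(0L, as.vector(rbind(1:10, -(1:10))) * 3L)) {
      jj <- j + delta
      lo <- if (k == 1) 0L else shifted[k - 1]
      hi <- if (k == length(internal)) nchar(s) else internal[k + 1]
      if (jj <= lo + 3L || jj >= hi - 3L) next
      if (ok_oh(oh_at(jj))) {
        shifted[k] <- jj; used <- c(used, oh_at(jj)); found <- TRUE; break
      }
    }
    if (!found) {
      abort_param(sprintf("no unique non-palindromic overhang near junction %d", j))
    }
  }
  # stop-module junction: slides back from the CDS end in codon steps
  # until its 4-mer overhang is unique and non-palindromic
  stop_j <- NA_integer_
  lo_bound <- (if (length(shifted) > 0) max(shifted) else 0L) + 4L
  for (q in seq(nchar(s) - 4L, lo_bound, by = -3L)) {
    oh <- substr(s, q + 1L, q + 4L)
    if (!is_palindromic(oh) && !(oh %in% used) && !(revcomp(oh) %in% used)) {
      stop_j <- q; break
    }
  }
  if (is.na(stop_j)) {
    abort_param("no unique fusion site found for the stop-module junction")
  }
  last_oh <- substr(s, stop_j + 1L, stop_j + 4L)
  used <- c(used, last_oh)

  junctions <- c(shifted, stop_j)
  starts <- c(0L, shifted)
  rows <- purrr::map_dfr(seq_along(junctions), function(k) {
    from <- starts[k]
    to <- junctions[k]
    payload_end <- min(to + 4L, nchar(s))
    payload <- substr(s, from + 1L, payload_end)
    synth <- build_synth(payload, min_len)
    tibble::tibble(
      module = modules[k], fragment = k,
      cds_from = from + 1L, cds_to = payload_end,
      payload = payload,
      overhang5 = substr(payload, 1, 4),
      overhang3 = substr(payload, nchar(payload) - 3L, nchar(payload)),
      spacer = synth$spacer,
      synth_sequence = synth$seq,
      synth_length = nchar(synth$seq))
  })
  # the stop module ends the chain; its terminal 4-mer must not double as
  # an internal fusion site, else ligation becomes ambiguous. A neutral
  # (A/C/T-only) 3' tail after the stop codon resolves collisions.
  used_all <- used
  stop_payload <- paste0(substr(s, stop_j + 1L, nchar(s)), "TAA")
  tail4 <- function(x) substr(x, nchar(x) - 3L, nchar(x))
  if (tail4(stop_payload) %in% used_all ||
      revcomp(tail4(stop_payload)) %in% used_all ||
      is_palindromic(tail4(stop_payload))) {
    resolved <- FALSE
    for (tl in c("CATT", "CTTC", "ACCT", "TCCT", "ATCC", "TACT")) {
      cand <- paste0(stop_payload, tl)
      if (!(tail4(cand) %in% used_all) &&
          !(revcomp(tail4(cand)) %in% used_all) &&
          !is_palindromic(tail4(cand))) {
        stop_payload <- cand; resolved <- TRUE; break
      }
    }
    if (!resolved) {
      abort_param("no unambiguous terminal overhang for the stop module")
    }
  }
  stop_synth <- build_synth(stop_payload, min_len)
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    module = "stop", fragment = nrow(rows) + 1L,
    cds_from = NA_integer_, cds_to = NA_integer_,
    payload = stop_payload,
    overhang5 = last_oh,
    overhang3 = substr(stop_payload, nchar(stop_payload) - 3L,
                       nchar(stop_payload)),
    spacer = stop_synth$spacer,
    synth_sequence = stop_synth$seq,
    synth_length = nchar(stop_synth$seq)))
  if (any(rows$synth_length < min_len | rows$synth_length > max_len)) {
    abort_param("fragment outside synthesis length limits")
  }
  for (i in seq_len(nrow(rows))) {
    found <- scan_restriction_sites(rows$synth_sequence[i], enzymes)
    bsa <- found[found$enzyme == "BsaI", ]
    if (nrow(bsa) != 2 || nrow(found) != 2) {
      abort_param("fragment flanks or spacer created an unintended site")
    }
  }
  structure(rows, class = c("cdh_fragment_plan", class(rows)),
            cds = s, sp_end = sp_end, dh_start = dh_start)
}

digest_fragment <- function(synth) {
  fwd <- find_all("GGTCTC", synth)
  rev <- find_all("GAGACC", synth)
  if (length(fwd) == 0 || length(rev) == 0) {
    abort_param("fragment lacks the expected BsaI flanks")
  }
  from <- fwd[1] + 6L + 1L          # recognition + 1-nt offset
  to <- rev[length(rev)] - 2L       # overhang ends before the spacer N
  substr(synth, from, to)
}

#' Validate a fragment plan by simulated digestion and ligation
#'
#' Simulates the one-pot Type IIS reaction: each synthesized fragment is
#' digested (adapters and spacers fall away, leaving the payload with its
#' 4-nt sticky ends) and the payloads are ligated by exact overhang
#' matching, independent of input order. The single linear product must
#' reconstruct the domesticated CDS followed by the TAA stop module, and
#' its translation must end with a stop codon. Duplicate overhangs make
#' the ligation ambiguous and raise an error.
#'
#' @param plan A `cdh_fragment_plan` (rows may be shuffled).
#' @param expected_cds CDS the product is compared against (defaults to
#'   the plan's recorded CDS).
#' @return A list: `valid`, `product`, `message`, `first_divergence` (NA
#'   when the product matches).
#' @export
validate_assembly <- function(plan, expected_cds = attr(plan, "cds")) {
  payloads <- vapply(plan$synth_sequence, digest_fragment, character(1),
                     USE.NAMES = FALSE)
  oh5 <- substr(payloads, 1, 4)
  oh3 <- substr(payloads, nchar(payloads) - 3L, nchar(payloads))
  if (anyDuplicated(oh5) || anyDuplicated(oh3)) {
    abort_param("ambiguous ligation: duplicate fusion overhangs")
  }
  start_idx <- which(!(oh5 %in% oh3))
  if (length(start_idx) != 1) {
    abort_param("ambiguous ligation: no unique starting fragment")
  }
  order_idx <- start_idx
  current <- start_idx
  while (length(order_idx) < length(payloads)) {
    nxt <- which(oh5 == oh3[current])
    if (length(nxt) != 1) abort_param("ambiguous or broken ligation chain")
    order_idx <- c(order_idx, nxt)
    current <- nxt
  }
  product <- payloads[order_idx[1]]
  for (i in order_idx[-1]) {
    stopifnot(substr(payloads[i], 1, 4) ==
                substr(product, nchar(product) - 3L, nchar(product)))
    product <- paste0(product, substr(payloads[i], 5, nchar(payloads[i])))
  }
  # the product must be the CDS followed by the stop codon; the stop
  # module may carry a short neutral (A/C/T) 3' tail after the TAA
  expected <- paste0(expected_cds, "TAA")
  remainder <- if (startsWith(product, expected)) {
    substr(product, nchar(expected) + 1L, nchar(product))
  } else NULL
  tail_ok <- !is.null(remainder) && nchar(remainder) <= 8 &&
    !grepl("G", remainder)
  if (tail_ok) {
    orf <- substr(product, 1, nchar(expected_cds) + 3L)
    list(valid = endsWith(translate_cds(orf), "*"), product = product,
         message = "assembly valid", first_divergence = NA_integer_)
  } else {
    pe <- seq_chars(expected); pp <- seq_chars(product)
    n <- min(length(pe), length(pp))
    div <- which(pe[1:n] != pp[1:n])
    first_div <- if (length(div) > 0) div[1] else n + 1L
    list(valid = FALSE, product = product,
         message = sprintf("product differs from expected ORF at position %d",
                           first_div),
         first_divergence = first_div)
  }
}
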