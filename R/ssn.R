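#' Build a sequence similarity network
#'
#' Scores all unordered pairs of records with [score_pair()] and keeps edges
#' whose alignment score (AS) is at or below `threshold`. Lower AS means
#' stronger similarity, so the threshold is the *loosest* similarity
#' admitted into the network; sweeps over stricter cut-offs then operate by
#' pure edge filtering, with no realignment. Isolated nodes are retained.
#'
#' Records are expected to be pre-filtered to the 150–1100 residue window
#' used for network construction; a warning is issued otherwise.
#'
#' @param records Record tibble (`accession`, `sequence`, optionally
#'   `class_label`).
#' @param threshold AS threshold at which the network is finalized
#'   (default `1e-30`).
#' @param params A [scoring_params()] configuration.
#' @param prefilter_kmer Optional integer k: skip pairs sharing fewer than
#'   `prefilter_min_shared` k-mers. `NULL` (default) disables the
#'   prefilter; it must stay off when exact edge sets matter.
#' @param prefilter_min_shared Minimum shared k-mer count when the
#'   prefilter is on.
#' @return A `cdh_network` object: list with `nodes` (tibble), `edges`
#'   (tibble `a`, `b`, `score`, `percent_identity`), `build_threshold`.
#' @export
build_network <- function(records, threshold = 1e-30,
                          params = scoring_params(),
                          prefilter_kmer = NULL, prefilter_min_shared = 1) {
  assert_records(records)
  if (nrow(records) < 2) abort_param("need at least 2 records to build a network")
  len <- nchar(records$sequence)
  if (any(len < 150 | len > 1100)) {
    warning("some records fall outside the 150-1100 residue network window",
            call. = FALSE)
  }
  n <- nrow(records)
  seqs <- toupper(records$sequence)
  acc <- records$accession

  kmer_sets <- NULL
  if (!is.null(prefilter_kmer)) {
    k <- as.integer(prefilter_kmer)
    kmer_sets <- lapply(seqs, function(s) {
      if (nchar(s) < k) return(character(0))
      unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
    })
  }

  edge_list <- vector("list", n)
  for (j in 2:n) {
    idx <- seq_len(j - 1)
    if (!is.null(kmer_sets)) {
      shared <- vapply(idx, function(i) {
        sum(kmer_sets[[i]] %in% kmer_sets[[j]])
      }, numeric(1))
      idx <- idx[shared >= prefilter_min_shared]
      if (length(idx) == 0) next
    }
    res <- local_align_many(seqs[idx], seqs[j], params)
    bits <- raw_to_bits(res$raw, params)
    as_score <- bits_to_as(bits, nchar(seqs[idx]), nchar(seqs[j]), params)
    keep <- as_score <= threshold
    if (any(keep)) {
      edge_list[[j]] <- tibble::tibble(
        a = acc[idx[keep]], b = acc[j],
        score = as_score[keep],
        percent_identity = (res$nmatch / res$width)[keep])
    }
  }
  edges <- dplyr::bind_rows(edge_list)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(a = character(), b = character(),
                            score = numeric(), percent_identity = numeric())
  }
  structure(list(nodes = records, edges = edges, build_threshold = threshold,
                 params = params),
            class = "cdh_network")
}

#' @export
print.cdh_network <- function(x, ...) {
  cat(sprintf("Sequence similarity network: %d nodes, %d edges (AS <= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$build_threshold))
  invisible(x)
}

components_at_cutoff <- function(network, cutoff) {
  keep <- network$edges$score <= cutoff
  g <- igraph::graph_from_data_frame(
    network$edges[keep, c("a", "b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = network$nodes$accession))
  memb <- igraph::components(g)$membership
  # renumber components deterministically by their smallest member accession
  first <- tapply(names(memb), memb, function(a) min(a))
  rank <- stats::setNames(rank(first, ties.method = "first"), names(first))
  comp <- unname(rank[as.character(memb)])
  tibble::tibble(accession = names(memb), component = as.integer(comp))
}

#' Sweep connected components across decreasing AS cut-offs
#'
#' For each cut-off, computes the connected components of the sub-network
#' whose edges satisfy `AS <= cutoff`. Because edges can only be removed as
#' the cut-off decreases, components can only split, never merge. When
#' `seed_groups` is given (a named list of accession vectors, e.g. the
#' characterized members of each CDH class), the sweep also reports each
#' group's separation cut-off: the first (largest-index, i.e. strictest so
#' far) cut-off at which no component mixes that group's members with
#' outsiders.
#'
#' @param network A `cdh_network`.
#' @param cutoffs Strictly decreasing numeric AS cut-offs, all at or below
#'   the network's build threshold.
#' @param seed_groups Optional named list of accession vectors.
#' @return A `cdh_sweep` object with `components` (tibble: `cutoff`,
#'   `accession`, `component`, `component_size`) and `separation` (tibble:
#'   `group`, `separation_cutoff`, NA if never separated in the sweep).
#' @export
sweep_components <- function(network, cutoffs, seed_groups = NULL) {
  stopifnot(inherits(network, "cdh_network"))
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) < 1 || any(diff(cutoffs) >= 0)) {
    abort_param("cutoffs must be strictly decreasing")
  }
  if (any(cutoffs > network$build_threshold)) {
    abort_param("all cutoffs must be <= the network build threshold")
  }
  per_cut <- lapply(cutoffs, function(co) {
    comp <- components_at_cutoff(network, co)
    comp <- dplyr::add_count(comp, .data$component, name = "component_size")
    dplyr::mutate(comp, cutoff = co, .before = 1)
  })
  components <- dplyr::bind_rows(per_cut)

  separation <- NULL
  if (!is.null(seed_groups)) {
    stopifnot(!is.null(names(seed_groups)))
    all_acc <- network$nodes$accession
    missing <- setdiff(unlist(seed_groups), all_acc)
    if (length(missing) > 0) {
      abort_param(sprintf("unknown seed accession(s): %s",
                          paste(missing, collapse = ", ")))
    }
    separation <- purrr::map_dfr(names(seed_groups), function(gname) {
      members <- seed_groups[[gname]]
      sep_at <- NA_real_
      for (k in seq_along(cutoffs)) {
        comp <- per_cut[[k]]
        comp_of_members <- unique(comp$component[comp$accession %in% members])
        occupants <- comp$accession[comp$component %in% comp_of_members]
        if (all(occupants %in% members)) { sep_at <- cutoffs[k]; break }
      }
      tibble::tibble(group = gname, separation_cutoff = sep_at)
    })
  }
  structure(list(cutoffs = cutoffs, components = components,
                 separation = separation),
            class = "cdh_sweep")
}

#' @export
print.cdh_sweep <- function(x, ...) {
  counts <- dplyr::summarise(
    dplyr::group_by(x$components, .data$cutoff),
    n_components = dplyr::n_distinct(.data$component))
  cat("AS cut-off sweep:\n")
  print(dplyr::arrange(counts, dplyr::desc(.data$cutoff)))
  if (!is.null(x$separation)) {
    cat("Seed-group separation cut-offs:\n")
    print(x$separation)
  }
  invisible(x)
}

#' Extract the cluster(s) containing seed sequences
#'
#' At the given cut-off, returns the union of connected components that
#' contain at least one seed accession — the operation used to pull the
#' putative class III cluster out of the full network.
#'
#' @param network A `cdh_network`.
#' @param cutoff AS cut-off at which components are formed.
#' @param seeds Character vector of seed accessions (must be nodes).
#' @return The extracted record tibble (subset of `network$nodes`), with
#'   attributes `cutoff` and `seeds` recording provenance.
#' @export
extract_cluster <- function(network, cutoff, seeds) {
  stopifnot(inherits(network, "cdh_network"))
  unknown <- setdiff(seeds, network$nodes$accession)
  if (length(unknown) > 0) {
    abort_param(sprintf("unknown seed accession(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  comp <- components_at_cutoff(network, cutoff)
  seed_comp <- unique(comp$component[comp$accession %in% seeds])
  members <- comp$accession[comp$component %in% seed_comp]
  out <- network$nodes[network$nodes$accession %in% members, , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  attr(out, "seeds") <- seeds
  out
}

#' Write a network as node and edge tables
#'
#' TSV tables importable by standard graph viewers: nodes with component id
#' and size at the build threshold, edges with AS and percent identity.
#'
#' @param network A `cdh_network`.
#' @param node_path,edge_path Output TSV paths.
#' @return Invisibly, a list of the two tibbles written.
#' @export
write_network_tables <- function(network, node_path, edge_path) {
  comp <- components_at_cutoff(network, network$build_threshold)
  comp <- dplyr::add_count(comp, .data$component, name = "component_size")
  utils::write.table(comp, node_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(network$edges, edge_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(nodes = comp, edges = network$edges))
}
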