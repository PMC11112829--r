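#' Assign tree leaves to sub-clades by an evolutionary-distance threshold
#'
#' After pruning the outgroup leaves, every edge whose child's root-to-node
#' path distance first exceeds `threshold` is cut; the leaves of each cut
#' subtree form one sub-clade. Leaves never separated from the root (all of
#' whose ancestors, and themselves, stay within the threshold) form a
#' single residual clade, so a zero-depth star tree yields one clade.
#' Clades are numbered deterministically by their smallest leaf name.
#'
#' @param tree A `phylo` object, a Newick string, or a path to a Newick
#'   file. Branch lengths are required.
#' @param threshold Root-to-node distance cut (default 0.4, the sub-clade
#'   definition used for candidate selection).
#' @param outgroups Accessions pruned before clade assignment.
#' @param records Optional record tibble; leaves absent from it trigger a
#'   warning.
#' @return A `cdh_clades` object: tibble `accession`, `clade`, plus the
#'   threshold and outgroups as attributes.
#' @export
clades_from_tree <- function(tree, threshold = 0.4, outgroups = character(),
                             records = NULL) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) abort_param("tree has no branch lengths")
  outgroups <- intersect(outgroups, phy$tip.label)
  if (length(outgroups) > 0) {
    if (length(outgroups) >= length(phy$tip.label) - 1) {
      abort_param("pruning outgroups leaves fewer than 2 leaves")
    }
    phy <- ape::drop.tip(phy, outgroups)
  }
  if (!is.null(records)) {
    absent <- setdiff(phy$tip.label, records$accession)
    if (length(absent) > 0) {
      warning(sprintf("%d tree leaves absent from the record set: %s",
                      length(absent), paste(absent, collapse = ", ")),
              call. = FALSE)
    }
  }
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)  # root-to-node distances
  root <- ntip + 1L
  parent_of <- integer(max(phy$edge))
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]

  # cut node: first node on its root path whose depth exceeds the threshold
  cut_of_leaf <- function(tip) {
    path <- tip
    node <- tip
    while (node != root) { node <- parent_of[node]; path <- c(path, node) }
    path <- rev(path)  # root ... tip
    over <- which(depth[path] > threshold)
    if (length(over) == 0) 0L else path[over[1]]
  }
  cuts <- vapply(seq_len(ntip), cut_of_leaf, integer(1))
  groups <- split(phy$tip.label, cuts)
  ord <- order(vapply(groups, min, character(1)))
  assignment <- purrr::map_dfr(seq_along(ord), function(k) {
    tibble::tibble(accession = sort(groups[[ord[k]]]), clade = k)
  })
  structure(assignment, class = c("cdh_clades", class(assignment)),
            threshold = threshold, outgroups = outgroups)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (grepl("\\(", tree)) return(ape::read.tree(text = tree))
    if (file.exists(tree)) return(ape::read.tree(tree))
  }
  abort_param("tree must be a phylo object, Newick string or file path")
}

#' Select expression candidates across sub-clades
#'
#' Picks `per_clade` records from every sub-clade to ensure a spread of
#' candidates across the tree, preferring records whose `priority` column
#' is TRUE (e.g. a plant-associated-lifestyle flag) and breaking ties by
#' accession order. Selection is fully deterministic.
#'
#' @param assignment A `cdh_clades` object (or tibble `accession`,
#'   `clade`).
#' @param records Record tibble covering the assigned accessions; an
#'   optional logical column named by `priority` marks preferred records.
#' @param per_clade Number of candidates per sub-clade.
#' @param priority Name of the logical priority column (default
#'   `"lifestyle"`); ignored when absent.
#' @return Tibble of selected records with their `clade`.
#' @export
select_candidates <- function(assignment, records, per_clade = 1,
                              priority = "lifestyle") {
  assert_records(records)
  joined <- dplyr::inner_join(tibble::as_tibble(assignment), records,
                              by = "accession")
  empty <- setdiff(unique(assignment$clade), unique(joined$clade))
  if (length(empty) > 0) {
    warning(sprintf("clade(s) with no records skipped: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  pri <- if (priority %in% names(joined)) {
    !is.na(joined[[priority]]) & as.logical(joined[[priority]])
  } else rep(FALSE, nrow(joined))
  joined$.priority <- pri
  out <- joined |>
    dplyr::arrange(.data$clade, dplyr::desc(.data$.priority),
                   .data$accession) |>
    dplyr::group_by(.data$clade) |>
    dplyr::slice_head(n = per_clade) |>
    dplyr::ungroup() |>
    dplyr::select(-".priority")
  out
}
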