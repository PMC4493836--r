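# Simplified phylogenetic placement: score each inferred peptide against
# every reference leaf, attach it to the best leaf or (under near-ties) the
# candidates' last common ancestor, trim low-mass nodes, classify, export a
# fat tree, and aggregate taxon abundances. This stands in for a full ML
# evolutionary-placement backend with the same query -> node + mass
# interface, so one can be swapped in later.

#' Bundle a reference alignment, tree and taxonomy
#'
#' @param alignment Protein multiple alignment: data.frame (`id`, `seq`)
#'   from [read_fasta()] or a named character vector of equal-length rows.
#' @param tree An `ape::phylo` tree (or path to a Newick file) whose leaf
#'   labels equal the alignment ids; at least 3 leaves.
#' @param taxonomy Data.frame with a `leaf_id` column plus ranked lineage
#'   columns (e.g. `domain` .. `species`), or path to such a TSV.
#' @return List of class `reference_set`.
#' @export
reference_set <- function(alignment, tree, taxonomy = NULL) {
  if (is.data.frame(alignment)) alignment <- stats::setNames(alignment$seq, alignment$id)
  if (length(unique(nchar(alignment))) != 1L) {
    stop("reference alignment rows must have equal length", call. = FALSE)
  }
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) stop("reference tree needs at least 3 leaves", call. = FALSE)
  if (!setequal(tree$tip.label, names(alignment))) {
    stop("tree leaf set must equal the alignment id set", call. = FALSE)
  }
  if (is.character(taxonomy)) taxonomy <- utils::read.delim(taxonomy, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    stopifnot("leaf_id" %in% names(taxonomy))
    missing <- setdiff(tree$tip.label, taxonomy$leaf_id)
    if (length(missing)) {
      stop("taxonomy is missing leaves: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(alignment = alignment, tree = tree, taxonomy = taxonomy),
            class = "reference_set")
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Align a peptide against each reference row
#'
#' Local alignment (BLOSUM62, gap open 11 / extend 1) of the query against
#' the ungapped form of every reference alignment row. A query matching
#' fewer than `min_matched_columns` positions against its best row is
#' flagged unalignable.
#'
#' @param peptide Amino-acid string (inferred peptide, >= 30 aa upstream of
#'   here, but any non-empty string is scored).
#' @param ref_alignment Reference alignment (data.frame or named character
#'   vector of gapped rows).
#' @param min_matched_columns Alignment width below which the query is
#'   unalignable.
#' @return List with `scores` (data.frame `ref_id`, `score`,
#'   `identity_pct`, `coverage_pct`, `matched_columns`), `best_ref` and
#'   `unalignable`.
#' @export
align_to_reference <- function(peptide, ref_alignment, min_matched_columns = 10L) {
  if (is.data.frame(ref_alignment)) {
    ref_alignment <- stats::setNames(ref_alignment$seq, ref_alignment$id)
  }
  mat <- .blosum62()
  q <- Biostrings::AAString(toupper(peptide))
  rows <- gsub("-", "", toupper(ref_alignment), fixed = TRUE)
  subj <- Biostrings::AAStringSet(rows)
  al <- Biostrings::pairwiseAlignment(rep(Biostrings::AAStringSet(as.character(q)),
                                          length(subj)),
                                      subj, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 11, gapExtension = 1)
  width <- Biostrings::nchar(al)  # alignment width, gaps included
  qlen <- length(q)
  aligned_q <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
  scores <- data.frame(
    ref_id = names(ref_alignment),
    score = Biostrings::score(al),
    identity_pct = Biostrings::pid(al),
    coverage_pct = 100 * aligned_q / qlen,
    matched_columns = width,
    stringsAsFactors = FALSE)
  best <- which.max(scores$score)
  unalignable <- !is.finite(scores$score[best]) ||
    scores$matched_columns[best] < min_matched_columns ||
    scores$score[best] <= 0
  list(scores = scores, best_ref = scores$ref_id[best], unalignable = unalignable)
}

#' Place one peptide on the reference tree
#'
#' Scores the query against every leaf; leaves within `near_tie_margin`
#' percent identity of the best form the candidate set. A single candidate
#' receives the placement (mass 1) at its leaf; several candidates place
#' the query at their last common ancestor with mass 1. In `multi` mode
#' the mass is instead spread over the `top_k` best leaves proportionally
#' to their (positive) alignment scores.
#'
#' @param peptide Amino-acid string.
#' @param refs A [reference_set()].
#' @param near_tie_margin Identity margin (percentage points) defining a
#'   near-tie.
#' @param mode `"best"` (leaf/LCA, default) or `"multi"`.
#' @param top_k Number of leaves receiving mass in `multi` mode.
#' @param peptide_id Label carried into the result.
#' @return Data.frame of placements (`peptide_id`, `node`, `node_label`,
#'   `mass`, `score`); zero rows when the query is unalignable (counted
#'   unclassified by the caller).
#' @export
place <- function(peptide, refs, near_tie_margin = 2, mode = c("best", "multi"),
                  top_k = 3L, peptide_id = "query") {
  mode <- match.arg(mode)
  stopifnot(inherits(refs, "reference_set"))
  tree <- refs$tree
  ali <- align_to_reference(peptide, refs$alignment)
  empty <- data.frame(peptide_id = character(0), node = integer(0),
                      node_label = character(0), mass = numeric(0), score = numeric(0))
  if (ali$unalignable) return(empty)
  sc <- ali$scores
  node_of_tip <- function(id) match(id, tree$tip.label)

  if (mode == "multi") {
    ord <- order(sc$score, decreasing = TRUE)
    top <- sc[ord[seq_len(min(top_k, nrow(sc)))], , drop = FALSE]
    top <- top[top$score > 0, , drop = FALSE]
    w <- top$score / sum(top$score)
    return(data.frame(peptide_id = peptide_id, node = node_of_tip(top$ref_id),
                      node_label = top$ref_id, mass = w, score = top$score,
                      stringsAsFactors = FALSE))
  }

  best <- max(sc$identity_pct)
  cand <- sc$ref_id[sc$identity_pct >= best - near_tie_margin]
  if (length(cand) == 1L) {
    node <- node_of_tip(cand)
    label <- cand
  } else {
    node <- ape::getMRCA(tree, cand)
    label <- if (!is.null(tree$node.label) &&
                 nzchar(tree$node.label[node - length(tree$tip.label)] %||% "")) {
      tree$node.label[node - length(tree$tip.label)]
    } else {
      paste0("node", node)
    }
  }
  data.frame(peptide_id = peptide_id, node = node, node_label = label,
             mass = 1, score = max(sc$score), stringsAsFactors = FALSE)
}

#' Place a set of peptides
#'
#' @param peptides Named character vector (or data.frame with `read_id`
#'   and `peptide` columns, as produced by [filter_peptides()]).
#' @inheritParams place
#' @return List with `placements` (row-bound [place()] results) and
#'   `n_unclassified` (queries with no placement).
#' @export
place_peptides <- function(peptides, refs, near_tie_margin = 2,
                           mode = "best", top_k = 3L) {
  if (is.data.frame(peptides)) peptides <- stats::setNames(peptides$peptide, peptides$read_id)
  if (is.null(names(peptides))) names(peptides) <- paste0("pep", seq_along(peptides))
  out <- list()
  n_unclassified <- 0L
  for (i in seq_along(peptides)) {
    p <- place(peptides[[i]], refs, near_tie_margin = near_tie_margin,
               mode = mode, top_k = top_k, peptide_id = names(peptides)[i])
    if (nrow(p) == 0L) n_unclassified <- n_unclassified + 1L else out[[length(out) + 1L]] <- p
  }
  placements <- if (length(out)) do.call(rbind, out) else
    data.frame(peptide_id = character(0), node = integer(0), node_label = character(0),
               mass = numeric(0), score = numeric(0))
  list(placements = placements, n_unclassified = n_unclassified)
}

#' Trim low-mass placements
#'
#' Aggregates mass per tree node and removes all placements at nodes whose
#' aggregate falls below `min_mass` of the total placed mass; surviving
#' placements are unchanged. A node at exactly the threshold is retained
#' (the threshold is the minimal admitted mass).
#'
#' @param placements Data.frame of placements.
#' @param min_mass Minimal retained node mass as a fraction of total.
#' @return The surviving placement rows.
#' @export
trim_placements <- function(placements, min_mass = 0.01) {
  if (nrow(placements) == 0L) return(placements)
  total <- sum(placements$mass)
  agg <- tapply(placements$mass, placements$node, sum)
  keep_nodes <- as.integer(names(agg)[agg >= min_mass * total - 1e-12])
  out <- placements[placements$node %in% keep_nodes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Composite classification score
#'
#' A query is classified when `(identity + coverage) / 2` strictly exceeds
#' the threshold (default 93); queries at or below it remain unclassified.
#'
#' @param identity_pct,coverage_pct Percentages in \[0, 100\] (vectorized).
#' @param threshold Composite-score threshold.
#' @return Character vector, `"classified"` or `"unclassified"`.
#' @examples
#' classify_score(90, 94)  # unclassified (score 92)
#' classify_score(96, 92)  # classified (score 94)
#' @export
classify_score <- function(identity_pct, coverage_pct, threshold = 93) {
  if (any(identity_pct < 0 | identity_pct > 100 | coverage_pct < 0 | coverage_pct > 100)) {
    stop("identity and coverage must be percentages in [0, 100]", call. = FALSE)
  }
  ifelse((identity_pct + coverage_pct) / 2 > threshold, "classified", "unclassified")
}

# children of each node in a phylo tree
.tree_children <- function(tree) {
  split(tree$edge[, 2], tree$edge[, 1])
}

# all nodes on the path from the root to `node` (inclusive, root excluded)
.path_to_root <- function(tree, node) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- length(tree$tip.label) + 1L
  path <- integer(0)
  while (node != root && node != 0L) {
    path <- c(path, node)
    node <- parent[node]
  }
  path
}

#' Export a fat tree with placements as PhyloXML
#'
#' Branch width is proportional to the read mass assigned at or below the
#' branch's child node; branches on a root-to-placement path are colored
#' red, all others black. With no placements every branch is black with
#' uniform width. The document is valid XML and re-parsable.
#'
#' @param refs A [reference_set()].
#' @param placements (Trimmed) placements data.frame.
#' @param path Output file.
#' @param max_width Width attached to the heaviest branch.
#' @return `path`, invisibly.
#' @export
export_fat_tree <- function(refs, placements, path, max_width = 10) {
  tree <- refs$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- .tree_children(tree)
  edge_len <- stats::setNames(tree$edge.length %||% rep(1, nrow(tree$edge)),
                              tree$edge[, 2])

  node_mass <- stats::setNames(numeric(max(tree$edge)), seq_len(max(tree$edge)))
  if (nrow(placements)) {
    agg <- tapply(placements$mass, placements$node, sum)
    node_mass[as.integer(names(agg))] <- agg
  }
  # mass at or below each node (post-order accumulation)
  subtree_mass <- node_mass
  accumulate <- function(node) {
    for (k in kids[[as.character(node)]] %||% integer(0)) {
      accumulate(k)
      subtree_mass[node] <<- subtree_mass[node] + subtree_mass[k]
    }
  }
  accumulate(root)
  red_nodes <- unique(unlist(lapply(placements$node, .path_to_root, tree = tree)))

  doc <- xml2::xml_new_root("phyloxml", xmlns = "http://www.phyloxml.org")
  phy <- xml2::xml_add_child(doc, "phylogeny", rooted = "true")
  build <- function(parent_xml, node) {
    clade <- xml2::xml_add_child(parent_xml, "clade")
    nm <- if (node <= ntip) tree$tip.label[node] else paste0("node", node)
    xml2::xml_add_child(clade, "name", nm)
    if (node != root) {
      xml2::xml_add_child(clade, "branch_length",
                          format(unname(edge_len[as.character(node)]), digits = 8))
      w <- if (subtree_mass[node] > 0) {
        max_width * subtree_mass[node] / subtree_mass[root]
      } else 1
      xml2::xml_add_child(clade, "width", format(w, digits = 6))
      col <- xml2::xml_add_child(clade, "color")
      is_red <- node %in% red_nodes
      xml2::xml_add_child(col, "red", if (is_red) "255" else "0")
      xml2::xml_add_child(col, "green", "0")
      xml2::xml_add_child(col, "blue", "0")
    }
    for (k in kids[[as.character(node)]] %||% integer(0)) build(clade, k)
  }
  build(phy, root)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Aggregate placements into a taxon abundance table
#'
#' A placement at a leaf contributes to that leaf's taxon at the requested
#' rank. A placement at an internal node contributes to the deepest rank
#' shared by all leaves of its subtree; if the subtree spans several taxa
#' at the requested rank, the mass is reported at that shallower shared
#' rank instead (it cannot be attributed more finely). Unclassified
#' queries form their own row, and fractions sum to one over classified
#' plus unclassified mass.
#'
#' @param placements Placements data.frame (after optional trimming).
#' @param refs A [reference_set()] with taxonomy.
#' @param rank Column name of the requested rank in the taxonomy.
#' @param n_unclassified Count of unplaced/unclassified queries.
#' @return Data.frame with columns `taxon`, `rank`, `count`, `fraction`.
#' @export
abundance_table <- function(placements, refs, rank, n_unclassified = 0) {
  stopifnot(inherits(refs, "reference_set"), !is.null(refs$taxonomy))
  tax <- refs$taxonomy
  tree <- refs$tree
  ranks <- setdiff(names(tax), "leaf_id")
  if (!rank %in% ranks) stop("unknown rank: ", rank, call. = FALSE)
  rank_idx <- match(rank, ranks)
  ntip <- length(tree$tip.label)

  lineage <- function(leaf) {
    row <- tax[tax$leaf_id == leaf, , drop = FALSE]
    if (nrow(row) == 0L) stop("leaf missing from taxonomy: ", leaf, call. = FALSE)
    unlist(row[1, ranks], use.names = FALSE)
  }
  label_of <- function(node) {
    leaves <- if (node <= ntip) tree$tip.label[node] else
      ape::extract.clade(tree, node)$tip.label
    lins <- vapply(leaves, lineage, character(length(ranks)))
    if (is.null(dim(lins))) lins <- matrix(lins, ncol = 1)
    shared <- 0L
    for (d in seq_len(rank_idx)) {
      if (length(unique(lins[d, ])) == 1L) shared <- d else break
    }
    if (shared == 0L) return(c(taxon = "Unresolved", rank = "none"))
    c(taxon = unname(lins[shared, 1]), rank = ranks[shared])
  }

  rows <- list()
  if (nrow(placements)) {
    for (node in unique(placements$node)) {
      lab <- label_of(node)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = lab[["taxon"]], rank = lab[["rank"]],
        count = sum(placements$mass[placements$node == node]),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) {
    agg <- do.call(rbind, rows)
    stats::aggregate(count ~ taxon + rank, agg, sum)
  } else {
    data.frame(taxon = character(0), rank = character(0), count = numeric(0))
  }
  tab <- rbind(tab, data.frame(taxon = "Unclassified", rank = "none",
                               count = n_unclassified))
  total <- sum(tab$count)
  tab$fraction <- if (total > 0) tab$count / total else 0
  tab <- tab[order(-tab$count, tab$taxon), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
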