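# Seeded generators for gene families, amplicon read libraries and
# reference sets with known ground truth. The default model: substitutions
# only (no indels), so the alignment is trivially the sequences themselves,
# positional-Hamming in-silico PCR stays exact, and truth checks are exact;
# codon-aware evolution keeps the reading frame open (no internal stops).

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Gene family model
#'
#' Describes a simulated gene family: an ancestor evolved down a random
#' birth tree under per-site substitution, with designated conserved blocks
#' mutating at a reduced rate (emulating the conserved regions that
#' degenerate marker-gene primers target).
#'
#' @param n_leaves Number of family members.
#' @param ancestor_len Ancestor length in nt (rounded up to a codon
#'   multiple when `codon_aware`).
#' @param tree_height Mean root-to-tip divergence in expected
#'   substitutions per site.
#' @param conserved_blocks Data.frame with `start` (0-based), `length`,
#'   `multiplier` (< 1; rate multiplier inside the block); `"auto"` (the
#'   default) plants three 30-nt blocks at 11%, 33% and 55% of the
#'   ancestor length with multiplier 0.05; `NULL` plants none.
#' @param codon_aware Keep frame 1 free of stop codons.
#' @param n_clades 1 for a single random family; 2 plants two diverged
#'   clades joined by long stem branches.
#' @param clade_separation Between-clade divergence (sum of the two stem
#'   branches, expected substitutions per site) when `n_clades == 2`. The
#'   default saturates the stems, so the clades are distinct sequence
#'   clusters that share no conserved windows: the situation in which a
#'   hypervariable gene family defeats single-pair primer design and must
#'   be partitioned phylogenetically before designing per-group primers.
#' @param seed RNG seed; identical seeds give identical families.
#' @export
family_model <- function(n_leaves = 20L, ancestor_len = 900L, tree_height = 0.10,
                         conserved_blocks = "auto",
                         codon_aware = TRUE, n_clades = 1L,
                         clade_separation = 1.5, seed = 1L) {
  stopifnot(n_leaves >= 2L, ancestor_len >= 30L, tree_height >= 0,
            n_clades %in% c(1L, 2L))
  if (identical(conserved_blocks, "auto")) {
    len <- max(10L, min(30L, ancestor_len %/% 10L))
    conserved_blocks <- data.frame(
      start = as.integer(round(ancestor_len * c(0.11, 0.33, 0.55))),
      length = len, multiplier = 0.05)
  }
  if (!is.null(conserved_blocks) && nrow(conserved_blocks)) {
    stopifnot(all(conserved_blocks$multiplier >= 0),
              all(conserved_blocks$start + conserved_blocks$length <= ancestor_len))
  }
  structure(list(n_leaves = as.integer(n_leaves), ancestor_len = as.integer(ancestor_len),
                 tree_height = tree_height, conserved_blocks = conserved_blocks,
                 codon_aware = isTRUE(codon_aware), n_clades = as.integer(n_clades),
                 clade_separation = clade_separation, seed = as.integer(seed)),
            class = "family_model")
}

.scale_tree <- function(tr, height) {
  depth <- max(ape::node.depth.edgelength(tr))
  if (depth > 0) tr$edge.length <- tr$edge.length * (height / depth)
  tr
}

.random_codon_seq <- function(len) {
  n_codons <- ceiling(len / 3)
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      if (!cd %in% STOP_CODONS) break
    }
    codons[i] <- cd
  }
  strsplit(paste(codons, collapse = ""), "")[[1]]
}

# substitute `seq` (char vector) along a branch: per-site substitution
# probability = branch_len * site_multiplier, capped at 0.75
.evolve_branch <- function(seq, branch_len, site_mult, codon_aware) {
  p <- pmin(branch_len * site_mult, 0.75)
  hit <- which(stats::runif(length(seq)) < p)
  for (i in hit) {
    alts <- setdiff(c("A", "C", "G", "T"), seq[i])
    if (codon_aware) {
      cd_start <- i - (i - 1L) %% 3L
      ok <- vapply(alts, function(b) {
        cd <- seq[cd_start:(cd_start + 2L)]
        cd[i - cd_start + 1L] <- b
        !(paste(cd, collapse = "") %in% STOP_CODONS)
      }, TRUE)
      alts <- alts[ok]
      if (length(alts) == 0L) next
    }
    seq[i] <- sample(alts, 1L)
  }
  seq
}

#' Simulate a gene family with known conserved blocks
#'
#' @param model A [family_model()].
#' @return List with `records` (data.frame `id`, `description`, `seq`; no
#'   indels, so this is simultaneously the alignment), `alignment` (named
#'   character vector), `tree` (`ape::phylo`, leaf ids match records),
#'   `ancestor`, `blocks` (the planted conserved-block coordinates),
#'   `clades` (named leaf -> clade label when two clades were planted) and
#'   `model`.
#' @export
simulate_family <- function(model = family_model()) {
  set.seed(model$seed)
  len <- model$ancestor_len
  if (model$codon_aware) len <- as.integer(3 * ceiling(len / 3))

  clades <- NULL
  if (model$n_clades == 2L) {
    n1 <- model$n_leaves %/% 2L
    n2 <- model$n_leaves - n1
    within <- model$tree_height
    t1 <- .scale_tree(ape::rtree(n1, tip.label = paste0("A", seq_len(n1))), within)
    t2 <- .scale_tree(ape::rtree(n2, tip.label = paste0("B", seq_len(n2))), within)
    stem <- model$clade_separation / 2
    nwk <- sprintf("(%s:%f,%s:%f);",
                   sub(";$", "", ape::write.tree(t1)), stem,
                   sub(";$", "", ape::write.tree(t2)), stem)
    tr <- ape::read.tree(text = nwk)
    clades <- stats::setNames(c(rep("A", n1), rep("B", n2)),
                              c(paste0("A", seq_len(n1)), paste0("B", seq_len(n2))))
  } else {
    tr <- .scale_tree(ape::rtree(model$n_leaves,
                                 tip.label = paste0("t", seq_len(model$n_leaves))),
                      model$tree_height)
  }

  site_mult <- rep(1, len)
  blocks <- model$conserved_blocks
  if (!is.null(blocks) && nrow(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      idx <- (blocks$start[b] + 1L):(blocks$start[b] + blocks$length[b])
      site_mult[idx] <- blocks$multiplier[b]
    }
  }

  ancestor <- if (model$codon_aware) .random_codon_seq(len) else
    sample(c("A", "C", "G", "T"), len, replace = TRUE)

  ntip <- length(tr$tip.label)
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  seqs <- vector("list", max(tr$edge))
  root <- ntip + 1L
  seqs[[root]] <- ancestor
  # In the two-clade model the stem branches evolve at full rate across all
  # sites: the clades diverge inside the conserved blocks too, emulating a
  # hypervariable family whose conserved clusters exist only within groups.
  walk <- function(node) {
    for (e in kids[[as.character(node)]] %||% integer(0)) {
      child <- tr$edge[e, 2]
      mult <- if (model$n_clades == 2L && node == root) rep(1, len) else site_mult
      seqs[[child]] <<- .evolve_branch(seqs[[node]], tr$edge.length[e],
                                       mult, model$codon_aware)
      if (child > ntip) walk(child)
    }
  }
  walk(root)

  leaf_seqs <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(leaf_seqs) <- tr$tip.label
  records <- data.frame(id = tr$tip.label, description = "", seq = unname(leaf_seqs),
                        stringsAsFactors = FALSE)
  list(records = records, alignment = leaf_seqs, tree = tr,
       ancestor = paste(ancestor, collapse = ""), blocks = blocks,
       clades = clades, model = model)
}

#' Amplicon library model
#'
#' @param n_read_pairs Number of read pairs.
#' @param read_len Read length in nt (250, the MiSeq 2x250 setting the
#'   markers were validated with).
#' @param on_target_fraction Fraction of pairs drawn from true amplicons.
#' @param error_rate Per-base substitution error rate.
#' @param quality Constant Phred score assigned to every base (constant
#'   qualities keep merge behavior deterministic).
#' @param seed RNG seed.
#' @export
library_model <- function(n_read_pairs = 2000L, read_len = 250L,
                          on_target_fraction = 0.6, error_rate = 0.002,
                          quality = 35L, seed = 1L) {
  stopifnot(n_read_pairs >= 0L, read_len >= 1L,
            on_target_fraction >= 0, on_target_fraction <= 1, error_rate >= 0)
  structure(list(n_read_pairs = as.integer(n_read_pairs), read_len = as.integer(read_len),
                 on_target_fraction = on_target_fraction, error_rate = error_rate,
                 quality = as.integer(quality), seed = as.integer(seed)),
            class = "library_model")
}

.seq_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a paired-end amplicon library with ground truth
#'
#' On-target pairs are read from predicted amplicons of randomly chosen
#' family members (read 1 from the 5' end, read 2 reverse-complemented
#' from the 3' end) with substitution sequencing errors; off-target
#' contaminant pairs are read the same way from random nucleotide
#' fragments of the same length, which merge but match no reference.
#'
#' @param family Result of [simulate_family()].
#' @param pair A [primer_pair()] that amplifies at least one member.
#' @param model A [library_model()].
#' @return List with `pairs` (list of read pairs as in
#'   [read_fastq_pairs()]), `truth` (data.frame `id`, `on_target`,
#'   `source`) and `model`.
#' @export
simulate_amplicon_library <- function(family, pair, model = library_model()) {
  set.seed(model$seed)
  amps <- predict_amplicons(family$records, pair)
  if (model$n_read_pairs > 0L && nrow(amps) == 0L) {
    stop("primer pair amplifies no family member; cannot simulate an on-target library",
         call. = FALSE)
  }
  frag_len <- if (nrow(amps)) as.integer(round(mean(amps$product_bp))) else 2L * model$read_len

  pairs <- vector("list", model$n_read_pairs)
  truth <- data.frame(id = character(model$n_read_pairs),
                      on_target = logical(model$n_read_pairs),
                      source = character(model$n_read_pairs), stringsAsFactors = FALSE)
  qual <- function(n) rep(model$quality, n)
  for (i in seq_len(model$n_read_pairs)) {
    id <- sprintf("read%06d", i)
    on <- stats::runif(1) < model$on_target_fraction
    if (on) {
      a <- amps[sample(nrow(amps), 1L), ]
      frag <- a$sequence
      src <- a$template_id
    } else {
      frag <- paste(sample(c("A", "C", "G", "T"), frag_len, replace = TRUE), collapse = "")
      src <- "contaminant"
    }
    L <- nchar(frag)
    r1 <- substr(frag, 1L, min(model$read_len, L))
    r2 <- revcomp_oligo(substr(frag, max(1L, L - model$read_len + 1L), L))
    r1 <- .seq_errors(r1, model$error_rate)
    r2 <- .seq_errors(r2, model$error_rate)
    pairs[[i]] <- structure(list(id = id, seq1 = r1, seq2 = r2,
                                 qual1 = qual(nchar(r1)), qual2 = qual(nchar(r2))),
                            class = "read_pair")
    truth$id[i] <- id; truth$on_target[i] <- on; truth$source[i] <- src
  }
  list(pairs = pairs, truth = truth, model = model)
}

#' Build a reference set (protein alignment, tree, taxonomy) from a family
#'
#' Translates every family member in frame 1 (codon-aware families are
#' stop-free there), reuses the true family tree as the reference tree and
#' assigns a synthetic ranked taxonomy by clade: a single domain, orders
#' from the two root subtrees, genera from average-linkage clusters of the
#' tree distances, species per leaf.
#'
#' @param family Result of [simulate_family()] with `codon_aware = TRUE`.
#' @param n_genera Number of genus-level clusters.
#' @return A [reference_set()].
#' @export
simulate_reference_set <- function(family, n_genera = 4L) {
  if (!family$model$codon_aware) {
    stop("reference sets need a codon-aware family (frame-1 translation)", call. = FALSE)
  }
  prot <- vapply(family$alignment, function(s) {
    as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(s), if.fuzzy.codon = "X")))
  }, "")
  tr <- family$tree
  ntip <- length(tr$tip.label)

  root_kids <- tr$edge[tr$edge[, 1] == ntip + 1L, 2]
  order_of <- stats::setNames(rep("Order_1", ntip), tr$tip.label)
  if (length(root_kids) >= 2L) {
    for (k in seq_along(root_kids)) {
      tips <- if (root_kids[k] <= ntip) tr$tip.label[root_kids[k]] else
        ape::extract.clade(tr, root_kids[k])$tip.label
      order_of[tips] <- paste0("Order_", k)
    }
  }
  d <- stats::as.dist(ape::cophenetic.phylo(tr))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = min(n_genera, ntip))
  taxonomy <- data.frame(leaf_id = tr$tip.label,
                         domain = "Archaea_syn",
                         order = unname(order_of[tr$tip.label]),
                         genus = paste0("Genus_", unname(cl[tr$tip.label])),
                         species = tr$tip.label, stringsAsFactors = FALSE)
  reference_set(alignment = prot, tree = tr, taxonomy = taxonomy)
}

#' Simulate a query peptide from a reference leaf
#'
#' Applies random amino-acid substitutions to (a fragment of) a leaf's
#' reference peptide; used to benchmark placement soundness.
#'
#' @param refs A [reference_set()].
#' @param leaf Leaf id to mutate.
#' @param divergence Fraction of residues substituted.
#' @param fragment_aa Optional fragment length drawn from a random
#'   position (NULL uses the whole row).
#' @return Amino-acid string.
#' @export
simulate_query_peptide <- function(refs, leaf, divergence = 0.05, fragment_aa = NULL) {
  aa <- gsub("-", "", refs$alignment[[leaf]], fixed = TRUE)
  if (!is.null(fragment_aa) && fragment_aa < nchar(aa)) {
    start <- sample(nchar(aa) - fragment_aa + 1L, 1L)
    aa <- substr(aa, start, start + fragment_aa - 1L)
  }
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_mut <- round(divergence * length(ch))
  if (n_mut > 0) {
    idx <- sample(length(ch), n_mut)
    for (i in idx) ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Write the parameters of a simulation as a JSON manifest
#'
#' @param model A `family_model`, `library_model`, or any parameter list.
#' @param path Output JSON file.
#' @export
write_manifest <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
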