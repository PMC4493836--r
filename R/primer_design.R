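# Conserved-window detection and minimal-degeneracy primer pair enumeration
# on a nucleotide multiple alignment, plus NJ-guided partitioning of
# hypervariable families into designable clusters.

#' Design configuration
#'
#' Constraints under which candidate degenerate primers are generated:
#' primer length range, maximum amplicon size (short products keep both
#' 454 and Illumina platforms usable), a cap on per-primer degeneracy,
#' and the fraction of aligned sequences a window consensus must cover.
#'
#' @param primer_len_range Integer vector `c(min, max)` primer length in nt.
#' @param max_product_bp Maximum amplicon length (primers included).
#' @param max_primer_degeneracy Windows whose minimal covering consensus is
#'   more degenerate than this are dropped.
#' @param min_coverage Per-column fraction of sequences the consensus code
#'   must cover; 1.0 covers every observed base, lower values allow rare
#'   variants to be ignored.
#' @param max_gap_fraction Maximum per-column gap fraction inside a window.
#' @param max_candidate_windows Pair enumeration considers at most this many
#'   lowest-degeneracy windows.
#' @return A list of class `design_config`.
#' @export
design_config <- function(primer_len_range = c(16L, 25L),
                          max_product_bp = 500L,
                          max_primer_degeneracy = 1024,
                          min_coverage = 1.0,
                          max_gap_fraction = 0,
                          max_candidate_windows = 100L) {
  stopifnot(length(primer_len_range) == 2L, primer_len_range[1] >= 1L,
            primer_len_range[2] >= primer_len_range[1],
            max_product_bp > 0, max_primer_degeneracy >= 1,
            min_coverage > 0, min_coverage <= 1,
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  structure(list(primer_len_range = as.integer(primer_len_range),
                 max_product_bp = as.integer(max_product_bp),
                 max_primer_degeneracy = max_primer_degeneracy,
                 min_coverage = min_coverage,
                 max_gap_fraction = max_gap_fraction,
                 max_candidate_windows = as.integer(max_candidate_windows)),
            class = "design_config")
}

#' A primer pair
#'
#' @param forward,reverse [degenerate_oligo()] objects (the reverse primer is
#'   written 5'->3' on the opposite strand, as primers are ordered).
#' @param expected_product_bp Expected amplicon length, primer-inclusive.
#' @param max_mismatch Per-primer mismatch budget used by in-silico PCR.
#' @return A list of class `primer_pair`; `pair_degeneracy` is the product
#'   of the two primer degeneracies.
#' @export
primer_pair <- function(forward, reverse, expected_product_bp = NA_integer_,
                        max_mismatch = 2L) {
  if (is.character(forward)) forward <- degenerate_oligo(forward, orientation = "forward")
  if (is.character(reverse)) reverse <- degenerate_oligo(reverse, orientation = "reverse")
  stopifnot(inherits(forward, "degenerate_oligo"), inherits(reverse, "degenerate_oligo"))
  if (!is.na(expected_product_bp) &&
      expected_product_bp < nchar(forward$seq) + nchar(reverse$seq)) {
    stop("expected_product_bp smaller than the two primers combined", call. = FALSE)
  }
  structure(list(forward = forward, reverse = reverse,
                 expected_product_bp = as.integer(expected_product_bp),
                 pair_degeneracy = oligo_degeneracy(forward) * oligo_degeneracy(reverse),
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s/%s product ~%s bp, pair degeneracy %d, budget %d mm\n",
              x$forward$name, x$reverse$name,
              ifelse(is.na(x$expected_product_bp), "?", x$expected_product_bp),
              x$pair_degeneracy, x$max_mismatch))
  cat(sprintf("  fwd 5'-%s-3'\n  rev 5'-%s-3'\n", x$forward$seq, x$reverse$seq))
  invisible(x)
}

# Coerce records (data.frame from read_fasta, named character vector, or a
# character matrix) to an upper-case character matrix rows = sequences.
alignment_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else {
    if (is.data.frame(aln)) {
      seqs <- stats::setNames(aln$seq, aln$id)
    } else {
      seqs <- aln
    }
    if (length(unique(nchar(seqs))) != 1L) {
      stop("aligned sequences must all have the same length", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  m[m == "U"] <- "T"
  bad <- !(m %in% c(IUPAC_LETTERS, "-"))
  if (any(bad)) {
    stop(sprintf("alignment contains invalid character '%s'", m[bad][1]), call. = FALSE)
  }
  m
}

# Minimal covering IUPAC code for one alignment column under min_coverage.
# Greedy: add the base covering the most additional sequences until the
# covered fraction reaches the threshold. A sequence is covered when its
# own code's expansion is contained in the chosen set; gapped sequences
# are never covered. Returns list(code, covered = logical per sequence).
.column_consensus <- function(col, min_coverage) {
  n <- length(col)
  exp_sets <- lapply(col, function(c) if (c == "-") character(0) else IUPAC_CODES[[c]])
  chosen <- character(0)
  repeat {
    covered <- vapply(exp_sets, function(s) length(s) > 0L && all(s %in% chosen), TRUE)
    if (sum(covered) / n >= min_coverage) break
    gain <- vapply(c("A", "C", "G", "T"), function(b) {
      if (b %in% chosen) return(-1L)
      cand <- c(chosen, b)
      sum(vapply(exp_sets, function(s) length(s) > 0L && all(s %in% cand), TRUE)) - sum(covered)
    }, 0L)
    if (all(gain <= 0L)) break  # nothing left to gain (e.g. all-gap column)
    chosen <- c(chosen, names(which.max(gain)))
  }
  chosen <- sort(chosen)
  code <- names(IUPAC_CODES)[vapply(IUPAC_CODES, function(s) identical(sort(s), chosen), TRUE)]
  if (length(code) == 0L) code <- NA_character_  # all-gap column
  covered <- vapply(exp_sets, function(s) length(s) > 0L && all(s %in% chosen), TRUE)
  list(code = code, covered = covered)
}

#' Find conserved windows in a nucleotide alignment
#'
#' Slides every window in the configured primer length range over the
#' alignment and reports those whose per-column minimal covering IUPAC
#' consensus stays under the degeneracy cap. A window is admissible only
#' when no column exceeds `max_gap_fraction`.
#'
#' @param aln Aligned sequences: data.frame from [read_fasta()], a named
#'   character vector, or a character matrix.
#' @param cfg A [design_config()].
#' @return A data.frame sorted by ascending degeneracy then start, with
#'   columns `start`, `end` (0-based half-open columns), `length`,
#'   `consensus`, `degeneracy` and `coverage` (fraction of sequences the
#'   expanded consensus fully matches over the window).
#' @export
find_conserved_windows <- function(aln, cfg = design_config()) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 aligned sequences", call. = FALSE)
  L <- ncol(m)
  if (cfg$primer_len_range[1] > L) {
    stop("primer length range exceeds alignment length", call. = FALSE)
  }

  gap_frac <- colMeans(m == "-")
  admissible <- gap_frac <= cfg$max_gap_fraction
  cons <- lapply(seq_len(L), function(j) .column_consensus(m[, j], cfg$min_coverage))
  codes <- vapply(cons, `[[`, "", "code")
  col_deg <- ifelse(is.na(codes), NA_real_, lengths(IUPAC_CODES)[codes])
  covered <- do.call(cbind, lapply(cons, `[[`, "covered"))  # n x L logical
  admissible <- admissible & !is.na(codes)

  # cumulative sums make per-window products / coverage O(1)
  cum_logdeg <- cumsum(c(0, log(ifelse(is.na(col_deg), 1, col_deg))))
  cum_bad <- cumsum(c(0, as.integer(!admissible)))
  cum_uncov <- cbind(0L, t(apply(!covered, 1L, cumsum)))  # n x (L+1)

  res <- list()
  for (len in cfg$primer_len_range[1]:cfg$primer_len_range[2]) {
    if (len > L) next
    starts <- seq_len(L - len + 1L)
    ok <- (cum_bad[starts + len] - cum_bad[starts]) == 0L
    if (!any(ok)) next
    starts <- starts[ok]
    deg <- exp(cum_logdeg[starts + len] - cum_logdeg[starts])
    keep <- deg <= cfg$max_primer_degeneracy * (1 + 1e-9)
    if (!any(keep)) next
    starts <- starts[keep]
    deg <- round(deg[keep])
    cov <- vapply(starts, function(s) {
      mean((cum_uncov[, s + len] - cum_uncov[, s]) == 0L)
    }, 0)
    consensus <- vapply(starts, function(s) paste(codes[s:(s + len - 1L)], collapse = ""), "")
    res[[length(res) + 1L]] <- data.frame(
      start = starts - 1L, end = starts - 1L + len, length = len,
      consensus = consensus, degeneracy = deg, coverage = cov,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0),
                      consensus = character(0), degeneracy = numeric(0),
                      coverage = numeric(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$degeneracy, out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate candidate primer pairs from conserved windows
#'
#' Forms all upstream/downstream window combinations, takes the upstream
#' consensus as the forward primer and the reverse complement of the
#' downstream consensus as the reverse primer, and keeps pairs whose
#' expected product (the median ungapped span across the aligned
#' sequences, primer-inclusive) does not exceed the configured maximum.
#' Ranking is by pair degeneracy ascending, then product length
#' descending (longer amplicons carry more phylogenetic signal), then
#' leftmost forward start.
#'
#' @inheritParams find_conserved_windows
#' @param windows Result of [find_conserved_windows()] on the same alignment.
#' @return A data.frame of ranked candidates with columns `fwd_seq`,
#'   `rev_seq`, `fwd_start`, `fwd_end`, `rev_start`, `rev_end`,
#'   `expected_product_bp`, `pair_degeneracy`. When no pair is admissible
#'   the empty result carries a `diagnostic` attribute naming the binding
#'   constraint.
#' @export
enumerate_pairs <- function(windows, aln, cfg = design_config()) {
  m <- alignment_matrix(aln)
  empty <- data.frame(fwd_seq = character(0), rev_seq = character(0),
                      fwd_start = integer(0), fwd_end = integer(0),
                      rev_start = integer(0), rev_end = integer(0),
                      expected_product_bp = integer(0), pair_degeneracy = numeric(0))
  if (nrow(windows) == 0L) {
    attr(empty, "diagnostic") <- "no conserved windows under the degeneracy/gap constraints"
    return(empty)
  }
  # candidate thinning must preserve positional spread: keep the few
  # lowest-degeneracy windows per 50-column stretch, then cap overall
  bucket <- windows$start %/% 50L
  ord <- order(windows$degeneracy, windows$start, windows$length)
  per_bucket <- unlist(lapply(split(ord, bucket[ord]),
                              utils::head, 3L), use.names = FALSE)
  w <- windows[sort(per_bucket), , drop = FALSE]
  if (nrow(w) > cfg$max_candidate_windows) {
    w <- w[order(w$degeneracy, w$start, w$length), , drop = FALSE]
    w <- utils::head(w, cfg$max_candidate_windows)
  }
  nongap <- m != "-"
  cum_nt <- cbind(0L, t(apply(nongap, 1L, cumsum)))  # per-seq ungapped prefix counts

  res <- list()
  n_disjoint <- 0L
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(nrow(w))) {
      if (w$start[j] < w$end[i]) next  # downstream, non-overlapping
      n_disjoint <- n_disjoint + 1L
      # ungapped span from forward start to reverse end, per sequence
      span <- cum_nt[, w$end[j] + 1L] - cum_nt[, w$start[i] + 1L]
      product <- as.integer(round(stats::median(span)))
      if (product > cfg$max_product_bp) next
      if (product < w$length[i] + w$length[j]) next
      res[[length(res) + 1L]] <- data.frame(
        fwd_seq = w$consensus[i], rev_seq = revcomp_oligo(w$consensus[j]),
        fwd_start = w$start[i], fwd_end = w$end[i],
        rev_start = w$start[j], rev_end = w$end[j],
        expected_product_bp = product,
        pair_degeneracy = w$degeneracy[i] * w$degeneracy[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    attr(empty, "diagnostic") <- if (n_disjoint == 0L) {
      "no two non-overlapping conserved windows"
    } else {
      sprintf("all %d window combinations violate the product-size bounds (max %d bp)",
              n_disjoint, cfg$max_product_bp)
    }
    return(empty)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$pair_degeneracy, -out$expected_product_bp, out$fwd_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design ranked primer pairs from an alignment
#'
#' Convenience wrapper: [find_conserved_windows()] then [enumerate_pairs()].
#'
#' @inheritParams find_conserved_windows
#' @return See [enumerate_pairs()].
#' @export
design_primers <- function(aln, cfg = design_config()) {
  enumerate_pairs(find_conserved_windows(aln, cfg), aln, cfg)
}

#' Convert one design candidate row to a primer_pair
#'
#' @param design Data.frame from [enumerate_pairs()].
#' @param row Row index (default: the top-ranked candidate).
#' @param max_mismatch Mismatch budget to attach.
#' @export
pair_from_design <- function(design, row = 1L, max_mismatch = 2L) {
  stopifnot(nrow(design) >= row)
  primer_pair(design$fwd_seq[row], design$rev_seq[row],
              expected_product_bp = design$expected_product_bp[row],
              max_mismatch = max_mismatch)
}

#' Partition a hypervariable gene family into designable clusters
#'
#' Some gene families (mcrG is the motivating case) are too variable for a
#' single primer pair. A neighbor-joining guide tree is built from pairwise
#' p-distances on the alignment, and the family is iteratively bisected at
#' the longest internal branch until every group admits at least one primer
#' pair under the design constraints, or `max_groups` is reached.
#'
#' @param seqs Aligned sequences (data.frame from [read_fasta()] or a named
#'   character vector); at least 4.
#' @param cfg A [design_config()].
#' @param max_groups Stop splitting beyond this many groups.
#' @return List of groups, each a list with `ids`, `seqs` (named character
#'   vector) and `designable` (logical).
#' @export
partition_by_tree <- function(seqs, cfg = design_config(), max_groups = 2L) {
  m <- alignment_matrix(seqs)
  if (nrow(m) < 4L) stop("need at least 4 sequences to partition", call. = FALSE)
  if (max_groups > nrow(m)) stop("more groups requested than sequences", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))

  designable <- function(rows) {
    sub <- m[rows, , drop = FALSE]
    keep <- colMeans(sub == "-") < 1          # drop all-gap columns
    sub <- sub[, keep, drop = FALSE]
    if (ncol(sub) < cfg$primer_len_range[1]) return(FALSE)
    nrow(design_primers(sub, cfg)) > 0L
  }

  split_group <- function(rows) {
    if (length(rows) < 4L) return(NULL)
    sub <- m[rows, , drop = FALSE]
    dn <- ape::as.DNAbin(sub)
    d <- ape::dist.dna(dn, model = "raw", pairwise.deletion = TRUE)
    if (any(!is.finite(d))) d[!is.finite(d)] <- max(d[is.finite(d)], 0) + 1
    tr <- ape::nj(d)
    tr <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
    ntip <- length(tr$tip.label)
    internal <- tr$edge[, 2] > ntip
    if (!any(internal)) return(NULL)
    e <- which(internal)[which.max(tr$edge.length[internal])]
    clade <- ape::extract.clade(tr, tr$edge[e, 2])$tip.label
    if (length(clade) == 0L || length(clade) == length(rows)) return(NULL)
    list(clade, setdiff(rownames(sub), clade))
  }

  groups <- list(rownames(m))
  flags <- vapply(groups, designable, TRUE)
  repeat {
    todo <- which(!flags & lengths(groups) >= 4L)
    if (length(todo) == 0L || length(groups) >= max_groups) break
    parts <- split_group(groups[[todo[1]]])
    if (is.null(parts)) break
    groups <- c(groups[-todo[1]], parts)
    flags <- vapply(groups, designable, TRUE)
  }
  lapply(seq_along(groups), function(i) {
    ids <- groups[[i]]
    list(ids = ids,
         seqs = stats::setNames(apply(m[ids, , drop = FALSE], 1L, paste, collapse = ""), ids),
         designable = flags[i])
  })
}
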