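# High-throughput amplicon validation: FLASH-like paired-end merging,
# six-frame translated Smith-Waterman search against a reference peptide
# set with Karlin-Altschul E-values, the published filtering rules, and
# the primer-sensitivity statistic.

#' Paired-end merge configuration
#'
#' @param min_overlap Minimum read overlap in nt.
#' @param max_overlap_mismatch_fraction Pairs whose best overlap has a
#'   larger mismatch fraction are left unmerged.
#' @export
merge_config <- function(min_overlap = 10L, max_overlap_mismatch_fraction = 0.25) {
  stopifnot(min_overlap >= 1L,
            max_overlap_mismatch_fraction >= 0, max_overlap_mismatch_fraction <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_overlap_mismatch_fraction = max_overlap_mismatch_fraction),
            class = "merge_config")
}

#' Pipeline configuration for translated search and filtering
#'
#' E-values use the Karlin-Altschul form `E = K * m * n * exp(-lambda * S)`
#' with the standard gapped BLOSUM62 (open 11 / extend 1) parameters
#' `lambda = 0.267`, `K = 0.041`. The effective database size `n` defaults
#' to the total residue count of the reference set at search time.
#'
#' @param evalue_threshold Hits above this E-value count as no-hit.
#' @param min_peptide_len_aa Inferred peptides shorter than this are
#'   discarded (boundary: exactly this length is kept).
#' @param discard_stop_codons Discard peptides containing a stop symbol
#'   (frameshift artifacts).
#' @param gap_opening,gap_extension Local-alignment gap costs.
#' @param lambda,K Karlin-Altschul parameters for the scoring system.
#' @param db_size_for_evalue Effective search-space letters; `NULL` means
#'   the reference set's residue count.
#' @export
pipeline_config <- function(evalue_threshold = 0.001,
                            min_peptide_len_aa = 30L,
                            discard_stop_codons = TRUE,
                            gap_opening = 11, gap_extension = 1,
                            lambda = 0.267, K = 0.041,
                            db_size_for_evalue = NULL) {
  stopifnot(evalue_threshold > 0, min_peptide_len_aa > 0)
  structure(list(evalue_threshold = evalue_threshold,
                 min_peptide_len_aa = as.integer(min_peptide_len_aa),
                 discard_stop_codons = isTRUE(discard_stop_codons),
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 lambda = lambda, K = K,
                 db_size_for_evalue = db_size_for_evalue),
            class = "pipeline_config")
}

.int_chars <- function(s) utf8ToInt(s)

#' Merge paired-end reads by best overlap
#'
#' For each pair, read 2 is reverse-complemented and every overlap length
#' from `min_overlap` up to the shorter read is scored by matched minus
#' mismatched bases; the best-scoring overlap wins (ties go to the shorter
#' overlap, which has the lower mismatch fraction). The mismatch penalty is
#' essential: a long spurious overlap matches about a quarter of its bases
#' by chance, which under a match-only objective would outscore a shorter
#' true overlap. Pairs with no positive-scoring overlap, or whose best
#' overlap exceeds the mismatch-fraction cap, are left unmerged. At
#' conflicting overlap positions the higher-quality base is kept.
#'
#' @param pairs List of read pairs from [read_fastq_pairs()] (elements with
#'   `id`, `seq1`, `seq2`, `qual1`, `qual2`).
#' @param cfg A [merge_config()].
#' @return List with `merged` (data.frame `id`, `seq`, `overlap`,
#'   `mismatch_fraction`) and `n_unmerged`.
#' @export
merge_pairs <- function(pairs, cfg = merge_config()) {
  ids <- character(0); seqs <- character(0); ovl <- integer(0); mmf <- numeric(0)
  n_unmerged <- 0L
  for (p in pairs) {
    r1 <- toupper(p$seq1)
    r2rc <- revcomp_oligo(toupper(p$seq2))
    q1 <- p$qual1
    q2 <- rev(p$qual2)
    a <- .int_chars(r1); b <- .int_chars(r2rc)
    l1 <- length(a); l2 <- length(b)
    best_o <- 0L; best_matches <- 0L; best_score <- 0L
    if (min(l1, l2) >= cfg$min_overlap) {
      for (o in cfg$min_overlap:min(l1, l2)) {
        matches <- sum(a[(l1 - o + 1L):l1] == b[1:o])
        score <- 2L * matches - o   # matches minus mismatches
        if (score > best_score) { best_score <- score; best_matches <- matches; best_o <- o }
      }
    }
    if (best_o == 0L) { n_unmerged <- n_unmerged + 1L; next }
    frac <- (best_o - best_matches) / best_o
    if (frac > cfg$max_overlap_mismatch_fraction) { n_unmerged <- n_unmerged + 1L; next }
    o <- best_o
    ov_idx1 <- (l1 - o + 1L):l1
    ov <- a[ov_idx1]
    conflict <- ov != b[1:o]
    take2 <- conflict & (q2[1:o] > q1[ov_idx1])
    ov[take2] <- b[1:o][take2]
    merged <- intToUtf8(c(a[seq_len(l1 - o)], ov, b[(o + 1L):l2][seq_len(max(0L, l2 - o))]))
    ids <- c(ids, p$id); seqs <- c(seqs, merged); ovl <- c(ovl, o); mmf <- c(mmf, frac)
  }
  list(merged = data.frame(id = ids, seq = seqs, overlap = ovl,
                           mismatch_fraction = mmf, stringsAsFactors = FALSE),
       n_unmerged = n_unmerged)
}

# Six-frame translations, vectorized over reads (one translate() call; the
# fuzzy genetic code is expensive to rebuild). Returns a character matrix
# with rows F1..F3, R1..R3 and one column per read; stops are '*', fuzzy
# codons 'X'.
six_frame_translate <- function(seqs) {
  n <- length(seqs)
  fwd <- Biostrings::DNAStringSet(toupper(seqs))
  rev <- Biostrings::reverseComplement(fwd)
  sub_frames <- list()
  for (off in 0:2) {
    for (s in c("F", "R")) {
      x <- if (s == "F") fwd else rev
      w <- Biostrings::width(x) - off
      w <- pmax(w - w %% 3L, 0L)
      start <- pmin(off + 1L, Biostrings::width(x) + 1L)
      end <- ifelse(w > 0L, off + w, start - 1L)
      sub_frames[[paste0(s, off + 1L)]] <- Biostrings::subseq(x, start, end)
    }
  }
  all_nt <- do.call(c, unname(sub_frames[c("F1", "F2", "F3", "R1", "R2", "R3")]))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(all_nt, if.fuzzy.codon = "X")))
  matrix(aa, nrow = 6L, ncol = n, byrow = TRUE,
         dimnames = list(c("F1", "F2", "F3", "R1", "R2", "R3"), names(seqs)))
}

.frame_code <- c(F1 = 1L, F2 = 2L, F3 = 3L, R1 = -1L, R2 = -2L, R3 = -3L)

#' Translated search of merged reads against a reference peptide set
#'
#' All six reading frames of each read are translated with the standard
#' genetic code (stops kept as `*`) and locally aligned (Smith-Waterman,
#' BLOSUM62, gap open 11 / extend 1) against every reference. The best
#' HSP per read is reported with its Karlin-Altschul E-value; hits with
#' E above the threshold are no-hits.
#'
#' @param merged Character vector of merged nucleotide reads (names used
#'   as read ids) or the `merged` data.frame from [merge_pairs()].
#' @param refs Reference peptides: data.frame (`id`, `seq`) from
#'   [read_fasta()] or a named character vector.
#' @param cfg A [pipeline_config()].
#' @return Data.frame, one row per read: `read_id`, `has_hit`, `frame`,
#'   `best_ref_id`, `score`, `evalue`, `peptide` (the HSP query peptide,
#'   gaps removed), `identity_pct`, `peptide_len`.
#' @export
translated_search <- function(merged, refs, cfg = pipeline_config()) {
  if (is.data.frame(merged)) merged <- stats::setNames(merged$seq, merged$id)
  if (is.data.frame(refs)) refs <- stats::setNames(refs$seq, refs$id)
  if (length(refs) == 0L) stop("reference peptide set is empty", call. = FALSE)
  if (is.null(names(merged))) names(merged) <- paste0("read", seq_along(merged))

  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  mat <- data_env$BLOSUM62
  db_n <- cfg$db_size_for_evalue %||% sum(nchar(refs))
  ref_set <- Biostrings::AAStringSet(toupper(refs))

  # score-only pass: all frames of all reads against each reference
  frames <- six_frame_translate(merged)
  frame_tab <- data.frame(
    read = rep(names(merged), each = 6L),
    frame = rep(names(.frame_code), times = length(merged)),
    aa = as.vector(frames), stringsAsFactors = FALSE)
  frame_tab <- frame_tab[nchar(frame_tab$aa) >= 1L, , drop = FALSE]
  pat <- Biostrings::AAStringSet(frame_tab$aa)

  best_score <- rep(-Inf, nrow(frame_tab))
  best_ref <- rep(NA_integer_, nrow(frame_tab))
  for (r in seq_along(ref_set)) {
    sc <- Biostrings::pairwiseAlignment(pat, ref_set[[r]], type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = cfg$gap_opening,
                                        gapExtension = cfg$gap_extension,
                                        scoreOnly = TRUE)
    better <- sc > best_score
    best_score[better] <- sc[better]
    best_ref[better] <- r
  }
  frame_tab$score <- best_score
  frame_tab$ref <- best_ref

  # best frame per read, E-value from the frame's length
  reads <- names(merged)
  idx_by_read <- split(seq_len(nrow(frame_tab)), frame_tab$read)[reads]
  best_idx <- vapply(idx_by_read, function(ix) {
    if (is.null(ix) || length(ix) == 0L) NA_integer_ else ix[which.max(frame_tab$score[ix])]
  }, 0L)
  out <- data.frame(read_id = reads, has_hit = FALSE, frame = NA_integer_,
                    best_ref_id = NA_character_, score = NA_real_, evalue = NA_real_,
                    peptide = NA_character_, identity_pct = NA_real_,
                    peptide_len = NA_integer_, stringsAsFactors = FALSE)
  ok <- !is.na(best_idx) & is.finite(frame_tab$score[best_idx])
  bi <- best_idx[ok]
  out$frame[ok] <- unname(.frame_code[frame_tab$frame[bi]])
  out$best_ref_id[ok] <- names(refs)[frame_tab$ref[bi]]
  out$score[ok] <- frame_tab$score[bi]
  out$evalue[ok] <- cfg$K * nchar(frame_tab$aa[bi]) * db_n *
    exp(-cfg$lambda * frame_tab$score[bi])
  out$has_hit <- !is.na(out$evalue) & out$evalue <= cfg$evalue_threshold

  # full alignment only for reads with a hit, batched per reference
  hit_rows <- which(out$has_hit)
  if (length(hit_rows)) {
    by_ref <- split(hit_rows, frame_tab$ref[best_idx[hit_rows]])
    for (r_chr in names(by_ref)) {
      rows <- by_ref[[r_chr]]
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(frame_tab$aa[best_idx[rows]]),
        ref_set[[as.integer(r_chr)]], type = "local",
        substitutionMatrix = mat, gapOpening = cfg$gap_opening,
        gapExtension = cfg$gap_extension)
      pep <- gsub("-", "", as.character(Biostrings::alignedPattern(al)), fixed = TRUE)
      out$peptide[rows] <- pep
      out$identity_pct[rows] <- Biostrings::pid(al)
      out$peptide_len[rows] <- nchar(pep)
    }
  }
  rownames(out) <- NULL
  out
}

#' Filter translated hits into inferred peptides
#'
#' Keeps exactly the hits that (i) have a reference match at the E-value
#' threshold, (ii) carry no stop codon in the HSP peptide (stops indicate
#' frameshifted off-target product), and (iii) are at least
#' `min_peptide_len_aa` residues long.
#'
#' @param hits Data.frame from [translated_search()].
#' @param cfg A [pipeline_config()].
#' @return The surviving rows, with a `counts` attribute giving the sizes
#'   of the discard classes (`no_hit`, `stop_codon`, `too_short`, `kept`).
#' @export
filter_peptides <- function(hits, cfg = pipeline_config()) {
  no_hit <- !hits$has_hit | is.na(hits$peptide)
  has_stop <- !no_hit & cfg$discard_stop_codons & grepl("*", hits$peptide, fixed = TRUE)
  too_short <- !no_hit & !has_stop & hits$peptide_len < cfg$min_peptide_len_aa
  keep <- !no_hit & !has_stop & !too_short
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(no_hit = sum(no_hit), stop_codon = sum(has_stop),
                           too_short = sum(too_short), kept = sum(keep))
  out
}

#' Primer sensitivity: inferred peptides per merged read
#'
#' The fraction of merged amplicon reads that yield an inferred peptide,
#' truncated to an integer percent.
#'
#' @param n_merged Number of merged reads (> 0).
#' @param n_peptides Number of inferred peptides (at most `n_merged`).
#' @return Integer percent `floor(100 * n_peptides / n_merged)`.
#' @examples
#' sensitivity(12816, 11931) # 93
#' @export
sensitivity <- function(n_merged, n_peptides) {
  if (n_merged <= 0) stop("sensitivity undefined for zero merged reads", call. = FALSE)
  if (n_peptides > n_merged) stop("more peptides than merged reads", call. = FALSE)
  as.integer(floor(100 * n_peptides / n_merged))
}

#' Generic nucleotide read quality control
#'
#' Drops reads shorter than `min_len`, with more than `max_ambiguity_frac`
#' ambiguous bases, or with more than `max_homopolymer_frac` of their bases
#' inside homopolymer runs of at least `homopolymer_run` nt.
#'
#' @param reads Character vector of reads (names preserved).
#' @param min_len,max_ambiguity_frac,max_homopolymer_frac QC thresholds.
#' @param homopolymer_run Minimum run length counted as a homopolymer.
#' @return The surviving reads.
#' @export
qc_nucleotide_reads <- function(reads, min_len = 50L, max_ambiguity_frac = 0.02,
                                max_homopolymer_frac = 0.02, homopolymer_run = 8L) {
  keep <- vapply(reads, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < min_len) return(FALSE)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    amb <- mean(!(ch %in% c("A", "C", "G", "T")))
    if (amb > max_ambiguity_frac) return(FALSE)
    r <- rle(ch)
    homo <- sum(r$lengths[r$lengths >= homopolymer_run]) / n
    homo <= max_homopolymer_frac
  }, TRUE)
  reads[keep]
}

#' Run the full amplicon validation pipeline
#'
#' [merge_pairs()] then [translated_search()] then [filter_peptides()],
#' summarized as a sensitivity report.
#'
#' @param pairs List of read pairs (see [read_fastq_pairs()]).
#' @param refs Reference peptide set (see [translated_search()]).
#' @param merge_cfg,cfg Stage configurations.
#' @return List with `report` (data.frame `n_paired`, `n_merged`,
#'   `n_peptides`, `sensitivity_pct`), `merged`, `hits`, `peptides` and
#'   `discards` (named counts; together with `n_peptides` they partition
#'   the merged reads).
#' @export
run_amplicon_pipeline <- function(pairs, refs, merge_cfg = merge_config(),
                                  cfg = pipeline_config()) {
  mg <- merge_pairs(pairs, merge_cfg)
  n_merged <- nrow(mg$merged)
  if (n_merged == 0L) stop("no read pairs merged; cannot compute sensitivity", call. = FALSE)
  hits <- translated_search(mg$merged, refs, cfg)
  peps <- filter_peptides(hits, cfg)
  counts <- attr(peps, "counts")
  report <- data.frame(n_paired = length(pairs), n_merged = n_merged,
                       n_peptides = nrow(peps),
                       sensitivity_pct = sensitivity(n_merged, nrow(peps)))
  list(report = report, merged = mg$merged, hits = hits, peptides = peps,
       discards = counts[c("no_hit", "stop_codon", "too_short")])
}

#' Published validation-run read counts
#'
#' Per-sample read counts from the high-throughput amplicon sequencing
#' validation of the five marker primer sets (mcrA plus the four new
#' pairs) on two anaerobic digesters (AD: agricultural biogas plant,
#' WD: wastewater treatment plant), together with the reported integer
#' sensitivity. One row (mcrB_WD) is flagged `consistent = FALSE`: its
#' reported percentage does not follow from its own counts under either
#' truncation or rounding and is treated as a typo.
#'
#' @return Data.frame with columns `sample`, `gene`, `digester`,
#'   `n_paired`, `n_merged`, `n_peptides`, `reported_sensitivity_pct`,
#'   `consistent`.
#' @export
load_validation_counts <- function() {
  path <- system.file("extdata", "validation_run_counts.tsv", package = "methaprimer")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
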