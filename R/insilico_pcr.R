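# iPCRess-style amplicon prediction: scan templates for degenerate primer
# binding sites under a per-primer mismatch budget (positional Hamming, no
# indels), pair opposite-orientation sites, and filter on product length.

#' In-silico PCR configuration
#'
#' @param max_mismatch_per_primer Mismatch budget per primer (the published
#'   screens used 2, raised to 4 for the longer mcrG primers).
#' @param product_tolerance_bp Keep products within this many bp of the
#'   pair's expected length.
#' @param both_strands Scan both template strands.
#' @param strict_template_ambiguity Require template ambiguity codes to be
#'   contained in the primer code's base set; the default counts any
#'   non-empty base-set intersection as a match, so a template `N` never
#'   costs a mismatch.
#' @param clamp_3prime Require 0 mismatches in the last `clamp_3prime`
#'   3'-end bases of each primer (0 disables; none by default).
#' @export
pcr_config <- function(max_mismatch_per_primer = 2L,
                       product_tolerance_bp = 50L,
                       both_strands = TRUE,
                       strict_template_ambiguity = FALSE,
                       clamp_3prime = 0L) {
  stopifnot(max_mismatch_per_primer >= 0L, product_tolerance_bp >= 0L, clamp_3prime >= 0L)
  structure(list(max_mismatch_per_primer = as.integer(max_mismatch_per_primer),
                 product_tolerance_bp = as.integer(product_tolerance_bp),
                 both_strands = isTRUE(both_strands),
                 strict_template_ambiguity = isTRUE(strict_template_ambiguity),
                 clamp_3prime = as.integer(clamp_3prime)),
            class = "pcr_config")
}

# Mismatch counts of `primer` (character vector of codes) at every start of
# `tmpl_idx` (template encoded as indices into IUPAC_LETTERS, NA = unknown).
.mismatch_profile <- function(primer_chars, tmpl_idx, match_matrix) {
  L <- length(primer_chars)
  n <- length(tmpl_idx) - L + 1L
  if (n < 1L) return(integer(0))
  p_idx <- match(primer_chars, IUPAC_LETTERS)
  mm <- integer(n)
  for (j in seq_len(L)) {
    t <- tmpl_idx[j:(j + n - 1L)]
    hit <- match_matrix[p_idx[j] + (t - 1L) * 15L]
    hit[is.na(hit)] <- FALSE
    mm <- mm + !hit
  }
  mm
}

.encode_template <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ch[ch == "U"] <- "T"
  match(ch, IUPAC_LETTERS)
}

#' Scan a template for primer binding sites
#'
#' Every template window whose per-position [base_match()] failures do not
#' exceed the mismatch budget is reported. Sites on the minus strand are
#' found by scanning with the primer's reverse complement; all coordinates
#' are 0-based half-open on the plus strand.
#'
#' @param template A single sequence: list/one-row data.frame with `id` and
#'   `seq`, or a plain string.
#' @param primer A [degenerate_oligo()] or IUPAC string.
#' @param cfg A [pcr_config()].
#' @return Data.frame with columns `template_id`, `strand` (`+`/`-`),
#'   `start`, `end`, `mismatches`, `primer_name`. Empty when there is no
#'   site (including templates shorter than the primer).
#' @export
scan_sites <- function(template, primer, cfg = pcr_config()) {
  if (is.character(template)) template <- list(id = "template", seq = template)
  if (is.data.frame(template)) template <- as.list(template[1, ])
  if (is.character(primer)) primer <- degenerate_oligo(primer)
  mmx <- if (cfg$strict_template_ambiguity) MATCH_SUBSET else MATCH_INTERSECT

  tmpl_idx <- .encode_template(template$seq)
  p_fwd <- iupac_chars(primer$seq, what = primer$name)
  L <- length(p_fwd)
  N <- length(tmpl_idx)

  clamp_ok <- function(mm_clamp) mm_clamp == 0L
  collect <- function(p_chars, strand) {
    mm <- .mismatch_profile(p_chars, tmpl_idx, mmx)
    keep <- which(mm <= cfg$max_mismatch_per_primer)
    if (cfg$clamp_3prime > 0L && length(keep)) {
      # 3' end of the primer: last bases in primer orientation
      k <- min(cfg$clamp_3prime, L)
      clamp_chars <- if (strand == "+") p_chars[(L - k + 1L):L] else p_chars[1:k]
      offset <- if (strand == "+") L - k else 0L
      mm_clamp <- vapply(keep, function(s) {
        idx <- tmpl_idx[(s + offset):(s + offset + k - 1L)]
        hit <- mmx[cbind(match(clamp_chars, IUPAC_LETTERS), idx)]
        hit[is.na(hit)] <- FALSE
        sum(!hit)
      }, 0L)
      keep <- keep[mm_clamp == 0L]
    }
    if (length(keep) == 0L) return(NULL)
    data.frame(template_id = template$id, strand = strand,
               start = keep - 1L, end = keep - 1L + L,
               mismatches = mm[keep], primer_name = primer$name,
               stringsAsFactors = FALSE)
  }

  out <- collect(p_fwd, "+")
  if (cfg$both_strands) {
    p_rc <- iupac_chars(revcomp_oligo(primer$seq), what = primer$name)
    out <- rbind(out, collect(p_rc, "-"))
  }
  if (is.null(out)) {
    out <- data.frame(template_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), primer_name = character(0))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Predict PCR amplicons for a primer pair on templates
#'
#' Pairs every forward-primer site with every opposite-orientation
#' reverse-primer site downstream on the same template; both primers must
#' match within the mismatch budget and the product length must lie within
#' `product_tolerance_bp` of the pair's expected length. Products whose
#' primer sites would overlap are rejected.
#'
#' @param templates Data.frame from [read_fasta()] (or a single sequence as
#'   accepted by [scan_sites()]).
#' @param pair A [primer_pair()] with `expected_product_bp` set.
#' @param cfg A [pcr_config()]; when `NULL`, a config using the pair's own
#'   mismatch budget is built.
#' @return Data.frame with one row per amplicon: `template_id`, `strand`
#'   (strand carrying the forward primer), `start`, `end` (0-based
#'   half-open product coordinates on the plus strand), `product_bp`,
#'   `fwd_mm`, `rev_mm`, `sequence` (product as written 5'->3' from the
#'   forward primer).
#' @export
predict_amplicons <- function(templates, pair, cfg = NULL) {
  stopifnot(inherits(pair, "primer_pair"))
  if (is.na(pair$expected_product_bp)) {
    stop("primer pair has no expected_product_bp; set it before predicting amplicons",
         call. = FALSE)
  }
  if (is.null(cfg)) cfg <- pcr_config(max_mismatch_per_primer = pair$max_mismatch)
  if (is.character(templates)) {
    templates <- data.frame(id = "template", seq = templates, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(templates)) templates <- as.data.frame(templates, stringsAsFactors = FALSE)

  res <- list()
  for (i in seq_len(nrow(templates))) {
    tmpl <- list(id = templates$id[i], seq = templates$seq[i])
    f_sites <- scan_sites(tmpl, pair$forward, cfg)
    r_sites <- scan_sites(tmpl, pair$reverse, cfg)
    if (nrow(f_sites) == 0L || nrow(r_sites) == 0L) next

    add <- function(fs, rs, strand) {
      # strand "+": forward site on +, reverse site on -, reverse downstream
      # strand "-": forward site on -, reverse site on +, reverse upstream
      for (a in seq_len(nrow(fs))) {
        for (b in seq_len(nrow(rs))) {
          if (strand == "+") {
            if (rs$start[b] < fs$end[a]) next
            start <- fs$start[a]; end <- rs$end[b]
          } else {
            if (fs$start[a] < rs$end[b]) next
            start <- rs$start[b]; end <- fs$end[a]
          }
          product <- end - start
          if (abs(product - pair$expected_product_bp) > cfg$product_tolerance_bp) next
          seq <- substr(tmpl$seq, start + 1L, end)
          if (strand == "-") seq <- revcomp_oligo(toupper(seq))
          res[[length(res) + 1L]] <<- data.frame(
            template_id = tmpl$id, strand = strand,
            start = start, end = end, product_bp = product,
            fwd_mm = fs$mismatches[a], rev_mm = rs$mismatches[b],
            sequence = toupper(seq), stringsAsFactors = FALSE)
        }
      }
    }
    add(f_sites[f_sites$strand == "+", , drop = FALSE],
        r_sites[r_sites$strand == "-", , drop = FALSE], "+")
    if (cfg$both_strands) {
      add(f_sites[f_sites$strand == "-", , drop = FALSE],
          r_sites[r_sites$strand == "+", , drop = FALSE], "-")
    }
  }
  if (length(res) == 0L) {
    return(data.frame(template_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0), product_bp = integer(0),
                      fwd_mm = integer(0), rev_mm = integer(0), sequence = character(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$template_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize primer inclusivity over a gene family
#'
#' Runs [predict_amplicons()] per family member and reports the fraction of
#' members yielding at least one amplicon.
#'
#' @inheritParams predict_amplicons
#' @param family Data.frame of unaligned family sequences (`id`, `seq`).
#' @return List with `hits` (per-sequence data.frame `id`, `n_amplicons`,
#'   `amplified`, ordered by id) and `coverage` (fraction amplified; 0 with
#'   a warning for an empty family).
#' @export
amplify_family <- function(family, pair, cfg = NULL) {
  if (is.null(cfg)) cfg <- pcr_config(max_mismatch_per_primer = pair$max_mismatch)
  if (nrow(family) == 0L) {
    warning("empty family: coverage undefined, reported as 0")
    return(list(hits = data.frame(id = character(0), n_amplicons = integer(0),
                                  amplified = logical(0)),
                coverage = 0))
  }
  n_amp <- vapply(seq_len(nrow(family)), function(i) {
    nrow(predict_amplicons(family[i, , drop = FALSE], pair, cfg))
  }, 0L)
  hits <- data.frame(id = family$id, n_amplicons = n_amp, amplified = n_amp > 0L,
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$id), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, coverage = mean(hits$amplified))
}

#' Write an amplicon table as TSV
#'
#' @param amplicons Data.frame from [predict_amplicons()].
#' @param path Output TSV.
#' @param one_based Emit inclusive 1-based coordinates instead of the
#'   0-based half-open default (for cross-checking against other scanners).
#' @export
write_amplicon_table <- function(amplicons, path, one_based = FALSE) {
  out <- amplicons[, setdiff(names(amplicons), "sequence"), drop = FALSE]
  if (one_based && nrow(out)) {
    out$start <- out$start + 1L  # end already equals the inclusive 1-based end
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
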