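# Sequence file I/O. Biostrings does the parsing; these wrappers return the
# plain containers the rest of the package works with: a data.frame of
# nucleotide records (id, description, seq) and a list of read pairs.

#' Read a (possibly gapped) nucleotide FASTA file
#'
#' @param path FASTA file. Ambiguity codes and `-` gaps are allowed.
#' @return A data.frame with columns `id` (first word of the header),
#'   `description` (remainder of the header) and `seq`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (any(!nzchar(ids)) || any(!nzchar(seqs))) {
    stop(sprintf("FASTA '%s' contains a record with an empty id or sequence", path),
         call. = FALSE)
  }
  data.frame(id = unname(ids), description = unname(desc), seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write nucleotide (or protein) records to FASTA
#'
#' @param records A data.frame with `id`, `seq` and optionally `description`,
#'   or a named character vector.
#' @param path Output file; sequences are wrapped at 60 columns.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "", seq = unname(records),
                          stringsAsFactors = FALSE)
  }
  headers <- ifelse(nzchar(records$description %||% ""),
                    paste(records$id, records$description), records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 60L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read paired FASTQ files into read pairs
#'
#' Qualities are decoded as Phred+33. Each element of the result is a
#' `read_pair`: `id`, `seq1`, `seq2`, `qual1`, `qual2` (integer Phred
#' scores, same length as the corresponding sequence).
#'
#' @param path1,path2 FASTQ files for reads 1 and 2, same record count and
#'   order.
#' @return List of `read_pair` objects.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (length(r1$id) != length(r2$id)) {
    stop(sprintf("paired FASTQ files differ in record count (%d vs %d)",
                 length(r1$id), length(r2$id)), call. = FALSE)
  }
  lapply(seq_along(r1$id), function(i) {
    structure(list(id = r1$id[i], seq1 = r1$seq[i], seq2 = r2$seq[i],
                   qual1 = r1$qual[[i]], qual2 = r2$qual[[i]]),
              class = "read_pair")
  })
}

#' Read a single FASTQ file
#'
#' @param path FASTQ file (Phred+33).
#' @return List with `id`, `seq` (character vectors) and `qual` (list of
#'   integer vectors).
#' @export
read_fastq <- function(path) {
  parsed <- tryCatch({
    # (suppressed warning: Biostrings notes dropped metadata columns on read)
    set <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
    list(ids = sub("\\s.*$", "", names(set)),
         seqs = as.character(set),
         quals = as.list(as(Biostrings::quality(set), "IntegerList")))
  }, error = function(e) stop(sprintf("malformed FASTQ '%s': %s",
                                      path, conditionMessage(e)), call. = FALSE))
  ids <- parsed$ids
  seqs <- parsed$seqs
  quals <- parsed$quals
  bad <- which(nchar(seqs) != lengths(quals))
  if (length(bad)) {
    stop(sprintf("FASTQ '%s': record %d ('%s') has sequence/quality length mismatch",
                 path, bad[1], ids[bad[1]]), call. = FALSE)
  }
  list(id = unname(ids), seq = unname(seqs), qual = unname(quals))
}

#' Write paired reads to a pair of FASTQ files
#'
#' @param pairs List of `read_pair` objects.
#' @param path1,path2 Output FASTQ files (Phred+33).
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_one <- function(seqs, quals, ids, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(c(paste0("@", ids[i]), seqs[i], "+",
                   intToUtf8(quals[[i]] + 33L)), con)
    }
  }
  ids <- vapply(pairs, `[[`, "", "id")
  write_one(vapply(pairs, `[[`, "", "seq1"), lapply(pairs, `[[`, "qual1"), ids, path1)
  write_one(vapply(pairs, `[[`, "", "seq2"), lapply(pairs, `[[`, "qual2"), ids, path2)
  invisible(c(path1, path2))
}

#' Load a primer table
#'
#' Reads a TSV with columns `name`, `sequence`, `orientation`, `gene`,
#' `expected_product_bp` and returns a list of [primer_pair()] objects,
#' one per gene. The packaged table (`system.file("extdata",
#' "marker_primers.tsv", package = "methaprimer")`) holds the four
#' published primer pairs for mcrB, mcrG (MCR_G1 group), mtaB and mtbA.
#'
#' @param path TSV file; defaults to the packaged primer set.
#' @return Named list of `primer_pair` objects keyed by gene.
#' @examples
#' primers <- load_primer_table()
#' primers$mcrB
#' @export
load_primer_table <- function(path = system.file("extdata", "marker_primers.tsv",
                                                 package = "methaprimer")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "sequence", "orientation", "gene", "expected_product_bp")
  if (!all(needed %in% names(tab))) {
    stop("primer table must have columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (g in unique(tab$gene)) {
    sub <- tab[tab$gene == g, ]
    fwd <- sub[sub$orientation == "forward", ]
    rev <- sub[sub$orientation == "reverse", ]
    if (nrow(fwd) != 1L || nrow(rev) != 1L) {
      stop(sprintf("gene '%s' must have exactly one forward and one reverse primer", g),
           call. = FALSE)
    }
    out[[g]] <- primer_pair(
      forward = degenerate_oligo(fwd$sequence, name = fwd$name, orientation = "forward"),
      reverse = degenerate_oligo(rev$sequence, name = rev$name, orientation = "reverse"),
      expected_product_bp = fwd$expected_product_bp[1],
      max_mismatch = if ("max_mismatch" %in% names(sub)) fwd$max_mismatch[1] else 2L
    )
  }
  out
}
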