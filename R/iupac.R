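#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide ambiguity codes and the base sets they denote.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_CODES)

# Complement of each ambiguity code is the code of the complemented base set.
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", W = "W", S = "S", K = "M", M = "K",
  D = "H", H = "D", V = "B", B = "V", N = "N"
)

# match_matrix[p, t]: does primer code p accept template code t?
# "intersect": non-empty expansion intersection (tolerates Ns in drafts).
# "subset":    template expansion must be contained in the primer expansion.
.build_match_matrix <- function(mode = c("intersect", "subset")) {
  mode <- match.arg(mode)
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  for (p in IUPAC_LETTERS) {
    for (t in IUPAC_LETTERS) {
      ep <- IUPAC_CODES[[p]]
      et <- IUPAC_CODES[[t]]
      m[p, t] <- if (mode == "intersect") length(intersect(ep, et)) > 0L else all(et %in% ep)
    }
  }
  m
}

MATCH_INTERSECT <- .build_match_matrix("intersect")
MATCH_SUBSET <- .build_match_matrix("subset")

# Normalize a nucleotide string: upper case, U -> T. Returns a character
# vector of single letters; errors (naming the first bad position) on any
# character outside the 15-letter IUPAC alphabet (or '-' when allow_gap).
iupac_chars <- function(seq, allow_gap = FALSE, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ch[ch == "U"] <- "T"
  ok <- ch %in% IUPAC_LETTERS
  if (allow_gap) ok <- ok | ch == "-"
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("invalid IUPAC character '%s' at position %d of %s", ch[bad], bad, what),
         call. = FALSE)
  }
  ch
}

#' Construct a degenerate oligonucleotide
#'
#' A degenerate oligo is a string over the 15-letter IUPAC nucleotide
#' alphabet (`A C G T R Y W S K M D H V B N`) representing a pool of
#' concrete primers. Input is case-insensitive and `U` is read as `T`.
#'
#' @param seq IUPAC nucleotide string.
#' @param name Short label (e.g. `"LMCRB"`).
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `degenerate_oligo` with elements `name`,
#'   `seq` and `orientation`.
#' @examples
#' o <- degenerate_oligo("TWYCARGGHYTVAAYGC", name = "LMCRB")
#' oligo_degeneracy(o)
#' @export
degenerate_oligo <- function(seq, name = "", orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  ch <- iupac_chars(seq, what = if (nzchar(name)) name else "oligo")
  if (length(ch) == 0L) stop("oligo sequence must be non-empty", call. = FALSE)
  structure(list(name = name, seq = paste(ch, collapse = ""), orientation = orientation),
            class = "degenerate_oligo")
}

#' @export
print.degenerate_oligo <- function(x, ...) {
  cat(sprintf("<degenerate_oligo> %s %s (%s, %d nt, degeneracy %d)\n",
              x$name, x$seq, x$orientation, nchar(x$seq), oligo_degeneracy(x)))
  invisible(x)
}

.oligo_seq <- function(x) {
  if (inherits(x, "degenerate_oligo")) x$seq else x
}

#' Degeneracy of a degenerate oligo
#'
#' The number of concrete A/C/G/T sequences the oligo represents: the
#' product over positions of the size of each code's base set. Computed
#' multiplicatively (never by enumeration), so N-rich oligos are cheap.
#'
#' @param oligo A `degenerate_oligo` or an IUPAC string.
#' @return A positive number (degeneracy can exceed `.Machine$integer.max`
#'   for long N-rich oligos, so a double is returned).
#' @examples
#' oligo_degeneracy("ACGT")              # 1
#' oligo_degeneracy("CCDCCDCCDCCRTARAT") # 108
#' @export
oligo_degeneracy <- function(oligo) {
  ch <- iupac_chars(.oligo_seq(oligo), what = "oligo")
  prod(lengths(IUPAC_CODES)[ch])
}

#' Expand a degenerate oligo into its concrete sequences
#'
#' Materializes the full pool of A/C/G/T sequences an IUPAC string
#' represents. Enumeration is capped (default one million) because the
#' pool grows multiplicatively; [oligo_degeneracy()] never enumerates.
#'
#' @inheritParams oligo_degeneracy
#' @param max_expansion Refuse to enumerate pools larger than this.
#' @return Character vector of distinct concrete sequences; its length
#'   equals `oligo_degeneracy(oligo)`.
#' @examples
#' expand_oligo("AR") # "AA" "AG"
#' @export
expand_oligo <- function(oligo, max_expansion = 1e6) {
  ch <- iupac_chars(.oligo_seq(oligo), what = "oligo")
  deg <- prod(lengths(IUPAC_CODES)[ch])
  if (deg > max_expansion) {
    stop(sprintf("degeneracy %.0f exceeds expansion cap %.0f", deg, max_expansion),
         call. = FALSE)
  }
  sets <- IUPAC_CODES[ch]
  grid <- do.call(expand.grid, c(rev(sets), list(stringsAsFactors = FALSE)))
  out <- do.call(paste0, rev(grid))
  sort(unique(out))
}

#' Reverse complement of a degenerate oligo
#'
#' Ambiguity codes map to the code of the complemented base set
#' (R<->Y, K<->M, D<->H, V<->B; W, S, N are self-complementary), so
#' the operation is an involution and commutes with expansion.
#'
#' @inheritParams oligo_degeneracy
#' @return Same type as the input: a `degenerate_oligo` (name suffixed
#'   `_rc`, orientation flipped) or a character string.
#' @examples
#' revcomp_oligo("CCDCCDCCDCCRTARAT") # "ATYTAYGGHGGHGGHGG"
#' @export
revcomp_oligo <- function(oligo) {
  ch <- iupac_chars(.oligo_seq(oligo), what = "oligo")
  rc <- paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
  if (inherits(oligo, "degenerate_oligo")) {
    degenerate_oligo(rc, name = paste0(oligo$name, "_rc"),
                     orientation = if (oligo$orientation == "forward") "reverse" else "forward")
  } else {
    rc
  }
}

#' Does a primer base accept a template base?
#'
#' For an unambiguous template base the primer code matches iff the base is
#' in the primer's expansion. For ambiguous template codes the default rule
#' is non-empty expansion intersection (a template `N` matches any primer
#' base, as an in-silico PCR scanner must tolerate in draft genomes);
#' `strict = TRUE` requires the template expansion to be contained in the
#' primer expansion.
#'
#' @param primer_code,template_code Single IUPAC characters.
#' @param strict Use the subset rule instead of the intersection rule.
#' @return Logical scalar.
#' @examples
#' base_match("R", "A") # TRUE
#' base_match("H", "G") # FALSE
#' @export
base_match <- function(primer_code, template_code, strict = FALSE) {
  p <- iupac_chars(primer_code, what = "primer code")
  t <- iupac_chars(template_code, what = "template code")
  if (length(p) != 1L || length(t) != 1L) stop("codes must be single characters", call. = FALSE)
  m <- if (strict) MATCH_SUBSET else MATCH_INTERSECT
  m[p, t]
}
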