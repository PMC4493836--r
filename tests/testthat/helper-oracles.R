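# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive the IUPAC semantics from the published code table
# rather than reusing the package's internals.

# hand-written IUPAC table (footnote semantics)
ORACLE_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

# enumerate every concrete sequence of a degenerate oligo by left-fold
oracle_expand <- function(seq) {
  sets <- ORACLE_CODES[strsplit(toupper(seq), "")[[1]]]
  Reduce(function(acc, s) as.vector(t(outer(acc, s, paste0))), sets, "")
}

oracle_revcomp_concrete <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force binding-site finder: expand the primer fully, slide over the
# template (A/C/G/T) and take the minimum Hamming distance per window
oracle_scan <- function(template, primer_seq, budget, both_strands = TRUE) {
  exps <- strsplit(oracle_expand(primer_seq), "")
  L <- length(exps[[1]])
  scan_one <- function(tmpl) {
    ch <- strsplit(tmpl, "")[[1]]
    n <- length(ch) - L + 1L
    if (n < 1L) return(data.frame(start = integer(0), mm = integer(0)))
    starts <- integer(0); mms <- integer(0)
    for (i in seq_len(n)) {
      win <- ch[i:(i + L - 1L)]
      h <- min(vapply(exps, function(e) sum(e != win), 0L))
      if (h <= budget) { starts <- c(starts, i - 1L); mms <- c(mms, h) }
    }
    data.frame(start = starts, mm = mms)
  }
  plus <- scan_one(template)
  plus$strand <- rep("+", nrow(plus))
  if (!both_strands) return(plus)
  rc <- oracle_revcomp_concrete(template)
  minus <- scan_one(rc)
  N <- nchar(template)
  minus <- data.frame(start = N - (minus$start + L), mm = minus$mm)
  minus$strand <- rep("-", nrow(minus))
  out <- rbind(plus, minus)
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# random degenerate oligo with a bounded number of ambiguity positions so
# enumeration stays cheap
random_oligo <- function(len, max_ambiguous = 5L) {
  amb <- c("R", "Y", "W", "S", "K", "M", "D", "H", "V", "B", "N")
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  k <- sample(0:min(max_ambiguous, len), 1)
  if (k > 0) {
    pos <- sample(len, k)
    ch[pos] <- sample(amb, k, replace = TRUE)
  }
  paste(ch, collapse = "")
}

# reverse-translate an amino-acid string with one fixed codon per residue
back_translate <- function(aa) {
  codon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
             E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
             M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
             Y = "TAT", V = "GTT", `*` = "TAA")
  paste(codon[strsplit(aa, "")[[1]]], collapse = "")
}

# is `node` the leaf itself or one of its ancestors?
is_leaf_or_ancestor <- function(tree, node, leaf) {
  lf <- match(leaf, tree$tip.label)
  if (node == lf) return(TRUE)
  if (node <= length(tree$tip.label)) return(FALSE)
  leaf %in% ape::extract.clade(tree, node)$tip.label
}

# split a fragment into an inward-facing read pair with constant quality
fragment_to_pair <- function(frag, read_len, id = "r", q = 35L) {
  L <- nchar(frag)
  r1 <- substr(frag, 1, min(read_len, L))
  r2 <- revcomp_oligo(substr(frag, max(1, L - read_len + 1), L))
  structure(list(id = id, seq1 = r1, seq2 = r2,
                 qual1 = rep(q, nchar(r1)), qual2 = rep(q, nchar(r2))),
            class = "read_pair")
}
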