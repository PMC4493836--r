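test_that("site scanning honors the mismatch budget and IUPAC matching", {
  one <- pcr_config(max_mismatch_per_primer = 0, both_strands = FALSE)
  s <- scan_sites("ACGT", "ACGT", one)
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 0)
  expect_equal(s$end, 4)
  expect_equal(s$strand, "+")

  expect_equal(nrow(scan_sites("ACGA", "ACGT", one)), 0)
  s1 <- scan_sites("ACGA", "ACGT", pcr_config(1, both_strands = FALSE))
  expect_equal(s1$mismatches, 1)

  # degenerate primer position matches at zero cost
  sr <- scan_sites("ACGT", "ACRT", one)
  expect_equal(sr$mismatches, 0)
  expect_equal(sr$strand, "+")

  # templates shorter than the primer yield no sites, no error
  expect_equal(nrow(scan_sites("AC", "ACGT", one)), 0)
})

test_that("template ambiguity codes match by intersection unless strict", {
  lax <- pcr_config(0, both_strands = FALSE)
  strict <- pcr_config(0, both_strands = FALSE, strict_template_ambiguity = TRUE)
  expect_equal(scan_sites("ANGT", "ACGT", lax)$mismatches, 0)
  expect_equal(nrow(scan_sites("ANGT", "ACGT", strict)), 0)
})

test_that("a 3' clamp disallows terminal mismatches", {
  cfg <- pcr_config(2, both_strands = FALSE, clamp_3prime = 3)
  expect_equal(nrow(scan_sites("ACGTACGA", "ACGTACGT", cfg)), 0)  # mm at 3' end
  expect_equal(nrow(scan_sites("TCGTACGT", "ACGTACGT", cfg)), 1)  # mm at 5' end
})

test_that("amplicon prediction pairs sites and applies the length tolerance", {
  set.seed(31)
  mid <- random_dna(300)
  f <- expand_oligo("TWYCARGGHYTVAAYGC")[5]
  r <- expand_oligo("CCDCCDCCDCCRTARAT")[9]
  tmpl <- data.frame(id = "g1", seq = paste0(f, mid, revcomp_oligo(r)))

  pair334 <- primer_pair("TWYCARGGHYTVAAYGC", "CCDCCDCCDCCRTARAT",
                         expected_product_bp = 334)
  amp <- predict_amplicons(tmpl, pair334)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$product_bp, 334)
  expect_equal(amp$fwd_mm + amp$rev_mm, 0)
  expect_equal(amp$sequence, tmpl$seq)

  # |334 - 392| = 58: rejected at the default +-50 bp, kept at +-60
  pair392 <- primer_pair("TWYCARGGHYTVAAYGC", "CCDCCDCCDCCRTARAT",
                         expected_product_bp = 392)
  expect_equal(nrow(predict_amplicons(tmpl, pair392,
    pcr_config(2, product_tolerance_bp = 50))), 0)
  expect_equal(nrow(predict_amplicons(tmpl, pair392,
    pcr_config(2, product_tolerance_bp = 60))), 1)

  # both primers must match: forward site alone is not an amplicon
  fwd_only <- data.frame(id = "g2", seq = paste0(f, mid))
  expect_equal(nrow(predict_amplicons(fwd_only, pair334)), 0)

  # a pair without expected product length is refused
  nolen <- primer_pair("TWYCARGGHYTVAAYGC", "CCDCCDCCDCCRTARAT")
  expect_error(predict_amplicons(tmpl, nolen), "expected_product_bp")
})

test_that("products on the minus strand mirror the plus strand", {
  set.seed(32)
  mid <- random_dna(300)
  f <- expand_oligo("TWYCARGGHYTVAAYGC")[1]
  r <- expand_oligo("CCDCCDCCDCCRTARAT")[1]
  fwd_tmpl <- paste0(f, mid, revcomp_oligo(r))
  pair <- primer_pair("TWYCARGGHYTVAAYGC", "CCDCCDCCDCCRTARAT",
                      expected_product_bp = 334)
  a_plus <- predict_amplicons(fwd_tmpl, pair)
  a_minus <- predict_amplicons(revcomp_oligo(fwd_tmpl), pair)
  expect_equal(nrow(a_minus), 1)
  expect_equal(a_minus$strand, "-")
  expect_equal(a_minus$product_bp, a_plus$product_bp)
  expect_equal(a_minus$sequence, a_plus$sequence)  # written 5'->3' from fwd primer
  expect_equal(a_minus$start, nchar(fwd_tmpl) - a_plus$end)
})

test_that("family amplification summarizes inclusivity deterministically", {
  set.seed(33)
  f <- random_dna(17); r <- random_dna(17)
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[b]
  core <- function(mut_fwd) {
    fseq <- f
    if (mut_fwd) {
      # plant 3 mismatches in the forward site
      for (p in c(2L, 7L, 12L)) substr(fseq, p, p) <- flip(substr(fseq, p, p))
    }
    paste0(fseq, random_dna(200), revcomp_oligo(r))
  }
  fam <- data.frame(id = sprintf("m%02d", 1:10),
                    seq = vapply(c(rep(FALSE, 7), rep(TRUE, 3)), core, ""))
  pair <- primer_pair(f, r, expected_product_bp = 234)
  res <- amplify_family(fam, pair, pcr_config(2))
  expect_equal(res$coverage, 0.7)
  expect_equal(res$hits$id, sort(fam$id))
  expect_warning(res0 <- amplify_family(fam[0, ], pair), "empty family")
  expect_equal(res0$coverage, 0)
})

test_that("scanner agrees with the expand-and-Hamming oracle", {
  set.seed(77)
  for (i in 1:60) {
    primer <- random_oligo(sample(6:12, 1), max_ambiguous = 3)
    tmpl <- random_dna(sample(50:300, 1))
    budget <- sample(0:2, 1)
    got <- scan_sites(tmpl, primer, pcr_config(budget))
    want <- oracle_scan(tmpl, primer, budget)
    expect_equal(nrow(got), nrow(want), info = paste("instance", i))
    if (nrow(got)) {
      expect_equal(got$start, want$start, info = paste("instance", i))
      expect_equal(got$mismatches, want$mm, info = paste("instance", i))
      expect_equal(got$strand, want$strand, info = paste("instance", i))
    }
  }
})

test_that("site sets grow monotonically with the mismatch budget", {
  set.seed(78)
  for (i in 1:20) {
    primer <- random_oligo(10, max_ambiguous = 2)
    tmpl <- random_dna(200)
    prev <- NULL
    for (budget in 0:3) {
      s <- scan_sites(tmpl, primer, pcr_config(budget))
      key <- paste(s$start, s$strand)
      if (!is.null(prev)) expect_true(all(prev %in% key))
      prev <- key
    }
  }
})

test_that("amplicon tables can be written 0-based or 1-based", {
  amp <- data.frame(template_id = "g", strand = "+", start = 10L, end = 110L,
                    product_bp = 100L, fwd_mm = 0L, rev_mm = 1L,
                    sequence = strrep("A", 100))
  p0 <- withr::local_tempfile(fileext = ".tsv")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_amplicon_table(amp, p0)
  write_amplicon_table(amp, p1, one_based = TRUE)
  t0 <- read.delim(p0); t1 <- read.delim(p1)
  expect_equal(t0$start, 10); expect_equal(t1$start, 11)
  expect_equal(t0$end, t1$end)
  expect_false("sequence" %in% names(t0))
})
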