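test_that("overlapping pairs reconstruct their fragment exactly", {
  set.seed(41)
  frag <- random_dna(16)
  p <- fragment_to_pair(frag, 10)
  res <- merge_pairs(list(p), merge_config(min_overlap = 4))
  expect_equal(res$merged$seq, frag)
  expect_equal(res$merged$overlap, 4)
  expect_equal(res$n_unmerged, 0)

  # a realistic amplicon-scale reconstruction
  frag2 <- random_dna(430)
  res2 <- merge_pairs(list(fragment_to_pair(frag2, 250)), merge_config())
  expect_equal(res2$merged$seq, frag2)
  expect_equal(res2$merged$overlap, 70)
})

test_that("non-overlapping pairs stay unmerged", {
  set.seed(42)
  p <- structure(list(id = "x", seq1 = random_dna(60), seq2 = random_dna(60),
                      qual1 = rep(35L, 60), qual2 = rep(35L, 60)),
                 class = "read_pair")
  res <- merge_pairs(list(p), merge_config(min_overlap = 10))
  expect_equal(nrow(res$merged), 0)
  expect_equal(res$n_unmerged, 1)
})

test_that("overlap conflicts resolve to the higher-quality base", {
  set.seed(43)
  frag <- random_dna(30)
  p <- fragment_to_pair(frag, 20)          # overlap 10
  conflict_pos <- 15L                       # inside the overlap [11, 20]
  truth <- substr(frag, conflict_pos, conflict_pos)
  wrong <- setdiff(c("A", "C", "G", "T"), truth)[1]
  # corrupt r2 at that fragment position, keep r1 the higher quality
  rc_pos <- 30 - conflict_pos + 1
  seq2 <- p$seq2
  substr(seq2, rc_pos, rc_pos) <- c(A = "T", C = "G", G = "C", T = "A")[wrong]
  p_low <- structure(list(id = "x", seq1 = p$seq1, seq2 = seq2,
                          qual1 = rep(35L, 20), qual2 = rep(20L, 20)),
                     class = "read_pair")
  res <- merge_pairs(list(p_low), merge_config(min_overlap = 5))
  expect_equal(substr(res$merged$seq, conflict_pos, conflict_pos), truth)
  # flip the qualities: the corrupted base wins
  p_hi <- p_low; p_hi$qual1 <- rep(20L, 20); p_hi$qual2 <- rep(35L, 20)
  res2 <- merge_pairs(list(p_hi), merge_config(min_overlap = 5))
  expect_equal(substr(res2$merged$seq, conflict_pos, conflict_pos), wrong)
})

test_that("an exact back-translated read hits its reference at full identity", {
  set.seed(44)
  aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40, TRUE),
              collapse = "")
  refs <- c(target = aa)
  read <- back_translate(aa)
  hit <- translated_search(c(r1 = read), refs)
  expect_true(hit$has_hit)
  expect_equal(hit$best_ref_id, "target")
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$peptide, aa)
  expect_equal(hit$frame, 1)
})

test_that("random reads almost never hit unrelated references", {
  set.seed(45)
  aa_alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  refs <- stats::setNames(
    replicate(5, paste(sample(aa_alpha, 150, TRUE), collapse = "")),
    paste0("ref", 1:5))
  reads <- stats::setNames(replicate(200, random_dna(120)),
                           paste0("rd", 1:200))
  hits <- translated_search(reads, refs)
  expect_gte(mean(!hits$has_hit), 0.95)
})

test_that("a stop-inducing substitution survives into the HSP and is filtered", {
  set.seed(46)
  aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, TRUE),
              collapse = "")
  broken <- paste0(substr(aa, 1, 30), "*", substr(aa, 32, 60))
  read <- back_translate(broken)
  hit <- translated_search(c(r1 = read), c(ref = aa))
  expect_true(hit$has_hit)
  expect_match(hit$peptide, "\\*")
  kept <- filter_peptides(hit)
  expect_equal(nrow(kept), 0)
  expect_equal(unname(attr(kept, "counts")["stop_codon"]), 1L)
})

test_that("peptide filtering applies the exact length boundary", {
  mk <- function(len, pep = NULL) {
    p <- if (is.null(pep)) strrep("A", len) else pep
    data.frame(read_id = "r", has_hit = TRUE, frame = 1L, best_ref_id = "x",
               score = 100, evalue = 1e-10, peptide = p,
               identity_pct = 99, peptide_len = nchar(p))
  }
  expect_equal(nrow(filter_peptides(mk(29))), 0)
  expect_equal(nrow(filter_peptides(mk(30))), 1)
  expect_equal(nrow(filter_peptides(mk(50, paste0(strrep("A", 25), "*",
                                                  strrep("A", 24))))), 0)
  no_hit <- mk(50); no_hit$has_hit <- FALSE
  expect_equal(nrow(filter_peptides(no_hit)), 0)
})

test_that("sensitivity truncates to integer percent and validates input", {
  expect_identical(sensitivity(12816, 11931), 93L)
  expect_identical(sensitivity(20753, 19163), 92L)
  expect_identical(sensitivity(100, 0), 0L)
  expect_identical(sensitivity(3, 2), 66L)     # floor, not round
  expect_error(sensitivity(0, 0), "zero merged")
  expect_error(sensitivity(10, 11), "more peptides")
})

test_that("nucleotide QC drops short, ambiguous and homopolymeric reads", {
  clean49 <- random_dna(49)
  clean100 <- random_dna(100)
  threeN <- paste0(substr(clean100, 1, 97), "NNN")
  oneN <- paste0(substr(clean100, 1, 99), "N")
  homopoly <- paste0(substr(clean100, 1, 90), strrep("A", 10))
  reads <- c(a = clean49, b = clean100, c = threeN, d = oneN, e = homopoly)
  kept <- qc_nucleotide_reads(reads)
  expect_setequal(names(kept), c("b", "d"))
})

test_that("discard classes partition the merged reads", {
  set.seed(48)
  fam <- simulate_family(family_model(n_leaves = 8, ancestor_len = 600, seed = 48))
  des <- design_primers(fam$alignment)
  pr <- pair_from_design(des)
  lib <- simulate_amplicon_library(fam, pr,
    library_model(n_read_pairs = 120, on_target_fraction = 0.5, seed = 49))
  refs <- simulate_reference_set(fam)
  refdf <- data.frame(id = names(refs$alignment), seq = unname(refs$alignment))
  res <- run_amplicon_pipeline(lib$pairs, refdf)
  expect_equal(res$report$n_peptides + sum(res$discards), res$report$n_merged)
  expect_lte(res$report$n_peptides, res$report$n_merged)
  expect_lte(res$report$n_merged, res$report$n_paired)
  expect_identical(res$report$sensitivity_pct,
                   sensitivity(res$report$n_merged, res$report$n_peptides))

  # identical inputs give byte-identical reports
  res2 <- run_amplicon_pipeline(lib$pairs, refdf)
  expect_identical(res, res2)
})
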