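ref_fixture <- function(seed = 5) {
  fam <- simulate_family(family_model(seed = seed))
  simulate_reference_set(fam)
}

test_that("reference sets validate their invariants", {
  refs <- ref_fixture()
  expect_s3_class(refs$tree, "phylo")
  expect_setequal(refs$tree$tip.label, names(refs$alignment))
  bad_tax <- refs$taxonomy[-1, ]
  expect_error(reference_set(refs$alignment, refs$tree, bad_tax), "missing leaves")
  expect_error(reference_set(refs$alignment[-1], refs$tree), "leaf set")
})

test_that("alignment against the reference rows reports identity and coverage", {
  refs <- ref_fixture()
  row <- gsub("-", "", refs$alignment[["t2"]], fixed = TRUE)
  full <- align_to_reference(row, refs$alignment)
  expect_false(full$unalignable)
  expect_equal(full$best_ref, "t2")
  self <- full$scores[full$scores$ref_id == "t2", ]
  expect_equal(self$identity_pct, 100)
  expect_equal(self$coverage_pct, 100)

  # 2 substitutions over a 40-aa fragment: 95% identity
  frag <- substr(row, 10, 49)
  ch <- strsplit(frag, "")[[1]]
  for (p in c(5L, 20L)) ch[p] <- setdiff(c("W", "Y"), ch[p])[1]
  mut <- paste(ch, collapse = "")
  sc <- align_to_reference(mut, refs$alignment)$scores
  expect_equal(sc$identity_pct[sc$ref_id == "t2"], 95)

  expect_true(align_to_reference(strrep("X", 40), refs$alignment)$unalignable)
})

test_that("placement lands on the source leaf or an LCA under near-ties", {
  refs <- ref_fixture()
  q <- gsub("-", "", refs$alignment[["t4"]], fixed = TRUE)
  pl <- place(q, refs, peptide_id = "q")
  expect_equal(nrow(pl), 1)
  expect_equal(pl$node_label, "t4")
  expect_equal(pl$mass, 1)

  # two identical reference rows force an LCA placement at their parent
  aln <- c(a = "MKVLLARHGDEFIKNPQRST", b = "MKVLLARHGDEFIKNPQRST",
           c = "MWWTTSRHGHHHIKNAAAST", d = "MWWTTSRHGHHHIKNAAASW")
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2);")
  refs2 <- reference_set(aln, tree,
    data.frame(leaf_id = c("a", "b", "c", "d"), domain = "D",
               genus = c("G1", "G1", "G2", "G2"),
               species = c("a", "b", "c", "d")))
  pl2 <- place("MKVLLARHGDEFIKNPQRST", refs2)
  expect_equal(pl2$node, ape::getMRCA(tree, c("a", "b")))

  # unalignable queries yield no placement
  expect_equal(nrow(place(strrep("X", 30), refs)), 0)
  pp <- place_peptides(c(q1 = q, q2 = strrep("X", 30)), refs)
  expect_equal(pp$n_unclassified, 1)
})

test_that("multi-placement mode spreads mass over the top leaves", {
  refs <- ref_fixture()
  q <- gsub("-", "", refs$alignment[["t4"]], fixed = TRUE)
  pl <- place(q, refs, mode = "multi", top_k = 3)
  expect_equal(nrow(pl), 3)
  expect_equal(sum(pl$mass), 1, tolerance = 1e-12)
  expect_equal(pl$node_label[1], "t4")
})

test_that("mass trimming removes sub-threshold nodes and nothing else", {
  pl <- data.frame(peptide_id = c("a", "b", "c"), node = c(1L, 1L, 2L),
                   node_label = c("t1", "t1", "t2"),
                   mass = c(0.6, 0.395, 0.005), score = 1)
  tr <- trim_placements(pl, min_mass = 0.01)
  expect_equal(unique(tr$node), 1L)
  expect_equal(tr$mass, c(0.6, 0.395))
  # a node at exactly the threshold mass is retained
  pl2 <- data.frame(peptide_id = c("a", "b"), node = c(1L, 2L),
                    node_label = c("t1", "t2"), mass = c(0.99, 0.01), score = 1)
  expect_equal(nrow(trim_placements(pl2, 0.01)), 2)
  # a single node carrying everything survives
  pl3 <- pl2[1, ]
  expect_equal(trim_placements(pl3, 0.01), pl3)
  # trimming never adds nodes or mass
  expect_true(all(tr$node %in% pl$node))
  expect_lte(sum(tr$mass), sum(pl$mass))
})

test_that("composite classification uses a strict > 93 threshold", {
  expect_equal(classify_score(90, 94), "unclassified")   # score 92
  expect_equal(classify_score(96, 92), "classified")     # score 94
  expect_equal(classify_score(93, 93), "unclassified")   # boundary: not exceeded
  expect_equal(classify_score(c(100, 80), c(100, 80)),
               c("classified", "unclassified"))
  expect_error(classify_score(101, 50), "\\[0, 100\\]")
})

test_that("fat-tree export colors placement paths and scales widths", {
  aln <- c(a = "MKVLLARHG", b = "MKVLLSRHG", c = "MWWTTSRHG")
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,c:0.3);")
  refs <- reference_set(aln, tree,
    data.frame(leaf_id = c("a", "b", "c"), domain = "D", species = c("a", "b", "c")))

  # no placements: all branches black, uniform width
  p0 <- withr::local_tempfile(fileext = ".xml")
  export_fat_tree(refs, data.frame(peptide_id = character(0), node = integer(0),
                                   node_label = character(0), mass = numeric(0),
                                   score = numeric(0)), p0)
  doc <- xml2::read_xml(p0)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "px")
  reds <- xml2::xml_text(xml2::xml_find_all(doc, "//px:color/px:red", ns))
  expect_true(all(reds == "0"))
  widths <- as.numeric(xml2::xml_text(xml2::xml_find_all(doc, "//px:width", ns)))
  expect_equal(length(unique(widths)), 1)

  # 75/25 split over two leaves: widths in ratio 3
  pl <- data.frame(peptide_id = c("x", "y"), node = match(c("a", "c"), tree$tip.label),
                   node_label = c("a", "c"), mass = c(75, 25), score = 1)
  p1 <- withr::local_tempfile(fileext = ".xml")
  export_fat_tree(refs, pl, p1)
  doc1 <- xml2::read_xml(p1)
  clades <- xml2::xml_find_all(doc1, "//px:clade", ns)
  get_leaf <- function(nm) {
    i <- which(xml2::xml_text(xml2::xml_find_first(clades, "./px:name", ns)) == nm)
    clades[[i]]
  }
  wa <- as.numeric(xml2::xml_text(xml2::xml_find_first(get_leaf("a"), "./px:width", ns)))
  wc <- as.numeric(xml2::xml_text(xml2::xml_find_first(get_leaf("c"), "./px:width", ns)))
  expect_equal(wa / wc, 3)
  red_a <- xml2::xml_text(xml2::xml_find_first(get_leaf("a"), "./px:color/px:red", ns))
  red_b <- xml2::xml_text(xml2::xml_find_first(get_leaf("b"), "./px:color/px:red", ns))
  expect_equal(red_a, "255")
  expect_equal(red_b, "0")
})

test_that("abundance aggregation respects ranks and conserves mass", {
  aln <- c(a = "MKVLLARHG", b = "MKVLLSRHG", c = "MWWTTSRHG", d = "MWWTTARHG")
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2);")
  tax <- data.frame(leaf_id = c("a", "b", "c", "d"),
                    domain = "D", order = "O1",
                    family = c("F1", "F1", "F2", "F2"),
                    genus = c("G1", "G1", "G2", "G3"))
  refs <- reference_set(aln, tree, tax)

  # all mass at leaves of one genus
  pl <- data.frame(peptide_id = c("x", "y"), node = match(c("a", "b"), tree$tip.label),
                   node_label = c("a", "b"), mass = c(60, 40), score = 1)
  ab <- abundance_table(pl, refs, "genus")
  expect_equal(ab$fraction[ab$taxon == "G1"], 1)
  expect_equal(sum(ab$fraction), 1)

  # placement at the LCA of two families reports at the shared order
  root <- length(tree$tip.label) + 1L
  pl2 <- data.frame(peptide_id = "z", node = root, node_label = "root",
                    mass = 1, score = 1)
  ab2 <- abundance_table(pl2, refs, "family")
  expect_equal(ab2$taxon[ab2$count > 0], "O1")
  expect_equal(ab2$rank[ab2$count > 0], "order")

  # empty placements: zero table plus explicit unclassified
  ab3 <- abundance_table(pl2[0, ], refs, "genus", n_unclassified = 0)
  expect_equal(sum(ab3$count), 0)
  expect_true("Unclassified" %in% ab3$taxon)

  # unclassified counts enter the denominator
  ab4 <- abundance_table(pl, refs, "genus", n_unclassified = 100)
  expect_equal(sum(ab4$fraction), 1)
  expect_equal(ab4$fraction[ab4$taxon == "Unclassified"], 0.5)

  # leaves missing from the taxonomy are named in the error
  refs_na <- refs; refs_na$taxonomy <- tax[tax$leaf_id != "b", ]
  expect_error(abundance_table(pl, refs_na, "genus"), "b")
})
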