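test_that("self-alignment scores 100% identity over the full length", {
  set.seed(31)
  s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 300,
                    replace = TRUE), collapse = "")
  hit <- pairwise_similarity(c(A = s), c(B = s))
  expect_equal(hit$percent_identity, 100)
  expect_gte(hit$alignment_length, 300)
  expect_lt(hit$e_value, 1e-30)
})

test_that("a shuffled permutation scores no edge at the family threshold", {
  set.seed(32)
  s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 300,
                    replace = TRUE), collapse = "")
  shuf <- paste(rev(sample(strsplit(s, "")[[1]])), collapse = "")
  hit <- pairwise_similarity(c(A = s), c(B = shuf))
  expect_gt(hit$e_value, 1e-30)
})

test_that("generated family members land near their target identity", {
  fam <- gen_sequence_family(root_length = 300,
                             clades = list(list(n = 3, identity = 0.5)),
                             seed = 5)
  hit <- pairwise_similarity(fam$sequences["ROOT"], fam$sequences["C1_01"])
  expect_lt(abs(hit$percent_identity - 50), 10)
  expect_error(pairwise_similarity(c(A = "ACDB"), c(B = "ACD")), "B")
})

test_that("BLAST tabular files parse and deduplicate reciprocals", {
  tmp <- tempfile(fileext = ".tsv")
  rows <- c(
    "A\tB\t95.0\t300\t10\t0\t1\t300\t1\t300\t1e-40\t200",
    "B\tA\t95.0\t300\t10\t0\t1\t300\t1\t300\t1e-35\t190",
    "A\tC\t40.0\t250\t100\t5\t1\t250\t1\t250\t1e-10\t80")
  writeLines(rows, tmp)
  hits <- parse_blast_tabular(tmp)
  expect_equal(nrow(hits), 2L)
  ab <- hits[hits$query_id %in% c("A", "B") & hits$subject_id %in% c("A", "B"), ]
  expect_equal(ab$e_value, 1e-40)
  # empty file gives an empty hit list
  writeLines(character(), tmp)
  expect_equal(nrow(parse_blast_tabular(tmp)), 0L)
  # wrong column count names the line
  writeLines("A\tB\t95.0", tmp)
  expect_error(parse_blast_tabular(tmp), "line 1")
  unlink(tmp)
})

test_that("network edges obey the strict threshold rule", {
  hits <- data.frame(query_id = c("A", "B"), subject_id = c("B", "C"),
                     percent_identity = c(90, 50),
                     alignment_length = c(300, 300),
                     e_value = c(1e-40, 1e-10))
  g <- build_ssn(hits, threshold = 1e-30)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C"))
  comp <- igraph::V(g)$component
  names(comp) <- igraph::V(g)$name
  expect_equal(comp[["A"]], comp[["B"]])
  expect_false(comp[["A"]] == comp[["C"]])
  # threshold 0 gives no edges; boundary hit at exactly the threshold is
  # excluded (strictly lower than)
  expect_equal(igraph::ecount(build_ssn(hits, threshold = 0)), 0L)
  hits$e_value <- c(1e-30, 1e-30)
  expect_equal(igraph::ecount(build_ssn(hits, threshold = 1e-30)), 0L)
})

test_that("network construction equals brute-force filtering", {
  for (seed in 1:20) {
    hits <- random_hits(seed = seed)
    thr <- 10^runif(1, -45, -5)
    g <- build_ssn(hits, threshold = thr)
    expect_equal(ssn_edge_keys(g), oracle_ssn_edges(dedup_hits(hits), thr))
    # node count is conserved under thresholding
    expect_equal(igraph::vcount(g),
                 length(unique(c(hits$query_id, hits$subject_id))))
  }
})

test_that("edge density never increases as the threshold tightens", {
  fam <- gen_sequence_family(root_length = 120,
                             clades = list(list(n = 4, identity = 0.9),
                                           list(n = 4, identity = 0.4)),
                             seed = 9)
  hits <- all_vs_all_hits(fam$sequences)
  thresholds <- 10^seq(-5, -60, by = -5)
  counts <- vapply(thresholds, function(t)
    igraph::ecount(build_ssn(hits, threshold = t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("induced subnetworks match brute force and report identity", {
  hits <- data.frame(query_id = c("A", "A", "B"),
                     subject_id = c("B", "C", "C"),
                     percent_identity = c(90, 80, 70),
                     alignment_length = 300, e_value = 1e-40)
  g <- build_ssn(hits)
  sub <- extract_subnetwork(g, c("A", "B"))
  expect_equal(igraph::ecount(sub), 1L)
  expect_equal(igraph::graph_attr(sub, "median_identity"), 90)
  expect_equal(igraph::vcount(extract_subnetwork(g, character())), 0L)
  expect_error(extract_subnetwork(g, "Z"), "unknown")
  for (seed in 1:5) {
    hits <- random_hits(seed = 100 + seed)
    g <- build_ssn(hits, threshold = 1e-20)
    keep <- sample(igraph::V(g)$name, 8)
    sub <- extract_subnetwork(g, keep)
    want <- oracle_ssn_edges(dedup_hits(hits), 1e-20)
    want <- want[vapply(strsplit(want, "|", fixed = TRUE),
                        function(p) all(p %in% keep), logical(1))]
    expect_equal(ssn_edge_keys(sub), want)
  }
})

test_that("reference positions map through gapped alignments", {
  msa <- c(REF = "M-KT", OTH = "MAKT")
  expect_equal(map_reference_position(msa, "REF", 2), 3L)
  expect_equal(map_reference_position(msa, "REF", 1), 1L)
  expect_error(map_reference_position(msa, "REF", 4), "beyond")
  expect_error(map_reference_position(msa, "NOPE", 1), "not in alignment")
  # random gapped rows agree with a naive scan
  set.seed(41)
  for (i in 1:10) {
    res <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30,
                  replace = TRUE)
    gaps <- sort(sample(1:40, 10))
    row <- character(40); row[gaps] <- "-"; row[setdiff(1:40, gaps)] <- res
    msa <- c(R = paste(row, collapse = ""))
    pos <- sample(30, 1)
    naive <- which(row != "-")[pos]
    expect_equal(map_reference_position(msa, "R", pos), naive)
  }
})

test_that("gap insertion left of a position leaves its residue unchanged", {
  msa <- c(R = "MKTAE")
  col <- map_reference_position(msa, "R", 4)
  before <- substr(msa[["R"]], col, col)
  msa2 <- c(R = "M--KTAE")
  col2 <- map_reference_position(msa2, "R", 4)
  expect_equal(substr(msa2[["R"]], col2, col2), before)
})

test_that("node annotation finds planted residues", {
  fam <- gen_sequence_family(root_length = 120,
                             clades = list(list(n = 10, identity = 0.8),
                                           list(n = 33, identity = 0.45)),
                             planted = list(position = 41, letter = "D",
                                            members = 5),
                             seed = 13)
  hits <- all_vs_all_hits(fam$sequences)
  g <- build_ssn(hits, threshold = 1e-5, nodes = names(fam$sequences))
  ann <- annotate_nodes(g, fam$msa, "ROOT", 41)[["41"]]
  expect_equal(unname(ann$counts[["D"]]), 5L)
  planted_rows <- ann$residues$residue[ann$residues$node %in%
                                         fam$truth$planted_members]
  expect_true(all(planted_rows == "D"))
  # the reference node carries its own letter
  expect_equal(ann$residues$residue[ann$residues$node == "ROOT"], "K")
})

test_that("nodes missing from the alignment are annotated NA with warning", {
  msa <- c(REF = "MKT", A = "MDT")
  hits <- data.frame(query_id = "REF", subject_id = "B",
                     percent_identity = 90, alignment_length = 3,
                     e_value = 1e-40)
  g <- build_ssn(hits, nodes = "A")
  expect_warning(ann <- annotate_nodes(g, msa, "REF", 2), "B")
  res <- ann[["2"]]$residues
  expect_true(is.na(res$residue[res$node == "B"]))
  expect_equal(res$residue[res$node == "A"], "D")
})

test_that("column probabilities sum to one over non-gap rows", {
  msa <- c(a = "AA", b = "AA", c = "CA", d = "-A")
  pp <- column_probabilities(msa, 1:2)
  expect_equal(pp$probabilities[["1"]][["A"]], 2 / 3)
  expect_equal(pp$probabilities[["1"]][["C"]], 1 / 3)
  expect_equal(pp$gap_fraction[["1"]], 0.25)
  expect_equal(pp$probabilities[["2"]][["A"]], 1.0)
  # random alignments: every column sums to 1
  fam <- gen_sequence_family(root_length = 50,
                             clades = list(list(n = 6, identity = 0.5)),
                             seed = 3)
  pp2 <- column_probabilities(fam$msa, 1:50)
  sums <- vapply(pp2$probabilities, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  # all-gap columns are flagged
  msa3 <- c(a = "A-", b = "C-")
  pp3 <- column_probabilities(msa3, 1:2)
  expect_true(pp3$all_gap[["2"]])
  expect_true(is.na(pp3$probabilities[["2"]][1]))
})

test_that("FASTA and network writers round-trip", {
  fam <- gen_sequence_family(root_length = 60,
                             clades = list(list(n = 2, identity = 0.7)),
                             seed = 8)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(fam$sequences, fa)
  back <- read_fasta(fa)
  expect_equal(back, fam$sequences)
  hits <- all_vs_all_hits(fam$sequences)
  tsv <- tempfile(fileext = ".tsv")
  write_blast_tabular(hits, tsv)
  reread <- parse_blast_tabular(tsv)
  expect_equal(nrow(reread), nrow(hits))
  g <- build_ssn(hits, threshold = 1e-5)
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(g, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  unlink(c(fa, tsv, gml))
})
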