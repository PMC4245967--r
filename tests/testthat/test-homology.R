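hit_line <- function(q, s, ev, bits = 200, pid = 80, len = 100,
                     qs = 1, qe = 100, ss = 1, se = 100) {
  sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
          q, s, pid, len, as.integer(len * 0.2), 0L, qs, qe, ss, se,
          format(ev, scientific = TRUE), bits)
}

two_cats <- function() {
  list(A = mk_catalog(4, "A"), B = mk_catalog(4, "B"))
}

test_that("the storage filter keeps only hits with e-value strictly below 0.01", {
  cats <- two_cats()
  p <- tempfile()
  writeLines(c(hit_line("A_01", "B_01", 1e-30),
               hit_line("A_02", "B_02", 0.5),
               hit_line("A_03", "B_03", 0.0099),
               hit_line("A_04", "B_04", 0.01)), p)   # boundary: discarded
  hits <- suppressMessages(parse_hits(p, cats))
  expect_equal(sort(hits$query_gene_id), c("A_01", "A_03"))
})

test_that("same-genome hits are discarded and an empty result is allowed", {
  cats <- two_cats()
  p <- tempfile()
  writeLines(c(hit_line("A_01", "A_02", 1e-30),
               hit_line("B_01", "B_03", 1e-20)), p)
  msgs <- capture_messages(hits <- parse_hits(p, cats))
  expect_equal(nrow(hits), 0)
  expect_match(paste(msgs, collapse = " "), "same-genome")
})

test_that("multiple HSPs collapse to the best one per gene pair", {
  cats <- two_cats()
  p <- tempfile()
  writeLines(c(hit_line("A_01", "B_01", 1e-10, bits = 100),
               hit_line("A_01", "B_01", 1e-30, bits = 250),
               hit_line("A_01", "B_01", 1e-30, bits = 300)), p)
  hits <- suppressMessages(parse_hits(p, cats))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$evalue, 1e-30)
  expect_equal(hits$bitscore, 300)
})

test_that("query coverage comes from the aligned query span and protein length", {
  cats <- two_cats()
  # mk_catalog protein_length = (51 %/% 3) - 1 = 16
  p <- tempfile()
  writeLines(hit_line("A_01", "B_01", 1e-30, qs = 3, qe = 10), p)
  hits <- suppressMessages(parse_hits(p, cats))
  expect_equal(hits$query_coverage, 100 * 8 / 16)
})

test_that("unresolvable gene ids and malformed lines are fatal", {
  cats <- two_cats()
  p <- tempfile()
  writeLines(hit_line("A_01", "Z_99", 1e-30), p)
  expect_error(suppressMessages(parse_hits(p, cats)), "unknown gene 'Z_99'")
  writeLines("A_01\tB_01\tonly-three", p)
  expect_error(parse_hits(p, cats), "expected 12 fields")
})

mk_hits <- function(df, qg, sg) {
  df$query_genome_id <- qg
  df$subject_genome_id <- sg
  for (cn in c("pct_identity", "aln_length", "mismatches", "gap_opens",
               "qstart", "qend", "sstart", "send", "query_coverage"))
    if (is.null(df[[cn]])) df[[cn]] <- 0
  df
}

test_that("mutual best hits become orthologs, others homologs", {
  h_ab <- mk_hits(data.frame(
    query_gene_id = c("A_01", "A_01", "A_02"),
    subject_gene_id = c("B_01", "B_02", "B_02"),
    evalue = c(1e-40, 1e-10, 1e-35), bitscore = c(300, 80, 250),
    stringsAsFactors = FALSE), "A", "B")
  h_ba <- mk_hits(data.frame(
    query_gene_id = c("B_01", "B_02"),
    subject_gene_id = c("A_01", "A_02"),
    evalue = c(1e-40, 1e-35), bitscore = c(300, 250),
    stringsAsFactors = FALSE), "B", "A")
  rel <- call_relations(h_ab, h_ba)
  kinds <- setNames(rel$kind, paste(rel$gene_a, rel$gene_b))
  expect_equal(kinds[["A_01 B_01"]], "ortholog")
  expect_equal(kinds[["A_02 B_02"]], "ortholog")
  expect_equal(kinds[["A_01 B_02"]], "homolog")
  expect_equal(nrow(rel), 3)
})

test_that("a one-sided best hit is not an ortholog", {
  # A_01's best is B_01, but B_01's best is A_02
  h_ab <- mk_hits(data.frame(
    query_gene_id = "A_01", subject_gene_id = "B_01",
    evalue = 1e-40, bitscore = 300, stringsAsFactors = FALSE), "A", "B")
  h_ba <- mk_hits(data.frame(
    query_gene_id = c("B_01", "B_01"), subject_gene_id = c("A_02", "A_01"),
    evalue = c(1e-50, 1e-40), bitscore = c(320, 300),
    stringsAsFactors = FALSE), "B", "A")
  rel <- call_relations(h_ab, h_ba)
  kinds <- setNames(rel$kind, paste(rel$gene_a, rel$gene_b))
  expect_equal(kinds[["A_01 B_01"]], "homolog")
  # B_01 -> A_02 is best one way but A_02 has no hits at all: homolog
  expect_equal(kinds[["A_02 B_01"]], "homolog")
})

test_that("e-value ties break by bitscore then lexicographic subject id", {
  h_ab <- mk_hits(data.frame(
    query_gene_id = c("A_01", "A_01"),
    subject_gene_id = c("B_02", "B_01"),
    evalue = c(1e-40, 1e-40), bitscore = c(300, 300),
    stringsAsFactors = FALSE), "A", "B")
  h_ba <- mk_hits(data.frame(
    query_gene_id = c("B_01", "B_02"), subject_gene_id = c("A_01", "A_01"),
    evalue = c(1e-40, 1e-40), bitscore = c(300, 300),
    stringsAsFactors = FALSE), "B", "A")
  rel <- call_relations(h_ab, h_ba)
  kinds <- setNames(rel$kind, paste(rel$gene_a, rel$gene_b))
  # lexicographically smaller B_01 is chosen as A_01's best
  expect_equal(kinds[["A_01 B_01"]], "ortholog")
  expect_equal(kinds[["A_01 B_02"]], "homolog")
  # deterministic across repeated calls
  expect_identical(rel, call_relations(h_ab, h_ba))
})

test_that("ortholog calls are symmetric in the direction of comparison", {
  toy <- toy_pipeline()
  fwd <- call_relations(toy$hits_ab, toy$hits_ba)
  rev <- call_relations(toy$hits_ba, toy$hits_ab)
  pair_fwd <- sort(paste(fwd$gene_a, fwd$gene_b)[fwd$kind == "ortholog"])
  pair_rev <- sort(paste(rev$gene_b, rev$gene_a)[rev$kind == "ortholog"])
  expect_identical(pair_fwd, pair_rev)
  # each gene in at most one ortholog relation
  ortho <- fwd[fwd$kind == "ortholog", ]
  expect_false(any(duplicated(ortho$gene_a)))
  expect_false(any(duplicated(ortho$gene_b)))
})

test_that("planted one-to-one orthologs are recovered exactly", {
  toy <- toy_pipeline()
  ortho <- toy$relations[toy$relations$kind == "ortholog", ]
  got <- sort(paste(ortho$gene_a, ortho$gene_b))
  want <- sort(vapply(toy$truth$pairs$g2$ortholog_pairs,
                      function(p) paste(p$ref_gene, p$cmp_gene), character(1)))
  expect_identical(got, want)
})

test_that("relation tables round-trip through TSV", {
  toy <- toy_pipeline()
  p <- tempfile()
  write_relations(toy$relations, p)
  back <- read_relations(p)
  expect_equal(back$gene_a, toy$relations$gene_a)
  expect_equal(back$kind, toy$relations$kind)
  expect_equal(back$evalue_ab, toy$relations$evalue_ab, tolerance = 1e-12)
})
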