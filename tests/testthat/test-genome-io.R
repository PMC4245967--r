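gb_record <- function(replicon, length_bp, cds_lines) {
  c(sprintf("LOCUS       %s %d bp    DNA     circular BCT 01-JAN-2024",
            replicon, length_bp),
    "FEATURES             Location/Qualifiers",
    cds_lines, "//")
}

gb_cds <- function(loc, locus_tag, extra = character(0)) {
  c(sprintf("     %-16s%s", "CDS", loc),
    sprintf('                     /locus_tag="%s"', locus_tag),
    '                     /product="hypothetical protein"',
    extra,
    sprintf('                     /translation="%s"',
            paste(rep("MKV", 40), collapse = "")))
}

test_that("GenBank CDS features become rank-ordered gene records", {
  path <- tempfile(fileext = ".gbk")
  writeLines(gb_record("chr", 2000, c(
    gb_cds("100..400", "a1"), gb_cds("500..800", "a2"),
    gb_cds("complement(900..1200)", "a3"))), path)
  cat <- load_genome(path, "genbank", genome_id = "gA")
  expect_equal(n_genes(cat), 3)
  expect_equal(cat$genes$rank, 0:2)
  expect_equal(cat$genes$gene_id, c("a1", "a2", "a3"))
  expect_equal(cat$genes$strand, c("+", "+", "-"))
  expect_equal(cat$genes$start, c(100L, 500L, 900L))
  # deterministic: a second load is identical
  expect_identical(cat, load_genome(path, "genbank", genome_id = "gA"))
})

test_that("plasmid genes rank after the chromosome's (file order)", {
  path <- tempfile(fileext = ".gbk")
  writeLines(c(
    gb_record("chr", 1000, c(gb_cds("100..300", "c1"),
                             gb_cds("400..600", "c2"))),
    gb_record("pls", 800, c(gb_cds("50..250", "p1"),
                            gb_cds("300..500", "p2")))), path)
  cat <- load_genome(path, "genbank", genome_id = "gB")
  expect_equal(cat$genes$gene_id, c("c1", "c2", "p1", "p2"))
  expect_equal(cat$genes$rank, 0:3)
  expect_equal(cat$replicons$replicon_id, c("chr", "pls"))
  expect_equal(cat$replicons$offset_bp, c(0L, 1000L))
})

test_that("shuffled record order still ranks by start coordinate", {
  # write CDS features out of coordinate order; ranks must follow an
  # independent sort of the coordinates
  set.seed(11)
  starts <- sort(sample(seq(100, 40000, by = 400), 50))
  perm <- sample(50)
  cds <- unlist(lapply(perm, function(i)
    gb_cds(sprintf("%d..%d", starts[i], starts[i] + 300),
           sprintf("s%02d", i))))
  path <- tempfile(fileext = ".gbk")
  writeLines(gb_record("chr", 50000, cds), path)
  cat <- load_genome(path, "genbank", genome_id = "gS")
  expect_equal(cat$genes$start, starts)
  expect_equal(cat$genes$gene_id, sprintf("s%02d", 1:50))
  expect_equal(cat$genes$rank, 0:49)
})

test_that("pseudogenes and partial CDS are skipped with a warning", {
  path <- tempfile(fileext = ".gbk")
  writeLines(gb_record("chr", 2000, c(
    gb_cds("100..400", "ok1"),
    gb_cds("500..800", "ps1", extra = "                     /pseudo"),
    gb_cds("<900..1200", "pt1"))), path)
  msgs <- capture_messages(cat <- load_genome(path, "genbank"))
  expect_equal(cat$genes$gene_id, "ok1")
  expect_match(paste(msgs, collapse = " "), "pseudogene")
  expect_match(paste(msgs, collapse = " "), "partial")
})

test_that("duplicate locus tags are fatal and name both locations", {
  path <- tempfile(fileext = ".gbk")
  writeLines(gb_record("chr", 2000, c(
    gb_cds("100..400", "dup"), gb_cds("500..800", "dup"))), path)
  expect_error(load_genome(path, "genbank"), "duplicate gene id 'dup'.*1 and 2")
})

test_that("GO namespaces and EC numbers are extracted from qualifiers", {
  path <- tempfile(fileext = ".gbk")
  writeLines(gb_record("chr", 2000, gb_cds("100..400", "g1", extra = c(
    '                     /GO_function="GO:0003001"',
    '                     /GO_process="GO:0008001"',
    '                     /EC_number="1.2.3.4"',
    '                     /db_xref="GO:0099999"',
    '                     /db_xref="UniProtKB:P12345"'))), path)
  cat <- load_genome(path, "genbank")
  g <- cat$genes
  expect_equal(g$go_mf, "GO:0003001")
  expect_equal(g$go_bp, "GO:0008001")
  expect_equal(g$ec_numbers, "1.2.3.4")
  expect_equal(g$go_unspecified, "GO:0099999")
  expect_equal(g$xrefs, "UniProtKB:P12345")
})

test_that("EMBL flat files parse to the same catalog as GenBank", {
  embl <- c(
    "ID   chr; SV 1; circular; genomic DNA; STD; PRO; 2000 BP.",
    "FH   Key             Location/Qualifiers",
    "FT   CDS             100..400",
    'FT                   /locus_tag="a1"',
    'FT                   /product="hypothetical protein"',
    sprintf('FT                   /translation="%s"',
            paste(rep("MKV", 40), collapse = "")),
    "FT   CDS             complement(500..800)",
    'FT                   /locus_tag="a2"',
    'FT                   /product="hypothetical protein"',
    sprintf('FT                   /translation="%s"',
            paste(rep("MKV", 40), collapse = "")),
    "//")
  path <- tempfile(fileext = ".embl")
  writeLines(embl, path)
  cat <- load_genome(path, "embl", genome_id = "gE")
  expect_equal(cat$genes$gene_id, c("a1", "a2"))
  expect_equal(cat$genes$strand, c("+", "-"))
  expect_equal(cat$replicons$length_bp, 2000L)
  expect_equal(cat$genes$protein_length, c(120L, 120L))
})

test_that("GFF3 plus protein FASTA loads with lengths from the FASTA", {
  gff <- c("##gff-version 3",
           "##sequence-region chr 1 5000",
           paste("chr", "test", "CDS", "100", "400", ".", "+", "0",
                 "ID=f1;locus_tag=f1;product=widget", sep = "\t"),
           paste("chr", "test", "CDS", "600", "900", ".", "-", "0",
                 "ID=f2;locus_tag=f2;product=gadget", sep = "\t"))
  gpath <- tempfile(fileext = ".gff3")
  writeLines(gff, gpath)
  fpath <- tempfile(fileext = ".faa")
  writeLines(c(">f1", strrep("M", 77), ">f2", strrep("K", 55)), fpath)
  cat <- load_genome(gpath, "gff3", genome_id = "gG", protein_fasta = fpath)
  expect_equal(cat$genes$gene_id, c("f1", "f2"))
  expect_equal(cat$genes$protein_length, c(77L, 55L))
  expect_equal(cat$replicons$length_bp, 5000L)
  expect_equal(cat$genes$product, c("widget", "gadget"))
})

test_that("gene tables round-trip field-for-field and deterministically", {
  toy <- toy_pipeline()
  for (cat in list(toy$ref, toy$cmp)) {
    p1 <- tempfile()
    write_catalog(cat, p1)
    back <- read_catalog(p1)
    expect_identical(back, cat)
    p2 <- tempfile()
    write_catalog(back, p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("an empty genome round-trips to an empty catalog", {
  e <- genome_catalog(data.frame(gene_id = character(0),
                                 replicon_id = character(0),
                                 start = integer(0), end = integer(0),
                                 strand = character(0)), "empty")
  p <- tempfile()
  write_catalog(e, p)
  back <- read_catalog(p)
  expect_equal(n_genes(back), 0)
  expect_identical(back$genes, e$genes)
})

test_that("rank is a bijection onto 0..N-1 for loaded genomes", {
  toy <- toy_pipeline()
  for (cat in list(toy$ref, toy$cmp))
    expect_identical(sort(cat$genes$rank), seq_len(n_genes(cat)) - 1L)
})

test_that("schema violations in gene tables are fatal with diagnostics", {
  p <- tempfile()
  writeLines(c("#pansynt-gene-table v1", "#genome: x",
               "#replicon: r\t100", "#columns: gene_id\tstart"), p)
  expect_error(read_catalog(p), "unexpected columns")
  p2 <- tempfile()
  writeLines("not a gene table", p2)
  expect_error(read_catalog(p2), "bad signature")
})
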