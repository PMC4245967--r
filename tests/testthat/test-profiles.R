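profile_fixture <- function() {
  ref <- mk_catalog(4, "A")
  relB <- rbind(full_relation("A_01", "B_01", "ortholog"),
                full_relation("A_02", "B_07", "homolog"),
                full_relation("A_02", "B_09", "homolog"))
  relD <- full_relation("A_02", "D_01", "ortholog", genome_b = "D")
  build_profile(ref, list(B = relB, D = relD))
}

test_that("profile labels follow the BDBH / homolog-only / absent rule", {
  prof <- profile_fixture()
  expect_equal(prof$labels["A_01", "B"], "ortholog")
  expect_equal(prof$labels["A_02", "B"], "homolog_only")
  expect_equal(prof$labels["A_03", "B"], "absent")
  expect_equal(prof$labels["A_02", "D"], "ortholog")
})

test_that("stacked homologies keep their supporting relations per cell", {
  prof <- profile_fixture()
  expect_length(cell_support(prof, "A_02", "B"), 2)
  expect_length(cell_support(prof, "A_03", "B"), 0)
})

test_that("planted losses appear as absent cells, islands as absent rows", {
  cfg <- sim_config(seed = 31, genes_per_genome = 60, n_inversions = 0,
                    n_duplications = 0, n_ref_islands = 1, island_size = 5,
                    n_losses = 2)
  pipe <- pair_pipeline(cfg, file.path(tempdir(), "prof_loss"))
  prof <- build_profile(pipe$ref, list(g2 = pipe$relations))
  lost <- unlist(pipe$truth$pairs$g2$lost_ref_genes)
  island <- unlist(pipe$truth$ref_island_genes)
  expect_equal(sort(prof$gene_ids[prof$labels[, "g2"] == "absent"]),
               sort(c(lost, island)))
})

test_that("filters AND/OR match independent set operations", {
  prof <- profile_fixture()
  ref <- mk_catalog(4, "A")
  pres_B <- apply_filter(prof, ref, flt_presence("B", "any_homolog"))
  abs_D <- apply_filter(prof, ref, flt_absence("D"))
  both <- apply_filter(prof, ref,
                       filter_and(flt_presence("B", "any_homolog"),
                                  flt_absence("D")))
  either <- apply_filter(prof, ref,
                         filter_or(flt_presence("B", "any_homolog"),
                                   flt_absence("D")))
  expect_identical(both, intersect(pres_B, abs_D))
  expect_identical(sort(either), sort(union(pres_B, abs_D)))
  expect_identical(both, "A_01")   # hand-enumerated truth
})

test_that("random filter trees distribute over set operations", {
  toy <- toy_pipeline()
  prof <- build_profile(toy$ref, list(g2 = toy$relations))
  set.seed(404)
  leaves <- list(flt_presence("g2"), flt_absence("g2"),
                 flt_presence("g2", "any_homolog"),
                 flt_name("_00"), flt_location("g1_rep1", 1, 8000))
  for (it in 1:10) {
    f1 <- leaves[[sample(length(leaves), 1)]]
    f2 <- leaves[[sample(length(leaves), 1)]]
    a <- apply_filter(prof, toy$ref, f1)
    b <- apply_filter(prof, toy$ref, f2)
    expect_identical(apply_filter(prof, toy$ref, filter_and(f1, f2)),
                     toy$ref$genes$gene_id[toy$ref$genes$gene_id %in%
                                             intersect(a, b)])
    expect_identical(apply_filter(prof, toy$ref, filter_or(f1, f2)),
                     toy$ref$genes$gene_id[toy$ref$genes$gene_id %in%
                                             union(a, b)])
  }
})

test_that("an empty AND selects every gene; an empty OR selects none", {
  prof <- profile_fixture()
  ref <- mk_catalog(4, "A")
  expect_identical(apply_filter(prof, ref, filter_and()),
                   ref$genes$gene_id)
  expect_identical(apply_filter(prof, ref, filter_or()), character(0))
})

test_that("annotation filters select by GO term, EC number and text", {
  cat <- annotated_catalog("A", list(
    list(gene_id = "A_01", go_mf = "GO:0003001", product = "kinase"),
    list(gene_id = "A_02", ec = "1.2.3.4", product = "ABC transporter"),
    list(gene_id = "A_03", go_mf = "GO:0003002;GO:0003001")))
  expect_equal(apply_filter(NULL, cat, flt_go("GO:0003001")),
               c("A_01", "A_03"))
  expect_equal(apply_filter(NULL, cat, flt_ec("1.2.3.4")), "A_02")
  expect_equal(apply_filter(NULL, cat, flt_annotation_text("transporter")),
               "A_02")
  expect_error(flt_go("banana"), "malformed GO")
  expect_error(flt_ec("x.y"), "malformed EC")
})

test_that("core and dispensable partition the reference gene set", {
  toy <- toy_pipeline()
  prof <- build_profile(toy$ref, list(g2 = toy$relations))
  for (pred in c("ortholog", "any_homolog")) {
    cd <- core_dispensable(prof, "g2", pred)
    expect_identical(sort(c(cd$core, cd$dispensable)),
                     sort(toy$ref$genes$gene_id))
    expect_length(intersect(cd$core, cd$dispensable), 0)
  }
})

test_that("the toy's island genes are exactly the dispensable set", {
  toy <- toy_pipeline()
  prof <- build_profile(toy$ref, list(g2 = toy$relations))
  cd <- core_dispensable(prof, "g2")
  expect_identical(sort(cd$dispensable),
                   sort(unlist(toy$truth$ref_island_genes)))
})

test_that("any_homolog core contains the ortholog core", {
  toy <- toy_pipeline()
  prof <- build_profile(toy$ref, list(g2 = toy$relations))
  core_o <- core_dispensable(prof, "g2", "ortholog")$core
  core_h <- core_dispensable(prof, "g2", "any_homolog")$core
  expect_true(all(core_o %in% core_h))
})

test_that("profile labels are stable under compared-genome input order", {
  ref <- mk_catalog(4, "A")
  relB <- full_relation("A_01", "B_01", "ortholog")
  relD <- full_relation("A_02", "D_01", "homolog", genome_b = "D")
  p1 <- build_profile(ref, list(B = relB, D = relD))
  p2 <- build_profile(ref, list(D = relD, B = relB))
  expect_identical(p1$labels[, c("B", "D")], p2$labels[, c("B", "D")])
})

test_that("profile exports write the documented TSV and CSV shapes", {
  prof <- profile_fixture()
  p <- tempfile()
  write_profile(prof, p)
  lines <- readLines(p)
  expect_equal(lines[1], paste(c("#genome", prof$gene_ids), collapse = "\t"))
  expect_equal(strsplit(lines[2], "\t")[[1]][1], "B")
  expect_equal(strsplit(lines[2], "\t")[[1]][2], "O")   # A_01 in B
  pc <- tempfile(fileext = ".csv")
  export_profile_csv(prof, pc)
  df <- utils::read.csv(pc, stringsAsFactors = FALSE)
  expect_equal(df$genome, c("B", "D"))
  expect_equal(df$A_01, c("ortholog", "absent"))
})
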