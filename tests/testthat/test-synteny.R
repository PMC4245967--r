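test_that("chain_score reproduces the scoring arithmetic", {
  p <- synteny_params()
  # three consecutive orthologs
  expect_equal(chain_score(data.frame(
    ref_rank = 0:2, cmp_rank = 0:2, kind = "ortholog"), p), 12)
  # ortholog, 2-gene gap on the compared side, ortholog
  expect_equal(chain_score(data.frame(
    ref_rank = c(0, 1), cmp_rank = c(0, 3), kind = "ortholog"), p), -2)
  # a single homolog anchor scores 2, meeting min_score and min size 1
  expect_equal(chain_score(data.frame(
    ref_rank = 0, cmp_rank = 5, kind = "homolog"), p), 2)
  expect_gte(2, p$min_score)
  expect_gte(1, p$min_anchor_count)
  # explicit mismatch column
  expect_equal(chain_score(data.frame(
    ref_rank = 0:2, cmp_rank = 0:2,
    kind = c("ortholog", "mismatch", "ortholog")), p), 4)
  # reversed chains score the same way
  expect_equal(chain_score(data.frame(
    ref_rank = 0:2, cmp_rank = c(9, 8, 7), kind = "ortholog"), p), 12)
})

test_that("chain_score rejects non-collinear or unanchored chains", {
  p <- synteny_params()
  expect_error(chain_score(data.frame(
    ref_rank = c(0, 0), cmp_rank = 0:1, kind = "ortholog"), p),
    "strictly increase")
  expect_error(chain_score(data.frame(
    ref_rank = 0:2, cmp_rank = c(0, 2, 1), kind = "ortholog"), p),
    "strictly monotone")
  expect_error(chain_score(data.frame(
    ref_rank = 0:1, cmp_rank = 0:1, kind = c("ortholog", "mismatch")), p),
    "terminally anchored")
})

test_that("the alternative gap model charges open plus per-gene extension", {
  p <- synteny_params(gap_model = "open_plus_per_gene")
  expect_equal(chain_score(data.frame(
    ref_rank = c(0, 1), cmp_rank = c(0, 3), kind = "ortholog"), p),
    4 + (-8 + 2 * -2) + 4)
})

test_that("an identical gene order yields one full-length forward block", {
  ref <- mk_catalog(10, "ra")
  cmp <- mk_catalog(10, "ca")
  rel <- mk_relations(sprintf("ra_%02d", 1:10), sprintf("ca_%02d", 1:10),
                      "ortholog")
  bl <- compute_blocks(ref, cmp, rel)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$orientation, "forward")
  expect_equal(bl$score, 40)
  expect_equal(bl$n_anchors, 10)
  expect_false(bl$is_offshoot)
})

test_that("an in-place inversion yields the forward-bowtie-forward pattern", {
  ref <- mk_catalog(10, "rb")
  cmp_order <- c(1:3, 7:4, 8:10)   # genes 4..7 reversed in place
  cmp <- genome_catalog(data.frame(
    gene_id = sprintf("cb_%02d", cmp_order), replicon_id = "r1",
    start = 100L * (1:10), end = 100L * (1:10) + 50L, strand = "+"), "cb")
  rel <- mk_relations(sprintf("rb_%02d", 1:10), sprintf("cb_%02d", 1:10),
                      "ortholog")
  bl <- compute_blocks(ref, cmp, rel)
  prim <- bl[!bl$is_offshoot, ]
  prim <- prim[order(prim$ref_start), ]
  expect_equal(prim$orientation, c("forward", "reversed", "forward"))
  expect_equal(prim$n_anchors, c(3, 4, 3))
  expect_equal(nrow(bl), nrow(prim))   # no offshoot fragments survive
})

test_that("a duplicated segment yields one primary and one offshoot block", {
  toy <- toy_pipeline()
  off <- toy$blocks[toy$blocks$is_offshoot, ]
  expect_equal(nrow(off), 1)
  expect_equal(unique(block_anchors(off, 1)$kind), "homolog")
  truth_off <- Filter(function(b) b$is_offshoot,
                      toy$truth$pairs$g2$expected_blocks)
  expect_equal(length(truth_off), 1)
})

test_that("recovered blocks equal the planted truth on the bundled toy", {
  toy <- toy_pipeline()
  expect_identical(canon_blocks(toy$blocks),
                   canon_truth_blocks(toy$truth$pairs$g2))
})

test_that("planted blocks are recovered exactly across event-rich fixtures", {
  for (seed in c(3, 17, 29)) {
    cfg <- sim_config(seed = seed, genes_per_genome = 80,
                      n_inversions = 1, inversion_size = 6,
                      n_duplications = 1, duplication_size = 3,
                      n_translocations = 1, translocation_size = 4,
                      n_ref_islands = 1, island_size = 5,
                      n_gains = 1, gain_size = 4, n_losses = 2)
    pipe <- pair_pipeline(cfg, file.path(tempdir(), paste0("syn_rec_", seed)))
    expect_identical(canon_blocks(pipe$blocks),
                     canon_truth_blocks(pipe$truth$pairs$g2),
                     info = paste("seed", seed))
  }
})

test_that("the DP matches exhaustive chain enumeration on random instances", {
  set.seed(101)
  for (it in 1:50) {
    inst <- random_instance()
    expect_true(check_oracle_instance(inst), info = paste("instance", it))
  }
})

test_that("raising min_score never increases the number of blocks", {
  set.seed(202)
  for (it in 1:10) {
    inst <- random_instance()
    if (nrow(inst$pairs) == 0) next
    ref <- mk_catalog(inst$n, "r")
    cmp <- mk_catalog(inst$m, "c")
    rel <- mk_relations(sprintf("r_%02d", inst$pairs$ri),
                        sprintf("c_%02d", inst$pairs$cj), inst$pairs$kind)
    counts <- vapply(c(2, 4, 8, 16, 9999), function(ms)
      nrow(compute_blocks(ref, cmp, rel, synteny_params(min_score = ms))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[length(counts)], 0)
  }
})

test_that("reversing the compared genome swaps orientations, keeps scores", {
  cfg <- sim_config(seed = 5, genes_per_genome = 60, n_inversions = 1,
                    inversion_size = 6, n_duplications = 0,
                    n_ref_islands = 1, island_size = 5)
  pipe <- pair_pipeline(cfg, file.path(tempdir(), "syn_orient"))
  bl_fwd <- pipe$blocks
  bl_rev <- compute_blocks(pipe$ref, reverse_catalog(pipe$cmp),
                           pipe$relations)
  expect_equal(sort(bl_fwd$score), sort(bl_rev$score))
  key <- function(bl) {
    o <- order(bl$ref_start)
    paste(bl$n_anchors[o], collapse = ",")
  }
  expect_equal(key(bl_fwd[!bl_fwd$is_offshoot, ]),
               key(bl_rev[!bl_rev$is_offshoot, ]))
  swap <- c(forward = "reversed", reversed = "forward")
  expect_equal(sort(unname(swap[bl_fwd$orientation])),
               sort(bl_rev$orientation))
})

test_that("swapping reference and compared genomes preserves primary scores", {
  cfg <- sim_config(seed = 9, genes_per_genome = 60, n_inversions = 1,
                    inversion_size = 6, n_duplications = 0,
                    n_ref_islands = 0)
  pipe <- pair_pipeline(cfg, file.path(tempdir(), "syn_swap"))
  bl_ab <- pipe$blocks
  bl_ba <- compute_blocks(pipe$cmp, pipe$ref, pipe$relations)
  expect_equal(sort(bl_ab$score[!bl_ab$is_offshoot]),
               sort(bl_ba$score[!bl_ba$is_offshoot]))
})

test_that("blocks never span replicon boundaries", {
  cfg <- sim_config(seed = 13, genes_per_genome = 60,
                    replicons_per_genome = 2, n_inversions = 1,
                    inversion_size = 6, n_duplications = 0,
                    n_ref_islands = 0)
  pipe <- pair_pipeline(cfg, file.path(tempdir(), "syn_rep2"))
  expect_gt(nrow(pipe$blocks), 1)
  for (i in seq_len(nrow(pipe$blocks))) {
    anc <- block_anchors(pipe$blocks, i)
    ref_reps <- pipe$ref$genes$replicon_id[
      match(anc$ref_gene_id, pipe$ref$genes$gene_id)]
    cmp_reps <- pipe$cmp$genes$replicon_id[
      match(anc$cmp_gene_id, pipe$cmp$genes$gene_id)]
    expect_equal(length(unique(ref_reps)), 1)
    expect_equal(length(unique(cmp_reps)), 1)
  }
})

test_that("no relations means no blocks", {
  expect_equal(nrow(compute_blocks(mk_catalog(3, "x"), mk_catalog(3, "y"),
                                   mk_relations(character(0), character(0),
                                                character(0)))), 0)
})

test_that("block tables round-trip through TSV", {
  toy <- toy_pipeline()
  p <- tempfile()
  write_blocks(toy$blocks, p)
  back <- read_blocks(p)
  expect_equal(back$score, toy$blocks$score)
  expect_equal(back$anchors, toy$blocks$anchors)
  expect_equal(back$is_offshoot, toy$blocks$is_offshoot)
})
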