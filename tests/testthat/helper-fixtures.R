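# Shared fixtures and independent oracles for the test suite.

# quick single-replicon catalog: n genes at regular spacing
mk_catalog <- function(n, id, replicon = "r1") {
  genome_catalog(data.frame(
    gene_id = sprintf("%s_%02d", id, seq_len(n)),
    replicon_id = replicon,
    start = 100L * seq_len(n), end = 100L * seq_len(n) + 50L,
    strand = "+", stringsAsFactors = FALSE), id)
}

mk_relations <- function(gene_a, gene_b, kind) {
  data.frame(gene_a = gene_a, gene_b = gene_b, kind = kind,
             stringsAsFactors = FALSE)
}

# a catalog with the same genes in reversed genomic order
reverse_catalog <- function(cat) {
  g <- cat$genes
  tot <- max(g$end) + 100L
  g2 <- g
  g2$start <- tot - g$end
  g2$end <- tot - g$start
  genome_catalog(g2[, c("gene_id", "replicon_id", "start", "end", "strand",
                        "protein_length", "product", "go_mf", "go_bp",
                        "go_cc", "go_unspecified", "ec_numbers", "xrefs")],
                 cat$genome_id, replicons = NULL)
}

canon_blocks <- function(bl) {
  sort(paste(bl$orientation, bl$is_offshoot, bl$anchors, sep = "|"))
}

canon_truth_blocks <- function(pair) {
  sort(vapply(pair$expected_blocks, function(b)
    paste(b$orientation, b$is_offshoot,
          paste(vapply(b$anchors, function(a)
            paste(a$ref_gene, a$cmp_gene, a$kind, sep = ":"), character(1)),
            collapse = ";"), sep = "|"), character(1)))
}

# run the whole pipeline on a simulated pair
pair_pipeline <- function(cfg, dir) {
  res <- simulate_genomes(cfg, dir)
  g1 <- suppressMessages(load_genome(res$genome_files[[1]], "genbank"))
  g2 <- suppressMessages(load_genome(res$genome_files[[2]], "genbank"))
  h_ab <- suppressMessages(parse_hits(res$hit_files[[1]], list(g1, g2)))
  h_ba <- suppressMessages(parse_hits(res$hit_files[[2]], list(g1, g2)))
  rel <- call_relations(h_ab, h_ba)
  blocks <- compute_blocks(g1, g2, rel)
  list(sim = res, ref = g1, cmp = g2, hits_ab = h_ab, hits_ba = h_ba,
       relations = rel, blocks = blocks, truth = res$truth)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# the bundled miniature comparison, computed once per test run
.toy_cache <- new.env(parent = emptyenv())
toy_pipeline <- function() {
  if (is.null(.toy_cache$res)) {
    dir <- file.path(tempdir(), "pansynt_test_toy")
    cfg <- sim_config(seed = 42L, n_genomes = 2L, genes_per_genome = 30L,
                      n_inversions = 1L, inversion_size = 6L,
                      n_duplications = 1L, duplication_size = 3L,
                      n_ref_islands = 1L, island_size = 5L)
    .toy_cache$res <- pair_pipeline(cfg, dir)
  }
  .toy_cache$res
}

# ---------------------------------------------------------------------------
# Independent oracle for chain scores: exhaustive enumeration of all
# terminally anchored collinear chains (both orientations), scored by
# direct summation.

oracle_jcost <- function(di, dj, p) {
  gc <- function(k) if (k == 0) 0 else p$gap_open + (k - 1) * p$gap_extend
  best <- -Inf
  for (a in 0:min(di, dj))
    best <- max(best, a * p$mismatch_score + gc(di - a) + gc(dj - a))
  best
}

oracle_best_score <- function(n, m, pairs, p) {
  best <- -Inf
  for (orient in c(1, -1)) {
    anc <- pairs
    anc$cj2 <- if (orient == 1) anc$cj else m + 1L - anc$cj
    anc$sc <- ifelse(anc$kind == "ortholog", p$ortholog_score,
                     p$homolog_score)
    A <- nrow(anc)
    ext <- function(k, sc) {
      best <<- max(best, sc)
      for (l in seq_len(A)) {
        di <- anc$ri[l] - anc$ri[k] - 1L
        dj <- anc$cj2[l] - anc$cj2[k] - 1L
        if (di >= 0 && dj >= 0 && di <= p$max_gap && dj <= p$max_gap)
          ext(l, sc + oracle_jcost(di, dj, p) + anc$sc[l])
      }
    }
    for (k in seq_len(A)) ext(k, anc$sc[k])
  }
  best
}

random_instance <- function() {
  n <- sample(3:8, 1)
  m <- sample(3:8, 1)
  pairs <- expand.grid(ri = seq_len(n), cj = seq_len(m))
  pairs <- pairs[runif(nrow(pairs)) < 0.25, , drop = FALSE]
  pairs$kind <- ifelse(runif(nrow(pairs)) < 0.5, "ortholog", "homolog")
  list(n = n, m = m, pairs = pairs)
}

# run implementation and oracle on one random instance; TRUE if they agree
check_oracle_instance <- function(inst, p = synteny_params()) {
  if (nrow(inst$pairs) == 0) return(TRUE)
  ref <- mk_catalog(inst$n, "r")
  cmp <- mk_catalog(inst$m, "c")
  rel <- mk_relations(sprintf("r_%02d", inst$pairs$ri),
                      sprintf("c_%02d", inst$pairs$cj), inst$pairs$kind)
  bl <- compute_blocks(ref, cmp, rel, p)
  got <- if (nrow(bl)) max(bl$score[!bl$is_offshoot]) else -Inf
  ob <- oracle_best_score(inst$n, inst$m, inst$pairs, p)
  want <- if (ob >= p$min_score) ob else -Inf
  isTRUE(all.equal(got, want))
}

# ---------------------------------------------------------------------------
# tiny hand-written annotation fixtures

annotated_catalog <- function(id, genes) {
  # genes: list of lists with gene_id and optional annotation fields
  df <- do.call(rbind, lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    data.frame(gene_id = g$gene_id, replicon_id = "r1",
               start = 100L * i, end = 100L * i + 50L, strand = "+",
               protein_length = 100L,
               product = g$product %||% "",
               go_mf = g$go_mf %||% "", go_bp = g$go_bp %||% "",
               go_cc = g$go_cc %||% "", go_unspecified = "",
               ec_numbers = g$ec %||% "", xrefs = g$xref %||% "",
               stringsAsFactors = FALSE)
  }))
  genome_catalog(df, id)
}

full_relation <- function(gene_a, gene_b, kind, evalue = 1e-30,
                          pct_identity = 80, coverage = 95, bitscore = 200,
                          genome_a = "A", genome_b = "B") {
  data.frame(gene_a = gene_a, gene_b = gene_b, genome_a = genome_a,
             genome_b = genome_b, kind = kind, evalue_ab = evalue,
             evalue_ba = evalue, pct_identity = pct_identity,
             query_coverage_ab = coverage, query_coverage_ba = coverage,
             bitscore_ab = bitscore, bitscore_ba = bitscore,
             stringsAsFactors = FALSE)
}
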