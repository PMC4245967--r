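# Seeded simulator of genome pairs/sets with planted evolutionary events
# and matching protein hit tables, plus a machine-readable truth table.
#
# The generator derives each compared genome from a common ancestor gene
# order by applying inversions, translocations, segmental duplications,
# gene gains (island insertions) and gene losses. Event segments are placed
# with a >= 3-gene buffer between them, gains/duplication insertions are at
# least 3 genes long and loss runs at most 2 genes, so that every planted
# block is recoverable exactly by the chaining defaults (max_gap = 2):
# gaps of <= 2 genes are bridged, runs of >= 3 idiosyncratic genes break a
# chain. Hit e-values and bit scores are synthesized, not computed from
# sequences; protein sequences are arbitrary amino-acid strings of the
# declared lengths.

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Event counts apply to every compared genome (positions are sampled
#' independently per genome). Planted true-hit e-values must lie strictly
#' below the storage threshold 0.01.
#'
#' @param seed integer; fully determines the output.
#' @param n_genomes total genomes (the first is the reference).
#' @param genes_per_genome ancestor gene count.
#' @param replicons_per_genome contiguous replicon chunks per genome.
#' @param n_inversions,inversion_size planted in-place inversions.
#' @param n_duplications,duplication_size segmental duplications: the copy
#'   is inserted at a distant locus and hits the same reference genes with
#'   weaker, non-best e-values.
#' @param n_translocations,translocation_size segments moved elsewhere.
#' @param n_ref_islands,island_size novel-gene islands inserted in the
#'   reference only (reference-specific regions).
#' @param n_gains,gain_size novel-gene islands inserted in a compared
#'   genome (compared-specific regions).
#' @param n_losses single ancestor genes deleted from a compared genome.
#' @param ortholog_evalue_range e-value range for planted ortholog hits.
#' @param decoy_evalue_range weaker range for duplication-copy and decoy
#'   hits; must not overlap the ortholog range.
#' @param decoy_rate expected decoy hits per conserved gene (spurious weak
#'   cross-hits between distant conserved genes).
#' @param n_suprathreshold rows emitted with e-value >= 0.01 (exercise the
#'   storage filter; never stored).
#' @param annotation_share_frac probability that an ortholog keeps each of
#'   its ancestor's annotations.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genomes = 2L, genes_per_genome = 60L,
                       replicons_per_genome = 1L,
                       n_inversions = 1L, inversion_size = 6L,
                       n_duplications = 1L, duplication_size = 3L,
                       n_translocations = 0L, translocation_size = 4L,
                       n_ref_islands = 1L, island_size = 5L,
                       n_gains = 0L, gain_size = 4L,
                       n_losses = 0L,
                       ortholog_evalue_range = c(1e-50, 1e-12),
                       decoy_evalue_range = c(1e-8, 1e-3),
                       decoy_rate = 0.1,
                       n_suprathreshold = 3L,
                       annotation_share_frac = 0.8) {
  cfg <- as.list(environment())
  for (nm in names(cfg))
    if (is.numeric(cfg[[nm]]) && all(cfg[[nm]] == floor(cfg[[nm]])))
      cfg[[nm]] <- as.integer(cfg[[nm]])
  counts <- c(n_genomes, genes_per_genome, replicons_per_genome,
              n_inversions, n_duplications, n_translocations, n_ref_islands,
              n_gains, n_losses, n_suprathreshold)
  if (!all(vapply(counts, is_count, logical(1))))
    ps_validation_error("simulation counts must be non-negative integers")
  if (n_genomes < 2) ps_validation_error("need at least 2 genomes")
  if (inversion_size < 2 || duplication_size < 1 || island_size < 3 ||
      gain_size < 3 || translocation_size < 1)
    ps_validation_error("event sizes out of range")
  if (max(ortholog_evalue_range) >= min(decoy_evalue_range))
    ps_validation_error("ortholog and decoy e-value ranges must not overlap")
  if (max(decoy_evalue_range) >= 0.01 || min(ortholog_evalue_range) <= 0)
    ps_validation_error("planted hit e-values must lie in (0, 0.01)")
  footprint <- n_inversions * (inversion_size + 3) +
    n_duplications * (duplication_size + 5) +
    n_translocations * (translocation_size + 5) + n_losses * 4 +
    n_gains * 2 + 8
  if (footprint > genes_per_genome)
    ps_validation_error(sprintf(
      "contradictory config: %d genes cannot host the requested events (need ~%d)",
      genes_per_genome, footprint))
  structure(cfg, class = "sim_config")
}

SIM_BUFFER <- 3L  # genes kept clear around every planted event

PRODUCT_POOL <- c(
  "ABC transporter ATP-binding protein", "DNA polymerase III subunit delta",
  "50S ribosomal protein L21", "MFS family permease",
  "two-component sensor histidine kinase", "cell division protein FtsZ",
  "phosphoglycerate kinase", "transcriptional regulator, LysR family",
  "peptidoglycan hydrolase", "NADH-quinone oxidoreductase subunit",
  "tRNA modification GTPase", "preprotein translocase subunit SecY",
  "glucose-6-phosphate isomerase", "signal peptidase I",
  "hypothetical protein")

rand_go <- function(n, base) sprintf("GO:%07d", base + sample.int(40, n))
rand_ec <- function(n)
  sprintf("%d.%d.%d.%d", sample(1:6, n, TRUE), sample(1:9, n, TRUE),
          sample(1:9, n, TRUE), sample(1:99, n, TRUE))

rand_annotations <- function(n) {
  data.frame(
    product = sample(PRODUCT_POOL, n, replace = TRUE),
    go_mf = vapply(seq_len(n), function(i)
      join_set(rand_go(sample(1:2, 1), 3000)), character(1)),
    go_bp = vapply(seq_len(n), function(i)
      join_set(rand_go(1, 8000)), character(1)),
    go_cc = vapply(seq_len(n), function(i)
      join_set(rand_go(sample(0:1, 1), 5000)), character(1)),
    ec_numbers = vapply(seq_len(n), function(i)
      join_set(if (runif(1) < 0.5) rand_ec(1) else character(0)), character(1)),
    xrefs = sprintf("UniProtKB:Q%05d", sample.int(99999, n)),
    stringsAsFactors = FALSE)
}

# Derive a homolog's annotations from its ancestor's: keep each with
# probability `share`, occasionally add one extra term.
derive_annotations <- function(anc_row, share) {
  keep <- function(joined) join_set(Filter(function(x) runif(1) < share,
                                           split_set(joined)))
  out <- anc_row
  for (col in c("go_mf", "go_bp", "go_cc", "ec_numbers"))
    out[[col]] <- keep(anc_row[[col]])
  if (runif(1) < 0.2)
    out$go_bp <- join_set(c(split_set(out$go_bp), rand_go(1, 8000)))
  out
}

# Sample positions for event intervals and insertion points on 1..n with
# SIM_BUFFER genes clear around each; fatal when no placement exists.
place_events <- function(n, interval_sizes, n_points, pre_blocked = integer(0)) {
  blocked <- rep(FALSE, n)
  block <- function(lo, hi) {
    blocked[max(1, lo - SIM_BUFFER):min(n, hi + SIM_BUFFER)] <<- TRUE
  }
  # keep SIM_BUFFER genes clear at the ends so terminal flanks hold >= 3
  # anchors (a gap next to a shorter flank would tie with splitting)
  blocked[c(1:SIM_BUFFER, (n - SIM_BUFFER + 1L):n)] <- TRUE
  for (b in pre_blocked) block(b, b)
  intervals <- list()
  for (sz in interval_sizes) {
    placed <- FALSE
    for (try in 1:400) {
      a <- sample.int(n - sz + 1L, 1L)
      if (!any(blocked[a:(a + sz - 1L)])) {
        intervals[[length(intervals) + 1L]] <- c(a, a + sz - 1L)
        block(a, a + sz - 1L)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      ps_validation_error("contradictory config: cannot place all events")
  }
  points <- integer(0)
  for (i in seq_len(n_points)) {
    placed <- FALSE
    for (try in 1:400) {
      a <- sample.int(n - 1L, 1L)   # insertion between a and a+1
      if (!any(blocked[a:(a + 1L)])) {
        points <- c(points, a)
        block(a, a + 1L)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      ps_validation_error("contradictory config: cannot place all insertions")
  }
  list(intervals = intervals, points = points)
}

# ---------------------------------------------------------------------------

#' Simulate genomes with planted events and matching hit tables
#'
#' Writes one GenBank flat file per genome, a pair of hit tables (both
#' directions) for the reference against every other genome, and a
#' `truth.json` describing the planted ortholog pairs, the expected synteny
#' blocks (primary and offshoot) under the default chaining parameters, and
#' the genome-specific gene sets. Identical seeds reproduce byte-identical
#' output.
#'
#' @param config a [sim_config].
#' @param out_dir output directory (created if needed).
#' @return list with `dir`, `genome_files` (named by genome id),
#'   `hit_files` (named `"<ref>_vs_<cmp>"` / `"<cmp>_vs_<ref>"`),
#'   `truth_file` and the parsed `truth` list.
#' @export
simulate_genomes <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_with_seed(config$seed, simulate_impl(config, out_dir))
}

simulate_impl <- function(config, out_dir) {
  N <- config$genes_per_genome
  genome_ids <- sprintf("g%d", seq_len(config$n_genomes))
  ref_id <- genome_ids[1]

  anc <- cbind(data.frame(anc_idx = seq_len(N),
                          plen = sample(80:250, N, replace = TRUE),
                          strand = sample(c("+", "-"), N, replace = TRUE),
                          stringsAsFactors = FALSE),
               rand_annotations(N))

  # --- reference genome: ancestor order plus novel islands
  ref_pl <- place_events(N, interval_sizes = integer(0),
                         n_points = config$n_ref_islands)
  ref_items <- lapply(seq_len(N), function(i)
    list(type = "anc", anc_idx = i))
  island_genes <- list()
  ins_shift <- 0L
  for (pt in sort(ref_pl$points)) {
    novel <- rand_annotations(config$island_size)
    novel$plen <- sample(80:250, config$island_size, replace = TRUE)
    novel$strand <- sample(c("+", "-"), config$island_size, replace = TRUE)
    items <- lapply(seq_len(config$island_size), function(i)
      c(list(type = "island"), as.list(novel[i, , drop = FALSE])))
    ref_items <- append(ref_items, items, after = pt + ins_shift)
    ins_shift <- ins_shift + config$island_size
    island_genes[[length(island_genes) + 1L]] <- items
  }

  materialize <- function(items, genome_id) {
    ng <- length(items)
    rows <- vector("list", ng)
    pos <- 0L
    n_rep <- config$replicons_per_genome
    rep_break <- ceiling(ng / n_rep)
    for (i in seq_len(ng)) {
      it <- items[[i]]
      if (identical(it$type, "anc")) {
        src <- anc[it$anc_idx, ]
      } else if (identical(it$type, "dup")) {
        src <- it$annot
      } else {
        src <- as.data.frame(it[c("plen", "strand", "product", "go_mf",
                                  "go_bp", "go_cc", "ec_numbers", "xrefs")],
                             stringsAsFactors = FALSE)
      }
      rep_no <- (i - 1L) %/% rep_break + 1L
      if (i > 1 && rep_no != rows[[i - 1]]$rep_no) pos <- 0L
      start <- pos + sample(30:150, 1L)
      end <- start + 3L * (src$plen + 1L) - 1L
      pos <- end
      rows[[i]] <- list(
        gene_id = sprintf("%s_%04d", genome_id, i),
        genome_id = genome_id,
        replicon_id = sprintf("%s_rep%d", genome_id, rep_no),
        rep_no = rep_no, start = start, end = end,
        strand = src$strand, plen = src$plen, product = src$product,
        go_mf = src$go_mf, go_bp = src$go_bp, go_cc = src$go_cc,
        ec_numbers = src$ec_numbers, xrefs = src$xrefs,
        type = it$type, anc_idx = it$anc_idx %||% NA_integer_,
        dup_target = it$target_anc %||% NA_integer_)
    }
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    df$go_unspecified <- ""
    df
  }
  ref_genes <- materialize(ref_items, ref_id)

  truth <- list(seed = config$seed, ref_genome = ref_id,
                genomes = as.list(genome_ids),
                ref_island_genes =
                  as.list(ref_genes$gene_id[ref_genes$type == "island"]),
                pairs = list())
  genome_files <- character(0)
  hit_files <- character(0)

  write_genome <- function(genes, genome_id) {
    path <- file.path(out_dir, paste0(genome_id, ".gbk"))
    write_genbank(genes, path)
    genome_files[genome_id] <<- path
  }
  write_genome(ref_genes, ref_id)

  for (k in 2:config$n_genomes) {
    gid <- genome_ids[k]
    # compared-genome events stay clear of the reference island insertion
    # points so every planted block keeps >= SIM_BUFFER anchors on each side
    derived <- derive_compared(anc, config,
                               pre_blocked = unlist(lapply(ref_pl$points,
                                                           function(p) p + 0:1)))
    cmp_genes <- materialize(derived$items, gid)
    write_genome(cmp_genes, gid)

    pair <- build_pair_truth(ref_genes, cmp_genes, config)
    pair$cmp_genome <- gid
    hits <- synthesize_hits(ref_genes, cmp_genes, pair, config)
    f_ab <- file.path(out_dir, sprintf("hits_%s_vs_%s.tsv", ref_id, gid))
    f_ba <- file.path(out_dir, sprintf("hits_%s_vs_%s.tsv", gid, ref_id))
    write_hit_table(hits$ab, f_ab)
    write_hit_table(hits$ba, f_ba)
    hit_files[sprintf("%s_vs_%s", ref_id, gid)] <- f_ab
    hit_files[sprintf("%s_vs_%s", gid, ref_id)] <- f_ba
    pair$hit_rows_total <- nrow(hits$ab) + nrow(hits$ba)
    pair$hit_rows_below_threshold <-
      sum(hits$ab$ev < 0.01) + sum(hits$ba$ev < 0.01)
    truth$pairs[[gid]] <- pair
  }

  truth_file <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(dir = out_dir, genome_files = genome_files, hit_files = hit_files,
       truth_file = truth_file, truth = truth)
}

# Apply the configured events to a fresh copy of the ancestor.
derive_compared <- function(anc, config, pre_blocked = integer(0)) {
  N <- nrow(anc)
  sizes <- c(rep(config$inversion_size, config$n_inversions),
             rep(config$duplication_size, config$n_duplications),
             rep(config$translocation_size, config$n_translocations),
             rep(1L, config$n_losses))
  pl <- place_events(N, interval_sizes = sizes,
                     n_points = config$n_duplications +
                       config$n_translocations + config$n_gains,
                     pre_blocked = pre_blocked)
  iv <- pl$intervals
  take <- function(n) { out <- iv[seq_len(n)]; iv <<- iv[-seq_len(n)]; out }
  inv_iv <- take(config$n_inversions)
  dup_iv <- take(config$n_duplications)
  tra_iv <- take(config$n_translocations)
  los_iv <- take(config$n_losses)
  pts <- pl$points
  dup_pts <- pts[seq_len(config$n_duplications)]
  tra_pts <- pts[config$n_duplications + seq_len(config$n_translocations)]
  gain_pts <- pts[config$n_duplications + config$n_translocations +
                  seq_len(config$n_gains)]

  items <- lapply(seq_len(N), function(i) list(type = "anc", anc_idx = i))
  pos_of <- function(anc_i)
    which(vapply(items, function(it)
      isTRUE(it$anc_idx == anc_i), logical(1)))

  for (v in inv_iv) {
    p <- pos_of(v[1]):pos_of(v[2])
    items[p] <- items[rev(p)]
  }
  insertions <- list()  # postponed so earlier positions stay valid
  for (i in seq_along(dup_iv)) {
    v <- dup_iv[[i]]
    copies <- lapply(v[1]:v[2], function(ai) list(
      type = "dup", anc_idx = NA_integer_, target_anc = ai,
      annot = derive_annotations(anc[ai, ], config$annotation_share_frac)))
    insertions[[length(insertions) + 1L]] <-
      list(after_anc = dup_pts[i], what = copies)
  }
  for (i in seq_along(tra_iv)) {
    v <- tra_iv[[i]]
    p <- pos_of(v[1]):pos_of(v[2])
    moved <- items[p]
    items <- items[-p]
    insertions[[length(insertions) + 1L]] <-
      list(after_anc = tra_pts[i], what = moved)
  }
  for (i in seq_along(gain_pts)) {
    novel <- rand_annotations(config$gain_size)
    novel$plen <- sample(80:250, config$gain_size, replace = TRUE)
    novel$strand <- sample(c("+", "-"), config$gain_size, replace = TRUE)
    gains <- lapply(seq_len(config$gain_size), function(j)
      c(list(type = "gain"), as.list(novel[j, , drop = FALSE])))
    insertions[[length(insertions) + 1L]] <-
      list(after_anc = gain_pts[i], what = gains)
  }
  for (ins in insertions) {
    at <- pos_of(ins$after_anc)
    if (length(at) == 0)  # anchor gene itself moved; fall back to its left
      at <- max(which(vapply(items, function(it)
        !is.na(it$anc_idx %||% NA_integer_) &&
          it$anc_idx < ins$after_anc, logical(1))))
    items <- append(items, ins$what, after = at)
  }
  for (v in los_iv) {
    p <- pos_of(v[1])
    if (length(p)) items <- items[-p]
  }
  list(items = items)
}

# Expected blocks under the default chaining rules (max_gap = 2): walk the
# compared gene order and chain consecutive anchors whose reference-rank
# deltas stay within the bridgeable window; insertions of >= 3 genes and
# replicon boundaries break chains. Independent of the DP implementation.
build_pair_truth <- function(ref_genes, cmp_genes, config, max_gap = 2L) {
  ref_rank <- setNames(seq_len(nrow(ref_genes)) - 1L, ref_genes$gene_id)
  anc_to_ref <- setNames(ref_genes$gene_id, ref_genes$anc_idx)
  anc_to_ref <- anc_to_ref[!is.na(ref_genes$anc_idx)]

  scan_blocks <- function(idx, kinds) {
    # idx: row indices of cmp_genes carrying an anchor, in cmp order
    blocks <- list()
    run <- list()
    dir <- 0L
    flush <- function() {
      if (length(run) == 0) return()
      anchors <- lapply(run, function(r) list(
        ref_gene = r$ref_gene, cmp_gene = r$cmp_gene, kind = r$kind))
      rr <- vapply(run, function(r) r$ref_rank, numeric(1))
      anchors <- anchors[order(rr)]
      blocks[[length(blocks) + 1L]] <<- list(
        orientation = if (dir < 0) "reversed" else "forward",
        anchors = anchors)
      run <<- list(); dir <<- 0L
    }
    prev <- NULL
    for (i in idx) {
      tgt <- cmp_genes$anc_idx[i]
      if (is.na(tgt)) tgt <- cmp_genes$target_anc_truth[i]
      rg <- anc_to_ref[[as.character(tgt)]]
      cur <- list(ref_gene = rg, cmp_gene = cmp_genes$gene_id[i],
                  ref_rank = ref_rank[[rg]], cmp_row = i,
                  ref_replicon = ref_genes$replicon_id[match(rg, ref_genes$gene_id)],
                  cmp_replicon = cmp_genes$replicon_id[i],
                  kind = kinds[match(i, idx)])
      ok <- FALSE
      if (!is.null(prev)) {
        dref <- cur$ref_rank - prev$ref_rank
        dcmp <- cur$cmp_row - prev$cmp_row - 1L
        same_rep <- cur$ref_replicon == prev$ref_replicon &&
          cur$cmp_replicon == prev$cmp_replicon
        if (same_rep && dcmp <= max_gap) {
          if (dref >= 1 && dref <= max_gap + 1 && dir >= 0) { dir <- 1L; ok <- TRUE }
          else if (dref <= -1 && dref >= -(max_gap + 1) && dir <= 0) {
            dir <- -1L; ok <- TRUE
          }
        }
      }
      if (!ok && !is.null(prev)) flush()
      run[[length(run) + 1L]] <- cur
      prev <- cur
    }
    flush()
    blocks
  }

  # truth bookkeeping columns on the cmp table
  cmp_genes$target_anc_truth <- cmp_genes$dup_target
  is_dup <- cmp_genes$type == "dup"

  ortho_idx <- which(cmp_genes$type == "anc" &
                     cmp_genes$anc_idx %in% as.integer(names(anc_to_ref)))
  primary <- scan_blocks(ortho_idx, rep("ortholog", length(ortho_idx)))
  for (b in seq_along(primary)) primary[[b]]$is_offshoot <- FALSE

  offshoots <- list()
  if (any(is_dup)) {
    dup_idx <- which(is_dup)
    offshoots <- scan_blocks(dup_idx, rep("homolog", length(dup_idx)))
    for (b in seq_along(offshoots)) offshoots[[b]]$is_offshoot <- TRUE
  }

  ortholog_pairs <- lapply(ortho_idx, function(i) list(
    ref_gene = anc_to_ref[[as.character(cmp_genes$anc_idx[i])]],
    cmp_gene = cmp_genes$gene_id[i]))
  homolog_pairs <- lapply(which(is_dup), function(i) list(
    ref_gene = anc_to_ref[[as.character(cmp_genes$dup_target[i])]],
    cmp_gene = cmp_genes$gene_id[i]))

  lost_anc <- setdiff(ref_genes$anc_idx[!is.na(ref_genes$anc_idx)],
                      cmp_genes$anc_idx[!is.na(cmp_genes$anc_idx)])
  list(
    cmp_genome = cmp_genes$genome_id[1],
    ortholog_pairs = ortholog_pairs,
    homolog_pairs = homolog_pairs,
    expected_blocks = c(primary, offshoots),
    cmp_specific_genes = as.list(cmp_genes$gene_id[cmp_genes$type == "gain"]),
    lost_ref_genes = as.list(unname(anc_to_ref[as.character(lost_anc)]))
  )
}

synthesize_hits <- function(ref_genes, cmp_genes, pair, config) {
  lo_o <- log10(config$ortholog_evalue_range[1])
  hi_o <- log10(config$ortholog_evalue_range[2])
  lo_d <- log10(config$decoy_evalue_range[1])
  hi_d <- log10(config$decoy_evalue_range[2])
  plen_ref <- setNames(ref_genes$plen, ref_genes$gene_id)
  plen_cmp <- setNames(cmp_genes$plen, cmp_genes$gene_id)

  hit_row <- function(q, s, plq, pls, ev) {
    pid <- round(runif(1, 60, 95), 1)
    len <- min(plq, pls)
    data.frame(q = q, s = s, pid = pid, len = len,
               mism = as.integer(round(len * (1 - pid / 100))),
               gapo = 0L, qs = 1L, qe = plq, ss = 1L, se = pls,
               ev = ev, bits = round(-10 * log10(ev) + runif(1, 40, 90), 1),
               stringsAsFactors = FALSE)
  }
  ab <- list(); ba <- list()
  add <- function(rg, cg, lo, hi) {
    ab[[length(ab) + 1L]] <<- hit_row(rg, cg, plen_ref[[rg]], plen_cmp[[cg]],
                                      10^runif(1, lo, hi))
    ba[[length(ba) + 1L]] <<- hit_row(cg, rg, plen_cmp[[cg]], plen_ref[[rg]],
                                      10^runif(1, lo, hi))
  }
  op <- pair$ortholog_pairs
  for (p in op) add(p$ref_gene, p$cmp_gene, lo_o, hi_o)
  for (p in pair$homolog_pairs) add(p$ref_gene, p$cmp_gene, lo_d, hi_d)

  # multi-HSP rows for the first two ortholog pairs: a weaker second HSP
  for (p in head(op, 2)) {
    r <- hit_row(p$ref_gene, p$cmp_gene, plen_ref[[p$ref_gene]],
                 plen_cmp[[p$cmp_gene]], 10^runif(1, hi_o + 2, -4))
    r$len <- as.integer(r$len %/% 2)
    ab[[length(ab) + 1L]] <- r
  }

  # decoys: weak cross-hits between conserved genes far off the diagonal
  n_decoy <- as.integer(round(config$decoy_rate * length(op)))
  if (n_decoy > 0 && length(op) > 20) {
    # anchor coordinates (reference rank, compared position) of every
    # planted relation; a decoy must stay outside the chaining window of
    # all of them so it can only ever form an isolated fragment
    anchor_r <- vapply(c(op, pair$homolog_pairs), function(p)
      match(p$ref_gene, ref_genes$gene_id), integer(1))
    anchor_c <- vapply(c(op, pair$homolog_pairs), function(p)
      match(p$cmp_gene, cmp_genes$gene_id), integer(1))
    refs <- vapply(op, function(p) p$ref_gene, character(1))
    cmps <- vapply(op, function(p) p$cmp_gene, character(1))
    for (d in seq_len(n_decoy)) {
      for (try in 1:80) {
        rg <- refs[sample.int(length(refs), 1)]
        cg <- cmps[sample.int(length(cmps), 1)]
        ri <- match(rg, ref_genes$gene_id)
        cj <- match(cg, cmp_genes$gene_id)
        clear <- all(abs(anchor_r - ri) > 4 | abs(anchor_c - cj) > 4)
        if (clear) {
          ab[[length(ab) + 1L]] <- hit_row(rg, cg, plen_ref[[rg]],
                                           plen_cmp[[cg]],
                                           10^runif(1, lo_d, hi_d))
          anchor_r <- c(anchor_r, ri)
          anchor_c <- c(anchor_c, cj)
          break
        }
      }
    }
  }

  # rows above the storage threshold (never stored)
  for (d in seq_len(config$n_suprathreshold)) {
    i <- sample.int(length(op), 1)
    j <- sample.int(length(op), 1)
    ab[[length(ab) + 1L]] <- hit_row(
      op[[i]]$ref_gene, op[[j]]$cmp_gene,
      plen_ref[[op[[i]]$ref_gene]], plen_cmp[[op[[j]]$cmp_gene]],
      round(runif(1, 0.02, 5), 3))
  }
  list(ab = do.call(rbind, ab), ba = do.call(rbind, ba))
}

write_hit_table <- function(hits, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(hits) && nrow(hits)) {
    lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3e\t%.1f",
                     hits$q, hits$s, hits$pid, hits$len, hits$mism,
                     hits$gapo, hits$qs, hits$qe, hits$ss, hits$se,
                     hits$ev, hits$bits)
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

write_genbank <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  for (rep_id in unique(genes$replicon_id)) {
    g <- genes[genes$replicon_id == rep_id, , drop = FALSE]
    rep_len <- max(g$end) + 50L
    wl(sprintf("LOCUS       %s %d bp    DNA     circular BCT 01-JAN-2024",
               rep_id, rep_len))
    wl(sprintf("DEFINITION  synthetic genome %s, %s.", g$genome_id[1], rep_id))
    wl("FEATURES             Location/Qualifiers")
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i], g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      wl(sprintf("     %-16s%s", "CDS", loc))
      q <- function(name, value) wl(sprintf('                     /%s="%s"',
                                            name, value))
      q("locus_tag", g$gene_id[i])
      q("product", g$product[i])
      for (go in split_set(g$go_mf[i])) q("GO_function", go)
      for (go in split_set(g$go_bp[i])) q("GO_process", go)
      for (go in split_set(g$go_cc[i])) q("GO_component", go)
      for (ec in split_set(g$ec_numbers[i])) q("EC_number", ec)
      for (xr in split_set(g$xrefs[i])) q("db_xref", xr)
      aa <- paste(sample(AA20, g$plen[i], replace = TRUE), collapse = "")
      chunks <- substring(aa, seq(1, nchar(aa), 48),
                          pmin(seq(1, nchar(aa), 48) + 47, nchar(aa)))
      chunks[length(chunks)] <- paste0(chunks[length(chunks)], '"')
      wl(sprintf('                     /translation="%s', chunks[1]))
      for (ch in chunks[-1])
        wl(sprintf("                     %s", ch))
    }
    wl("//")
  }
  invisible(path)
}

#' The bundled miniature comparison
#'
#' Generates (deterministically, seed 42) the small worked dataset used in
#' the documentation and smoke tests: two genomes of ~30 ancestral genes
#' with one inversion, one reference-specific island and one segmental
#' duplication. A pre-generated copy of the same bytes ships under
#' `inst/extdata/toy/`.
#'
#' @param out_dir where to generate; default a session temporary directory.
#' @return the [simulate_genomes()] result list.
#' @export
worked_toy <- function(out_dir = file.path(tempdir(), "pansynt_toy")) {
  simulate_genomes(toy_config(), out_dir)
}

toy_config <- function() {
  sim_config(seed = 42L, n_genomes = 2L, genes_per_genome = 30L,
             n_inversions = 1L, inversion_size = 6L,
             n_duplications = 1L, duplication_size = 3L,
             n_ref_islands = 1L, island_size = 5L)
}
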