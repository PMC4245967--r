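# Collinear synteny block detection by dynamic programming over gene orders.
#
# Chains are sequences of anchors (homologous gene pairs) whose ranks
# strictly increase on the reference and strictly increase (forward) or
# decrease (reversed) on the compared genome. Genes skipped between
# consecutive anchors are penalized with an affine gap model, and skipped
# genes facing each other may instead be paired up as mismatch columns when
# that is cheaper. Chains start and end on anchors. The highest scoring
# chain is extracted, its anchors are masked, and extraction repeats until
# no chain reaches the score threshold.

#' Synteny scoring parameters
#'
#' Defaults are the classical gene-order alignment scores for bacterial
#' pairwise synteny: ortholog +4, other homolog +2, mismatch -4, gap
#' creation -8, gap extension -2, with any chain of at least one anchor and
#' score at least 2 reported.
#'
#' @param ortholog_score score for aligning a BDBH ortholog pair.
#' @param homolog_score score for aligning a non-BDBH homolog pair.
#' @param mismatch_score score for aligning two unrelated genes.
#' @param gap_open cost of creating a gap (covers the first skipped gene
#'   under the default `gap_model`).
#' @param gap_extend cost per additional skipped gene.
#' @param min_anchor_count minimum number of anchors for a reported chain.
#' @param min_score minimum chain score.
#' @param max_gap maximum number of genes that may be skipped on either
#'   genome between two consecutive anchors of a chain. Small gaps are
#'   allowed within a conserved synteny; a longer run of unrelated genes
#'   breaks the chain and becomes a genome-specific region.
#' @param gap_model `"open_covers_first"` (a k-gene gap costs
#'   `gap_open + (k-1) * gap_extend`) or `"open_plus_per_gene"`
#'   (`gap_open + k * gap_extend`).
#' @return a `synteny_params` list.
#' @export
synteny_params <- function(ortholog_score = 4, homolog_score = 2,
                           mismatch_score = -4, gap_open = -8,
                           gap_extend = -2, min_anchor_count = 1,
                           min_score = 2, max_gap = 2,
                           gap_model = c("open_covers_first",
                                         "open_plus_per_gene")) {
  gap_model <- match.arg(gap_model)
  if (!(ortholog_score >= homolog_score && homolog_score > 0))
    ps_validation_error("require ortholog_score >= homolog_score > 0")
  if (!(mismatch_score < 0 && gap_open < 0 && gap_extend < 0))
    ps_validation_error("mismatch_score, gap_open and gap_extend must be < 0")
  if (!is_count(min_anchor_count) || min_anchor_count < 1)
    ps_validation_error("min_anchor_count must be >= 1")
  if (!is_count(max_gap))
    ps_validation_error("max_gap must be a non-negative integer")
  structure(list(
    ortholog_score = ortholog_score, homolog_score = homolog_score,
    mismatch_score = mismatch_score, gap_open = gap_open,
    gap_extend = gap_extend, min_anchor_count = min_anchor_count,
    min_score = min_score, max_gap = max_gap, gap_model = gap_model
  ), class = "synteny_params")
}

# Cost of a maximal run of k skipped genes on one genome.
gap_cost <- function(k, params) {
  if (k == 0) return(0)
  if (params$gap_model == "open_covers_first")
    params$gap_open + (k - 1) * params$gap_extend
  else
    params$gap_open + k * params$gap_extend
}

# Best cost of the inter-anchor stretch with di skipped reference genes and
# dj skipped compared genes: pair up `a` of them as mismatch columns, gap
# the rest. Maximized over a.
transition_cost <- function(di, dj, params) {
  best <- -Inf
  for (a in 0:min(di, dj)) {
    v <- a * params$mismatch_score +
      gap_cost(di - a, params) + gap_cost(dj - a, params)
    if (v > best) best <- v
  }
  best
}

anchor_score <- function(kind, params) {
  ifelse(kind == "ortholog", params$ortholog_score, params$homolog_score)
}

#' Score an explicit synteny chain
#'
#' Scores a chain given as its aligned columns: anchors (ortholog/homolog
#' pairs) and mismatch columns, in order. Genes skipped between consecutive
#' columns are inferred from the rank jumps and charged as affine gaps (a
#' maximal run of k skipped genes costs `gap_open + (k-1) * gap_extend`
#' under the default gap model).
#'
#' @param chain data.frame with columns `ref_rank`, `cmp_rank` (integer
#'   gene ranks) and `kind` (`"ortholog"`, `"homolog"` or `"mismatch"`).
#' @param params a [synteny_params].
#' @return integer chain score.
#' @export
chain_score <- function(chain, params = synteny_params()) {
  if (!is.data.frame(chain) || nrow(chain) == 0)
    ps_validation_error("chain must be a non-empty data.frame")
  kinds <- as.character(chain$kind)
  if (!all(kinds %in% c("ortholog", "homolog", "mismatch")))
    ps_validation_error("chain kinds must be ortholog/homolog/mismatch")
  if (kinds[1] == "mismatch" || kinds[length(kinds)] == "mismatch")
    ps_abort("chain is not terminally anchored (ends on a mismatch)",
             class = "pansynt_contract_error")
  ri <- as.integer(chain$ref_rank)
  cj <- as.integer(chain$cmp_rank)
  n <- length(ri)
  if (n > 1) {
    if (any(diff(ri) <= 0))
      ps_abort("chain is not collinear: reference ranks must strictly increase",
               class = "pansynt_contract_error")
    dj <- diff(cj)
    if (!(all(dj > 0) || all(dj < 0)))
      ps_abort("chain is not collinear: compared ranks must be strictly monotone",
               class = "pansynt_contract_error")
  }
  col_scores <- ifelse(kinds == "mismatch", params$mismatch_score,
                       anchor_score(kinds, params))
  s <- sum(col_scores)
  if (n > 1) {
    for (t in seq_len(n - 1)) {
      s <- s + gap_cost(ri[t + 1] - ri[t] - 1L, params) +
        gap_cost(abs(cj[t + 1] - cj[t]) - 1L, params)
    }
  }
  s
}

# ---------------------------------------------------------------------------
# Anchor-chaining DP with iterative masking (one replicon pair, one
# orientation). Anchors: data.frame(ri, cj, kind, score) in local indices
# with both ri and cj increasing along a valid chain (the caller flips cj
# for the reversed orientation). Returns a list of chains, each
# list(anchor_idx, score), best first.
extract_chains <- function(anchors, params) {
  chains <- list()
  if (nrow(anchors) == 0) return(chains)
  G <- outer(0:params$max_gap, 0:params$max_gap,
             Vectorize(function(di, dj) transition_cost(di, dj, params)))
  active <- rep(TRUE, nrow(anchors))
  o <- order(anchors$ri, anchors$cj)
  anchors <- anchors[o, , drop = FALSE]
  orig_idx <- o
  key <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(anchors)))
    assign(sprintf("%d,%d", anchors$ri[k], anchors$cj[k]), k, envir = key)

  repeat {
    n <- nrow(anchors)
    dp <- rep(-Inf, n)
    ptr <- rep(0L, n)
    for (k in seq_len(n)) {
      if (!active[k]) next
      best_prev <- 0
      best_l <- 0L
      # candidate predecessors within the gap window, nearest first
      for (di in 0:params$max_gap) {
        for (dj in 0:params$max_gap) {
          kk <- sprintf("%d,%d", anchors$ri[k] - di - 1L,
                        anchors$cj[k] - dj - 1L)
          l <- get0(kk, envir = key, ifnotfound = 0L)
          if (l == 0L || !active[l]) next
          v <- dp[l] + G[di + 1L, dj + 1L]
          if (v > best_prev) { best_prev <- v; best_l <- l }
        }
      }
      dp[k] <- anchors$score[k] + best_prev
      ptr[k] <- best_l
    }
    if (all(dp == -Inf)) break
    best <- which(dp == max(dp))
    best <- best[order(anchors$ri[best], anchors$cj[best])][1]
    if (dp[best] < params$min_score) break
    # traceback
    path <- integer(0)
    k <- best
    while (k != 0L) { path <- c(k, path); k <- ptr[k] }
    active[path] <- FALSE
    if (length(path) >= params$min_anchor_count)
      chains[[length(chains) + 1L]] <-
        list(anchor_idx = orig_idx[path], score = dp[best])
    if (!any(active)) break
  }
  chains
}

replicon_gene_view <- function(catalog, replicon_id) {
  g <- catalog$genes[catalog$genes$replicon_id == replicon_id, , drop = FALSE]
  g <- g[order(g$rank), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Orient a relation table so gene_a lives in `ref` and gene_b in `cmp`.
orient_relations <- function(relations, ref, cmp) {
  if (nrow(relations) == 0) return(relations)
  a_in_ref <- relations$gene_a %in% ref$genes$gene_id
  b_in_ref <- relations$gene_b %in% ref$genes$gene_id
  a_in_cmp <- relations$gene_a %in% cmp$genes$gene_id
  b_in_cmp <- relations$gene_b %in% cmp$genes$gene_id
  ok_fwd <- a_in_ref & b_in_cmp
  ok_rev <- a_in_cmp & b_in_ref
  if (any(!(ok_fwd | ok_rev)))
    ps_abort("relations reference genes outside the two catalogs")
  out <- relations
  if (any(ok_rev)) {
    out$gene_a[ok_rev] <- relations$gene_b[ok_rev]
    out$gene_b[ok_rev] <- relations$gene_a[ok_rev]
  }
  out[, c("gene_a", "gene_b", "kind")]
}

#' Compute synteny blocks between two genomes
#'
#' Runs the chaining dynamic programming per replicon pair and per
#' orientation (the compared gene order as-is, and reversed), extracts
#' successive non-overlapping best chains by iterative anchor masking, then
#' merges the two orientations: candidate blocks are ranked by score
#' (ties: forward preferred, then smaller reference start), a block whose
#' reference rank interval overlaps an already accepted primary block, or
#' that reuses compared genes claimed by one, is demoted to an offshoot,
#' and fragments wholly inside already-covered territory on both genomes
#' are dropped.
#'
#' @param ref reference [genome_catalog].
#' @param cmp compared [genome_catalog].
#' @param relations relation table from [call_relations()] (or any
#'   data.frame with `gene_a`, `gene_b`, `kind`), either orientation.
#' @param params a [synteny_params].
#' @return data.frame of blocks; `anchors` holds the ordered anchor pairs
#'   as `"ref_gene:cmp_gene:kind"` joined by `";"` (see [block_anchors()]).
#' @export
compute_blocks <- function(ref, cmp, relations, params = synteny_params()) {
  stopifnot(inherits(ref, "genome_catalog"), inherits(cmp, "genome_catalog"))
  if (is.null(relations) || nrow(relations) == 0) return(empty_block_frame())
  rel <- orient_relations(relations, ref, cmp)

  candidates <- list()
  for (rrep in ref$replicons$replicon_id) {
    rg <- replicon_gene_view(ref, rrep)
    if (nrow(rg) == 0) next
    for (crep in cmp$replicons$replicon_id) {
      cg <- replicon_gene_view(cmp, crep)
      if (nrow(cg) == 0) next
      ridx <- match(rel$gene_a, rg$gene_id)
      cidx <- match(rel$gene_b, cg$gene_id)
      keep <- !is.na(ridx) & !is.na(cidx)
      if (!any(keep)) next
      anc <- data.frame(ri = ridx[keep], cj = cidx[keep],
                        kind = rel$kind[keep], stringsAsFactors = FALSE)
      anc <- anc[!duplicated(paste(anc$ri, anc$cj)), , drop = FALSE]
      anc$score <- anchor_score(anc$kind, params)
      m <- nrow(cg)
      for (orientation in c("forward", "reversed")) {
        a2 <- anc
        if (orientation == "reversed") a2$cj <- m + 1L - a2$cj
        chains <- extract_chains(a2, params)
        for (ch in chains) {
          rows <- anc[ch$anchor_idx, , drop = FALSE]
          # order anchors along the reference
          rows <- rows[order(rows$ri), , drop = FALSE]
          candidates[[length(candidates) + 1L]] <- list(
            orientation = orientation, score = ch$score,
            ref_replicon = rrep, cmp_replicon = crep,
            ref_gene = rg$gene_id[rows$ri], cmp_gene = cg$gene_id[rows$cj],
            kind = rows$kind,
            ref_rank = rg$rank[rows$ri], cmp_rank = cg$rank[rows$cj],
            ref_start = min(rg$start[rows$ri]), ref_end = max(rg$end[rows$ri]),
            cmp_start = min(cg$start[rows$cj]), cmp_end = max(cg$end[rows$cj])
          )
        }
      }
    }
  }
  if (length(candidates) == 0) return(empty_block_frame())

  # merge orientations / resolve overlaps
  sc <- vapply(candidates, `[[`, numeric(1), "score")
  fw <- vapply(candidates, function(x) x$orientation == "forward", logical(1))
  rs <- vapply(candidates, `[[`, numeric(1), "ref_start")
  cs <- vapply(candidates, `[[`, numeric(1), "cmp_start")
  ord <- order(-sc, !fw, rs, cs)

  prim_ref_iv <- list()   # per accepted block: c(replicon=..., lo, hi) on ref ranks
  prim_cmp_iv <- list()
  cov_ref_iv <- list()    # primary + offshoot coverage, for the discard rule
  cov_cmp_iv <- list()
  claimed_cmp <- character(0)
  out <- list()

  overlaps <- function(ivs, replicon, lo, hi) {
    for (iv in ivs)
      if (iv$replicon == replicon && lo <= iv$hi && hi >= iv$lo) return(TRUE)
    FALSE
  }
  covered_all <- function(ivs, replicon, ranks) {
    all(vapply(ranks, function(r) overlaps(ivs, replicon, r, r), logical(1)))
  }

  for (i in ord) {
    cand <- candidates[[i]]
    lo_r <- min(cand$ref_rank); hi_r <- max(cand$ref_rank)
    lo_c <- min(cand$cmp_rank); hi_c <- max(cand$cmp_rank)
    ref_clash <- overlaps(prim_ref_iv, cand$ref_replicon, lo_r, hi_r)
    cmp_clash <- any(cand$cmp_gene %in% claimed_cmp)
    if (!ref_clash && !cmp_clash) {
      is_off <- FALSE
      prim_ref_iv[[length(prim_ref_iv) + 1L]] <-
        list(replicon = cand$ref_replicon, lo = lo_r, hi = hi_r)
      prim_cmp_iv[[length(prim_cmp_iv) + 1L]] <-
        list(replicon = cand$cmp_replicon, lo = lo_c, hi = hi_c)
      claimed_cmp <- c(claimed_cmp, cand$cmp_gene)
    } else {
      ref_redundant <- covered_all(cov_ref_iv, cand$ref_replicon, cand$ref_rank)
      cmp_redundant <- covered_all(cov_cmp_iv, cand$cmp_replicon, cand$cmp_rank)
      if (ref_redundant && cmp_redundant) next   # fragment of accepted blocks
      is_off <- TRUE
    }
    cov_ref_iv[[length(cov_ref_iv) + 1L]] <-
      list(replicon = cand$ref_replicon, lo = lo_r, hi = hi_r)
    cov_cmp_iv[[length(cov_cmp_iv) + 1L]] <-
      list(replicon = cand$cmp_replicon, lo = lo_c, hi = hi_c)
    cand$is_offshoot <- is_off
    out[[length(out) + 1L]] <- cand
  }

  blocks <- do.call(rbind, lapply(out, function(b) data.frame(
    ref_genome_id = ref$genome_id, cmp_genome_id = cmp$genome_id,
    orientation = b$orientation, score = b$score,
    n_anchors = length(b$ref_gene),
    ref_replicon = b$ref_replicon, ref_start = b$ref_start,
    ref_end = b$ref_end, ref_rank_min = min(b$ref_rank),
    ref_rank_max = max(b$ref_rank),
    cmp_replicon = b$cmp_replicon, cmp_start = b$cmp_start,
    cmp_end = b$cmp_end, cmp_rank_min = min(b$cmp_rank),
    cmp_rank_max = max(b$cmp_rank),
    is_offshoot = b$is_offshoot,
    anchors = paste(sprintf("%s:%s:%s", b$ref_gene, b$cmp_gene, b$kind),
                    collapse = ";"),
    stringsAsFactors = FALSE)))
  blocks <- blocks[order(blocks$is_offshoot,
                         match(blocks$ref_replicon, ref$replicons$replicon_id),
                         blocks$ref_start), , drop = FALSE]
  blocks$block_id <- sprintf("B%03d", seq_len(nrow(blocks)))
  rownames(blocks) <- NULL
  blocks[, c("block_id", setdiff(names(blocks), "block_id"))]
}

empty_block_frame <- function() {
  data.frame(block_id = character(0), ref_genome_id = character(0),
             cmp_genome_id = character(0), orientation = character(0),
             score = numeric(0), n_anchors = integer(0),
             ref_replicon = character(0), ref_start = integer(0),
             ref_end = integer(0), ref_rank_min = integer(0),
             ref_rank_max = integer(0), cmp_replicon = character(0),
             cmp_start = integer(0), cmp_end = integer(0),
             cmp_rank_min = integer(0), cmp_rank_max = integer(0),
             is_offshoot = logical(0), anchors = character(0),
             stringsAsFactors = FALSE)
}

#' Anchor pairs of one synteny block
#'
#' @param blocks block data.frame from [compute_blocks()].
#' @param i row index (or block id).
#' @return data.frame(ref_gene_id, cmp_gene_id, kind), in reference order.
#' @export
block_anchors <- function(blocks, i = 1L) {
  if (is.character(i)) i <- match(i, blocks$block_id)
  parts <- strsplit(strsplit(blocks$anchors[i], ";", fixed = TRUE)[[1]],
                    ":", fixed = TRUE)
  data.frame(ref_gene_id = vapply(parts, `[`, character(1), 1),
             cmp_gene_id = vapply(parts, `[`, character(1), 2),
             kind = vapply(parts, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Write / read a synteny block table
#' @param blocks block data.frame.
#' @param path file path.
#' @return `path` (write) or the block data.frame (read).
#' @export
write_blocks <- function(blocks, path) {
  tmpl <- empty_block_frame()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#pansynt-blocks v1"), con, sep = "\n")
  writeLines(paste0("#", paste(names(tmpl), collapse = "\t")), con, sep = "\n")
  if (nrow(blocks)) {
    body <- do.call(paste, c(lapply(names(tmpl), function(cn) blocks[[cn]]),
                             sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tmpl <- empty_block_frame()
  if (length(lines) < 2 || lines[1] != "#pansynt-blocks v1")
    ps_abort(sprintf("%s is not a pansynt block table", path),
             class = "pansynt_parse_error")
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0) return(tmpl)
  m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  bl <- data.frame(m, stringsAsFactors = FALSE)
  names(bl) <- names(tmpl)
  for (cn in names(tmpl)) {
    if (is.numeric(tmpl[[cn]])) bl[[cn]] <- as.numeric(bl[[cn]])
    if (is.integer(tmpl[[cn]])) bl[[cn]] <- as.integer(bl[[cn]])
    if (is.logical(tmpl[[cn]])) bl[[cn]] <- as.logical(bl[[cn]])
  }
  bl
}
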