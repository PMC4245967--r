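# Segmentation of a pairwise comparison into the chain of annotation
# events: synteny blocks alternating with genome-specific regions.

new_event <- function(kind, ...) {
  ev <- list(kind = kind, ...)
  ev
}

#' Segment a pairwise comparison into annotation events
#'
#' Orders the primary (non-offshoot) synteny blocks along the reference
#' genome and fills the space between them: maximal reference regions not
#' covered by any primary block become `ref_specific` events (carrying the
#' genes they contain, or no gene at all for a bare intergenic region
#' between two blocks), and maximal compared-genome regions not covered by
#' any block become `cmp_specific` events attached to their nearest
#' flanking block on the compared genome (leftmost flank; regions at a
#' replicon end attach to the terminal block there). The reference gene
#' sets of synteny and `ref_specific` events partition the reference gene
#' catalog.
#'
#' @param ref reference [genome_catalog].
#' @param cmp compared [genome_catalog].
#' @param blocks block table from [compute_blocks()].
#' @return an `annotation_events` object: a list of events, each with
#'   `kind` (`synteny`/`ref_specific`/`cmp_specific`), `ordinal`, spans and
#'   gene ids; `cmp_specific` events carry `attaches_to` (the ordinal of
#'   the event they surround).
#' @export
segment_events <- function(ref, cmp, blocks) {
  prim <- blocks[!blocks$is_offshoot, , drop = FALSE]
  # sanity: primary blocks must be interval-disjoint on the reference
  if (nrow(prim) > 1) {
    for (rrep in unique(prim$ref_replicon)) {
      p <- prim[prim$ref_replicon == rrep, , drop = FALSE]
      p <- p[order(p$ref_rank_min), , drop = FALSE]
      if (any(p$ref_rank_min[-1] <= head(p$ref_rank_max, -1)))
        ps_abort("internal error: overlapping primary blocks",
                 class = "pansynt_internal_error")
    }
  }

  chain <- list()
  block_event <- integer(0)  # block_id -> index into chain
  for (rrep in ref$replicons$replicon_id) {
    rg <- replicon_gene_view(ref, rrep)
    rep_len <- ref$replicons$length_bp[
      match(rrep, ref$replicons$replicon_id)]
    p <- prim[prim$ref_replicon == rrep, , drop = FALSE]
    p <- p[order(p$ref_rank_min), , drop = FALSE]
    prev_end_bp <- 0L
    prev_rank_max <- -1L
    prev_was_block <- FALSE
    for (bi in seq_len(nrow(p))) {
      b <- p[bi, ]
      gap_genes <- rg$gene_id[rg$rank > prev_rank_max & rg$rank < b$ref_rank_min]
      gap_lo <- prev_end_bp + 1L
      gap_hi <- b$ref_start - 1L
      if (length(gap_genes) > 0 || (prev_was_block && gap_hi >= gap_lo)) {
        chain[[length(chain) + 1L]] <- new_event(
          "ref_specific", ref_replicon = rrep,
          ref_start = gap_lo, ref_end = max(gap_hi, gap_lo - 1L),
          ref_genes = gap_genes)
      }
      chain[[length(chain) + 1L]] <- new_event(
        "synteny", block_id = b$block_id, orientation = b$orientation,
        score = b$score, n_anchors = b$n_anchors,
        ref_replicon = rrep, ref_start = b$ref_start, ref_end = b$ref_end,
        ref_genes = rg$gene_id[rg$rank >= b$ref_rank_min &
                               rg$rank <= b$ref_rank_max],
        cmp_replicon = b$cmp_replicon, cmp_start = b$cmp_start,
        cmp_end = b$cmp_end)
      block_event[b$block_id] <- length(chain)
      prev_end_bp <- b$ref_end
      prev_rank_max <- b$ref_rank_max
      prev_was_block <- TRUE
    }
    trailing <- rg$gene_id[rg$rank > prev_rank_max]
    if (length(trailing) > 0) {
      chain[[length(chain) + 1L]] <- new_event(
        "ref_specific", ref_replicon = rrep,
        ref_start = prev_end_bp + 1L, ref_end = rep_len,
        ref_genes = trailing)
    }
  }

  # compared-genome-specific regions: genes covered by no block at all.
  # Flanks are sought over the genome-wide gene order (replicons
  # concatenate), but an event never spans a replicon boundary.
  ins <- list()  # list of (after_chain_index, event)
  cg <- cmp$genes[order(cmp$genes$rank), , drop = FALSE]
  if (nrow(cg) > 0) {
    covered <- rep(FALSE, nrow(cg))
    cover_block <- rep(NA_character_, nrow(cg))
    for (bi in seq_len(nrow(blocks))) {
      sel <- cg$replicon_id == blocks$cmp_replicon[bi] &
        cg$rank >= blocks$cmp_rank_min[bi] &
        cg$rank <= blocks$cmp_rank_max[bi]
      covered[sel] <- TRUE
      cover_block[sel & is.na(cover_block)] <- blocks$block_id[bi]
    }
    left_block <- rep(NA_character_, nrow(cg))
    cur <- NA_character_
    for (gi in seq_len(nrow(cg))) {
      if (!is.na(cover_block[gi])) cur <- cover_block[gi]
      left_block[gi] <- cur
    }
    runs <- rle(paste(covered, cg$replicon_id))
    pos <- cumsum(c(1L, head(runs$lengths, -1)))
    for (ri in seq_along(runs$values)) {
      i0 <- pos[ri]
      if (covered[i0]) next
      i1 <- i0 + runs$lengths[ri] - 1L
      flank <- left_block[i0]
      if (is.na(flank)) {
        # run precedes every block: attach to the first block to the right
        right <- cover_block[which(!is.na(cover_block) &
                                     seq_len(nrow(cg)) > i1)]
        flank <- if (length(right)) right[1] else NA_character_
      }
      ev <- new_event(
        "cmp_specific", cmp_replicon = cg$replicon_id[i0],
        cmp_start = min(cg$start[i0:i1]), cmp_end = max(cg$end[i0:i1]),
        cmp_genes = cg$gene_id[i0:i1],
        attached_block = flank)
      after <- if (!is.na(flank) && flank %in% names(block_event))
        block_event[[flank]] else length(chain)
      ins[[length(ins) + 1L]] <- list(after = after, event = ev)
    }
  }

  # splice cmp_specific events in right after the event they attach to
  if (length(ins)) {
    ins <- ins[order(vapply(ins, `[[`, numeric(1), "after"),
                     vapply(ins, function(x) x$event$cmp_start, numeric(1)))]
    out <- list()
    for (i in seq_along(chain)) {
      out[[length(out) + 1L]] <- chain[[i]]
      for (x in ins)
        if (x$after == i) out[[length(out) + 1L]] <- x$event
    }
    for (x in ins)
      if (x$after == 0) out[[length(out) + 1L]] <- x$event
    chain <- out
  }

  for (i in seq_along(chain)) chain[[i]]$ordinal <- i
  # resolve attached_block into the ordinal of its event
  ord_of_block <- setNames(
    vapply(seq_along(chain),
           function(i) chain[[i]]$block_id %||% NA_character_, character(1)),
    seq_along(chain))
  for (i in seq_along(chain)) {
    if (chain[[i]]$kind == "cmp_specific") {
      ab <- chain[[i]]$attached_block
      chain[[i]]$attaches_to <- if (!is.na(ab))
        as.integer(names(ord_of_block)[match(ab, ord_of_block)])
      else NA_integer_
    }
  }

  structure(chain,
            class = "annotation_events",
            ref_genome_id = ref$genome_id,
            cmp_genome_id = cmp$genome_id)
}

#' @export
print.annotation_events <- function(x, ...) {
  cat(sprintf("<annotation_events> %s vs %s: %d event(s)\n",
              attr(x, "ref_genome_id"), attr(x, "cmp_genome_id"), length(x)))
  for (ev in x) {
    desc <- switch(ev$kind,
      synteny = sprintf("block %s (%s, score %g, %d anchors)",
                        ev$block_id, ev$orientation, ev$score, ev$n_anchors),
      ref_specific = sprintf("%d reference-specific gene(s)",
                             length(ev$ref_genes)),
      cmp_specific = sprintf("%d compared-specific gene(s), attached to #%s",
                             length(ev$cmp_genes), ev$attaches_to))
    cat(sprintf("  %2d %-12s %s\n", ev$ordinal, ev$kind, desc))
  }
  invisible(x)
}

#' Summarize an event chain as a data.frame
#' @param x an `annotation_events` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return one row per event.
#' @export
as.data.frame.annotation_events <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  do.call(rbind, lapply(x, function(ev) data.frame(
    ordinal = ev$ordinal, kind = ev$kind,
    ref_replicon = ev$ref_replicon %||% NA_character_,
    ref_start = ev$ref_start %||% NA_integer_,
    ref_end = ev$ref_end %||% NA_integer_,
    n_ref_genes = length(ev$ref_genes %||% character(0)),
    cmp_replicon = ev$cmp_replicon %||% NA_character_,
    cmp_start = ev$cmp_start %||% NA_integer_,
    cmp_end = ev$cmp_end %||% NA_integer_,
    n_cmp_genes = length(ev$cmp_genes %||% character(0)),
    block_id = ev$block_id %||% NA_character_,
    attaches_to = ev$attaches_to %||% NA_integer_,
    stringsAsFactors = FALSE)))
}

#' Write an event chain to JSON
#'
#' Ordered JSON array (schema `pansynt-events v1`), one object per event.
#' @param events an `annotation_events` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  payload <- list(
    schema = "pansynt-events v1",
    ref_genome_id = attr(events, "ref_genome_id"),
    cmp_genome_id = attr(events, "cmp_genome_id"),
    events = lapply(events, function(ev) {
      ev$ref_genes <- as.list(ev$ref_genes %||% character(0))
      ev$cmp_genes <- as.list(ev$cmp_genes %||% character(0))
      ev
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
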