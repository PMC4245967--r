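# Static rendering of one pairwise comparison: the symbolic event chain on
# top of a proportional dual-track (trapezoid) view, written as SVG.

GLYPH_KINDS <- c(synteny_forward = "glyph-synteny",
                 synteny_reversed = "glyph-bowtie",
                 ref_specific_empty = "glyph-empty-region",
                 ref_specific_genes = "glyph-gene-region",
                 cmp_specific = "glyph-cmp-region")

#' Build the layout model of an event chain
#'
#' Symbols are laid out left to right in reference-start order, one per
#' event: a rectangle for a forward synteny block, a bowtie for a reversed
#' one, a line for an empty reference-specific region, a rectangle for a
#' gene-bearing one; compared-genome-specific regions are drawn at half
#' size below the symbol they attach to. The proportional tracks map base
#' pair coordinates affinely onto the drawing width (replicon offsets
#' concatenate multi-replicon genomes), and every synteny symbol gets a
#' trapezoid joining its reference and compared spans plus a triangular
#' position marker.
#'
#' @param events an `annotation_events` chain from [segment_events()].
#' @param ref,cmp the two [genome_catalog]s (for track extents).
#' @param window optional `c(start, end)` reference bp range: the tracks
#'   are clipped to it and symbols wholly outside are dropped.
#' @return a `layout_model` list: `symbols` data.frame (ordinal, glyph,
#'   slot, spans), `tracks`, `trapezoids`.
#' @export
build_layout <- function(events, ref, cmp, window = NULL) {
  genome_bp <- function(cat, replicon, pos) {
    off <- cat$replicons$offset_bp[match(replicon, cat$replicons$replicon_id)]
    off + pos
  }
  symbols <- list()
  for (ev in events) {
    glyph <- switch(ev$kind,
      synteny = if (ev$orientation == "reversed")
        GLYPH_KINDS[["synteny_reversed"]] else GLYPH_KINDS[["synteny_forward"]],
      ref_specific = if (length(ev$ref_genes) == 0)
        GLYPH_KINDS[["ref_specific_empty"]] else GLYPH_KINDS[["ref_specific_genes"]],
      cmp_specific = GLYPH_KINDS[["cmp_specific"]])
    sym <- data.frame(
      ordinal = ev$ordinal, kind = ev$kind, glyph = glyph,
      ref_start = NA_real_, ref_end = NA_real_,
      cmp_start = NA_real_, cmp_end = NA_real_,
      attaches_to = ev$attaches_to %||% NA_integer_,
      stringsAsFactors = FALSE)
    if (!is.null(ev$ref_start)) {
      sym$ref_start <- genome_bp(ref, ev$ref_replicon, ev$ref_start)
      sym$ref_end <- genome_bp(ref, ev$ref_replicon, ev$ref_end)
    }
    if (!is.null(ev$cmp_start)) {
      sym$cmp_start <- genome_bp(cmp, ev$cmp_replicon, ev$cmp_start)
      sym$cmp_end <- genome_bp(cmp, ev$cmp_replicon, ev$cmp_end)
    }
    symbols[[length(symbols) + 1L]] <- sym
  }
  symbols <- if (length(symbols)) do.call(rbind, symbols) else
    data.frame(ordinal = integer(0), kind = character(0),
               glyph = character(0), ref_start = numeric(0),
               ref_end = numeric(0), cmp_start = numeric(0),
               cmp_end = numeric(0), attaches_to = integer(0),
               stringsAsFactors = FALSE)

  ref_lo <- 1; ref_hi <- max(ref$total_bp, 1)
  if (!is.null(window)) {
    ref_lo <- window[1]; ref_hi <- window[2]
    keep <- is.na(symbols$ref_start) |
      (symbols$ref_end >= ref_lo & symbols$ref_start <= ref_hi)
    # cmp-attached symbols survive with their attached event
    kept_ord <- symbols$ordinal[keep]
    keep <- keep & (is.na(symbols$attaches_to) |
                    symbols$attaches_to %in% kept_ord)
    symbols <- symbols[keep, , drop = FALSE]
    symbols$ref_start <- pmax(symbols$ref_start, ref_lo)
    symbols$ref_end <- pmin(symbols$ref_end, ref_hi)
  }
  symbols$slot <- seq_len(nrow(symbols))

  width <- 900; sym_w <- 46
  x_of_ref <- function(bp) 40 + (bp - ref_lo) / max(ref_hi - ref_lo, 1) * (width - 80)
  x_of_cmp <- function(bp) 40 + (bp - 1) / max(cmp$total_bp - 1, 1) * (width - 80)
  symbols$x_sym <- 40 + (symbols$slot - 1) * (sym_w + 8)
  symbols$x_ref_track <- ifelse(is.na(symbols$ref_start), NA,
                                x_of_ref(symbols$ref_start))
  symbols$x_ref_track_end <- ifelse(is.na(symbols$ref_end), NA,
                                    x_of_ref(symbols$ref_end))
  symbols$x_cmp_track <- ifelse(is.na(symbols$cmp_start), NA,
                                x_of_cmp(symbols$cmp_start))
  symbols$x_cmp_track_end <- ifelse(is.na(symbols$cmp_end), NA,
                                    x_of_cmp(symbols$cmp_end))

  trapezoids <- symbols[symbols$kind == "synteny", , drop = FALSE]
  structure(list(symbols = symbols,
                 tracks = list(ref = c(lo = ref_lo, hi = ref_hi,
                                       y = 150),
                               cmp = c(lo = 1, hi = max(cmp$total_bp, 1),
                                       y = 210)),
                 trapezoids = trapezoids,
                 width = width, sym_w = sym_w),
            class = "layout_model")
}

fmt_n <- function(x) sprintf("%.2f", x)

#' Render a layout model to SVG
#'
#' Deterministic SVG 1.1; glyph kinds are exposed as CSS classes
#' (`glyph-synteny`, `glyph-bowtie`, `glyph-empty-region`,
#' `glyph-gene-region`, `glyph-cmp-region`, `trapezoid`, `track-ref`,
#' `track-cmp`, `marker`). Rendering the same model twice produces
#' identical bytes.
#'
#' @param model a `layout_model`.
#' @param path output SVG path.
#' @return `path`, invisibly.
#' @export
render_svg <- function(model, path) {
  s <- model$symbols
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="260" viewBox="0 0 %d 260">',
            model$width, model$width),
    sprintf('<line class="track-ref" x1="40" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            model$tracks$ref[["y"]], model$width - 40, model$tracks$ref[["y"]]),
    sprintf('<line class="track-cmp" x1="40" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            model$tracks$cmp[["y"]], model$width - 40, model$tracks$cmp[["y"]]))
  y0 <- 40; h <- 36; w <- model$sym_w
  for (i in seq_len(nrow(s))) {
    x <- s$x_sym[i]
    g <- s$glyph[i]
    if (g == "glyph-bowtie") {
      out <- c(out, sprintf(
        '<polygon class="%s" points="%s,%s %s,%s %s,%s %s,%s" fill="tan" stroke="black"/>',
        g, fmt_n(x), fmt_n(y0), fmt_n(x + w), fmt_n(y0 + h),
        fmt_n(x + w), fmt_n(y0), fmt_n(x), fmt_n(y0 + h)))
    } else if (g == "glyph-empty-region") {
      out <- c(out, sprintf(
        '<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
        g, fmt_n(x), fmt_n(y0 + h / 2), fmt_n(x + w), fmt_n(y0 + h / 2)))
    } else if (g == "glyph-cmp-region") {
      out <- c(out, sprintf(
        '<rect class="%s" x="%s" y="%s" width="%s" height="%s" fill="lightsteelblue" stroke="black"/>',
        g, fmt_n(x), fmt_n(y0 + h), fmt_n(w / 2), fmt_n(h / 2)))
    } else {
      fill <- if (g == "glyph-synteny") "tan" else "white"
      out <- c(out, sprintf(
        '<rect class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="black"/>',
        g, fmt_n(x), fmt_n(y0), fmt_n(w), fmt_n(h), fill))
    }
    if (!is.na(s$x_ref_track[i]))
      out <- c(out, sprintf(
        '<polygon class="marker" points="%s,%s %s,%s %s,%s" fill="black"/>',
        fmt_n(s$x_ref_track[i] - 3), fmt_n(model$tracks$ref[["y"]] - 6),
        fmt_n(s$x_ref_track[i] + 3), fmt_n(model$tracks$ref[["y"]] - 6),
        fmt_n(s$x_ref_track[i]), fmt_n(model$tracks$ref[["y"]])))
  }
  tz <- model$trapezoids
  for (i in seq_len(nrow(tz))) {
    if (is.na(tz$x_ref_track[i]) || is.na(tz$x_cmp_track[i])) next
    out <- c(out, sprintf(
      '<polygon class="trapezoid" points="%s,%s %s,%s %s,%s %s,%s" fill="tan" fill-opacity="0.5"/>',
      fmt_n(tz$x_ref_track[i]), fmt_n(model$tracks$ref[["y"]]),
      fmt_n(tz$x_ref_track_end[i]), fmt_n(model$tracks$ref[["y"]]),
      fmt_n(tz$x_cmp_track_end[i]), fmt_n(model$tracks$cmp[["y"]]),
      fmt_n(tz$x_cmp_track[i]), fmt_n(model$tracks$cmp[["y"]])))
  }
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
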