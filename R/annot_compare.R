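# Shared / Missing / Unique classification of functional annotations of a
# reference gene against its admitted homologs.

ANNOT_CLASSES <- c(molecular_function = "go_mf",
                   biological_process = "go_bp",
                   cellular_component = "go_cc",
                   ec_number = "ec_numbers")

#' Homolog admission filter for the annotations comparator
#'
#' A homolog relation is admitted iff it passes every set threshold:
#' maximum e-value, minimum percent identity, minimum percent query
#' alignment length (query coverage), and optionally only BDBH orthologs.
#' `NULL` thresholds are inactive.
#'
#' @param max_evalue maximum e-value of the admitted relation.
#' @param min_pct_identity minimum percent identity.
#' @param min_query_coverage_pct minimum query coverage (percent of the
#'   reference protein aligned).
#' @param orthologs_only admit only BDBH ortholog relations.
#' @param genomes optional subset of compared genome ids to consider.
#' @return a `comparator_filter` object.
#' @export
comparator_filter <- function(max_evalue = NULL, min_pct_identity = NULL,
                              min_query_coverage_pct = NULL,
                              orthologs_only = FALSE, genomes = NULL) {
  structure(list(max_evalue = max_evalue,
                 min_pct_identity = min_pct_identity,
                 min_query_coverage_pct = min_query_coverage_pct,
                 orthologs_only = isTRUE(orthologs_only),
                 genomes = genomes),
            class = "comparator_filter")
}

relation_admitted <- function(rel, filter) {
  ok <- rep(TRUE, nrow(rel))
  ev <- ifelse(is.na(rel$evalue_ab), rel$evalue_ba, rel$evalue_ab)
  qc <- ifelse(is.na(rel$query_coverage_ab), rel$query_coverage_ba,
               rel$query_coverage_ab)
  if (!is.null(filter$max_evalue)) ok <- ok & !is.na(ev) & ev <= filter$max_evalue
  if (!is.null(filter$min_pct_identity))
    ok <- ok & !is.na(rel$pct_identity) &
      rel$pct_identity >= filter$min_pct_identity
  if (!is.null(filter$min_query_coverage_pct))
    ok <- ok & !is.na(qc) & qc >= filter$min_query_coverage_pct
  if (filter$orthologs_only) ok <- ok & rel$kind == "ortholog"
  ok
}

gene_class_annots <- function(gene_row, class_col) {
  split_set(gene_row[[class_col]])
}

#' Compare the functional annotations of a gene with its homologs
#'
#' For each annotation class (GO molecular function, GO biological process,
#' GO cellular component, EC number) the annotations are classified into:
#' Shared (present in the reference gene and in at least one admitted
#' homolog), Unique (present in the reference gene but in no admitted
#' homolog) and Missing (absent from the reference gene but present in at
#' least one admitted homolog). Counting is per compared organism: one
#' organism contributes an annotation if any of its admitted homologs
#' carries it, and the reported ratio is organism count over the total
#' number of organisms compared. GO terms without a namespace are ignored,
#' as is the free-text product field.
#'
#' @param ref_gene_id reference gene id.
#' @param relation_sets named list of relation tables per compared genome
#'   (as for [build_profile()]).
#' @param catalogs named list of [genome_catalog]s, including the reference
#'   genome and every compared genome.
#' @param filter a [comparator_filter].
#' @return an `annotation_comparison`: per class, data.frames `shared`,
#'   `missing`, `unique` with columns annotation, n_organisms, organisms,
#'   ratio; plus `organisms_compared`.
#' @export
compare_annotations <- function(ref_gene_id, relation_sets, catalogs,
                                filter = comparator_filter()) {
  ref_cat <- NULL
  for (cat in catalogs)
    if (ref_gene_id %in% cat$genes$gene_id) ref_cat <- cat
  if (is.null(ref_cat))
    ps_abort(sprintf("reference gene '%s' not found in any catalog",
                     ref_gene_id))
  ref_row <- catalog_gene(ref_cat, ref_gene_id)

  genomes <- names(relation_sets)
  if (!is.null(filter$genomes)) genomes <- intersect(genomes, filter$genomes)
  n_org <- length(genomes)

  # admitted homolog gene rows per organism
  homologs <- list()
  for (g in genomes) {
    rel <- relation_sets[[g]]
    if (nrow(rel) == 0) next
    swap <- !(rel$gene_a %in% ref_cat$genes$gene_id)
    if (any(swap)) {
      tmp <- rel$gene_a[swap]
      rel$gene_a[swap] <- rel$gene_b[swap]
      rel$gene_b[swap] <- tmp
    }
    rel <- rel[rel$gene_a == ref_gene_id, , drop = FALSE]
    if (nrow(rel) == 0) next
    rel <- rel[relation_admitted(rel, filter), , drop = FALSE]
    if (nrow(rel) == 0) next
    if (is.null(catalogs[[g]]))
      ps_abort(sprintf("no catalog supplied for compared genome '%s'", g))
    homologs[[g]] <- do.call(rbind, lapply(rel$gene_b, function(gb)
      catalog_gene(catalogs[[g]], gb)))
  }

  result <- list(ref_gene_id = ref_gene_id, organisms_compared = genomes,
                 classes = list())
  for (cls in names(ANNOT_CLASSES)) {
    col <- ANNOT_CLASSES[[cls]]
    ref_annots <- gene_class_annots(ref_row, col)
    org_annots <- lapply(homologs, function(h)
      unique(unlist(lapply(seq_len(nrow(h)), function(i)
        gene_class_annots(h[i, , drop = FALSE], col)))))
    all_hom <- unique(unlist(org_annots))
    tally <- function(annots) {
      if (length(annots) == 0)
        return(data.frame(annotation = character(0), n_organisms = integer(0),
                          organisms = character(0), ratio = numeric(0),
                          stringsAsFactors = FALSE))
      orgs <- lapply(annots, function(a)
        names(org_annots)[vapply(org_annots, function(v) a %in% v, logical(1))])
      data.frame(annotation = annots,
                 n_organisms = lengths(orgs),
                 organisms = vapply(orgs, paste, character(1), collapse = ";"),
                 ratio = if (n_org > 0) lengths(orgs) / n_org else 0,
                 stringsAsFactors = FALSE)
    }
    shared <- sort(intersect(ref_annots, all_hom))
    uniq <- sort(setdiff(ref_annots, all_hom))
    missing <- sort(setdiff(all_hom, ref_annots))
    result$classes[[cls]] <- list(shared = tally(shared),
                                  missing = tally(missing),
                                  unique = tally(uniq))
  }
  structure(result, class = "annotation_comparison")
}

#' @export
print.annotation_comparison <- function(x, ...) {
  cat(sprintf("<annotation_comparison> gene %s vs %d organism(s)\n",
              x$ref_gene_id, length(x$organisms_compared)))
  for (cls in names(x$classes)) {
    c3 <- x$classes[[cls]]
    cat(sprintf("  %-20s shared %d, missing %d, unique %d\n", cls,
                nrow(c3$shared), nrow(c3$missing), nrow(c3$unique)))
  }
  invisible(x)
}

#' Detailed annotation diff between a gene and one homolog
#'
#' For each annotation class: the annotations common to both genes, those
#' only on the reference gene, and those only on the homolog — the
#' green/red similarity report for one homolog — plus the alignment
#' summary of the supporting relation.
#'
#' @param ref_gene_id reference gene id.
#' @param homolog_gene_id the homolog's gene id.
#' @param catalogs named list of [genome_catalog]s covering both genes.
#' @param relation optional one-row relation (for the alignment summary).
#' @return list per class with `common`, `ref_only`, `homolog_only`, plus
#'   `alignment` (e-value, percent identity, query coverage, bit score).
#' @export
diff_detail <- function(ref_gene_id, homolog_gene_id, catalogs,
                        relation = NULL) {
  find_row <- function(id) {
    for (cat in catalogs)
      if (id %in% cat$genes$gene_id) return(catalog_gene(cat, id))
    ps_abort(sprintf("gene '%s' not found in any catalog", id))
  }
  a <- find_row(ref_gene_id)
  b <- find_row(homolog_gene_id)
  out <- list()
  for (cls in names(ANNOT_CLASSES)) {
    col <- ANNOT_CLASSES[[cls]]
    sa <- gene_class_annots(a, col)
    sb <- gene_class_annots(b, col)
    out[[cls]] <- list(common = sort(intersect(sa, sb)),
                       ref_only = sort(setdiff(sa, sb)),
                       homolog_only = sort(setdiff(sb, sa)))
  }
  if (!is.null(relation) && nrow(relation) >= 1) {
    out$alignment <- list(
      evalue = relation$evalue_ab[1],
      pct_identity = relation$pct_identity[1],
      query_coverage = relation$query_coverage_ab[1],
      bitscore = relation$bitscore_ab[1])
  }
  out
}

#' Write an annotation comparison report
#'
#' JSON (nested category/class/annotation/organisms) or flat TSV.
#' @param comparison an `annotation_comparison`.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(comparison), path, auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    rows <- list()
    for (cls in names(comparison$classes))
      for (cat3 in c("shared", "missing", "unique")) {
        df <- comparison$classes[[cls]][[cat3]]
        if (nrow(df))
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(gene = comparison$ref_gene_id, class = cls,
                       category = cat3, stringsAsFactors = FALSE), df)
      }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene = character(0), class = character(0),
                 category = character(0), annotation = character(0),
                 n_organisms = integer(0), organisms = character(0),
                 ratio = numeric(0))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
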