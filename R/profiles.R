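# Gene-by-genome presence profiles, combinable gene filters and
# core/dispensable gene set construction.

#' Build a gene-by-genome presence profile
#'
#' For each reference gene and each compared genome the cell label is
#' `"ortholog"` if a BDBH relation exists, `"homolog_only"` if at least one
#' non-BDBH relation (and no BDBH) exists, and `"absent"` otherwise.
#' Multiple homologies stack in one cell: the supporting relations are kept
#' per cell so that offshoots (duplications/paralogs) can be browsed.
#'
#' @param ref reference [genome_catalog].
#' @param relation_sets named list, one relation table (from
#'   [call_relations()]) per compared genome; names are the compared
#'   genome ids (defaulted from the tables when omitted).
#' @return a `presence_profile`: gene ids in rank order, genome ids in
#'   input order, a label matrix (genes x genomes) and per-cell supporting
#'   relation ids.
#' @export
build_profile <- function(ref, relation_sets) {
  stopifnot(inherits(ref, "genome_catalog"))
  if (is.null(names(relation_sets)) || any(!nzchar(names(relation_sets)))) {
    names(relation_sets) <- vapply(relation_sets, function(rel) {
      other <- setdiff(unique(c(rel$genome_a, rel$genome_b)), ref$genome_id)
      if (length(other) != 1)
        ps_validation_error("cannot infer compared genome id; name the list")
      other
    }, character(1))
  }
  gene_ids <- ref$genes$gene_id
  genomes <- names(relation_sets)
  labels <- matrix("absent", nrow = length(gene_ids), ncol = length(genomes),
                   dimnames = list(gene_ids, genomes))
  support <- list()
  for (g in genomes) {
    rel <- relation_sets[[g]]
    if (nrow(rel) == 0) next
    # orient so gene_a is the reference gene
    swap <- !(rel$gene_a %in% gene_ids)
    if (any(swap)) {
      tmp <- rel$gene_a[swap]
      rel$gene_a[swap] <- rel$gene_b[swap]
      rel$gene_b[swap] <- tmp
    }
    bad <- setdiff(rel$gene_a, gene_ids)
    if (length(bad))
      ps_abort(sprintf(
        "relation references gene '%s' absent from reference genome '%s'",
        bad[1], ref$genome_id))
    for (i in seq_len(nrow(rel))) {
      ga <- rel$gene_a[i]
      cur <- labels[ga, g]
      labels[ga, g] <-
        if (rel$kind[i] == "ortholog" || cur == "ortholog") "ortholog"
        else "homolog_only"
      key <- paste(ga, g, sep = "\r")
      support[[key]] <- c(support[[key]],
                          paste(rel$gene_a[i], rel$gene_b[i], sep = "--"))
    }
  }
  structure(list(ref_genome_id = ref$genome_id, gene_ids = gene_ids,
                 genome_ids = genomes, labels = labels, support = support),
            class = "presence_profile")
}

#' @export
print.presence_profile <- function(x, ...) {
  cat(sprintf("<presence_profile> %s: %d gene(s) x %d compared genome(s)\n",
              x$ref_genome_id, length(x$gene_ids), length(x$genome_ids)))
  invisible(x)
}

#' Supporting relations for one profile cell
#' @param profile a `presence_profile`.
#' @param gene_id reference gene.
#' @param genome_id compared genome.
#' @return character vector of relation ids (`"geneA--geneB"`).
#' @export
cell_support <- function(profile, gene_id, genome_id) {
  profile$support[[paste(gene_id, genome_id, sep = "\r")]] %||% character(0)
}

label_satisfies <- function(label, predicate) {
  if (predicate == "ortholog") label == "ortholog"
  else label %in% c("ortholog", "homolog_only")   # any_homolog
}

# ---------------------------------------------------------------------------
# Gene filters: leaf predicates over the catalog/profile, combined with
# AND (intersection) / OR (union) nodes.

#' Gene filters
#'
#' Constructors for the filter algebra used by [apply_filter()]. Leaf
#' filters select reference genes by location, identifier, annotation text,
#' GO term, EC number, cross-reference, or by the presence/absence of
#' homologs in a set of compared genomes; `filter_and()` / `filter_or()`
#' combine any number of filters (intersection / union). An `filter_and()`
#' with no children selects every reference gene; an empty `filter_or()`
#' selects none.
#'
#' `flt_presence()` keeps genes whose profile label satisfies `predicate`
#' in every listed genome; `flt_absence()` keeps genes for which it fails
#' in every listed genome ("and/or" questions are expressed by combining
#' single-genome filters with `filter_or()`).
#'
#' @param replicon_id,start,end genomic window (leaf `location`).
#' @param pattern regular expression (leaves `name_or_id`,
#'   `annotation_text`, `domain_motif`; the latter two match the product
#'   and free-text annotation fields).
#' @param terms GO identifiers (leaf `go_term`); any namespace.
#' @param numbers EC numbers (leaf `ec_number`).
#' @param refs cross-reference strings (leaf `xref`).
#' @param genomes compared genome ids (leaves `presence` / `absence`).
#' @param predicate `"ortholog"` (BDBH only) or `"any_homolog"`.
#' @param ... child filters for the combinators.
#' @return a `gene_filter` object.
#' @name gene_filters
NULL

new_filter <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "gene_filter")
}

#' @rdname gene_filters
#' @export
flt_location <- function(replicon_id, start = 1L, end = .Machine$integer.max)
  new_filter("location", replicon_id = replicon_id,
             start = as.integer(start), end = as.integer(end))

#' @rdname gene_filters
#' @export
flt_name <- function(pattern) new_filter("name_or_id", pattern = pattern)

#' @rdname gene_filters
#' @export
flt_annotation_text <- function(pattern)
  new_filter("annotation_text", pattern = pattern)

#' @rdname gene_filters
#' @export
flt_domain_motif <- function(pattern)
  new_filter("domain_motif", pattern = pattern)

#' @rdname gene_filters
#' @export
flt_go <- function(terms) {
  bad <- terms[!grepl("^GO:\\d+$", terms)]
  if (length(bad))
    ps_abort(sprintf("malformed GO identifier: '%s'", bad[1]),
             class = "pansynt_validation_error")
  new_filter("go_term", terms = terms)
}

#' @rdname gene_filters
#' @export
flt_ec <- function(numbers) {
  bad <- numbers[!grepl("^[0-9]+(\\.([0-9]+|-)){0,3}$", numbers)]
  if (length(bad))
    ps_abort(sprintf("malformed EC number: '%s'", bad[1]),
             class = "pansynt_validation_error")
  new_filter("ec_number", numbers = numbers)
}

#' @rdname gene_filters
#' @export
flt_xref <- function(refs) new_filter("xref", refs = refs)

#' @rdname gene_filters
#' @export
flt_presence <- function(genomes, predicate = c("ortholog", "any_homolog"))
  new_filter("presence", genomes = genomes, predicate = match.arg(predicate))

#' @rdname gene_filters
#' @export
flt_absence <- function(genomes, predicate = c("ortholog", "any_homolog"))
  new_filter("absence", genomes = genomes, predicate = match.arg(predicate))

#' @rdname gene_filters
#' @export
filter_and <- function(...) new_filter("and", children = list(...))

#' @rdname gene_filters
#' @export
filter_or <- function(...) new_filter("or", children = list(...))

gene_annotation_blob <- function(genes) {
  paste(genes$product, genes$xrefs, genes$ec_numbers, sep = " ")
}

eval_filter <- function(filter, profile, catalog) {
  g <- catalog$genes
  all_ids <- g$gene_id
  switch(filter$kind,
    and = {
      res <- all_ids
      for (child in filter$children)
        res <- intersect(res, eval_filter(child, profile, catalog))
      res
    },
    or = {
      res <- character(0)
      for (child in filter$children)
        res <- union(res, eval_filter(child, profile, catalog))
      res
    },
    location = all_ids[g$replicon_id == filter$replicon_id &
                       g$end >= filter$start & g$start <= filter$end],
    name_or_id = all_ids[grepl(filter$pattern, g$gene_id)],
    annotation_text = all_ids[grepl(filter$pattern, gene_annotation_blob(g),
                                    ignore.case = TRUE)],
    domain_motif = all_ids[grepl(filter$pattern, gene_annotation_blob(g),
                                 ignore.case = TRUE)],
    go_term = {
      gos <- paste(g$go_mf, g$go_bp, g$go_cc, g$go_unspecified, sep = ";")
      hit <- vapply(strsplit(gos, ";", fixed = TRUE),
                    function(v) any(filter$terms %in% v), logical(1))
      all_ids[hit]
    },
    ec_number = {
      hit <- vapply(strsplit(g$ec_numbers, ";", fixed = TRUE),
                    function(v) any(filter$numbers %in% v), logical(1))
      all_ids[hit]
    },
    xref = {
      hit <- vapply(strsplit(g$xrefs, ";", fixed = TRUE),
                    function(v) any(filter$refs %in% v), logical(1))
      all_ids[hit]
    },
    presence = ,
    absence = {
      unknown <- setdiff(filter$genomes, profile$genome_ids)
      if (length(unknown))
        ps_validation_error(sprintf(
          "filter references genome '%s' absent from the profile", unknown[1]))
      sat <- matrix(
        label_satisfies(profile$labels[, filter$genomes, drop = FALSE],
                        filter$predicate),
        nrow = length(profile$gene_ids),
        dimnames = list(profile$gene_ids, filter$genomes))
      keep <- if (filter$kind == "presence") apply(sat, 1, all)
              else apply(sat, 1, function(v) !any(v))
      intersect(all_ids, profile$gene_ids[keep])
    },
    ps_validation_error(sprintf("unknown filter kind '%s'", filter$kind))
  )
}

#' Apply a gene filter
#'
#' Evaluates a filter tree against a presence profile and its reference
#' catalog; AND nodes intersect, OR nodes unite.
#'
#' @param profile a `presence_profile` (may be `NULL` when the tree uses no
#'   presence/absence leaf).
#' @param catalog the reference [genome_catalog].
#' @param filter a [gene_filters] object.
#' @return character vector of gene ids, in reference rank order.
#' @export
apply_filter <- function(profile, catalog, filter) {
  stopifnot(inherits(filter, "gene_filter"))
  ids <- eval_filter(filter, profile, catalog)
  catalog$genes$gene_id[catalog$genes$gene_id %in% ids]
}

#' Core and dispensable gene sets
#'
#' The core set contains the reference genes whose profile label satisfies
#' the presence predicate in every genome of `genome_subset`; the
#' dispensable set is the complement within the reference gene catalog.
#'
#' @param profile a `presence_profile`.
#' @param genome_subset non-empty character vector of compared genome ids.
#' @param predicate `"ortholog"` (default: BDBH presence) or
#'   `"any_homolog"`.
#' @return list(core = character, dispensable = character), both in rank
#'   order; together they partition the reference gene set.
#' @export
core_dispensable <- function(profile, genome_subset,
                             predicate = c("ortholog", "any_homolog")) {
  predicate <- match.arg(predicate)
  if (length(genome_subset) == 0)
    ps_validation_error("genome_subset must be non-empty")
  unknown <- setdiff(genome_subset, profile$genome_ids)
  if (length(unknown))
    ps_validation_error(sprintf("unknown genome id '%s'", unknown[1]))
  sat <- label_satisfies(profile$labels[, genome_subset, drop = FALSE],
                         predicate)
  sat <- matrix(sat, nrow = length(profile$gene_ids))
  in_core <- apply(sat, 1, all)
  list(core = profile$gene_ids[in_core],
       dispensable = profile$gene_ids[!in_core])
}

#' Export a presence profile as TSV / CSV
#'
#' `write_profile()` writes the label matrix as TSV (genes as columns,
#' genomes as rows, cells `O` = ortholog, `H` = homolog only, `-` =
#' absent); `export_profile_csv()` writes the whole table as a
#' comma-separated file.
#'
#' @param profile a `presence_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  code <- matrix(c(ortholog = "O", homolog_only = "H",
                   absent = "-")[profile$labels],
                 nrow = nrow(profile$labels))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("#genome", profile$gene_ids), collapse = "\t"),
             con, sep = "\n")
  for (j in seq_along(profile$genome_ids))
    writeLines(paste(c(profile$genome_ids[j], code[, j]), collapse = "\t"),
               con, sep = "\n")
  invisible(path)
}

#' @rdname write_profile
#' @export
export_profile_csv <- function(profile, path) {
  df <- as.data.frame(t(profile$labels), stringsAsFactors = FALSE)
  df <- cbind(genome = profile$genome_ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
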