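# Protein hit-table parsing and bidirectional-best-hit ortholog calling.

HIT_COLUMNS <- c("query_gene_id", "subject_gene_id", "pct_identity",
                 "aln_length", "mismatches", "gap_opens", "qstart", "qend",
                 "sstart", "send", "evalue", "bitscore")

empty_hit_frame <- function() {
  data.frame(query_gene_id = character(0), subject_gene_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), evalue = numeric(0), bitscore = numeric(0),
             query_coverage = numeric(0),
             query_genome_id = character(0), subject_genome_id = character(0),
             stringsAsFactors = FALSE)
}

#' Parse an all-vs-all protein hit table
#'
#' Reads a 12-column tabular hit file (the BLAST `outfmt 6` dialect: query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, bit score) and applies the storage
#' rule: only hits with e-value strictly below `max_evalue` are kept.
#' Same-genome hits are discarded (with a logged count) and multiple HSPs
#' for one query/subject pair are collapsed to the single best HSP (lowest
#' e-value, then highest bit score). Query coverage is derived as
#' `100 * (qend - qstart + 1) / query protein length`.
#'
#' @param path hit-table file.
#' @param catalogs list of the two [genome_catalog]s the gene ids resolve in.
#' @param max_evalue storage threshold; hits with `evalue >= max_evalue`
#'   are discarded. Default 0.01.
#' @return data.frame of retained hits, one row per query/subject pair.
#' @export
parse_hits <- function(path, catalogs, max_evalue = 0.01) {
  if (!file.exists(path))
    ps_abort(sprintf("hit table not found: %s", path),
             class = "pansynt_parse_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0) return(empty_hit_frame())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    ps_abort(sprintf("malformed hit line %d in %s: expected 12 fields, got %d",
                     bad[1], path, lengths(parts)[bad[1]]),
             class = "pansynt_parse_error")
  m <- do.call(rbind, parts)
  hits <- data.frame(m, stringsAsFactors = FALSE)
  names(hits) <- HIT_COLUMNS
  for (cn in c("pct_identity", "evalue", "bitscore"))
    hits[[cn]] <- as.numeric(hits[[cn]])
  for (cn in c("aln_length", "mismatches", "gap_opens", "qstart", "qend",
               "sstart", "send"))
    hits[[cn]] <- as.integer(hits[[cn]])

  gene2genome <- list()
  gene2plen <- list()
  for (cat in catalogs) {
    gene2genome[cat$genes$gene_id] <- cat$genome_id
    gene2plen[cat$genes$gene_id] <- cat$genes$protein_length
  }
  unresolved <- which(!(hits$query_gene_id %in% names(gene2genome)) |
                      !(hits$subject_gene_id %in% names(gene2genome)))
  if (length(unresolved)) {
    i <- unresolved[1]
    offender <- if (hits$query_gene_id[i] %in% names(gene2genome))
      hits$subject_gene_id[i] else hits$query_gene_id[i]
    ps_abort(sprintf("hit line %d of %s references unknown gene '%s'",
                     i, path, offender), class = "pansynt_parse_error")
  }
  hits$query_genome_id <- unlist(gene2genome[hits$query_gene_id], use.names = FALSE)
  hits$subject_genome_id <- unlist(gene2genome[hits$subject_gene_id], use.names = FALSE)

  n0 <- nrow(hits)
  hits <- hits[hits$evalue < max_evalue, , drop = FALSE]
  n_evalue <- n0 - nrow(hits)
  same <- hits$query_genome_id == hits$subject_genome_id
  if (any(same))
    ps_log(sprintf("discarded %d same-genome hit(s) from %s", sum(same), path))
  hits <- hits[!same, , drop = FALSE]
  if (n_evalue > 0)
    ps_log(sprintf("discarded %d hit(s) with e-value >= %g from %s",
                   n_evalue, max_evalue, path))
  if (nrow(hits) == 0) {
    ps_log(sprintf("no cross-genome hits retained from %s", path),
           level = "warn")
    return(empty_hit_frame())
  }

  # best HSP per query/subject pair: lowest e-value, then highest bitscore
  o <- order(hits$query_gene_id, hits$subject_gene_id,
             hits$evalue, -hits$bitscore)
  hits <- hits[o, , drop = FALSE]
  key <- paste(hits$query_gene_id, hits$subject_gene_id, sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]

  plen <- unlist(gene2plen[hits$query_gene_id], use.names = FALSE)
  hits$query_coverage <- 100 * (hits$qend - hits$qstart + 1) / plen
  rownames(hits) <- NULL
  hits
}

# Best subject per query: lowest e-value, then highest bitscore, then
# lexicographically smallest subject id (determinism).
best_subject <- function(hits) {
  if (nrow(hits) == 0)
    return(setNames(character(0), character(0)))
  o <- order(hits$query_gene_id, hits$evalue, -hits$bitscore,
             hits$subject_gene_id)
  h <- hits[o, , drop = FALSE]
  keep <- !duplicated(h$query_gene_id)
  setNames(h$subject_gene_id[keep], h$query_gene_id[keep])
}

#' Call ortholog and homolog relations between two genomes
#'
#' Orthologs are bidirectional best hits (BDBH): for each query gene the
#' best subject is the retained hit with the lowest e-value (ties broken by
#' highest bit score, then smallest subject id); two genes form an ortholog
#' relation iff each is the other's best subject. Every other retained
#' query/subject pair, in either direction, yields a homolog relation. Each
#' unordered gene pair appears at most once in the result.
#'
#' @param hits_ab hits with genome A queries and genome B subjects
#'   (as returned by [parse_hits()]); may be empty.
#' @param hits_ba the reverse direction; may be empty.
#' @return data.frame with one row per relation: `gene_a`, `gene_b`,
#'   `genome_a`, `genome_b`, `kind` (`"ortholog"`/`"homolog"`), and the
#'   per-direction alignment summaries (`evalue_ab`, `evalue_ba`,
#'   `pct_identity`, `query_coverage_ab`, `query_coverage_ba`,
#'   `bitscore_ab`, `bitscore_ba`; `NA` when a direction is absent).
#' @export
call_relations <- function(hits_ab, hits_ba) {
  if (nrow(hits_ab) == 0 && nrow(hits_ba) == 0)
    return(empty_relation_frame())
  genome_a <- c(hits_ab$query_genome_id, hits_ba$subject_genome_id)[1]
  genome_b <- c(hits_ab$subject_genome_id, hits_ba$query_genome_id)[1]

  pairs_ab <- unique(data.frame(
    gene_a = c(hits_ab$query_gene_id, hits_ba$subject_gene_id),
    gene_b = c(hits_ab$subject_gene_id, hits_ba$query_gene_id),
    stringsAsFactors = FALSE))

  best_a <- best_subject(hits_ab)   # query in A -> best subject in B
  best_b <- best_subject(hits_ba)   # query in B -> best subject in A
  is_bdbh <- function(ga, gb) {
    !is.na(best_a[ga]) && !is.na(best_b[gb]) &&
      best_a[[ga]] == gb && best_b[[gb]] == ga
  }
  kind <- vapply(seq_len(nrow(pairs_ab)), function(i) {
    ga <- pairs_ab$gene_a[i]; gb <- pairs_ab$gene_b[i]
    if (ga %in% names(best_a) && gb %in% names(best_b) && is_bdbh(ga, gb))
      "ortholog" else "homolog"
  }, character(1))

  key_ab <- paste(hits_ab$query_gene_id, hits_ab$subject_gene_id, sep = "\r")
  key_ba <- paste(hits_ba$subject_gene_id, hits_ba$query_gene_id, sep = "\r")
  key_pair <- paste(pairs_ab$gene_a, pairs_ab$gene_b, sep = "\r")
  i_ab <- match(key_pair, key_ab)
  i_ba <- match(key_pair, key_ba)

  get_num <- function(df, idx, col) {
    out <- rep(NA_real_, length(idx))
    ok <- !is.na(idx)
    if (any(ok)) out[ok] <- df[[col]][idx[ok]]
    out
  }
  rel <- data.frame(
    gene_a = pairs_ab$gene_a, gene_b = pairs_ab$gene_b,
    genome_a = genome_a, genome_b = genome_b,
    kind = kind,
    evalue_ab = get_num(hits_ab, i_ab, "evalue"),
    evalue_ba = get_num(hits_ba, i_ba, "evalue"),
    pct_identity = ifelse(!is.na(i_ab),
                          get_num(hits_ab, i_ab, "pct_identity"),
                          get_num(hits_ba, i_ba, "pct_identity")),
    query_coverage_ab = get_num(hits_ab, i_ab, "query_coverage"),
    query_coverage_ba = get_num(hits_ba, i_ba, "query_coverage"),
    bitscore_ab = get_num(hits_ab, i_ab, "bitscore"),
    bitscore_ba = get_num(hits_ba, i_ba, "bitscore"),
    stringsAsFactors = FALSE
  )
  rel <- rel[order(rel$gene_a, rel$gene_b), , drop = FALSE]
  rownames(rel) <- NULL
  rel
}

empty_relation_frame <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             genome_a = character(0), genome_b = character(0),
             kind = character(0), evalue_ab = numeric(0),
             evalue_ba = numeric(0), pct_identity = numeric(0),
             query_coverage_ab = numeric(0), query_coverage_ba = numeric(0),
             bitscore_ab = numeric(0), bitscore_ba = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write / read a relation table
#'
#' Plain TSV with a single `#`-prefixed header line.
#' @param relations data.frame from [call_relations()].
#' @param path file path.
#' @return `path` (write) or the relations data.frame (read).
#' @export
write_relations <- function(relations, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(empty_relation_frame()), collapse = "\t")),
             con, sep = "\n")
  if (nrow(relations)) {
    body <- do.call(paste, c(lapply(names(empty_relation_frame()),
                                    function(cn) relations[[cn]]), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_relations
#' @export
read_relations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tmpl <- empty_relation_frame()
  if (length(lines) == 0 ||
      !identical(strsplit(sub("^#", "", lines[1]), "\t")[[1]], names(tmpl)))
    ps_abort(sprintf("%s is not a pansynt relation table", path),
             class = "pansynt_parse_error")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) return(tmpl)
  m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  rel <- data.frame(m, stringsAsFactors = FALSE)
  names(rel) <- names(tmpl)
  for (cn in names(tmpl)[vapply(tmpl, is.numeric, logical(1))])
    rel[[cn]] <- suppressWarnings(as.numeric(rel[[cn]]))
  rel
}
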