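# Genome ingestion: ordered gene catalogs from annotated complete genomes.

GENE_TABLE_COLUMNS <- c(
  "gene_id", "genome_id", "replicon_id", "start", "end", "strand", "rank",
  "protein_length", "product", "go_mf", "go_bp", "go_cc", "go_unspecified",
  "ec_numbers", "xrefs"
)

empty_gene_frame <- function() {
  df <- data.frame(
    gene_id = character(0), genome_id = character(0),
    replicon_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), rank = integer(0), protein_length = integer(0),
    product = character(0), go_mf = character(0), go_bp = character(0),
    go_cc = character(0), go_unspecified = character(0),
    ec_numbers = character(0), xrefs = character(0),
    stringsAsFactors = FALSE
  )
  df
}

#' Construct a genome catalog
#'
#' A genome catalog is the ordered gene inventory of one annotated genome:
#' one row per protein-coding gene, with 1-based inclusive coordinates, a
#' genome-wide rank following the concatenation of replicons in file order,
#' and the functional annotation fields used elsewhere (GO terms split by
#' namespace, EC numbers, databank cross-references).
#'
#' Genes are re-sorted within each replicon by start coordinate (ties broken
#' by end, then by gene id) and ranks are (re)assigned as a contiguous
#' 0..N-1 sequence over the whole genome, so the caller need not supply the
#' `rank` column.
#'
#' @param genes data.frame with at least gene_id, replicon_id, start, end,
#'   strand; optional protein_length, product, go_mf, go_bp, go_cc,
#'   go_unspecified, ec_numbers, xrefs (semicolon-joined sets).
#' @param genome_id genome identifier.
#' @param replicons optional data.frame(replicon_id, length_bp) in display
#'   order; defaults to first-appearance order with length = max gene end.
#' @return an object of class `genome_catalog`.
#' @export
genome_catalog <- function(genes, genome_id, replicons = NULL) {
  stopifnot_scalar_string(genome_id, "genome_id")
  if (!is.data.frame(genes))
    ps_validation_error("genes must be a data.frame")
  needed <- c("gene_id", "replicon_id", "start", "end", "strand")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols))
    ps_validation_error(paste0("genes is missing columns: ",
                               paste(missing_cols, collapse = ", ")))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  n <- nrow(genes)
  genes$gene_id <- as.character(genes$gene_id)
  genes$genome_id <- rep(genome_id, n)
  genes$replicon_id <- as.character(genes$replicon_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  for (col in c("product", "go_mf", "go_bp", "go_cc", "go_unspecified",
                "ec_numbers", "xrefs")) {
    if (is.null(genes[[col]])) genes[[col]] <- rep("", n)
    genes[[col]] <- as.character(genes[[col]])
    genes[[col]][is.na(genes[[col]])] <- ""
  }
  if (is.null(genes$protein_length))
    genes$protein_length <- pmax(1L, (genes$end - genes$start + 1L) %/% 3L - 1L)
  genes$protein_length <- as.integer(genes$protein_length)

  if (n > 0) {
    if (any(is.na(genes$start)) || any(is.na(genes$end)))
      ps_validation_error("gene coordinates contain NA")
    if (any(genes$start < 1L))
      ps_validation_error("gene start coordinates must be >= 1")
    bad <- genes$start > genes$end
    if (any(bad))
      ps_validation_error(paste0("start > end for gene(s): ",
                                 paste(genes$gene_id[bad], collapse = ", ")))
    dup <- genes$gene_id[duplicated(genes$gene_id)]
    if (length(dup)) {
      where <- which(genes$gene_id %in% dup[1])
      ps_abort(sprintf(
        "duplicate gene id '%s' (rows %s of the gene table)",
        dup[1], paste(where, collapse = " and ")),
        class = "pansynt_parse_error")
    }
    if (!all(genes$strand %in% c("+", "-")))
      ps_validation_error("strand must be '+' or '-'")
  }

  if (is.null(replicons)) {
    rep_ids <- unique(genes$replicon_id)
    lens <- vapply(rep_ids, function(r) {
      idx <- genes$replicon_id == r
      if (!any(idx)) 0L else max(genes$end[idx])
    }, integer(1))
    replicons <- data.frame(replicon_id = rep_ids, length_bp = as.integer(lens),
                            stringsAsFactors = FALSE)
  } else {
    replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
    replicons$replicon_id <- as.character(replicons$replicon_id)
    replicons$length_bp <- as.integer(replicons$length_bp)
    orphan <- setdiff(genes$replicon_id, replicons$replicon_id)
    if (length(orphan))
      ps_validation_error(paste0("genes reference unknown replicon(s): ",
                                 paste(unique(orphan), collapse = ", ")))
  }
  replicons$offset_bp <- c(0L, cumsum(replicons$length_bp))[seq_len(nrow(replicons))]

  # rank: replicons in file order, genes by start (ties: end, gene_id)
  if (n > 0) {
    rep_order <- match(genes$replicon_id, replicons$replicon_id)
    o <- order(rep_order, genes$start, genes$end, genes$gene_id)
    genes <- genes[o, , drop = FALSE]
  }
  genes$rank <- seq_len(n) - 1L
  rownames(genes) <- NULL
  genes <- genes[, GENE_TABLE_COLUMNS]

  structure(
    list(
      genome_id = genome_id,
      replicons = replicons,
      genes = genes,
      total_bp = sum(replicons$length_bp)
    ),
    class = "genome_catalog"
  )
}

#' @export
print.genome_catalog <- function(x, ...) {
  cat(sprintf("<genome_catalog> %s: %d gene(s) on %d replicon(s), %d bp\n",
              x$genome_id, nrow(x$genes), nrow(x$replicons), x$total_bp))
  invisible(x)
}

#' Number of genes in a catalog
#' @param catalog a `genome_catalog`.
#' @return integer gene count.
#' @export
n_genes <- function(catalog) nrow(catalog$genes)

catalog_gene <- function(catalog, gene_id) {
  i <- match(gene_id, catalog$genes$gene_id)
  if (is.na(i))
    ps_abort(sprintf("gene '%s' not found in genome '%s'",
                     gene_id, catalog$genome_id))
  catalog$genes[i, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Flat-file feature-table parsing (GenBank / EMBL dialects)

# Split a record's lines into (replicon_id, length, list of features).
# A feature is list(key, location, qualifiers = named list of character).
parse_feature_table <- function(lines, dialect, path) {
  replicon_id <- NA_character_
  replicon_len <- NA_integer_
  feats <- list()
  cur_key <- NULL
  cur_loc <- NULL
  cur_quals <- list()
  qual_name <- NULL
  qual_open <- FALSE   # inside a multi-line quoted qualifier value
  in_features <- FALSE

  flush_feature <- function() {
    if (!is.null(cur_key)) {
      feats[[length(feats) + 1L]] <<- list(
        key = cur_key, location = cur_loc, qualifiers = cur_quals,
        line = cur_line_no)
    }
    cur_key <<- NULL; cur_loc <<- NULL; cur_quals <<- list()
    qual_name <<- NULL; qual_open <<- FALSE
  }
  cur_line_no <- NA_integer_

  add_qual_text <- function(txt) {
    cur_quals[[qual_name]][length(cur_quals[[qual_name]])] <<-
      paste0(cur_quals[[qual_name]][length(cur_quals[[qual_name]])],
             if (identical(qual_name, "translation")) "" else " ", txt)
  }

  for (k in seq_along(lines)) {
    line <- lines[[k]]
    if (dialect == "genbank") {
      if (grepl("^LOCUS", line)) {
        toks <- strsplit(trimws(line), "\\s+")[[1]]
        replicon_id <- toks[2]
        len_tok <- suppressWarnings(as.integer(toks[3]))
        if (!is.na(len_tok)) replicon_len <- len_tok
        next
      }
      if (grepl("^FEATURES", line)) { in_features <- TRUE; next }
      if (in_features && grepl("^[A-Z]", line)) { in_features <- FALSE }
      if (!in_features) next
      new_feat <- regmatches(line, regexec("^ {5}([A-Za-z0-9_'-]+) +(\\S.*)$", line))[[1]]
      cont <- if (length(new_feat) == 0)
        regmatches(line, regexec("^ {21}(\\S.*)$", line))[[1]] else character(0)
    } else {  # embl
      if (grepl("^ID ", line)) {
        toks <- strsplit(line, ";")[[1]]
        replicon_id <- sub("^ID\\s+", "", trimws(toks[1]))
        bp <- regmatches(line, regexec("(\\d+)\\s+BP", line))[[1]]
        if (length(bp)) replicon_len <- as.integer(bp[2])
        next
      }
      if (!grepl("^FT", line)) next
      new_feat <- regmatches(line, regexec("^FT   ([A-Za-z0-9_'-]+) +(\\S.*)$", line))[[1]]
      cont <- if (length(new_feat) == 0)
        regmatches(line, regexec("^FT {16,}(\\S.*)$", line))[[1]] else character(0)
    }

    if (length(new_feat)) {
      flush_feature()
      cur_key <- new_feat[2]
      cur_loc <- new_feat[3]
      cur_line_no <- k
      next
    }
    if (length(cont) == 0) next
    txt <- cont[2]
    if (is.null(cur_key)) next
    if (qual_open) {
      # continuation of a quoted qualifier value
      if (grepl("\"\\s*$", txt)) {
        qual_open <- FALSE
        txt <- sub("\"\\s*$", "", txt)
      }
      add_qual_text(txt)
    } else if (grepl("^/", txt)) {
      m <- regmatches(txt, regexec('^/([A-Za-z_0-9-]+)(=(.*))?$', txt))[[1]]
      if (length(m) == 0)
        ps_abort(sprintf("malformed qualifier in %s near line %d: %s",
                         path, k, txt), class = "pansynt_parse_error")
      qual_name <- m[2]
      val <- m[4]
      if (!nzchar(m[3])) {
        cur_quals[[qual_name]] <- c(cur_quals[[qual_name]] %||% character(0), "TRUE")
      } else if (grepl('^"', val)) {
        body <- sub('^"', "", val)
        if (grepl('"\\s*$', body)) {
          body <- sub('"\\s*$', "", body)
        } else {
          qual_open <- TRUE
        }
        cur_quals[[qual_name]] <- c(cur_quals[[qual_name]] %||% character(0), body)
      } else {
        cur_quals[[qual_name]] <- c(cur_quals[[qual_name]] %||% character(0), val)
      }
    } else {
      # location continuation (join(... split over lines)
      cur_loc <- paste0(cur_loc, txt)
    }
  }
  flush_feature()
  list(replicon_id = replicon_id, length_bp = replicon_len, features = feats)
}

# Parse a feature location string. Returns list(start, end, strand, partial,
# wraps) where wraps marks an origin-spanning join on a circular replicon.
parse_location <- function(loc) {
  partial <- grepl("[<>]", loc)
  s <- gsub("[<>]", "", loc)
  strand <- if (grepl("complement", s)) "-" else "+"
  s <- gsub("complement\\(|join\\(|order\\(|\\)", "", s)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  nums <- lapply(parts, function(p) {
    v <- suppressWarnings(as.integer(strsplit(p, "\\.\\.")[[1]]))
    if (any(is.na(v))) NULL else range(v)
  })
  if (any(vapply(nums, is.null, logical(1))) || length(nums) == 0)
    return(NULL)
  first <- nums[[1]]; last <- nums[[length(nums)]]
  wraps <- length(nums) > 1 && last[1] < first[1]
  list(start = first[1],
       end = if (wraps) NA_integer_ else max(vapply(nums, `[`, integer(1), 2)),
       strand = strand, partial = partial, wraps = wraps)
}

record_to_genes <- function(rec, genome_id, path) {
  rows <- list()
  for (f in rec$features) {
    if (f$key != "CDS") next
    q <- f$qualifiers
    loc <- parse_location(f$location)
    gid <- q$locus_tag[1] %||% q$gene[1] %||% q$protein_id[1] %||% NA_character_
    if (is.null(loc))
      ps_abort(sprintf("unparseable CDS location '%s' in %s (feature at line %d)",
                       f$location, path, f$line), class = "pansynt_parse_error")
    if (is.na(gid))
      ps_abort(sprintf("CDS at %s in %s has no locus_tag/gene/protein_id",
                       f$location, path), class = "pansynt_parse_error")
    if (!is.null(q$pseudo) || !is.null(q$pseudogene)) {
      ps_log(sprintf("skipping pseudogene %s in %s", gid, rec$replicon_id),
             level = "warn")
      next
    }
    if (loc$partial) {
      ps_log(sprintf("skipping partial CDS %s in %s", gid, rec$replicon_id),
             level = "warn")
      next
    }
    if (loc$wraps) {
      # origin-spanning gene on a circular replicon: keep its annotated
      # start; extend to the replicon end so start <= end holds, and note it.
      loc$end <- rec$length_bp %||% loc$start
      ps_log(sprintf(
        "gene %s spans the origin of %s; stored as %d..%d and ranked last",
        gid, rec$replicon_id, loc$start, loc$end), level = "note")
    }
    translation <- q$translation[1]
    if (!is.null(translation) && !is.na(translation)) {
      plen <- nchar(gsub("\\s", "", translation))
    } else {
      plen <- (loc$end - loc$start + 1L) %/% 3L - 1L
    }
    if (is.na(plen) || plen < 1) {
      ps_log(sprintf("skipping CDS %s with no usable protein product", gid),
             level = "warn")
      next
    }

    go_mf <- character(0); go_bp <- character(0); go_cc <- character(0)
    go_un <- character(0); xrefs <- character(0)
    grab_go <- function(v) unlist(regmatches(v, gregexpr("GO:\\d+", v)))
    if (!is.null(q$GO_function)) go_mf <- grab_go(q$GO_function)
    if (!is.null(q$GO_process))  go_bp <- grab_go(q$GO_process)
    if (!is.null(q$GO_component)) go_cc <- grab_go(q$GO_component)
    for (xr in q$db_xref %||% character(0)) {
      if (grepl("^GO:", xr)) go_un <- c(go_un, xr) else xrefs <- c(xrefs, xr)
    }
    go_un <- setdiff(go_un, c(go_mf, go_bp, go_cc))

    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, replicon_id = rec$replicon_id,
      start = loc$start, end = loc$end, strand = loc$strand,
      protein_length = as.integer(plen),
      product = q$product[1] %||% "",
      go_mf = join_set(go_mf), go_bp = join_set(go_bp),
      go_cc = join_set(go_cc), go_unspecified = join_set(go_un),
      ec_numbers = join_set(q$EC_number %||% character(0)),
      xrefs = join_set(xrefs),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Load an annotated genome into a gene catalog
#'
#' Reads a complete-genome annotation file and extracts one gene record per
#' CDS feature. Non-CDS features are ignored; pseudogenes and CDS without a
#' usable protein product are skipped with a logged warning. Replicons
#' (chromosome, plasmids) are kept in file order and genome-wide gene ranks
#' follow their concatenation, so that a plasmid's genes rank after the
#' chromosome's.
#'
#' @param path path to the genome file (for `gff3` the GFF3 file).
#' @param format one of `"genbank"`, `"embl"`, `"gff3"`.
#' @param genome_id genome identifier; defaults to the file base name.
#' @param protein_fasta for `format = "gff3"`: protein FASTA whose sequence
#'   names match CDS `ID`/`locus_tag` attributes (used for protein lengths).
#' @return a [genome_catalog].
#' @export
load_genome <- function(path, format = c("genbank", "embl", "gff3"),
                        genome_id = NULL, protein_fasta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    ps_abort(sprintf("genome file not found: %s", path),
             class = "pansynt_parse_error")
  genome_id <- genome_id %||% sub("\\.[A-Za-z0-9]+$", "", basename(path))

  if (format %in% c("genbank", "embl")) {
    lines <- readLines(path, warn = FALSE)
    sep <- grepl("^//\\s*$", lines)
    rec_idx <- cumsum(c(TRUE, head(sep, -1)))
    rec_idx[sep] <- NA
    gene_frames <- list()
    replicons <- list()
    for (r in unique(rec_idx[!is.na(rec_idx)])) {
      rl <- lines[!is.na(rec_idx) & rec_idx == r]
      if (!any(nzchar(trimws(rl)))) next
      rec <- parse_feature_table(rl, dialect = format, path = path)
      if (is.na(rec$replicon_id))
        ps_abort(sprintf("record %d of %s has no %s header line",
                         r, path, if (format == "genbank") "LOCUS" else "ID"),
                 class = "pansynt_parse_error")
      replicons[[length(replicons) + 1L]] <- data.frame(
        replicon_id = rec$replicon_id,
        length_bp = rec$length_bp %||% NA_integer_,
        stringsAsFactors = FALSE)
      gf <- record_to_genes(rec, genome_id, path)
      if (!is.null(gf)) gene_frames[[length(gene_frames) + 1L]] <- gf
    }
    genes <- if (length(gene_frames)) do.call(rbind, gene_frames)
             else empty_gene_frame()
    reps <- do.call(rbind, replicons)
    na_len <- is.na(reps$length_bp)
    if (any(na_len)) {
      for (i in which(na_len)) {
        idx <- genes$replicon_id == reps$replicon_id[i]
        reps$length_bp[i] <- if (any(idx)) max(genes$end[idx]) else 0L
      }
    }
    return(genome_catalog(genes, genome_id, replicons = reps))
  }

  # GFF3 + protein FASTA
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    ps_abort("the rtracklayer package is required to read GFF3")
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0)
    return(genome_catalog(empty_gene_frame(), genome_id))
  meta <- as.data.frame(cds)
  gid <- as.character(meta$locus_tag %||% meta$ID)
  if (all(is.na(gid))) gid <- as.character(meta$ID)
  plen <- rep(NA_integer_, nrow(meta))
  if (!is.null(protein_fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      ps_abort("the Biostrings package is required to read protein FASTA")
    aa <- Biostrings::readAAStringSet(protein_fasta)
    nm <- sub("\\s.*$", "", names(aa))
    plen <- unname(Biostrings::width(aa)[match(gid, nm)])
  }
  genes <- data.frame(
    gene_id = gid,
    replicon_id = as.character(meta$seqnames),
    start = as.integer(meta$start), end = as.integer(meta$end),
    strand = ifelse(as.character(meta$strand) == "-", "-", "+"),
    protein_length = ifelse(is.na(plen),
                            pmax(1L, (meta$end - meta$start + 1L) %/% 3L - 1L),
                            plen),
    product = as.character(meta$product %||% ""),
    stringsAsFactors = FALSE
  )
  genes$product[is.na(genes$product)] <- ""
  if (!is.null(meta$Ontology_term)) {
    genes$go_unspecified <- vapply(meta$Ontology_term, function(v)
      join_set(grep("^GO:", as.character(v), value = TRUE)), character(1))
  }
  if (!is.null(meta$ec_number)) {
    genes$ec_numbers <- vapply(meta$ec_number, function(v)
      join_set(as.character(v)), character(1))
  }
  # replicon order: first appearance in the file; lengths from pragmas if any
  rep_ids <- unique(genes$replicon_id)
  lens <- vapply(rep_ids, function(r) max(genes$end[genes$replicon_id == r]),
                 numeric(1))
  pragma <- grep("^##sequence-region", readLines(path, warn = FALSE), value = TRUE)
  for (p in pragma) {
    toks <- strsplit(trimws(p), "\\s+")[[1]]
    if (length(toks) >= 4 && toks[2] %in% rep_ids)
      lens[match(toks[2], rep_ids)] <- as.numeric(toks[4])
  }
  genome_catalog(genes, genome_id,
                 replicons = data.frame(replicon_id = rep_ids,
                                        length_bp = as.integer(lens),
                                        stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# Tabular catalog serialization

#' Write a genome catalog as a tab-separated gene table
#'
#' The format is a TSV with `#`-prefixed header lines carrying the genome id
#' and replicon lengths, a `#columns:` line naming the fixed column order,
#' and one row per gene. [read_catalog()] inverts it field-for-field.
#'
#' @param catalog a [genome_catalog].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "genome_catalog"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl("#pansynt-gene-table v1")
  wl(sprintf("#genome: %s", catalog$genome_id))
  for (i in seq_len(nrow(catalog$replicons)))
    wl(sprintf("#replicon: %s\t%d",
               catalog$replicons$replicon_id[i],
               catalog$replicons$length_bp[i]))
  wl(paste0("#columns: ", paste(GENE_TABLE_COLUMNS, collapse = "\t")))
  g <- catalog$genes
  if (nrow(g)) {
    g$product <- gsub("[\t\n]", " ", g$product)
    body <- do.call(paste, c(lapply(GENE_TABLE_COLUMNS, function(cn) g[[cn]]),
                             sep = "\t"))
    wl(body)
  }
  invisible(path)
}

#' Read a gene table written by [write_catalog()]
#'
#' @param path file path.
#' @return a [genome_catalog].
#' @export
read_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "#pansynt-gene-table v1")
    ps_abort(sprintf("%s is not a pansynt gene table (bad signature line)",
                     path), class = "pansynt_parse_error")
  genome_id <- sub("^#genome: ", "", grep("^#genome: ", lines, value = TRUE)[1])
  rep_lines <- grep("^#replicon: ", lines, value = TRUE)
  reps <- do.call(rbind, lapply(rep_lines, function(l) {
    toks <- strsplit(sub("^#replicon: ", "", l), "\t", fixed = TRUE)[[1]]
    data.frame(replicon_id = toks[1], length_bp = as.integer(toks[2]),
               stringsAsFactors = FALSE)
  }))
  col_line <- grep("^#columns: ", lines, value = TRUE)[1]
  cols <- strsplit(sub("^#columns: ", "", col_line), "\t", fixed = TRUE)[[1]]
  if (!identical(cols, GENE_TABLE_COLUMNS))
    ps_abort(sprintf(
      "gene table %s has unexpected columns.\n  expected: %s\n  found:    %s",
      path, paste(GENE_TABLE_COLUMNS, collapse = ","),
      paste(cols, collapse = ",")), class = "pansynt_parse_error")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    genes <- empty_gene_frame()
  } else {
    mat <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(mat) != length(cols))
    if (length(bad))
      ps_abort(sprintf("gene table %s: row %d has %d fields, expected %d",
                       path, bad[1], lengths(mat)[bad[1]], length(cols)),
               class = "pansynt_parse_error")
    m <- do.call(rbind, mat)
    genes <- as.data.frame(m, stringsAsFactors = FALSE)
    names(genes) <- cols
    for (cn in c("start", "end", "rank", "protein_length"))
      genes[[cn]] <- as.integer(genes[[cn]])
  }
  genome_catalog(genes, genome_id, replicons = reps)
}
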