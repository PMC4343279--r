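## Builders that derive gene-to-MeSH link tables from literature links and
## from reciprocal-best-hit ortholog pairs, plus the custom-store builder.

.stopAtLine <- function(file, rows, what) {
  ## rows are 1-based data rows; +1 accounts for the header line
  stop(file, ":", rows[1L] + 1L, ": ", what, call. = FALSE)
}

.requireCols <- function(df, file, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(file, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Read the plain-text exchange formats
#'
#' Readers for the TSV dialects used throughout the package (all with a
#' header row): gene lists (one positive integer id per line, no header),
#' vocabulary tables (`mesh_id`, `term`, `category`, `qualifiers`,
#' `synonyms`), edge lists (`parent_id`, `child_id`), link tables
#' (`gene_id`, `mesh_id`, `source`, `pubmed_ids`) and gene2pubmed-style
#' tables (`gene_id`, `pubmed_id`). Schema violations are reported with
#' the file name and line number.
#'
#' @param file path to the input file.
#' @return a `data.frame` (or integer vector for `readGeneList`).
#' @name readers
NULL

#' @rdname readers
#' @export
readGeneList <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  ids <- suppressWarnings(as.integer(lines))
  bad <- which(is.na(ids) | ids < 1L)
  if (length(bad))
    stop(file, ":", bad[1L], ": not a positive integer gene id: '",
         lines[bad[1L]], "'", call. = FALSE)
  ids
}

#' @rdname readers
#' @export
readVocabularyTsv <- function(file) {
  df <- .readTsv(file, colClasses = "character")
  .requireCols(df, file, c("mesh_id", "term", "category"))
  for (col in c("qualifiers", "synonyms"))
    if (!col %in% names(df)) df[[col]] <- ""
  df$qualifiers[is.na(df$qualifiers)] <- ""
  df$synonyms[is.na(df$synonyms)] <- ""
  bad <- which(is.na(df$term) | df$term == "")
  if (length(bad)) .stopAtLine(file, bad, "empty term label")
  bad <- which(!df$category %in% .validCategoryCodes())
  if (length(bad))
    .stopAtLine(file, bad, paste0("invalid category code '",
                                  df$category[bad[1L]], "'"))
  bad <- which(duplicated(df$mesh_id))
  if (length(bad))
    .stopAtLine(file, bad, paste0("duplicated mesh_id '",
                                  df$mesh_id[bad[1L]], "'"))
  df[c("mesh_id", "term", "category", "qualifiers", "synonyms")]
}

#' @rdname readers
#' @export
readEdgesTsv <- function(file) {
  df <- .readTsv(file, colClasses = "character")
  if (all(c("parent", "child") %in% names(df)))
    names(df)[match(c("parent", "child"), names(df))] <-
      c("parent_id", "child_id")
  .requireCols(df, file, c("parent_id", "child_id"))
  bad <- which(df$parent_id == df$child_id)
  if (length(bad))
    .stopAtLine(file, bad, paste0("self-edge at '", df$parent_id[bad[1L]], "'"))
  data.frame(parent = df$parent_id, child = df$child_id,
             stringsAsFactors = FALSE)
}

#' @rdname readers
#' @export
readLinksTsv <- function(file) {
  df <- .readTsv(file, colClasses = c(gene_id = "character",
                                      mesh_id = "character",
                                      source = "character",
                                      pubmed_ids = "character"))
  .requireCols(df, file, c("gene_id", "mesh_id", "source"))
  if (!"pubmed_ids" %in% names(df)) df$pubmed_ids <- ""
  df$pubmed_ids[is.na(df$pubmed_ids)] <- ""
  gid <- suppressWarnings(as.integer(df$gene_id))
  bad <- which(is.na(gid) | gid < 1L)
  if (length(bad))
    .stopAtLine(file, bad, paste0("gene_id must be a positive integer, got '",
                                  df$gene_id[bad[1L]], "'"))
  bad <- which(!df$source %in% .validSources())
  if (length(bad))
    .stopAtLine(file, bad, paste0("invalid source '", df$source[bad[1L]],
                                  "'; valid sources: ",
                                  paste(.validSources(), collapse = ", ")))
  data.frame(gene_id = gid, mesh_id = df$mesh_id, source = df$source,
             pubmed_ids = df$pubmed_ids, stringsAsFactors = FALSE)
}

#' @rdname readers
#' @export
readGenePubmedTsv <- function(file) {
  df <- .readTsv(file, colClasses = c(gene_id = "integer",
                                      pubmed_id = "integer"))
  .requireCols(df, file, c("gene_id", "pubmed_id"))
  df[c("gene_id", "pubmed_id")]
}

#' Join literature links into gene-to-term annotations
#'
#' Reproduces the gene2pubmed-style construction of annotation links: a
#' gene-to-article table and an article-to-term table are joined on the
#' article id. Articles tagged with very many genes (genome papers,
#' database descriptions) carry little gene-specific signal, so any
#' article linked to more than `maxGenesPerPaper` distinct genes is
#' dropped *before* the join — the threshold is strict, an article with
#' exactly `maxGenesPerPaper` genes is retained. Surviving matches are
#' aggregated to one link per (gene, term) whose `pubmed_ids` field
#' collects every contributing article.
#'
#' @param g2p `data.frame` with columns `gene_id`, `pubmed_id`.
#' @param p2m `data.frame` with columns `pubmed_id`, `mesh_id`.
#' @param maxGenesPerPaper drop articles with more distinct genes than
#'   this (default 1000).
#' @param source provenance label recorded on the produced links.
#' @return links `data.frame` (`gene_id`, `mesh_id`, `source`,
#'   `pubmed_ids`), deterministically ordered; empty inputs give an empty
#'   table.
#' @examples
#' g2p <- data.frame(gene_id = 1L, pubmed_id = 11L)
#' p2m <- data.frame(pubmed_id = 11L, mesh_id = "D0001")
#' joinGenePubmedMesh(g2p, p2m)
#' @export
joinGenePubmedMesh <- function(g2p, p2m, maxGenesPerPaper = 1000,
                               source = "gene2pubmed") {
  stopifnot(maxGenesPerPaper >= 1)
  source <- match.arg(source, .validSources())
  g2p <- unique(as.data.frame(g2p)[c("gene_id", "pubmed_id")])
  p2m <- unique(as.data.frame(p2m)[c("pubmed_id", "mesh_id")])
  if (!nrow(g2p) || !nrow(p2m)) return(.emptyLinks())
  genesPerPaper <- tapply(g2p$gene_id, g2p$pubmed_id,
                          function(g) length(unique(g)))
  keep <- names(genesPerPaper)[genesPerPaper <= maxGenesPerPaper]
  g2p <- g2p[as.character(g2p$pubmed_id) %in% keep, , drop = FALSE]
  if (!nrow(g2p)) return(.emptyLinks())
  j <- merge(g2p, p2m, by = "pubmed_id")
  if (!nrow(j)) return(.emptyLinks())
  key <- paste(j$gene_id, j$mesh_id, sep = "\r")
  docs <- tapply(j$pubmed_id, key, function(p)
    paste(sort(unique(p)), collapse = "|"))
  parts <- strsplit(names(docs), "\r", fixed = TRUE)
  out <- data.frame(gene_id = as.integer(vapply(parts, `[`, "", 1L)),
                    mesh_id = vapply(parts, `[`, "", 2L),
                    source = source,
                    pubmed_ids = as.character(docs),
                    stringsAsFactors = FALSE)
  out <- out[.orderBy(out, c("gene_id", "mesh_id")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project annotations across organisms via reciprocal best hits
#'
#' Genes of a poorly annotated organism inherit the MeSH links of their
#' reciprocal-best-hit partners in well annotated organisms. Every link of
#' a partner gene is copied to the recipient gene with provenance `RBBH`
#' and its supporting document ids preserved; when a recipient gene has
#' reciprocal hits in several organisms the inherited term sets are
#' unioned (document ids merged per term). A pair whose partner gene has
#' no links contributes nothing. No term can appear in the output that was
#' absent from `majorLinks`.
#'
#' @param majorLinks links `data.frame` of the annotation donors
#'   (`gene_id`, `mesh_id`, `source`, `pubmed_ids`).
#' @param pairs `data.frame` with columns `gene_id_minor`, `gene_id_major`
#'   (as produced from [reciprocalBestHits()] pairings).
#' @return links `data.frame` for the recipient genes, `source = "RBBH"`.
#' @export
transferByRbbh <- function(majorLinks, pairs) {
  pairs <- unique(as.data.frame(pairs)[c("gene_id_minor", "gene_id_major")])
  majorLinks <- as.data.frame(majorLinks)
  if (!nrow(pairs) || !nrow(majorLinks)) return(.emptyLinks())
  if (!"pubmed_ids" %in% names(majorLinks)) majorLinks$pubmed_ids <- ""
  m <- merge(pairs, majorLinks,
             by.x = "gene_id_major", by.y = "gene_id")
  if (!nrow(m)) return(.emptyLinks())
  key <- paste(m$gene_id_minor, m$mesh_id, sep = "\r")
  docs <- tapply(m$pubmed_ids, key, function(p) {
    ids <- unique(unlist(.splitBar(p), use.names = FALSE))
    paste(sort(ids), collapse = "|")
  })
  parts <- strsplit(names(docs), "\r", fixed = TRUE)
  out <- data.frame(gene_id = as.integer(vapply(parts, `[`, "", 1L)),
                    mesh_id = vapply(parts, `[`, "", 2L),
                    source = "RBBH",
                    pubmed_ids = as.character(docs),
                    stringsAsFactors = FALSE)
  out <- out[.orderBy(out, c("gene_id", "mesh_id")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a MeshDb from user-supplied TSV tables
#'
#' Validates and assembles a custom annotation store from the plain-text
#' exchange formats (see [readers]): a vocabulary table, a parent-child
#' edge list and a link table. Violations are reported with file and line;
#' in particular a link referencing a term absent from the vocabulary is
#' rejected with the offending line. When `outDir` is given the validated
#' store is also written to disk with [writeMeshDb()].
#'
#' @param linksTsv,vocabularyTsv,edgesTsv input file paths; `edgesTsv` may
#'   be `NULL` for a flat vocabulary.
#' @param metadata named character vector stored in the manifest.
#' @param outDir optional directory for the on-disk store.
#' @return a validated [MeshDb].
#' @export
buildCustomStore <- function(linksTsv, vocabularyTsv, edgesTsv = NULL,
                             metadata = character(), outDir = NULL) {
  terms <- readVocabularyTsv(vocabularyTsv)
  edges <- if (is.null(edgesTsv)) NULL else readEdgesTsv(edgesTsv)
  links <- readLinksTsv(linksTsv)
  bad <- which(!links$mesh_id %in% terms$mesh_id)
  if (length(bad))
    .stopAtLine(linksTsv, bad,
                paste0("link references unknown mesh_id '",
                       links$mesh_id[bad[1L]], "'"))
  if (!is.null(edges)) {
    for (col in c("parent", "child")) {
      bad <- which(!edges[[col]] %in% terms$mesh_id)
      if (length(bad))
        .stopAtLine(edgesTsv, bad,
                    paste0("edge references unknown mesh_id '",
                           edges[[col]][bad[1L]], "'"))
    }
  }
  db <- MeshDb(terms, edges, links, metadata = metadata)
  if (!is.null(outDir)) writeMeshDb(db, outDir)
  db
}
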