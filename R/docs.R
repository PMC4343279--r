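## Local organization of literature artifacts attached to enriched
## (gene, term) pairs. Retrieval is delegated to an injected fetcher
## callable; the package core never opens a network connection.

#' Collect document records for enriched gene-term pairs
#'
#' For every significant row of an over-representation result, emits one
#' record per combination of an overlapping gene and a supporting
#' document id of the corresponding annotation link (restricted to the
#' annotation sources used in the run), deduplicated. These (PubMed,
#' gene, term) triples are what make MeSH enrichment actionable: each one
#' points at concrete literature connecting a gene of interest to an
#' enriched concept.
#'
#' @param result a [MeshOraResult].
#' @param db the [MeshDb] the result was computed from.
#' @return `data.frame` with columns `pubmed_id`, `gene_id`, `mesh_id`,
#'   deterministically ordered.
#' @export
collectDocRecords <- function(result, db) {
  stopifnot(is(result, "MeshOraResult"), is(db, "MeshDb"))
  tab <- result@table[result@table$significant, , drop = FALSE]
  lk <- db@links
  lk <- lk[lk$source %in% result@params@sources, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tab))) {
    genes <- as.integer(.splitBar(tab$gene_ids[i])[[1L]])
    sub <- lk[lk$mesh_id == tab$mesh_id[i] & lk$gene_id %in% genes, ,
              drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      docs <- as.integer(.splitBar(sub$pubmed_ids[j])[[1L]])
      if (length(docs))
        out[[length(out) + 1L]] <- data.frame(
          pubmed_id = docs, gene_id = sub$gene_id[j],
          mesh_id = sub$mesh_id[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pubmed_id = integer(0), gene_id = integer(0),
                      mesh_id = character(0), stringsAsFactors = FALSE))
  rec <- unique(do.call(rbind, out))
  rec <- rec[.orderBy(rec, c("pubmed_id", "gene_id", "mesh_id")), ,
             drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Stub document fetcher
#'
#' Default offline fetcher: returns a small placeholder text for a given
#' PubMed id instead of retrieving anything. Real deployments inject
#' their own `function(pubmed_id)` returning the document payload as a
#' character scalar (and erroring on failure).
#'
#' @param pubmedId a single document id.
#' @return character payload.
#' @export
stubFetcher <- function(pubmedId) {
  paste0("placeholder document for PubMed ID ", pubmedId, "\n")
}

#' Organize fetched documents on disk
#'
#' Writes one file per (record, document) under a deterministic layout
#' `root/<by-value>/<pubmed_id>.txt`, where the grouping value is the
#' record's gene id, term id or document id. Retrieval goes exclusively
#' through the injected `fetcher`; a fetcher failure for one id is
#' recorded as `missing` in the manifest and the run continues.
#' Re-running over the same records reproduces the identical manifest.
#'
#' @param records `data.frame` from [collectDocRecords()].
#' @param root output directory (created if needed).
#' @param by grouping key: `"GENEID"`, `"MESHID"` or `"PUBMEDID"`.
#' @param fetcher `function(pubmed_id)` returning the document payload.
#' @return the manifest `data.frame` (columns `pubmed_id`, `gene_id`,
#'   `mesh_id`, `path`, `status`), also written to
#'   `root/manifest.tsv`.
#' @export
organizeDocs <- function(records, root, by = c("GENEID", "MESHID",
                                               "PUBMEDID"),
                         fetcher = stubFetcher) {
  by <- match.arg(by)
  stopifnot(is.function(fetcher))
  records <- unique(as.data.frame(records)[c("pubmed_id", "gene_id",
                                             "mesh_id")])
  records <- records[.orderBy(records, c("pubmed_id", "gene_id",
                                         "mesh_id")), , drop = FALSE]
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  groupOf <- switch(by,
                    GENEID = as.character(records$gene_id),
                    MESHID = records$mesh_id,
                    PUBMEDID = as.character(records$pubmed_id))
  paths <- character(nrow(records))
  status <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    dir <- file.path(root, groupOf[i])
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dest <- file.path(dir, paste0(records$pubmed_id[i], ".txt"))
    payload <- tryCatch(fetcher(records$pubmed_id[i]), error = function(e) NULL)
    if (is.null(payload)) {
      paths[i] <- NA_character_
      status[i] <- "missing"
    } else {
      writeLines(as.character(payload), dest, sep = "")
      paths[i] <- file.path(groupOf[i], paste0(records$pubmed_id[i], ".txt"))
      status[i] <- "ok"
    }
  }
  manifest <- data.frame(pubmed_id = records$pubmed_id,
                         gene_id = records$gene_id,
                         mesh_id = records$mesh_id,
                         path = paths, status = status,
                         stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  .writeTsv(manifest, file.path(root, "manifest.tsv"))
  manifest
}
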