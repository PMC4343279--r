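## MeshDb construction, hierarchy queries and the SELECT retrieval contract.

## Kahn topological sort; returns the order or stops naming a cycle member.
.topoOrder <- function(nodes, parent, child) {
  indeg <- structure(integer(length(nodes)), names = nodes)
  tab <- table(child)
  indeg[names(tab)] <- as.integer(tab)
  childrenOf <- split(child, factor(parent, levels = nodes))
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    n <- queue[1L]; queue <- queue[-1L]
    out <- c(out, n)
    for (ch in childrenOf[[n]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < length(nodes)) {
    stop("cycle detected in parent-child hierarchy involving term '",
         nodes[indeg > 0L][1L], "'")
  }
  out
}

## Strict transitive closure of the PCR DAG by dynamic programming over a
## reverse topological order: offspring(n) = children(n) U offspring(children).
.transitiveClosure <- function(nodes, edges) {
  if (!nrow(edges))
    return(data.frame(ancestor = character(0), offspring = character(0),
                      stringsAsFactors = FALSE))
  ord <- .topoOrder(nodes, edges$parent, edges$child)
  childrenOf <- split(edges$child, factor(edges$parent, levels = nodes))
  reach <- vector("list", length(nodes))
  names(reach) <- nodes
  for (n in rev(ord)) {
    kids <- childrenOf[[n]]
    reach[[n]] <- unique(c(kids, unlist(reach[kids], use.names = FALSE)))
  }
  nOff <- lengths(reach)
  out <- data.frame(ancestor = rep(nodes, nOff),
                    offspring = unlist(reach, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[.orderBy(out, c("ancestor", "offspring")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyLinks <- function() {
  data.frame(gene_id = integer(0), mesh_id = character(0),
             source = character(0), pubmed_ids = character(0),
             stringsAsFactors = FALSE)
}

.normTerms <- function(terms) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  for (col in c("qualifiers", "synonyms"))
    if (!col %in% names(terms)) terms[[col]] <- ""
  terms <- terms[c("mesh_id", "term", "category", "qualifiers", "synonyms")]
  terms$qualifiers[is.na(terms$qualifiers)] <- ""
  terms$synonyms[is.na(terms$synonyms)] <- ""
  terms[.orderBy(terms, "mesh_id"), , drop = FALSE]
}

.normLinks <- function(links) {
  if (is.null(links) || !NROW(links)) return(.emptyLinks())
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (!"pubmed_ids" %in% names(links)) links$pubmed_ids <- ""
  links$pubmed_ids[is.na(links$pubmed_ids)] <- ""
  links$gene_id <- as.integer(links$gene_id)
  links <- links[c("gene_id", "mesh_id", "source", "pubmed_ids")]
  links <- unique(links)
  links <- links[.orderBy(links, c("gene_id", "mesh_id", "source")), ,
                 drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Construct a MeshDb annotation store
#'
#' Assembles a validated [MeshDb] from a term vocabulary, direct
#' parent-child edges and gene-to-term links. Ancestor-offspring relations
#' are computed here as the strict transitive closure of the parent-child
#' edges; a cyclic edge set is rejected with the name of one term on the
#' cycle, and any edge or link referencing an unknown `mesh_id` is rejected
#' naming the offending identifier.
#'
#' @param terms `data.frame` with columns `mesh_id`, `term`, `category` and
#'   optionally `qualifiers`, `synonyms` (`|`-separated).
#' @param edges `data.frame` of direct parent-child edges with columns
#'   `parent`, `child` (may have zero rows).
#' @param links `data.frame` with columns `gene_id`, `mesh_id`, `source`
#'   and optionally `pubmed_ids` (`|`-separated), or `NULL`.
#' @param metadata named character vector of key/value annotations.
#'
#' @return A validated [MeshDb] object.
#' @examples
#' terms <- data.frame(mesh_id = c("D01", "D02", "D03"),
#'                     term = c("Root", "Mid", "Leaf"),
#'                     category = "D")
#' edges <- data.frame(parent = c("D01", "D02"), child = c("D02", "D03"))
#' db <- MeshDb(terms, edges,
#'              links = data.frame(gene_id = 101L, mesh_id = "D03",
#'                                 source = "gene2pubmed",
#'                                 pubmed_ids = "555"))
#' meshAncestors(db, "D03")
#' @export
MeshDb <- function(terms, edges, links = NULL, metadata = character()) {
  terms <- .normTerms(terms)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges))
    edges <- data.frame(parent = character(0), child = character(0),
                        stringsAsFactors = FALSE)
  edges <- unique(edges[c("parent", "child")])
  if (any(edges$parent == edges$child))
    stop("self-edge in hierarchy at term '",
         edges$parent[edges$parent == edges$child][1L], "'")
  dangling <- setdiff(unique(c(edges$parent, edges$child)), terms$mesh_id)
  if (length(dangling))
    stop("hierarchy edge references unknown mesh_id '", dangling[1L], "'")
  edges <- edges[.orderBy(edges, c("parent", "child")), , drop = FALSE]
  rownames(edges) <- NULL
  links <- .normLinks(links)
  unres <- setdiff(unique(links$mesh_id), terms$mesh_id)
  if (length(unres))
    stop("link references unknown mesh_id '", unres[1L], "'")
  aor <- .transitiveClosure(terms$mesh_id, edges)
  md <- as.character(metadata)
  names(md) <- names(metadata)
  rownames(terms) <- NULL
  new("MeshDb", terms = terms, pcr = edges, aor = aor, links = links,
      metadata = md)
}

#' @rdname accessors
#' @param db a [MeshDb].
#' @param relation which edge set to return: direct parent-child edges
#'   (`"PCR"`) or their transitive closure (`"AOR"`).
#' @return `meshTerms`, `meshEdges` and `meshLinks` return `data.frame`s;
#'   `meshMetadata` a named character vector.
#' @name accessors
#' @title MeshDb accessors
NULL

#' @rdname accessors
#' @export
setMethod("meshTerms", "MeshDb", function(db) db@terms)

#' @rdname accessors
#' @export
setMethod("meshEdges", "MeshDb", function(db, relation = c("PCR", "AOR")) {
  relation <- match.arg(relation)
  if (relation == "PCR") db@pcr else db@aor
})

#' @rdname accessors
#' @export
setMethod("meshLinks", "MeshDb", function(db) db@links)

#' @rdname accessors
#' @export
setMethod("meshMetadata", "MeshDb", function(db) db@metadata)

setMethod("show", "MeshDb", function(object) {
  cat("MeshDb annotation store\n")
  cat("  terms: ", nrow(object@terms), " (categories: ",
      paste(sort(unique(object@terms$category)), collapse = ""), ")\n",
      sep = "")
  cat("  hierarchy edges (PCR):", nrow(object@pcr),
      "| closure (AOR):", nrow(object@aor), "\n")
  cat("  gene-term links:", nrow(object@links), "| genes:",
      length(unique(object@links$gene_id)), "\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), object@metadata,
                             sep = "=", collapse = "; "), "\n")
})

.KEYTYPES <- c("GENEID", "MESHID", "MESHTERM", "MESHCATEGORY", "SOURCEID",
               "PUBMEDID")
.COLUMNS <- c("GENEID", "MESHID", "MESHTERM", "MESHCATEGORY", "QUALIFIER",
              "SYNONYM", "SOURCEID", "PUBMEDID")

#' Valid keytypes and columns of a MeshDb
#'
#' The SELECT interface addresses the store through a fixed relational
#' schema. `meshKeytypes` lists the column names usable as the match key;
#' `meshColumns` lists all retrievable columns (the multi-valued
#' `QUALIFIER`, `SYNONYM` and `PUBMEDID` columns are unnested into long
#' format when requested).
#'
#' @param db a [MeshDb].
#' @return character vector of valid names.
#' @name meshKeytypes
NULL

#' @rdname meshKeytypes
#' @export
setMethod("meshKeytypes", "MeshDb", function(db) .KEYTYPES)

#' @rdname meshKeytypes
#' @export
setMethod("meshColumns", "MeshDb", function(db) .COLUMNS)

## Build the joined term/link relation restricted to the needed schema
## columns, unnesting multi-valued columns on demand.
.selectRelation <- function(db, needed) {
  tm <- db@terms
  lk <- db@links
  base <- data.frame(
    MESHID = tm$mesh_id, MESHTERM = tm$term, MESHCATEGORY = tm$category,
    QUALIFIER = tm$qualifiers, SYNONYM = tm$synonyms,
    stringsAsFactors = FALSE)
  idx <- match(lk$mesh_id, tm$mesh_id)
  linkpart <- data.frame(
    GENEID = lk$gene_id, SOURCEID = lk$source, PUBMEDID = lk$pubmed_ids,
    stringsAsFactors = FALSE)
  joined <- cbind(base[idx, , drop = FALSE], linkpart)
  ## left join: keep vocabulary-only rows for terms without links
  unlinked <- !(tm$mesh_id %in% lk$mesh_id)
  if (any(unlinked)) {
    extra <- base[unlinked, , drop = FALSE]
    extra$GENEID <- NA_integer_
    extra$SOURCEID <- NA_character_
    extra$PUBMEDID <- ""
    joined <- rbind(joined, extra)
  }
  rownames(joined) <- NULL
  for (col in intersect(c("QUALIFIER", "SYNONYM", "PUBMEDID"), needed)) {
    vals <- .splitBar(joined[[col]])
    n <- pmax(lengths(vals), 1L)
    rep_idx <- rep(seq_len(nrow(joined)), n)
    flat <- unlist(lapply(vals, function(v)
      if (length(v)) v else NA_character_), use.names = FALSE)
    joined <- joined[rep_idx, , drop = FALSE]
    joined[[col]] <- flat
    rownames(joined) <- NULL
  }
  if ("PUBMEDID" %in% needed)
    joined$PUBMEDID <- suppressWarnings(as.integer(joined$PUBMEDID))
  joined
}

#' Retrieve annotation rows from a MeshDb
#'
#' A relational SELECT over the joined term/link table: rows whose
#' `keytype` column matches any of `keys` are returned with the requested
#' `cols`, in long format (duplicates preserved, multi-valued columns
#' unnested). Keys absent from the store simply contribute no rows. Row
#' order is deterministic: sorted by the keytype column, then by the
#' remaining requested columns, using C-locale radix order.
#'
#' @param db a [MeshDb].
#' @param keys vector of key values (coerced to the key column's type).
#' @param cols non-empty subset of `meshColumns(db)`.
#' @param keytype one of `meshKeytypes(db)`.
#' @return `data.frame` with columns `cols`, zero or more rows.
#' @examples
#' db <- MeshDb(data.frame(mesh_id = "D0001", term = "TermA", category = "D"),
#'              edges = NULL,
#'              links = data.frame(gene_id = 101L, mesh_id = "D0001",
#'                                 source = "gendoo", pubmed_ids = ""))
#' meshSelect(db, keys = 101, cols = "MESHID", keytype = "GENEID")
#' @export
setMethod("meshSelect", "MeshDb", function(db, keys, cols, keytype) {
  if (length(keytype) != 1L || !keytype %in% .KEYTYPES)
    stop("unknown keytype '", paste(keytype, collapse = ","),
         "'; valid keytypes: ", paste(.KEYTYPES, collapse = ", "))
  if (!length(cols) || !all(cols %in% .COLUMNS))
    stop("cols must be a non-empty subset of: ",
         paste(.COLUMNS, collapse = ", "))
  cols <- unique(cols)
  needed <- unique(c(keytype, cols))
  rel <- .selectRelation(db, needed)
  keycol <- rel[[keytype]]
  if (is.integer(keycol)) {
    keys <- suppressWarnings(as.integer(keys))
  } else {
    keys <- as.character(keys)
  }
  rel <- rel[keycol %in% keys, needed, drop = FALSE]
  ord <- .orderBy(rel, c(keytype, setdiff(cols, keytype)))
  rel <- rel[ord, cols, drop = FALSE]
  rownames(rel) <- NULL
  rel
})

.checkMeshId <- function(db, meshId) {
  if (length(meshId) != 1L || !meshId %in% db@terms$mesh_id)
    stop("unknown mesh_id '", paste(meshId, collapse = ","), "'")
  meshId
}

#' Hierarchy queries
#'
#' `meshParents`/`meshChildren` return the direct parent-child neighbours
#' of a term; `meshAncestors`/`meshOffspring` return all strict ancestors
#' or descendants under the transitive closure. A term occurring at several
#' positions of the poly-hierarchy can have multiple parents. The term
#' itself is never included in its own ancestors or offspring.
#'
#' @param db a [MeshDb].
#' @param meshId a single term identifier present in the store.
#' @return character vector of `mesh_id`s (sorted; possibly empty).
#' @name hierarchy
NULL

#' @rdname hierarchy
#' @export
setMethod("meshParents", "MeshDb", function(db, meshId) {
  .checkMeshId(db, meshId)
  sort(unique(db@pcr$parent[db@pcr$child == meshId]), method = "radix")
})

#' @rdname hierarchy
#' @export
setMethod("meshChildren", "MeshDb", function(db, meshId) {
  .checkMeshId(db, meshId)
  sort(unique(db@pcr$child[db@pcr$parent == meshId]), method = "radix")
})

#' @rdname hierarchy
#' @export
setMethod("meshAncestors", "MeshDb", function(db, meshId) {
  .checkMeshId(db, meshId)
  sort(unique(db@aor$ancestor[db@aor$offspring == meshId]), method = "radix")
})

#' @rdname hierarchy
#' @export
setMethod("meshOffspring", "MeshDb", function(db, meshId) {
  .checkMeshId(db, meshId)
  sort(unique(db@aor$offspring[db@aor$ancestor == meshId]), method = "radix")
})

#' Write / read a MeshDb store directory
#'
#' The on-disk representation is a directory of plain TSV tables
#' (`terms.tsv`, `edges_pcr.tsv`, `links.tsv`) plus a `manifest.txt` of
#' `key=value` metadata. Only the direct parent-child edges are stored;
#' the ancestor-offspring closure is recomputed on load, so a reloaded
#' store answers every query identically to the original.
#'
#' @param db a [MeshDb].
#' @param dir directory to create/read.
#' @return `writeMeshDb` returns `dir` invisibly; `readMeshDb` returns a
#'   [MeshDb].
#' @export
writeMeshDb <- function(db, dir) {
  stopifnot(is(db, "MeshDb"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(db@terms, file.path(dir, "terms.tsv"))
  edgesOut <- db@pcr
  names(edgesOut) <- c("parent_id", "child_id")
  .writeTsv(edgesOut, file.path(dir, "edges_pcr.tsv"))
  .writeTsv(db@links, file.path(dir, "links.tsv"))
  md <- c(format_version = "1", db@metadata)
  writeLines(paste0(names(md), "=", md), file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname writeMeshDb
#' @export
readMeshDb <- function(dir) {
  need <- file.path(dir, c("terms.tsv", "edges_pcr.tsv", "links.tsv",
                           "manifest.txt"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("not a MeshDb store directory; missing ", basename(missing)[1L])
  terms <- .readTsv(need[1L], colClasses = "character")
  edges <- .readTsv(need[2L], colClasses = "character")
  names(edges) <- sub("_id$", "", names(edges))
  links <- .readTsv(need[3L],
                    colClasses = c(gene_id = "integer", mesh_id = "character",
                                   source = "character",
                                   pubmed_ids = "character"))
  mdlines <- readLines(need[4L])
  mdlines <- mdlines[nzchar(mdlines)]
  kv <- regmatches(mdlines, regexpr("=", mdlines, fixed = TRUE),
                   invert = TRUE)
  md <- vapply(kv, `[`, character(1), 2L)
  names(md) <- vapply(kv, `[`, character(1), 1L)
  md <- md[names(md) != "format_version"]
  MeshDb(terms, edges, links, metadata = md)
}
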