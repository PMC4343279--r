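#' @import methods
NULL

#' MeshDb: an annotation store for gene-to-MeSH links
#'
#' A `MeshDb` bundles a MeSH term vocabulary, the parent-child hierarchy
#' over those terms, and a table of gene-to-term annotation links. The
#' hierarchy is a poly-hierarchy: a term may sit under several parents, so
#' parent-child relations (PCR) form a directed acyclic graph rather than a
#' tree. Ancestor-offspring relations (AOR) are not stored independently;
#' they are derived once, at construction time, as the strict transitive
#' closure of the PCR edges, which makes the AOR/PCR consistency invariant
#' hold by construction.
#'
#' Objects are created with [MeshDb()] (in-memory), [buildCustomStore()]
#' (from TSV files) or [readMeshDb()] (from a store directory); they are
#' treated as immutable thereafter.
#'
#' @slot terms `data.frame` with columns `mesh_id`, `term`, `category`,
#'   `qualifiers`, `synonyms` (the last two `|`-separated, possibly empty).
#' @slot pcr `data.frame` of direct edges with columns `parent`, `child`.
#' @slot aor `data.frame` of closure edges with columns `ancestor`,
#'   `offspring` (strict: no self pairs).
#' @slot links `data.frame` with columns `gene_id` (positive integer),
#'   `mesh_id`, `source` (one of `gendoo`, `gene2pubmed`, `RBBH`) and
#'   `pubmed_ids` (`|`-separated document ids, possibly empty).
#' @slot metadata named character vector of free-form key/value pairs
#'   (organism tag, build date, source versions, ...).
#'
#' @seealso [meshSelect()], [meshAncestors()], [writeMeshDb()]
#' @aliases MeshDb-class
#' @exportClass MeshDb
setClass("MeshDb",
  representation(terms = "data.frame",
                 pcr = "data.frame",
                 aor = "data.frame",
                 links = "data.frame",
                 metadata = "character"))

.validMeshDb <- function(object) {
  msg <- character(0)
  tm <- object@terms
  need <- c("mesh_id", "term", "category", "qualifiers", "synonyms")
  if (!all(need %in% names(tm)))
    return(paste("terms must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tm$mesh_id))
    msg <- c(msg, paste("duplicated mesh_id:",
                        tm$mesh_id[duplicated(tm$mesh_id)][1L]))
  if (any(is.na(tm$term) | tm$term == ""))
    msg <- c(msg, "every term needs a non-empty preferred label")
  badcat <- setdiff(unique(tm$category), .validCategoryCodes())
  if (length(badcat))
    msg <- c(msg, paste("invalid category code(s):",
                        paste(badcat, collapse = ", ")))
  ed <- object@pcr
  if (!all(c("parent", "child") %in% names(ed)))
    return("pcr must have columns parent, child")
  if (nrow(ed)) {
    if (any(ed$parent == ed$child))
      msg <- c(msg, "self-edge in hierarchy")
    dangling <- setdiff(unique(c(ed$parent, ed$child)), tm$mesh_id)
    if (length(dangling))
      msg <- c(msg, paste("hierarchy edge references unknown mesh_id:",
                          dangling[1L]))
  }
  lk <- object@links
  needl <- c("gene_id", "mesh_id", "source", "pubmed_ids")
  if (!all(needl %in% names(lk)))
    return(paste("links must have columns:", paste(needl, collapse = ", ")))
  if (nrow(lk)) {
    if (!is.integer(lk$gene_id) || any(is.na(lk$gene_id)) ||
        any(lk$gene_id < 1L))
      msg <- c(msg, "gene_id must be positive integers")
    badsrc <- setdiff(unique(lk$source), .validSources())
    if (length(badsrc))
      msg <- c(msg, paste("invalid link source(s):",
                          paste(badsrc, collapse = ", ")))
    unres <- setdiff(unique(lk$mesh_id), tm$mesh_id)
    if (length(unres))
      msg <- c(msg, paste("link references unknown mesh_id:", unres[1L]))
    if (anyDuplicated(lk[c("gene_id", "mesh_id", "source")]))
      msg <- c(msg, "duplicated (gene_id, mesh_id, source) link")
  }
  if (length(msg)) msg else TRUE
}

setValidity("MeshDb", .validMeshDb)

#' Parameters for a MeSH over-representation run
#'
#' Mirrors the parameter object of classic hypergeometric ORA tools: which
#' MeSH category to test, which annotation provenance(s) to trust, how to
#' correct for multiple testing across the terms of that category, and the
#' significance threshold applied to the corrected values.
#'
#' @slot category single MeSH category code (see [meshCategories()]).
#' @slot sources subset of `c("gendoo", "gene2pubmed", "RBBH")`.
#' @slot correction one of `"none"`, `"BH"`, `"QV"`, `"lFDR"`.
#' @slot threshold significance level in (0, 1) applied to the adjusted
#'   values (raw p-values when `correction = "none"`).
#'
#' @aliases MeshOraParams-class
#' @exportClass MeshOraParams
setClass("MeshOraParams",
  representation(category = "character",
                 sources = "character",
                 correction = "character",
                 threshold = "numeric"))

setValidity("MeshOraParams", function(object) {
  msg <- character(0)
  if (length(object@category) != 1L ||
      !object@category %in% .validCategoryCodes())
    msg <- c(msg, paste("category must be one of",
                        paste(.validCategoryCodes(), collapse = "")))
  if (!length(object@sources) ||
      !all(object@sources %in% .validSources()))
    msg <- c(msg, paste("sources must be a non-empty subset of",
                        paste(.validSources(), collapse = ", ")))
  if (length(object@correction) != 1L ||
      !object@correction %in% c("none", "BH", "QV", "lFDR"))
    msg <- c(msg, "correction must be one of none, BH, QV, lFDR")
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie strictly between 0 and 1")
  if (length(msg)) msg else TRUE
})

#' Result of a MeSH over-representation run
#'
#' One row per tested term, sorted by raw p-value (ties broken by
#' `mesh_id`). `N` is the number of universe genes carrying at least one
#' annotation in the tested category/source slice, `k` the selected genes
#' among them, `M` the universe genes annotated to the term and `x` the
#' selected genes annotated to it; `p_raw` is the upper-tail
#' hypergeometric probability of observing `x` or more.
#'
#' An empty table with `nothingTestable(x) == TRUE` is the explicit
#' "nothing testable" outcome returned when no selected gene carries any
#' annotation in the requested slice.
#'
#' @slot table `data.frame` with columns `mesh_id`, `term`, `category`,
#'   `N`, `k`, `M`, `x`, `p_raw`, `p_adjusted`, `method`, `significant`,
#'   `gene_ids` (`|`-separated).
#' @slot params the [MeshOraParams] used.
#' @slot nUniverse,nSelected annotated universe size `N` and annotated
#'   selected count `k`.
#' @slot pi0 the null-proportion estimate used by the `QV` correction
#'   (`NA` otherwise).
#'
#' @aliases MeshOraResult-class
#' @exportClass MeshOraResult
setClass("MeshOraResult",
  representation(table = "data.frame",
                 params = "MeshOraParams",
                 nUniverse = "integer",
                 nSelected = "integer",
                 pi0 = "numeric"))

#' Adjusted p-values from a multiple-testing correction
#'
#' Container returned by [bhAdjust()], [qvalueAdjust()] and [localFdr()].
#' `values` is aligned to the input order; `reject` flags hypotheses whose
#' adjusted value falls strictly below `alpha`.
#'
#' @slot method `"BH"`, `"QV"` or `"lFDR"`.
#' @slot values adjusted values in `[0, 1]`, input order.
#' @slot alpha the threshold used for the reject calls.
#' @slot pi0 null-proportion estimate used (`1` for plain BH).
#' @slot reject logical vector aligned to `values`.
#'
#' @aliases AdjustedPvalues-class
#' @exportClass AdjustedPvalues
setClass("AdjustedPvalues",
  representation(method = "character",
                 values = "numeric",
                 alpha = "numeric",
                 pi0 = "numeric",
                 reject = "logical"))

setValidity("AdjustedPvalues", function(object) {
  if (any(object@values < 0 | object@values > 1, na.rm = TRUE))
    return("adjusted values must lie in [0, 1]")
  if (length(object@reject) != length(object@values))
    return("reject must align with values")
  TRUE
})
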