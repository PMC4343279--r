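#' @rdname meshSelect
#' @export
setGeneric("meshSelect", function(db, keys, cols, keytype)
  standardGeneric("meshSelect"))

#' @rdname meshKeytypes
#' @export
setGeneric("meshKeytypes", function(db) standardGeneric("meshKeytypes"))

#' @rdname meshKeytypes
#' @export
setGeneric("meshColumns", function(db) standardGeneric("meshColumns"))

#' @rdname hierarchy
#' @export
setGeneric("meshParents", function(db, meshId) standardGeneric("meshParents"))

#' @rdname hierarchy
#' @export
setGeneric("meshChildren", function(db, meshId) standardGeneric("meshChildren"))

#' @rdname hierarchy
#' @export
setGeneric("meshAncestors", function(db, meshId)
  standardGeneric("meshAncestors"))

#' @rdname hierarchy
#' @export
setGeneric("meshOffspring", function(db, meshId)
  standardGeneric("meshOffspring"))

#' @rdname accessors
#' @export
setGeneric("meshTerms", function(db) standardGeneric("meshTerms"))

#' @rdname accessors
#' @export
setGeneric("meshEdges", function(db, relation = c("PCR", "AOR"))
  standardGeneric("meshEdges"))

#' @rdname accessors
#' @export
setGeneric("meshLinks", function(db) standardGeneric("meshLinks"))

#' @rdname accessors
#' @export
setGeneric("meshMetadata", function(db) standardGeneric("meshMetadata"))

#' @rdname MeshOraResult-accessors
#' @export
setGeneric("oraTable", function(x) standardGeneric("oraTable"))

#' @rdname MeshOraResult-accessors
#' @export
setGeneric("oraParams", function(x) standardGeneric("oraParams"))

#' @rdname MeshOraResult-accessors
#' @export
setGeneric("significantTerms", function(x) standardGeneric("significantTerms"))

#' @rdname MeshOraResult-accessors
#' @export
setGeneric("nothingTestable", function(x) standardGeneric("nothingTestable"))

#' @rdname AdjustedPvalues-accessors
#' @export
setGeneric("adjustedValues", function(x) standardGeneric("adjustedValues"))

#' @rdname AdjustedPvalues-accessors
#' @export
setGeneric("rejected", function(x) standardGeneric("rejected"))
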