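## Hypergeometric over-representation core.

.checkCounts <- function(N, k, M, x) {
  n <- max(length(N), length(k), length(M), length(x))
  N <- rep_len(N, n); k <- rep_len(k, n)
  M <- rep_len(M, n); x <- rep_len(x, n)
  if (any(c(N, k, M, x) < 0)) stop("counts must be non-negative")
  if (any(M > N)) stop("invariant violated: M <= N")
  if (any(k > N)) stop("invariant violated: k <= N")
  if (any(x > pmin(k, M))) stop("invariant violated: x <= min(k, M)")
  if (any(k - x > N - M)) stop("invariant violated: k - x <= N - M")
  list(N = N, k = k, M = M, x = x)
}

#' Hypergeometric point probability
#'
#' Probability of drawing exactly `x` annotated genes when `k` genes are
#' drawn without replacement from a universe of `N` genes of which `M`
#' carry the annotation:
#' `P(X = x) = choose(M, x) * choose(N - M, k - x) / choose(N, k)`,
#' evaluated in log-factorial arithmetic for numerical stability. The
#' point masses over all feasible `x` sum to one.
#'
#' @param N universe size; @param k number of selected genes;
#' @param M universe genes annotated to the term;
#' @param x selected genes annotated to the term. All vectorised.
#' @return numeric probability vector.
#' @examples
#' hypergeomPmf(10, 4, 5, 4)  # 1/42
#' @export
hypergeomPmf <- function(N, k, M, x) {
  cc <- .checkCounts(N, k, M, x)
  exp(lchoose(cc$M, cc$x) + lchoose(cc$N - cc$M, cc$k - cc$x) -
        lchoose(cc$N, cc$k))
}

#' Upper-tail hypergeometric enrichment probability
#'
#' The enrichment p-value reported for a term is the upper tail
#' `P(X >= x)`, i.e. the probability of observing an overlap at least as
#' large as the one seen — the convention followed by classical ORA
#' engines, not the bare point mass (see the package vignette; the point
#' mass is available separately as [hypergeomPmf()]). With `x = 0` the
#' tail is 1.
#'
#' @inheritParams hypergeomPmf
#' @return numeric probability vector in (0, 1].
#' @examples
#' hypergeomPvalue(10, 4, 5, 4)  # 1/42: the tail is a single point here
#' @export
hypergeomPvalue <- function(N, k, M, x) {
  cc <- .checkCounts(N, k, M, x)
  vapply(seq_along(cc$N), function(i) {
    hi <- min(cc$k[i], cc$M[i])
    j <- cc$x[i]:hi
    min(1, sum(exp(lchoose(cc$M[i], j) +
                     lchoose(cc$N[i] - cc$M[i], cc$k[i] - j) -
                     lchoose(cc$N[i], cc$k[i]))))
  }, numeric(1))
}

#' Construct parameters for a MeSH over-representation run
#'
#' @param category single MeSH category code to test (see
#'   [meshCategories()]).
#' @param sources annotation provenances to use, subset of
#'   `c("gendoo", "gene2pubmed", "RBBH")` (default: all three).
#' @param correction multiple-testing correction across the tested terms:
#'   `"none"`, `"BH"`, `"QV"` (q-value) or `"lFDR"` (local FDR).
#' @param threshold significance level in (0, 1) applied to the adjusted
#'   values.
#' @return a [MeshOraParams] object.
#' @examples
#' MeshOraParams("D", sources = "gendoo", correction = "QV",
#'               threshold = 0.05)
#' @export
MeshOraParams <- function(category, sources = .validSources(),
                          correction = c("BH", "none", "QV", "lFDR"),
                          threshold = 0.05) {
  correction <- match.arg(correction)
  new("MeshOraParams", category = as.character(category),
      sources = as.character(sources), correction = correction,
      threshold = as.numeric(threshold))
}

setMethod("show", "MeshOraParams", function(object) {
  cat("MeshOraParams: category", object@category,
      "| sources:", paste(object@sources, collapse = ","),
      "| correction:", object@correction,
      "| threshold:", object@threshold, "\n")
})

.ORA_COLUMNS <- c("mesh_id", "term", "category", "N", "k", "M", "x",
                  "p_raw", "p_adjusted", "method", "significant", "gene_ids")

.emptyOraTable <- function() {
  data.frame(mesh_id = character(0), term = character(0),
             category = character(0), N = integer(0), k = integer(0),
             M = integer(0), x = integer(0), p_raw = numeric(0),
             p_adjusted = numeric(0), method = character(0),
             significant = logical(0), gene_ids = character(0),
             stringsAsFactors = FALSE)
}

#' MeSH term over-representation test
#'
#' Tests every MeSH term of one category for over-representation among a
#' selected gene list, relative to a gene universe, with the upper-tail
#' hypergeometric test. The store's links are first restricted to the
#' requested category and annotation sources; the effective universe size
#' `N` counts only universe genes carrying at least one such link (genes
#' without any annotation in the slice carry no information for the
#' test), and `k` counts the selected genes among them. One test is run
#' per term annotating at least one universe gene, and the chosen
#' correction is applied across exactly that family of tests. Rows are
#' sorted by raw p-value, ties broken by `mesh_id`, and flagged
#' significant when the adjusted value falls strictly below the
#' threshold.
#'
#' If no selected gene carries any annotation in the slice the run
#' returns an explicit empty result (`nothingTestable(x)` is `TRUE`)
#' rather than failing.
#'
#' @param db a [MeshDb].
#' @param universe integer vector of all candidate gene ids.
#' @param selected integer vector of genes of interest; must be a subset
#'   of `universe`.
#' @param params a [MeshOraParams].
#' @param fdrEngine optional override: a `function(p)` returning adjusted
#'   values aligned to `p`, used in place of the built-in correction.
#' @return a [MeshOraResult].
#' @seealso [hypergeomPvalue()], [bhAdjust()], [qvalueAdjust()],
#'   [localFdr()], [termWeights()]
#' @export
meshHyperGTest <- function(db, universe, selected, params,
                           fdrEngine = NULL) {
  stopifnot(is(db, "MeshDb"), is(params, "MeshOraParams"))
  validObject(params)
  universe <- unique(as.integer(universe))
  selected <- unique(as.integer(selected))
  if (!length(universe) || !length(selected))
    stop("universe and selected gene lists must be non-empty")
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  lk <- db@links
  lk <- lk[lk$source %in% params@sources, , drop = FALSE]
  cat_of <- db@terms$category[match(lk$mesh_id, db@terms$mesh_id)]
  lk <- lk[cat_of == params@category, , drop = FALSE]
  lk <- lk[lk$gene_id %in% universe, , drop = FALSE]
  annotated <- unique(lk$gene_id)
  N <- length(annotated)
  selAnnot <- intersect(selected, annotated)
  k <- length(selAnnot)
  if (N == 0L || k == 0L) {
    return(new("MeshOraResult", table = .emptyOraTable(), params = params,
               nUniverse = N, nSelected = k, pi0 = NA_real_))
  }
  perTerm <- split(lk$gene_id, lk$mesh_id)
  meshIds <- names(perTerm)
  M <- vapply(perTerm, function(g) length(unique(g)), integer(1))
  hitGenes <- lapply(perTerm, function(g)
    sort(unique(g[g %in% selAnnot])))
  x <- lengths(hitGenes)
  p <- hypergeomPvalue(N, k, M, x)
  pi0 <- NA_real_
  if (!is.null(fdrEngine)) {
    padj <- fdrEngine(p)
    method <- "custom"
  } else if (params@correction == "none") {
    padj <- p
    method <- "none"
  } else if (params@correction == "BH") {
    padj <- adjustedValues(bhAdjust(p, alpha = params@threshold))
    method <- "BH"
  } else if (params@correction == "QV") {
    adj <- qvalueAdjust(p, alpha = params@threshold)
    padj <- adjustedValues(adj)
    pi0 <- adj@pi0
    method <- "QV"
  } else {
    adj <- localFdr(p, alpha = params@threshold)
    padj <- adjustedValues(adj)
    pi0 <- adj@pi0
    method <- "lFDR"
  }
  tab <- data.frame(
    mesh_id = meshIds,
    term = db@terms$term[match(meshIds, db@terms$mesh_id)],
    category = params@category,
    N = N, k = k, M = unname(M), x = unname(x),
    p_raw = unname(p), p_adjusted = unname(padj), method = method,
    significant = (params@threshold - unname(padj)) > 1e-12,
    gene_ids = vapply(hitGenes, function(g) paste(g, collapse = "|"),
                      character(1)),
    stringsAsFactors = FALSE)
  ## order by p ascending, ties by mesh_id; radix on the formatted p keeps
  ## the comparison exact
  tab <- tab[order(tab$p_raw, tab$mesh_id, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  new("MeshOraResult", table = tab, params = params,
      nUniverse = N, nSelected = k, pi0 = pi0)
}

#' MeshOraResult accessors
#'
#' `oraTable` returns the per-term result table, `significantTerms` the
#' `mesh_id`s flagged significant, `nothingTestable` whether the run had
#' no testable annotation overlap.
#'
#' @param x a [MeshOraResult].
#' @name MeshOraResult-accessors
NULL

#' @rdname MeshOraResult-accessors
#' @export
setMethod("oraTable", "MeshOraResult", function(x) x@table)

#' @rdname MeshOraResult-accessors
#' @export
setMethod("oraParams", "MeshOraResult", function(x) x@params)

#' @rdname MeshOraResult-accessors
#' @export
setMethod("significantTerms", "MeshOraResult", function(x)
  x@table$mesh_id[x@table$significant])

#' @rdname MeshOraResult-accessors
#' @export
setMethod("nothingTestable", "MeshOraResult", function(x)
  nrow(x@table) == 0L)

setMethod("show", "MeshOraResult", function(object) {
  cat("MeSH over-representation result\n")
  show(object@params)
  if (nothingTestable(object)) {
    cat("  nothing testable: no selected gene carries an annotation in",
        "this category/source slice\n")
    return(invisible(NULL))
  }
  cat("  annotated universe N =", object@nUniverse,
      "| annotated selected k =", object@nSelected, "\n")
  cat("  terms tested:", nrow(object@table),
      "| significant:", sum(object@table$significant), "\n")
  if (!is.na(object@pi0)) cat("  pi0 estimate:", round(object@pi0, 4), "\n")
  print(utils::head(object@table[c("mesh_id", "term", "M", "x", "p_raw",
                                   "p_adjusted", "significant")], 5L))
})

#' Tag-cloud weights from enrichment p-values
#'
#' Enrichment displays scale term labels by `-log10` of the raw p-value;
#' `p = 1` maps to weight 0 and smaller p-values to larger weights.
#'
#' @param x a [MeshOraResult] or a named numeric vector of p-values.
#' @return named numeric vector of weights (names are `mesh_id`s).
#' @export
termWeights <- function(x) {
  if (is(x, "MeshOraResult")) {
    p <- x@table$p_raw
    names(p) <- x@table$mesh_id
  } else {
    p <- x
  }
  if (any(p <= 0)) stop("p-values must be strictly positive")
  if (any(p > 1)) stop("p-values must not exceed 1")
  -log10(p)
}

#' Write / read an over-representation report
#'
#' Serialises the per-term result table with a stable column order to TSV
#' or JSON. Numeric columns are written with full (round-trip-exact)
#' precision, so serialise -> parse -> serialise is byte-identical.
#'
#' @param x a [MeshOraResult] or a report `data.frame`.
#' @param file output path.
#' @param format `"tsv"` or `"json"`.
#' @return `writeOraReport` returns `file` invisibly; `readOraReport`
#'   returns the report `data.frame`.
#' @export
writeOraReport <- function(x, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- if (is(x, "MeshOraResult")) x@table else as.data.frame(x)
  stopifnot(identical(names(tab), .ORA_COLUMNS))
  if (format == "tsv") {
    .writeTsv(tab, file)
  } else {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeLines(jsonlite::toJSON(tab, dataframe = "rows", digits = NA,
                                na = "null", pretty = TRUE), con)
  }
  invisible(file)
}

#' @rdname writeOraReport
#' @export
readOraReport <- function(file, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- .readTsv(file, colClasses = c(
      mesh_id = "character", term = "character", category = "character",
      N = "integer", k = "integer", M = "integer", x = "integer",
      p_raw = "numeric", p_adjusted = "numeric", method = "character",
      significant = "logical", gene_ids = "character"))
    tab$gene_ids[is.na(tab$gene_ids)] <- ""
  } else {
    tab <- jsonlite::fromJSON(file)
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
    if (!nrow(tab)) tab <- .emptyOraTable()
    tab$gene_ids[is.na(tab$gene_ids)] <- ""
  }
  stopifnot(identical(names(tab), .ORA_COLUMNS))
  tab
}
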