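## Reciprocal best-hit orthology at desk scale: exact Smith-Waterman local
## alignment (BLOSUM62, affine gaps) in place of a heuristic search engine;
## the best-hit and reciprocity logic is what matters for annotation
## transfer, and at these problem sizes the exact aligner is affordable.

.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V","X")

#' Alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties used by [alignScore()]
#' and the best-hit searches. The defaults (BLOSUM62, gap open 11, gap
#' extend 1) are the classic protein-search settings; a gap of length L
#' costs `gapOpen + L * gapExtend`.
#'
#' @param matrix substitution matrix name (resolved from the matrices
#'   shipped with Biostrings) or a numeric matrix.
#' @param gapOpen,gapExtend non-negative gap penalties.
#' @return a list with elements `matrix`, `gapOpen`, `gapExtend`.
#' @export
alignScoring <- function(matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), gapOpen >= 0, gapExtend >= 0)
  list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend)
}

.checkProtein <- function(x) {
  seqs <- if (is(x, "AAStringSet") || is(x, "AAString")) as.character(x)
          else as.character(x)
  chars <- unique(unlist(strsplit(seqs, ""), use.names = FALSE))
  bad <- setdiff(chars, .AA_ALPHABET)
  if (length(bad))
    stop("invalid amino-acid residue(s): ", paste(bad, collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty protein sequence")
  seqs
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two protein sequences under the given
#' scoring scheme. The score is symmetric in its arguments and a sequence
#' aligned against itself attains the maximal score over all subjects of
#' equal length. Sequences must use the 20 standard residues plus `X`.
#'
#' @param a,b protein sequences (character or `Biostrings::AAString`).
#' @param scoring an [alignScoring()] list.
#' @return a single numeric score (>= 0).
#' @examples
#' alignScore("MKV", "MKV")  # BLOSUM62 diagonal: 5 + 5 + 4
#' @export
alignScore <- function(a, b, scoring = alignScoring()) {
  a <- .checkProtein(a)[1L]
  b <- .checkProtein(b)[1L]
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend,
    scoreOnly = TRUE)
}

## |A| x |B| local-alignment score matrix, vectorised over patterns.
.scoreMatrix <- function(A, B, scoring) {
  A <- Biostrings::AAStringSet(A)
  B <- Biostrings::AAStringSet(B)
  .checkProtein(A); .checkProtein(B)
  if (is.null(names(A)) || is.null(names(B)) ||
      anyDuplicated(names(A)) || anyDuplicated(names(B)))
    stop("protein sets must carry unique sequence ids as names")
  S <- matrix(0, nrow = length(A), ncol = length(B),
              dimnames = list(names(A), names(B)))
  for (j in seq_along(B)) {
    S[, j] <- Biostrings::pairwiseAlignment(
      A, B[[j]], type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend,
      scoreOnly = TRUE)
  }
  S
}

#' Best-hit search between two protein sets
#'
#' For every query in `A` with at least one subject scoring positively and
#' at least `minScore`, reports the maximal-scoring subject in `B`. Ties
#' are broken deterministically by the lexicographically smallest subject
#' id.
#'
#' @param A,B named character vectors or `AAStringSet`s of protein
#'   sequences; names are the gene ids.
#' @param scoring an [alignScoring()] list.
#' @param minScore minimum alignment score for a hit to count; the
#'   default 0 keeps every positive-scoring hit (mirroring a search run
#'   at an extremely permissive significance cutoff).
#' @return named character vector mapping query id to best-subject id.
#' @export
bestHits <- function(A, B, scoring = alignScoring(), minScore = 0) {
  if (!length(A) || !length(B)) return(structure(character(0), names = character(0)))
  S <- .scoreMatrix(A, B, scoring)
  subjects <- colnames(S)[order(colnames(S), method = "radix")]
  S <- S[, subjects, drop = FALSE]
  hits <- apply(S, 1L, function(row) {
    ok <- row > 0 & row >= minScore
    if (!any(ok)) return(NA_character_)
    cand <- which(ok)
    subjects[cand[which.max(row[cand])]]  # first max = smallest id (sorted)
  })
  hits[!is.na(hits)]
}

#' Reciprocal best hits between two protein sets
#'
#' A pair (a, b) is emitted iff b is a's best hit in `B` *and* a is b's
#' best hit in `A` (each after deterministic tie-breaking). This is the
#' standard orthology proxy used to transfer annotations between
#' organisms. The result is invariant under swapping `A` and `B` up to
#' the orientation of the pairs, and raising `minScore` can only remove
#' pairs.
#'
#' @inheritParams bestHits
#' @return `data.frame` with columns `id_a`, `id_b`, `score_ab`,
#'   `score_ba`, sorted by `id_a`.
#' @seealso [transferByRbbh()] to project annotations over the pairs,
#'   [planComparisons()] for the size of an all-vs-all campaign.
#' @export
reciprocalBestHits <- function(A, B, scoring = alignScoring(), minScore = 0) {
  ab <- bestHits(A, B, scoring, minScore)
  ba <- bestHits(B, A, scoring, minScore)
  keep <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  keep <- sort(keep, method = "radix")
  if (!length(keep))
    return(data.frame(id_a = character(0), id_b = character(0),
                      score_ab = numeric(0), score_ba = numeric(0),
                      stringsAsFactors = FALSE))
  idb <- unname(ab[keep])
  sab <- mapply(function(i, j) alignScore(as.character(Biostrings::AAStringSet(A)[[i]]),
                                          as.character(Biostrings::AAStringSet(B)[[j]]),
                                          scoring),
                keep, idb)
  data.frame(id_a = keep, id_b = idb,
             score_ab = unname(sab), score_ba = unname(sab),
             stringsAsFactors = FALSE)
}

#' Size of an all-vs-all reciprocal search campaign
#'
#' Comparing every one of `nMinor` query organisms against every one of
#' `nMajor` reference organisms in both directions requires
#' `2 * nMinor * nMajor` directed search runs.
#'
#' @param nMinor,nMajor positive organism counts.
#' @return integer count of directed runs.
#' @examples
#' planComparisons(100, 15)  # 3000
#' @export
planComparisons <- function(nMinor, nMajor) {
  if (length(nMinor) != 1L || length(nMajor) != 1L ||
      is.na(nMinor) || is.na(nMajor) || nMinor < 1 || nMajor < 1 ||
      nMinor != floor(nMinor) || nMajor != floor(nMajor))
    stop("organism counts must be positive integers")
  as.integer(2 * nMinor * nMajor)
}

#' Karlin-Altschul style E-value proxy
#'
#' A monotone significance proxy for a local alignment score `S` between
#' sequences of lengths `m` and `n`: `E = K * m * n * exp(-lambda * S)`.
#' The default `K` and `lambda` are the customary gapped BLOSUM62 values;
#' the proxy orders hits the same way the score does and is offered only
#' for expressing permissive cutoffs on the familiar E-value scale.
#'
#' @param score alignment score(s).
#' @param m,n sequence lengths.
#' @param K,lambda Karlin-Altschul parameters.
#' @return numeric E-value proxy, same length as `score`.
#' @export
evalueProxy <- function(score, m, n, K = 0.041, lambda = 0.267) {
  K * m * n * exp(-lambda * score)
}

#' Write / read reciprocal best-hit pairs
#'
#' Pairs travel as TSV with columns `id_a`, `id_b`, `score_ab`,
#' `score_ba`.
#'
#' @param pairs `data.frame` from [reciprocalBestHits()].
#' @param file path.
#' @return `writeRbbhPairs` returns `file` invisibly.
#' @export
writeRbbhPairs <- function(pairs, file) {
  .writeTsv(pairs, file)
}

#' @rdname writeRbbhPairs
#' @export
readRbbhPairs <- function(file) {
  df <- .readTsv(file, colClasses = c(id_a = "character", id_b = "character",
                                      score_ab = "numeric",
                                      score_ba = "numeric"))
  .requireCols(df, file, c("id_a", "id_b"))
  df
}
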