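## Synthetic fixture generators: a small MeSH-like vocabulary with a
## poly-hierarchy, random gene-term annotations with an optionally planted
## enriched term, p-value mixtures for the FDR layer, and mutated proteome
## pairs for the reciprocal-best-hit layer. Every generator is a pure
## function of its parameters and seed.

.QUALIFIER_POOL <- c("genetics", "metabolism", "pathology", "physiology",
                     "drug effects", "chemistry", "immunology")

#' Specification of a synthetic annotation fixture
#'
#' Bundles the knobs of the fixture generators. The defaults describe the
#' benchmark condition used throughout the package's recovery tests: a
#' universe of 2000 genes, 200 terms spread over the 16 MeSH categories,
#' an independent-link annotation density of 0.05, a baseline
#' gene-selection rate of 0.05 and a planted enrichment odds multiplier
#' of 8 on the genes of one designated term.
#'
#' @param nGenes,nTerms positive counts.
#' @param categories category codes to draw term categories from (subset
#'   of the 16 valid codes).
#' @param density probability in (0, 1) that a given (gene, term) link
#'   exists, independently.
#' @param plantedTerm `mesh_id` of the enriched term, `"auto"` to let
#'   [makeStudy()] pick a typical term, or `NULL` for a null fixture.
#' @param plantedEffect odds multiplier >= 1 applied to the selection
#'   probability of genes annotated to the planted term.
#' @param baseRate baseline probability that a gene is selected as
#'   "interesting".
#' @param seed integer seed making every generator deterministic.
#' @return a list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(nGenes = 2000, nTerms = 200,
                        categories = .validCategoryCodes(),
                        density = 0.05, plantedTerm = "auto",
                        plantedEffect = 8, baseRate = 0.05, seed = 1L) {
  stopifnot(nGenes >= 1, nTerms >= 1,
            density > 0, density < 1,
            plantedEffect >= 1,
            baseRate > 0, baseRate < 1)
  .checkCategoryCodes(categories)
  structure(list(nGenes = as.integer(nGenes), nTerms = as.integer(nTerms),
                 categories = categories, density = density,
                 plantedTerm = plantedTerm, plantedEffect = plantedEffect,
                 baseRate = baseRate, seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Generate a synthetic MeSH-like vocabulary
#'
#' Terms are laid out in a random directed acyclic graph: each term after
#' the first receives one parent among the earlier terms and roughly 10%
#' of terms receive a second, distinct parent, producing the multi-parent
#' (poly-hierarchy) structure characteristic of MeSH. Categories are
#' drawn from the codes in the spec; qualifier and synonym sets are small
#' random samples from fixed pools.
#'
#' @param spec a [fixtureSpec()].
#' @return list with elements `terms` (vocabulary `data.frame`) and
#'   `edges` (`parent`/`child` `data.frame`), suitable for [MeshDb()].
#' @export
makeVocabulary <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  withSeed(spec$seed, {
    n <- spec$nTerms
    ids <- sprintf("D%06d", seq_len(n))
    cats <- sample(spec$categories, n, replace = TRUE)
    quals <- vapply(seq_len(n), function(i)
      paste(sort(sample(.QUALIFIER_POOL, sample(0:3, 1))), collapse = "|"),
      character(1))
    syns <- ifelse(stats::runif(n) < 0.3,
                   paste0("synthetic synonym ", ids), "")
    terms <- data.frame(mesh_id = ids,
                        term = paste("Synthetic term", ids),
                        category = cats, qualifiers = quals,
                        synonyms = syns, stringsAsFactors = FALSE)
    if (n == 1L) {
      edges <- data.frame(parent = character(0), child = character(0),
                          stringsAsFactors = FALSE)
    } else {
      first <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
      edges <- data.frame(parent = ids[first], child = ids[2:n],
                          stringsAsFactors = FALSE)
      extra <- which(2:n >= 3L & stats::runif(n - 1L) < 0.10)
      for (e in extra) {
        i <- e + 1L  # child index in ids
        cand <- setdiff(seq_len(i - 1L), first[e])
        if (length(cand))
          edges <- rbind(edges, data.frame(
            parent = ids[cand[sample.int(length(cand), 1L)]],
            child = ids[i], stringsAsFactors = FALSE))
      }
    }
    list(terms = terms, edges = edges)
  })
}

#' Generate random gene-to-term annotations
#'
#' Every (gene, term) pair is linked independently with probability
#' `spec$density`; each link carries a small random set of 1-3 synthetic
#' document ids. Gene ids are `1..nGenes`.
#'
#' @param spec a [fixtureSpec()].
#' @param vocabulary output of [makeVocabulary()].
#' @param source provenance label for the generated links.
#' @return links `data.frame` (`gene_id`, `mesh_id`, `source`,
#'   `pubmed_ids`).
#' @export
makeAnnotations <- function(spec, vocabulary, source = "gene2pubmed") {
  stopifnot(inherits(spec, "FixtureSpec"))
  source <- match.arg(source, .validSources())
  withSeed(spec$seed + 1L, {
    ids <- vocabulary$terms$mesh_id
    hit <- which(stats::runif(spec$nGenes * length(ids)) < spec$density)
    if (!length(hit)) return(.emptyLinks())
    gene <- ((hit - 1L) %% spec$nGenes) + 1L
    term <- ids[((hit - 1L) %/% spec$nGenes) + 1L]
    ndoc <- sample(1:3, length(hit), replace = TRUE)
    docs <- sample.int(999999L, sum(ndoc), replace = TRUE)
    pub <- vapply(split(docs, rep(seq_along(ndoc), ndoc)), function(d)
      paste(sort(unique(d)), collapse = "|"), character(1))
    out <- data.frame(gene_id = gene, mesh_id = term, source = source,
                      pubmed_ids = unname(pub), stringsAsFactors = FALSE)
    out <- out[.orderBy(out, c("gene_id", "mesh_id")), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

## deterministic "typical" planted term: the one whose annotation count is
## closest to the median (ties by mesh_id)
.autoPlantedTerm <- function(links) {
  M <- table(links$mesh_id)
  med <- stats::median(as.numeric(M))
  cand <- names(M)[order(abs(as.numeric(M) - med), names(M),
                         method = "radix")]
  cand[1L]
}

#' Generate a study: universe and selected gene list
#'
#' Emulates the "interesting gene list from an omics analysis" input of
#' an ORA run. The universe is all `nGenes` genes; each gene is selected
#' independently with baseline probability `baseRate`, except that genes
#' annotated to the planted term have their selection *odds* multiplied
#' by `plantedEffect` — with effect 1 the selection is independent of the
#' annotation. Ground-truth labels are returned for scoring.
#'
#' @param spec a [fixtureSpec()].
#' @param annotations links from [makeAnnotations()].
#' @return list with `universe` (integer vector), `selected` (integer
#'   vector), `plantedTerm` (`mesh_id` or `NA`), and `truth`
#'   (`data.frame` with `gene_id`, `planted`, `selected`).
#' @export
makeStudy <- function(spec, annotations) {
  stopifnot(inherits(spec, "FixtureSpec"))
  planted <- spec$plantedTerm
  if (!is.null(planted) && identical(planted, "auto"))
    planted <- if (nrow(annotations)) .autoPlantedTerm(annotations) else NULL
  if (!is.null(planted) && !planted %in% annotations$mesh_id)
    stop("planted term '", planted, "' has no annotations in this fixture")
  withSeed(spec$seed + 2L, {
    universe <- seq_len(spec$nGenes)
    inPlanted <- if (is.null(planted)) rep(FALSE, spec$nGenes) else
      universe %in% annotations$gene_id[annotations$mesh_id == planted]
    odds <- spec$baseRate / (1 - spec$baseRate)
    odds <- ifelse(inPlanted, odds * spec$plantedEffect, odds)
    prob <- odds / (1 + odds)
    sel <- stats::runif(spec$nGenes) < prob
    list(universe = universe,
         selected = universe[sel],
         plantedTerm = if (is.null(planted)) NA_character_ else planted,
         truth = data.frame(gene_id = universe, planted = inPlanted,
                            selected = sel))
  })
}

#' Generate a p-value mixture with ground-truth labels
#'
#' Null hypotheses contribute Uniform(0, 1) p-values and alternatives
#' contribute Beta(`altShape`, 1) p-values (concentrated near 0 for
#' `altShape < 1`); each hypothesis is null independently with
#' probability `pi0`. The labels allow false-discovery scoring of the
#' correction methods.
#'
#' @param m number of hypotheses.
#' @param pi0 null proportion in `[0, 1]`.
#' @param altShape Beta shape of the alternative p-values (default 0.1).
#' @param seed integer seed.
#' @return list with `p` (numeric vector) and `is_null` (logical vector).
#' @export
makePvalueMixture <- function(m, pi0, altShape = 0.1, seed = 1L) {
  stopifnot(m >= 1, pi0 >= 0, pi0 <= 1, altShape > 0)
  withSeed(seed, {
    isNull <- stats::runif(m) < pi0
    p <- numeric(m)
    p[isNull] <- stats::runif(sum(isNull))
    p[!isNull] <- stats::rbeta(sum(!isNull), altShape, 1)
    ## keep strictly inside (0, 1]
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    list(p = p, is_null = isNull)
  })
}

#' Generate two synthetic proteomes with known orthology
#'
#' Each of `nPairs` ancestral protein sequences is mutated independently
#' into one descendant per proteome by substituting residues at rate
#' `mutRate`; these descendant pairs are the ground-truth orthologs. Each
#' proteome additionally receives `nDecoys` unrelated random sequences.
#' With `mutRate = 0` the orthologs are exact copies.
#'
#' @param nPairs number of ortholog pairs.
#' @param nDecoys number of unrelated decoy sequences per proteome.
#' @param length sequence length.
#' @param mutRate per-residue substitution probability.
#' @param seed integer seed.
#' @return list with `a`, `b` (named `Biostrings::AAStringSet`s) and
#'   `truth` (`data.frame` of `id_a`, `id_b` ortholog pairs).
#' @export
makeProteomes <- function(nPairs = 20, nDecoys = 20, length = 120,
                          mutRate = 0.05, seed = 1L) {
  stopifnot(nPairs >= 0, nDecoys >= 0, length >= 1,
            mutRate >= 0, mutRate <= 1)
  aa <- .AA_ALPHABET[.AA_ALPHABET != "X"]
  rndSeq <- function(n) vapply(seq_len(n), function(i)
    paste(sample(aa, length, replace = TRUE), collapse = ""), character(1))
  mutate <- function(s) {
    v <- strsplit(s, "")[[1L]]
    hit <- stats::runif(length) < mutRate
    if (any(hit))
      v[hit] <- vapply(v[hit], function(r)
        sample(setdiff(aa, r), 1L), character(1))
    paste(v, collapse = "")
  }
  withSeed(seed, {
    anc <- rndSeq(nPairs)
    aSeqs <- c(vapply(anc, mutate, character(1), USE.NAMES = FALSE),
               rndSeq(nDecoys))
    bSeqs <- c(vapply(anc, mutate, character(1), USE.NAMES = FALSE),
               rndSeq(nDecoys))
    aIds <- sprintf("a%04d", seq_len(nPairs + nDecoys))
    bIds <- sprintf("b%04d", seq_len(nPairs + nDecoys))
    a <- Biostrings::AAStringSet(stats::setNames(aSeqs, aIds))
    b <- Biostrings::AAStringSet(stats::setNames(bSeqs, bIds))
    list(a = a, b = b,
         truth = data.frame(id_a = aIds[seq_len(nPairs)],
                            id_b = bIds[seq_len(nPairs)],
                            stringsAsFactors = FALSE))
  })
}
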