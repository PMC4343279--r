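## High-level workflow runners binding the modules into the end-to-end
## analysis: build a store, run the ORA, compute reciprocal best hits,
## emit fixture bundles, organize documents. The shell entry point in
## inst/scripts/meshora.R is a thin dispatcher over these functions.

#' Build an annotation store from TSV inputs
#'
#' Thin workflow wrapper over [buildCustomStore()] + [writeMeshDb()].
#'
#' @param linksTsv,vocabularyTsv,edgesTsv input files (see [readers]).
#' @param outDir store directory to write.
#' @param metadata named character vector for the manifest.
#' @return the [MeshDb], invisibly.
#' @export
runBuildDb <- function(linksTsv, vocabularyTsv, edgesTsv = NULL, outDir,
                       metadata = character()) {
  db <- buildCustomStore(linksTsv, vocabularyTsv, edgesTsv,
                         metadata = metadata, outDir = outDir)
  invisible(db)
}

#' Run a MeSH over-representation analysis end to end
#'
#' Loads a store directory plus universe/selected gene lists, runs
#' [meshHyperGTest()] with the given parameters and writes the report
#' (`report.tsv`, `report.json`) and the tag-cloud weights
#' (`weights.tsv`) into `outDir`.
#'
#' @param storeDir a [writeMeshDb()] directory.
#' @param universeFile,selectedFile gene list files (one id per line).
#' @param outDir output directory.
#' @param category,sources,correction,threshold see [MeshOraParams()].
#' @return the [MeshOraResult], invisibly.
#' @export
runOra <- function(storeDir, universeFile, selectedFile, outDir,
                   category, sources = .validSources(),
                   correction = c("BH", "none", "QV", "lFDR"),
                   threshold = 0.05) {
  correction <- match.arg(correction)
  db <- readMeshDb(storeDir)
  universe <- readGeneList(universeFile)
  selected <- readGeneList(selectedFile)
  params <- MeshOraParams(category, sources = sources,
                          correction = correction, threshold = threshold)
  res <- meshHyperGTest(db, universe, selected, params)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeOraReport(res, file.path(outDir, "report.tsv"), "tsv")
  writeOraReport(res, file.path(outDir, "report.json"), "json")
  w <- termWeights(res)
  .writeTsv(data.frame(mesh_id = names(w), weight = unname(w),
                       stringsAsFactors = FALSE),
            file.path(outDir, "weights.tsv"))
  invisible(res)
}

#' Run a reciprocal best-hit comparison of two FASTA files
#'
#' Reads two protein FASTA files, computes [reciprocalBestHits()] and
#' writes the pairs TSV.
#'
#' @param fastaA,fastaB protein FASTA paths.
#' @param outFile pairs TSV path.
#' @param minScore minimum alignment score for a hit to count.
#' @return the pairs `data.frame`, invisibly.
#' @export
runRbbh <- function(fastaA, fastaB, outFile, minScore = 0) {
  A <- Biostrings::readAAStringSet(fastaA)
  B <- Biostrings::readAAStringSet(fastaB)
  if (!length(A) || !length(B))
    stop("empty FASTA input")
  ## FASTA headers may carry descriptions; the id is the first word
  names(A) <- sub("\\s.*$", "", names(A))
  names(B) <- sub("\\s.*$", "", names(B))
  pairs <- reciprocalBestHits(A, B, minScore = minScore)
  writeRbbhPairs(pairs, outFile)
  invisible(pairs)
}

#' Generate a self-contained fixture bundle
#'
#' Writes every input dialect the other workflow commands consume:
#' vocabulary/edges/links TSVs, universe and selected gene lists, a
#' p-value mixture TSV, two proteome FASTA files with their true pairing,
#' and a `fixture_manifest.txt` echoing the generating parameters.
#'
#' @param outDir output directory.
#' @param spec a [fixtureSpec()].
#' @param mixtureM,mixturePi0 size and null proportion of the p-value
#'   mixture sample.
#' @param proteomePairs,proteomeDecoys,proteomeLength,proteomeMutRate
#'   proteome generator settings.
#' @return `outDir`, invisibly.
#' @export
runFixtures <- function(outDir, spec = fixtureSpec(),
                        mixtureM = 1000, mixturePi0 = 0.8,
                        proteomePairs = 20, proteomeDecoys = 20,
                        proteomeLength = 120, proteomeMutRate = 0.05) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  voc <- makeVocabulary(spec)
  links <- makeAnnotations(spec, voc)
  study <- makeStudy(spec, links)
  .writeTsv(voc$terms, file.path(outDir, "vocabulary.tsv"))
  edgesOut <- voc$edges
  names(edgesOut) <- c("parent_id", "child_id")
  .writeTsv(edgesOut, file.path(outDir, "edges.tsv"))
  .writeTsv(links, file.path(outDir, "links.tsv"))
  writeLines(as.character(study$universe),
             file.path(outDir, "universe.txt"))
  writeLines(as.character(study$selected),
             file.path(outDir, "selected.txt"))
  mix <- makePvalueMixture(mixtureM, mixturePi0, seed = spec$seed + 3L)
  writePvalues(sprintf("h%05d", seq_len(mixtureM)), mix$p,
               file.path(outDir, "pvalues.tsv"))
  prot <- makeProteomes(proteomePairs, proteomeDecoys, proteomeLength,
                        proteomeMutRate, seed = spec$seed + 4L)
  Biostrings::writeXStringSet(prot$a, file.path(outDir, "proteome_a.fasta"))
  Biostrings::writeXStringSet(prot$b, file.path(outDir, "proteome_b.fasta"))
  .writeTsv(prot$truth, file.path(outDir, "true_pairs.tsv"))
  manifest <- c(
    n_genes = spec$nGenes, n_terms = spec$nTerms,
    categories = paste(spec$categories, collapse = ""),
    density = spec$density,
    planted_term = if (is.null(spec$plantedTerm)) "none" else
      as.character(study$plantedTerm),
    planted_effect = spec$plantedEffect, base_rate = spec$baseRate,
    seed = spec$seed, mixture_m = mixtureM, mixture_pi0 = mixturePi0,
    proteome_pairs = proteomePairs, proteome_decoys = proteomeDecoys,
    proteome_length = proteomeLength, proteome_mut_rate = proteomeMutRate)
  writeLines(paste0(names(manifest), "=", manifest),
             file.path(outDir, "fixture_manifest.txt"))
  invisible(outDir)
}

#' Organize documents for an over-representation report
#'
#' Loads a store and a previously written report, rebuilds the
#' significant rows, collects the (PubMed, gene, term) records and lays
#' the fetched documents out under `outDir` (see [organizeDocs()]).
#'
#' @param storeDir a store directory.
#' @param reportTsv a `report.tsv` written by [runOra()].
#' @param outDir output directory.
#' @param by grouping key (`"GENEID"`, `"MESHID"` or `"PUBMEDID"`).
#' @param fetcher injected document fetcher.
#' @return the manifest `data.frame`, invisibly.
#' @export
runOrganizeDocs <- function(storeDir, reportTsv, outDir, by = "MESHID",
                            fetcher = stubFetcher) {
  db <- readMeshDb(storeDir)
  tab <- readOraReport(reportTsv, "tsv")
  sig <- tab[tab$significant, , drop = FALSE]
  lk <- db@links
  out <- list()
  for (i in seq_len(nrow(sig))) {
    genes <- as.integer(.splitBar(sig$gene_ids[i])[[1L]])
    sub <- lk[lk$mesh_id == sig$mesh_id[i] & lk$gene_id %in% genes, ,
              drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      docs <- as.integer(.splitBar(sub$pubmed_ids[j])[[1L]])
      if (length(docs))
        out[[length(out) + 1L]] <- data.frame(
          pubmed_id = docs, gene_id = sub$gene_id[j],
          mesh_id = sub$mesh_id[j], stringsAsFactors = FALSE)
    }
  }
  records <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(pubmed_id = integer(0), gene_id = integer(0),
               mesh_id = character(0), stringsAsFactors = FALSE)
  invisible(organizeDocs(records, outDir, by = by, fetcher = fetcher))
}
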