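# Independent oracles used across the suite. They deliberately share no
# code with the implementation they check.

# Quadratic-space Smith-Waterman with affine gaps (three-matrix recursion);
# brute-force reference for the alignment engine.
swOracle <- function(a, b, mat, gapOpen = 11, gapExtend = 1) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)   # best ending in match/mismatch or 0
  E <- matrix(NEG, n + 1L, m + 1L) # gap in a (horizontal)
  F <- matrix(NEG, n + 1L, m + 1L) # gap in b (vertical)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - gapOpen - gapExtend,
                     E[i, j - 1L] - gapExtend)
      F[i, j] <- max(H[i - 1L, j] - gapOpen - gapExtend,
                     F[i - 1L, j] - gapExtend)
      s <- mat[av[i - 1L], bv[j - 1L]]
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Reachability closure of a DAG by per-node breadth-first search over the
# raw edge list.
bfsClosureOracle <- function(nodes, parent, child) {
  out <- list()
  for (n in nodes) {
    seen <- character(0)
    frontier <- child[parent == n]
    while (length(frontier)) {
      frontier <- setdiff(unique(frontier), seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
      frontier <- child[parent %in% frontier]
    }
    if (length(seen))
      out[[length(out) + 1L]] <- data.frame(ancestor = n,
                                            offspring = sort(seen),
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(ancestor = character(0), offspring = character(0)))
  res <- do.call(rbind, out)
  res[order(res$ancestor, res$offspring, method = "radix"), ]
}

# Random DAG on n nodes: edges only from lower to higher index.
randomDagEdges <- function(n, pEdge = 0.1) {
  ids <- sprintf("D%06d", seq_len(n))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    hit <- which(stats::runif(n - i) < pEdge) + i
    from <- c(from, rep(i, length(hit)))
    to <- c(to, hit)
  }
  list(terms = data.frame(mesh_id = ids, term = paste("t", ids),
                          category = "A", stringsAsFactors = FALSE),
       edges = data.frame(parent = ids[from], child = ids[to],
                          stringsAsFactors = FALSE))
}

# Exhaustive hypergeometric upper tail: enumerate every size-k draw from
# a universe of N genes of which the first M are annotated.
exhaustiveTail <- function(N, k, M, x) {
  draws <- utils::combn(N, k)
  overlap <- colSums(draws <= M)
  mean(overlap >= x)
}

# Tiny three-term chain store with one annotated gene per term.
chainDb <- function() {
  terms <- data.frame(mesh_id = c("DX", "DY", "DZ"),
                      term = c("X", "Y", "Z"),
                      category = "D", stringsAsFactors = FALSE)
  edges <- data.frame(parent = c("DX", "DY"), child = c("DY", "DZ"),
                      stringsAsFactors = FALSE)
  links <- data.frame(gene_id = 101:103, mesh_id = c("DX", "DY", "DZ"),
                      source = "gene2pubmed",
                      pubmed_ids = c("11", "12|13", ""),
                      stringsAsFactors = FALSE)
  MeshDb(terms, edges, links, metadata = c(organism = "synthetic-test"))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
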