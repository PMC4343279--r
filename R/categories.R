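#' MeSH category codes
#'
#' MeSH organises its vocabulary into 16 top-level categories, each
#' abbreviated by a single capital letter (A for Anatomy, D for Chemicals
#' and Drugs, C for Diseases, and so on). The mapping is fixed by the
#' National Library of Medicine; every term in a [MeshDb] carries one of
#' these codes.
#'
#' @return A named character vector of length 16 mapping the one-letter
#'   code to the category name.
#' @examples
#' meshCategories()[["D"]]
#' @export
meshCategories <- function() {
  c(A = "Anatomy",
    B = "Organisms",
    C = "Diseases",
    D = "Chemicals and Drugs",
    E = "Analytical Diagnostic and Therapeutic Techniques and Equipment",
    F = "Psychiatry and Psychology",
    G = "Phenomena and Processes",
    H = "Disciplines and Occupations",
    I = "Anthropology, Education, Sociology and Social Phenomena",
    J = "Technology and Food and Beverages",
    K = "Humanities",
    L = "Information Science",
    M = "Persons",
    N = "Health Care",
    V = "Publication Type",
    Z = "Geographical Locations")
}

.validCategoryCodes <- function() names(meshCategories())

.validSources <- function() c("gendoo", "gene2pubmed", "RBBH")

.checkCategoryCodes <- function(codes) {
  bad <- setdiff(unique(codes), .validCategoryCodes())
  if (length(bad))
    stop("invalid MeSH category code(s): ", paste(bad, collapse = ", "),
         "; valid codes are ", paste(.validCategoryCodes(), collapse = ""))
  invisible(TRUE)
}
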