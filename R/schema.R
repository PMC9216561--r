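#' The unified output attribute schema
#'
#' The extraction target is a fixed table of 15 attributes harmonized from the
#' Cistrome and ENCODE annotation vocabularies: biosample identity (cell line,
#' cell type, tissue, classification), assay (technique, technique type,
#' target, feature) and donor characteristics (species, life stage, age, age
#' units, sex, ethnicity, disease).
#'
#' @return A data frame with one row per attribute and columns `name`,
#'   `description`, `common_values` (comma-separated examples) and `link`
#'   (external reference used when reviewing predictions).
#' @examples
#' attribute_schema()$name
#' @export
attribute_schema <- function() {
  df <- data.frame(
    name = c(
      "cell line", "cell type", "tissue", "technique", "technique type",
      "target", "species", "life stage", "age", "age units", "sex",
      "ethnicity", "disease", "classification", "feature"
    ),
    description = c(
      "Name of the cultured cell line the sample derives from",
      "Cell type of the biosample",
      "Tissue of origin of the biosample",
      "Assay name (sequencing technique)",
      "Broad class of the assay",
      "Molecular target of the assay (e.g. ChIP antibody target)",
      "Organism of the donor",
      "Developmental stage of the donor",
      "Age of the donor",
      "Unit in which the donor age is expressed",
      "Sex of the donor",
      "Ethnicity of the donor",
      "Health status / disease of the donor or biosample",
      "Whether the biosample is a cell line or a tissue",
      "What the assay target is investigated as"
    ),
    common_values = c(
      "k562, hela-s3, gm12878, hepg2",
      "erythroblast, epithelial cell, fibroblast",
      "liver, lung, haematopoietic and lymphoid tissue",
      "chip-seq, rna-seq, atac-seq, wgbs",
      "dna binding, transcription profiling, chromatin accessibility",
      "ctcf, polr2a, h3k27ac, h3k4me3",
      "homo sapiens, mus musculus",
      "adult, child, embryonic",
      "53, 31, 6",
      "year, day",
      "male, female",
      "caucasian, asian, african american",
      "healthy, leukemia, adenocarcinoma",
      "cell line, tissue",
      "transcription factor, histone, control"
    ),
    link = c(
      "https://web.expasy.org/cellosaurus/", "https://www.ebi.ac.uk/ols/ontologies/cl",
      "https://www.ebi.ac.uk/ols/ontologies/uberon", "", "",
      "https://www.genenames.org/", "https://www.ncbi.nlm.nih.gov/taxonomy",
      "", "", "", "", "", "https://disease-ontology.org/", "", ""
    ),
    stringsAsFactors = FALSE
  )
  df
}

#' Names of the 15 schema attributes
#'
#' @return Character vector of the 15 attribute names, in schema order.
#' @export
schema_attributes <- function() attribute_schema()$name

#' An empty unified record
#'
#' @return Named character vector over the 15 schema attributes, all `NA`.
#' @export
empty_unified_record <- function() {
  r <- rep(NA_character_, 15L)
  names(r) <- schema_attributes()
  r
}

# validate an attribute name against the schema
assert_attribute <- function(attribute) {
  if (!is.character(attribute) || length(attribute) != 1L ||
      !(attribute %in% schema_attributes())) {
    stop("unknown schema attribute: ", paste(attribute, collapse = ", "),
         call. = FALSE)
  }
  invisible(attribute)
}
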