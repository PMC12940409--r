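#' Default tissue panel
#'
#' The thirteen GTEx tissues with established relevance to Alzheimer's
#' disease pathophysiology used throughout the pipeline: twelve central
#' nervous system regions plus whole blood. Labels follow the GTEx v8
#' `egenes` file naming convention.
#'
#' @return character vector of 13 tissue labels.
#' @examples
#' tissue_panel()
#' @export
tissue_panel <- function() {
  c(
    "Brain_Cortex",
    "Brain_Hippocampus",
    "Brain_Frontal_Cortex_BA9",
    "Brain_Anterior_cingulate_cortex_BA24",
    "Brain_Amygdala",
    "Brain_Caudate_basal_ganglia",
    "Brain_Cerebellum",
    "Brain_Cerebellar_Hemisphere",
    "Brain_Nucleus_accumbens_basal_ganglia",
    "Brain_Putamen_basal_ganglia",
    "Brain_Hypothalamus",
    "Brain_Substantia_nigra",
    "Whole_Blood"
  )
}

.chromosome_levels <- c(as.character(1:22), "X", "Y")

# strip an optional "chr" prefix and validate against the allowed label set;
# invalid labels come back as NA for the caller to report
normalize_chromosome <- function(x) {
  lab <- sub("^chr", "", trimws(as.character(x)), ignore.case = TRUE)
  lab <- toupper(lab)
  lab[!(lab %in% .chromosome_levels)] <- NA_character_
  lab
}

#' Normalize dbSNP rsIDs
#'
#' Trims whitespace and lowercases the `rs` prefix. No merged-rsID
#' resolution is attempted: downstream matching is by exact identifier.
#' The GTEx sentinel `"."` (no dbSNP identifier) is passed through
#' unchanged.
#'
#' @param x character vector of rsIDs.
#' @return normalized character vector.
#' @examples
#' normalize_rsid(c(" RS769449 ", "rs7412", "."))
#' @export
normalize_rsid <- function(x) {
  out <- trimws(as.character(x))
  out <- sub("^rs", "rs", out, ignore.case = TRUE)
  has_rs <- grepl("^rs", out, ignore.case = TRUE)
  out[has_rs] <- paste0("rs", sub("^rs", "", out[has_rs], ignore.case = TRUE))
  out
}

is_valid_rsid <- function(x) grepl("^rs[0-9]+$", x)
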