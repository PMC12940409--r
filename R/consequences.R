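# Most-severe-consequence vocabulary and severity ranking.
#
# The nine consequence classes are the ones GWAS-Catalog-style exports
# produce for Alzheimer's association tables; severity follows the
# Ensembl impact ordering restricted to these classes.

.consequence_levels <- c(
  "3_prime_utr",
  "downstream_gene",
  "intergenic",
  "intron",
  "missense",
  "non_coding_transcript_exon",
  "regulatory_region",
  "synonymous",
  "upstream_gene"
)

# rank 1 = most severe
.consequence_severity <- c(
  missense                   = 1L,
  synonymous                 = 2L,
  `3_prime_utr`              = 3L,
  non_coding_transcript_exon = 4L,
  intron                     = 5L,
  upstream_gene              = 6L,
  downstream_gene            = 7L,
  regulatory_region          = 8L,
  intergenic                 = 9L
)

#' Consequence classes and their severity ranks
#'
#' The pipeline recognises exactly nine most-severe functional consequence
#' classes for GWAS variants. `consequence_classes()` returns them in their
#' canonical (alphabetical) order; `consequence_severity()` returns the fixed
#' severity ranking used by [assign_most_severe()], with rank 1 the most
#' severe (missense) and rank 9 the least (intergenic).
#'
#' @return `consequence_classes()`: a character vector of the nine canonical
#'   class tokens. `consequence_severity()`: a named integer vector of ranks.
#' @examples
#' consequence_classes()
#' consequence_severity()["missense"]
#' @export
consequence_classes <- function() .consequence_levels

#' @rdname consequence_classes
#' @export
consequence_severity <- function() .consequence_severity

#' Normalize consequence labels to canonical tokens
#'
#' Accepts the human-readable spellings found in annotation exports
#' ("Intron variant", "3 prime UTR variant", "non_coding_transcript_exon_variant")
#' and maps them onto the canonical lowercase tokens of
#' [consequence_classes()]. Unknown labels are fatal: a typo in a consequence
#' column would otherwise silently distort the consequence table.
#'
#' @param x character vector of consequence labels.
#' @return character vector of canonical class tokens.
#' @examples
#' normalize_consequence(c("Intron variant", "missense_variant"))
#' @export
normalize_consequence <- function(x) {
  token <- tolower(trimws(as.character(x)))
  token <- gsub("[ '’-]+", "_", token)
  token <- sub("_variant$", "", token)
  token <- sub("^3_prime_utr$|^3_prime_ut_r$", "3_prime_utr", token)
  bad <- !(token %in% .consequence_levels)
  if (any(bad)) {
    stop("unknown consequence class: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  token
}

#' Most severe consequence of a set of annotations
#'
#' Given every consequence class annotated for one variant, returns the single
#' most severe class under the package's fixed severity ranking
#' ([consequence_severity()]).
#'
#' @param consequences non-empty character vector of consequence labels
#'   (any spelling accepted by [normalize_consequence()]).
#' @return a single canonical class token.
#' @examples
#' assign_most_severe(c("intron", "missense")) # "missense"
#' assign_most_severe(c("upstream_gene", "downstream_gene"))
#' @export
assign_most_severe <- function(consequences) {
  if (length(consequences) == 0) {
    stop("cannot assign a most-severe consequence to an empty annotation list",
         call. = FALSE)
  }
  token <- normalize_consequence(consequences)
  token[which.min(.consequence_severity[token])]
}
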