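# Directional-consistency analysis of multi-tissue eQTL slope profiles.

#' Classify the directional consistency of a slope profile
#'
#' A gene regulated in several tissues either keeps one effect direction
#' everywhere (consistent) or flips sign between tissues (divergent, the
#' hallmark of tissue-context-dependent regulation). Exact zeros carry no
#' directional information and are ignored for the sign vote; a profile
#' consisting only of zeros is classified `consistent_positive` by
#' convention and flagged via the `all_zero` attribute.
#'
#' @param slopes non-empty numeric vector of eQTL slopes, one per tissue.
#' @return one of `"single_tissue"`, `"consistent_positive"`,
#'   `"consistent_negative"`, `"divergent"`; the all-zero degenerate case
#'   carries `attr(, "all_zero") = TRUE`.
#' @examples
#' classify_direction(c(0.247, 0.366, 0.125)) # consistent_positive
#' classify_direction(c(0.392, -0.377))       # divergent
#' @export
classify_direction <- function(slopes) {
  stopifnot(is.numeric(slopes), length(slopes) >= 1, !anyNA(slopes))
  if (length(slopes) == 1) return("single_tissue")
  signs <- sign(slopes[slopes != 0])
  if (length(signs) == 0) {
    return(structure("consistent_positive", all_zero = TRUE))
  }
  if (all(signs > 0)) return("consistent_positive")
  if (all(signs < 0)) return("consistent_negative")
  "divergent"
}

#' Per-gene regulatory profiles with direction classes
#'
#' Builds one regulatory profile per (group, gene) from matched eQTL
#' records: the tissue-to-slope map, its direction class, the extreme
#' entries and the strongest-magnitude tissue. "Strongest" compares
#' absolute slopes, since effect strength is a magnitude; ties are broken
#' by lexicographic tissue label so results are deterministic.
#'
#' @param records eQTL record tibble from [match_variants()], or a
#'   consolidated list from [consolidate_records()].
#' @return tibble with one row per (group, gene_name): `n_tissues`,
#'   list columns `tissues` and `slopes`, `direction_class`, `all_zero`,
#'   `min_slope`/`min_tissue`, `max_slope`/`max_tissue`, `range`,
#'   `strongest_tissue`/`strongest_slope`, `mean_slope`.
#' @export
regulatory_profiles <- function(records) {
  if (is.list(records) && !is.data.frame(records) &&
      !is.null(records$profiles)) {
    profiles <- records$profiles
  } else {
    profiles <- consolidate_records(records)$profiles
  }
  if (nrow(profiles) == 0) {
    return(tibble(
      group = character(), gene_name = character(), n_tissues = integer(),
      tissues = list(), slopes = list(), direction_class = character(),
      all_zero = logical(), min_slope = double(), min_tissue = character(),
      max_slope = double(), max_tissue = character(), range = double(),
      strongest_tissue = character(), strongest_slope = double(),
      mean_slope = double()
    ))
  }
  stats_one <- function(tissues, slopes) {
    cls <- classify_direction(slopes)
    i_min <- which(slopes == min(slopes))
    i_min <- i_min[order(tissues[i_min])][1]
    i_max <- which(slopes == max(slopes))
    i_max <- i_max[order(tissues[i_max])][1]
    i_str <- which(abs(slopes) == max(abs(slopes)))
    i_str <- i_str[order(tissues[i_str])][1]
    tibble(
      direction_class = as.character(cls),
      all_zero = isTRUE(attr(cls, "all_zero")),
      min_slope = slopes[i_min], min_tissue = tissues[i_min],
      max_slope = slopes[i_max], max_tissue = tissues[i_max],
      range = max(slopes) - min(slopes),
      strongest_tissue = tissues[i_str], strongest_slope = slopes[i_str],
      mean_slope = mean(slopes)
    )
  }
  extra <- dplyr::bind_rows(Map(stats_one, profiles$tissues, profiles$slopes))
  dplyr::bind_cols(profiles, extra)
}

#' Summarise slope profiles across the dataset
#'
#' Per-gene extremes plus the single strongest regulatory effect over all
#' (gene, tissue, slope) entries in the dataset -- the global maximum
#' slope and, separately, the globally strongest absolute effect.
#'
#' @param profiles profile tibble from [regulatory_profiles()] (an eQTL
#'   record tibble is also accepted and profiled first).
#' @return a list: `per_gene` (the profile tibble without list columns),
#'   `global_max` and `global_strongest`, each a one-row tibble
#'   (`gene_name`, `tissue`, `slope`).
#' @export
slope_summary <- function(profiles) {
  if (!("direction_class" %in% names(profiles))) {
    profiles <- regulatory_profiles(profiles)
  }
  if (nrow(profiles) == 0) {
    empty_entry <- tibble(gene_name = character(), tissue = character(),
                          slope = double())
    return(list(per_gene = profiles, global_max = empty_entry,
                global_strongest = empty_entry))
  }
  long <- tibble(
    gene_name = rep(profiles$gene_name, lengths(profiles$tissues)),
    tissue = unlist(profiles$tissues),
    slope = unlist(profiles$slopes)
  ) %>% arrange(gene_name, tissue)

  pick <- function(i) long[i, c("gene_name", "tissue", "slope")]
  list(
    per_gene = profiles[, setdiff(names(profiles), c("tissues", "slopes"))],
    global_max = pick(which.max(long$slope)),
    global_strongest = pick(which.max(abs(long$slope)))
  )
}

#' Long-format slope table for dot plots
#'
#' Flattens eQTL records to a (tissue, gene, slope) long table, the layout
#' from which per-tissue slope dot plots are drawn.
#'
#' @param records eQTL record tibble.
#' @return tibble with columns `tissue`, `gene_name`, `slope`, `group`,
#'   sorted by (tissue, gene_name).
#' @export
slope_long_table <- function(records) {
  records %>%
    dplyr::select(tissue, gene_name, slope, group) %>%
    arrange(tissue, gene_name)
}
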