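#' Read a sample sheet
#'
#' TSV with header columns `sample_id`, `condition`, `replicate` mapping each
#' metatranscriptome sample to its reactor condition and replicate number.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer()
  ))
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample sheet has duplicated sample ids", call. = FALSE)
  }
  sheet
}

#' Within-guild activity shares for one pathway and sample
#'
#' The functional guild of a pathway is the set of MAGs in which the pathway
#' is called present; each eligible MAG's share is its pathway expression as a
#' percentage of the guild's summed expression. Expression by MAGs that do
#' not encode the complete pathway (stray single-gene hits) is excluded.
#'
#' @param pathway_id Pathway to analyze.
#' @param activities Long activity tibble from [pathway_activity()].
#' @param calls Presence calls from [call_presence()].
#' @param sample_id Sample to evaluate.
#' @return A tibble: `pathway_id`, `sample_id`, `mag_id`, `activity`, `share`
#'   (percent), `zero_guild` (TRUE when no eligible MAG expresses the pathway,
#'   in which case all shares are 0).
#' @export
guild_shares <- function(pathway_id, activities, calls, sample_id) {
  if (!pathway_id %in% calls$pathway_id) {
    stop(sprintf("unknown pathway '%s'", pathway_id), call. = FALSE)
  }
  eligible <- calls$mag_id[calls$pathway_id == pathway_id & calls$present]
  act <- activities[activities$pathway_id == pathway_id &
                      activities$sample_id == sample_id &
                      activities$mag_id %in% eligible, , drop = FALSE]
  act <- dplyr::arrange(act, .data$mag_id)
  total <- sum(act$value)
  tibble(
    pathway_id = pathway_id, sample_id = sample_id, mag_id = act$mag_id,
    activity = act$value,
    share = if (total > 0) 100 * act$value / total else rep(0, nrow(act)),
    zero_guild = total == 0
  )
}

#' Guild shares for every pathway and sample
#'
#' @inheritParams guild_shares
#' @return Row-bound [guild_shares()] output over all pathways x samples.
#' @export
guild_shares_all <- function(activities, calls) {
  combos <- expand.grid(
    pathway_id = sort(unique(activities$pathway_id)),
    sample_id = sort(unique(activities$sample_id)),
    stringsAsFactors = FALSE
  )
  dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    guild_shares(combos$pathway_id[i], activities, calls,
                 combos$sample_id[i])
  }))
}

#' Aggregate guild shares over replicates
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of each
#' MAG's share across the replicates of each condition; conditions with a
#' single replicate report `sd_share = NA`.
#'
#' @param shares Output of [guild_shares()] / [guild_shares_all()].
#' @param sample_sheet Tibble from [read_sample_sheet()].
#' @return A tibble: `pathway_id`, `condition`, `mag_id`, `mean_share`,
#'   `sd_share`, `n_replicates`, plus `mean_activity`.
#' @export
replicate_aggregate <- function(shares, sample_sheet) {
  unknown <- setdiff(unique(shares$sample_id), sample_sheet$sample_id)
  if (length(unknown) > 0L) {
    stop(sprintf("sample '%s' absent from the sample sheet", unknown[1]),
         call. = FALSE)
  }
  joined <- dplyr::inner_join(shares, sample_sheet, by = "sample_id")
  dplyr::summarise(
    dplyr::group_by(joined, .data$pathway_id, .data$condition, .data$mag_id),
    mean_share = mean(.data$share),
    sd_share = if (dplyr::n() >= 2L) sd(.data$share) else NA_real_,
    mean_activity = mean(.data$activity),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
}

#' Rank active populations within a guild
#'
#' Orders a pathway's eligible MAGs by decreasing mean share in one condition;
#' ties are broken by ascending MAG id so the ranking is deterministic.
#'
#' @param agg Aggregated shares from [replicate_aggregate()].
#' @param pathway_id Pathway to rank.
#' @param condition Condition to rank within.
#' @return A tibble sorted by rank: `rank`, `mag_id`, `mean_share`,
#'   `sd_share`; empty guild gives zero rows.
#' @export
rank_active <- function(agg, pathway_id, condition) {
  sel <- agg[agg$pathway_id == pathway_id & agg$condition == condition, ,
             drop = FALSE]
  sel <- dplyr::arrange(sel, dplyr::desc(.data$mean_share), .data$mag_id)
  tibble(
    rank = seq_len(nrow(sel)), mag_id = sel$mag_id,
    mean_share = sel$mean_share, sd_share = sel$sd_share
  )
}

METHANOGENESIS_ROUTES <- c(
  "hydrogenotrophic_methanogenesis", "aceticlastic_methanogenesis",
  "methylotrophic_methanol", "methylotrophic_methylamine"
)

#' Methanogenesis route shares in the archaeal community
#'
#' For each methanogenesis route, sums pathway expression over the archaeal
#' MAGs in which the route is present, then normalizes across routes to 100%.
#' Distinguishes hydrogenotrophic from aceticlastic (and methylotrophic)
#' methane production where a single mcr biomarker cannot.
#'
#' @param activities Long activity tibble from [pathway_activity()].
#' @param calls Presence calls from [call_presence()].
#' @param archaeal_mags Character vector of archaeal MAG ids.
#' @param sample_id Sample to evaluate.
#' @param routes Pathway ids of the methanogenesis routes.
#' @return A tibble: `pathway_id`, `sample_id`, `total_activity`, `share`
#'   (percent across routes; 0 everywhere when no route is expressed).
#' @export
methanogenesis_route_shares <- function(activities, calls, archaeal_mags,
                                        sample_id,
                                        routes = METHANOGENESIS_ROUTES) {
  if (length(archaeal_mags) == 0L) {
    stop("no archaeal MAGs flagged", call. = FALSE)
  }
  totals <- unname(vapply(routes, function(r) {
    g <- guild_shares(r, activities, calls, sample_id)
    sum(g$activity[g$mag_id %in% archaeal_mags])
  }, numeric(1)))
  grand <- sum(totals)
  tibble(
    pathway_id = routes, sample_id = sample_id, total_activity = totals,
    share = if (grand > 0) 100 * totals / grand else rep(0, length(routes))
  )
}

#' Community carbon-flux table
#'
#' Per pathway and condition, the summed transcriptional expression over
#' eligible MAGs (mean across replicates first, then summed over the guild) —
#' the quantity drawn as connector thickness in community carbon-flux maps.
#'
#' @param catalog A `mf_catalog` (supplies the pathway category).
#' @param activities Long activity tibble from [pathway_activity()].
#' @param calls Presence calls from [call_presence()].
#' @param sample_sheet Tibble from [read_sample_sheet()].
#' @return A tibble: `pathway_id`, `category`, `condition`,
#'   `total_expression`, sorted by (pathway_id, condition).
#' @export
flux_table <- function(catalog, activities, calls, sample_sheet) {
  shares <- guild_shares_all(activities, calls)
  agg <- replicate_aggregate(shares, sample_sheet)
  categories <- vapply(catalog$pathways, `[[`, character(1), "category")
  totals <- dplyr::summarise(
    dplyr::group_by(agg, .data$pathway_id, .data$condition),
    total_expression = sum(.data$mean_activity),
    .groups = "drop"
  )
  # pathways with an empty guild still get a 0 row per condition
  full <- tidyr::expand_grid(
    pathway_id = names(catalog$pathways),
    condition = sort(unique(sample_sheet$condition))
  )
  out <- dplyr::left_join(full, totals, by = c("pathway_id", "condition"))
  out$total_expression[is.na(out$total_expression)] <- 0
  out$category <- categories[out$pathway_id]
  dplyr::arrange(
    out[, c("pathway_id", "category", "condition", "total_expression")],
    .data$pathway_id, .data$condition
  )
}

#' Filter MAGs by relative transcriptional expression
#'
#' Keeps MAGs whose relative expression strictly exceeds `threshold_percent`
#' in at least one sample (default: over 1% of a sample's transcriptome),
#' selecting the community's active populations.
#'
#' @param rel_expr MAG-by-sample fraction matrix from
#'   [mag_relative_expression_matrix()].
#' @param threshold_percent Strict lower bound, in percent.
#' @return Character vector of retained MAG ids (sorted).
#' @export
active_population_filter <- function(rel_expr, threshold_percent = 1.0) {
  keep <- apply(rel_expr > threshold_percent / 100, 1, any)
  sort(rownames(rel_expr)[keep])
}
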