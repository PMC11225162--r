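#' Ranked active populations for every pathway and condition
#'
#' Applies [rank_active()]'s ordering (descending mean share, MAG id as the
#' tie-break) across the whole aggregated share table.
#'
#' @param agg Output of [replicate_aggregate()].
#' @return A tibble sorted by (pathway_id, condition, rank).
#' @export
ranked_populations <- function(agg) {
  ranked <- dplyr::arrange(agg, .data$pathway_id, .data$condition,
                           dplyr::desc(.data$mean_share), .data$mag_id)
  dplyr::mutate(
    dplyr::group_by(ranked, .data$pathway_id, .data$condition),
    rank = dplyr::row_number(), .before = 1
  ) |> dplyr::ungroup()
}

#' Run the full pathway-activity pipeline on files
#'
#' Reads the gene table, KO annotations, count matrix, and sample sheet;
#' computes TPM, presence calls, pathway activities, guild shares, replicate
#' aggregates, rankings, the active-population filter, and the carbon-flux
#' table; writes every result as a deterministically sorted TSV plus a run
#' manifest under `out_dir`. Outputs never overwrite inputs.
#'
#' @param genes_path Gene table TSV (see [read_gene_table()]).
#' @param ko_path Optional GhostKOALA-style annotation TSV; `NULL` when the
#'   gene table already carries KOs.
#' @param counts_path Gene-by-sample count matrix TSV.
#' @param samples_path Sample sheet TSV.
#' @param out_dir Output directory (created if needed).
#' @param catalog A `mf_catalog`; defaults to the packaged 90-pathway catalog.
#' @param min_active_percent Active-population filter threshold (strict, in
#'   percent of a sample's transcriptome).
#' @param archaeal_mags Optional character vector of archaeal MAG ids; when
#'   given, methanogenesis route shares are computed per sample.
#' @return Invisibly, a list with every computed object (`genes`, `tpm`,
#'   `calls`, `activities`, `shares`, `agg`, `ranked`, `rel_expr`,
#'   `active_mags`, `flux`, `route_shares`).
#' @export
run_pipeline <- function(genes_path, ko_path = NULL, counts_path,
                         samples_path, out_dir,
                         catalog = default_catalog(),
                         min_active_percent = 1.0,
                         archaeal_mags = NULL) {
  inputs <- c(genes_path, ko_path, counts_path, samples_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (any(normalizePath(inputs) %in%
          normalizePath(list.files(out_dir, full.names = TRUE),
                        mustWork = FALSE))) {
    stop("outputs would overwrite an input file", call. = FALSE)
  }

  genes <- read_gene_table(genes_path)
  if (!is.null(ko_path)) genes <- attach_ko_annotations(genes, ko_path)
  counts <- read_count_matrix(counts_path)
  sheet <- read_sample_sheet(samples_path)
  missing_samples <- setdiff(colnames(counts), sheet$sample_id)
  if (length(missing_samples) > 0L) {
    stop(sprintf("sample '%s' missing from the sample sheet",
                 missing_samples[1]), call. = FALSE)
  }

  tpm <- compute_tpm(counts, genes)
  calls <- call_presence(genes, catalog)
  activities <- pathway_activity(tpm, genes, catalog)
  shares <- guild_shares_all(activities, calls)
  agg <- replicate_aggregate(shares, sheet)
  ranked <- ranked_populations(agg)
  rel_expr <- mag_relative_expression_matrix(tpm, genes)
  active_mags <- active_population_filter(rel_expr, min_active_percent)
  flux <- flux_table(catalog, activities, calls, sheet)

  write_presence_calls(calls, file.path(out_dir, "presence.tsv"))
  readr::write_tsv(activities, file.path(out_dir, "pathway_activity.tsv"))
  readr::write_tsv(
    dplyr::arrange(shares, .data$pathway_id, .data$sample_id,
                   dplyr::desc(.data$share), .data$mag_id),
    file.path(out_dir, "guild_shares.tsv")
  )
  readr::write_tsv(ranked, file.path(out_dir, "ranked_populations.tsv"))
  readr::write_tsv(flux, file.path(out_dir, "flux_table.tsv"))
  readr::write_tsv(
    tibble::as_tibble(rel_expr, rownames = "mag_id"),
    file.path(out_dir, "mag_relative_expression.tsv")
  )
  readr::write_tsv(tibble(mag_id = active_mags),
                   file.path(out_dir, "active_mags.tsv"))
  write_activity_matrix(agg, calls, active_mags,
                        file.path(out_dir, "activity_matrix.tsv"))

  route_shares <- NULL
  if (!is.null(archaeal_mags)) {
    route_shares <- dplyr::bind_rows(lapply(sort(sheet$sample_id), function(s) {
      methanogenesis_route_shares(activities, calls, archaeal_mags, s)
    }))
    readr::write_tsv(route_shares, file.path(out_dir, "route_shares.tsv"))
  }

  write_manifest(
    file.path(out_dir, "manifest.yaml"),
    inputs = list(genes = genes_path, ko = ko_path, counts = counts_path,
                  samples = samples_path),
    parameters = list(min_active_percent = min_active_percent,
                      n_pathways = length(catalog$pathways),
                      archaeal_mags = archaeal_mags)
  )

  invisible(list(
    genes = genes, tpm = tpm, calls = calls, activities = activities,
    shares = shares, agg = agg, ranked = ranked, rel_expr = rel_expr,
    active_mags = active_mags, flux = flux, route_shares = route_shares
  ))
}

# Activity-heatmap table: per (mag, pathway) present in an active MAG, the
# mean pathway expression per condition in wide form.
write_activity_matrix <- function(agg, calls, active_mags, path) {
  present <- calls[calls$present, c("mag_id", "pathway_id")]
  sel <- dplyr::semi_join(
    agg[agg$mag_id %in% active_mags, , drop = FALSE], present,
    by = c("mag_id", "pathway_id")
  )
  wide <- tidyr::pivot_wider(
    sel[, c("pathway_id", "mag_id", "condition", "mean_activity")],
    names_from = "condition", values_from = "mean_activity", values_fill = 0
  )
  readr::write_tsv(dplyr::arrange(wide, .data$pathway_id, .data$mag_id), path)
  invisible(path)
}

# Provenance manifest: inputs, parameters, package version. Content-stable
# for identical runs so pipeline outputs stay byte-reproducible.
write_manifest <- function(path, inputs, parameters) {
  yaml::write_yaml(
    list(
      tool = "magflux",
      version = as.character(packageVersion("magflux")),
      inputs = inputs,
      parameters = parameters
    ),
    path
  )
  invisible(path)
}
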