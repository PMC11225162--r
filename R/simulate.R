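#' Configuration for a synthetic community simulation
#'
#' Defines a community of MAGs with known pathway content and transcriptional
#' activity. Defaults mirror the study design this package targets: five
#' reactor conditions along an organic-loading gradient (hydraulic retention
#' times of 15 down to 1 day), three metatranscriptome replicates per
#' condition, and an 86% full-length gene proportion; community size and
#' count-model parameters are desk-scale choices documented in the methods
#' vignette.
#'
#' @param n_mags Number of MAGs.
#' @param catalog Pathway catalog the community draws from.
#' @param presence_profile Named list: MAG id -> character vector of truly
#'   encoded pathway ids. `NULL` draws `pathways_per_mag` pathways per MAG
#'   uniformly from the catalog.
#' @param pathways_per_mag Integer range (length 2) of encoded pathways per
#'   MAG when the profile is drawn.
#' @param annotation_dropout Probability that a truly present gene loses its
#'   KO label in the emitted annotations.
#' @param copies_per_ko Integer range of gene copies per required subunit.
#' @param gene_length_range Gene length range in nucleotides.
#' @param full_length_prob Probability a gene's Prodigal flag is "00".
#' @param activity_multiplier Named list: MAG id -> named numeric vector of
#'   per-pathway activity multipliers. `NULL` draws log-normal multipliers
#'   (meanlog 0, sdlog 1) per MAG x encoded pathway.
#' @param condition_effect Optional pathway-by-condition multiplier matrix
#'   modulating expression along the loading gradient; `NULL` = none.
#' @param baseline_mean Expected count of a 1 kb reference gene at
#'   multiplier 1.
#' @param nb_dispersion Negative-binomial dispersion (1/size); variance is
#'   `mu + dispersion * mu^2`.
#' @param n_decoys_per_mag Genes per MAG outside any encoded pathway.
#' @param decoy_ko_fraction Fraction of decoys carrying an off-catalog KO
#'   (the rest are unannotated).
#' @param conditions Condition labels.
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed; fixes all randomness.
#' @return A `mf_sim_config` list.
#' @export
sim_config <- function(n_mags = 20,
                       catalog = default_catalog(),
                       presence_profile = NULL,
                       pathways_per_mag = c(6, 12),
                       annotation_dropout = 0,
                       copies_per_ko = c(1, 2),
                       gene_length_range = c(300, 3000),
                       full_length_prob = 0.86,
                       activity_multiplier = NULL,
                       condition_effect = NULL,
                       baseline_mean = 50,
                       nb_dispersion = 0.2,
                       n_decoys_per_mag = 15,
                       decoy_ko_fraction = 0.3,
                       conditions = c("H15", "H7", "H4", "H2", "H1"),
                       n_replicates = 3,
                       seed = 1) {
  stopifnot(
    n_mags >= 1, inherits(catalog, "mf_catalog"),
    annotation_dropout >= 0, annotation_dropout <= 1,
    nb_dispersion > 0, baseline_mean > 0,
    length(copies_per_ko) == 2, copies_per_ko[1] >= 1,
    length(gene_length_range) == 2, gene_length_range[1] >= 3,
    full_length_prob >= 0, full_length_prob <= 1,
    n_replicates >= 1, length(conditions) >= 1
  )
  structure(
    list(
      n_mags = as.integer(n_mags), catalog = catalog,
      presence_profile = presence_profile,
      pathways_per_mag = as.integer(pathways_per_mag),
      annotation_dropout = annotation_dropout,
      copies_per_ko = as.integer(copies_per_ko),
      gene_length_range = as.integer(gene_length_range),
      full_length_prob = full_length_prob,
      activity_multiplier = activity_multiplier,
      condition_effect = condition_effect,
      baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
      n_decoys_per_mag = as.integer(n_decoys_per_mag),
      decoy_ko_fraction = decoy_ko_fraction,
      conditions = conditions, n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "mf_sim_config"
  )
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream) %% 2147483647)
}

#' Simulate a synthetic community with known ground truth
#'
#' For each MAG and each truly encoded pathway, every step receives at least
#' one gene per required subunit of one uniformly chosen variant, so with no
#' annotation dropout the presence profile is recovered exactly. Decoy genes
#' (unannotated or carrying off-catalog KOs) are added per MAG. Counts are
#' drawn per gene and sample from a negative binomial with
#' `mu = baseline_mean * length_nt/1000 * activity_multiplier` (length
#' proportionality makes TPM recover the configured activity structure) and
#' `size = 1/nb_dispersion`. All randomness derives from the config seed.
#'
#' @param config A `mf_sim_config` from [sim_config()].
#' @return A `mf_simulation` list: `genes` (a `mf_gene_table`, with annotation
#'   dropout applied), `counts` (gene-by-sample matrix), `sample_sheet`,
#'   and `truth` (presence profile, per-MAG/pathway multipliers, per-gene
#'   true NB means, pre-dropout KO assignments).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "mf_sim_config"))
  catalog <- config$catalog
  mags <- sprintf("MAG%03d", seq_len(config$n_mags))

  set.seed(sub_seed(config$seed, 1))
  profile <- config$presence_profile
  if (is.null(profile)) {
    profile <- setNames(lapply(mags, function(m) {
      n <- sample(config$pathways_per_mag[1]:config$pathways_per_mag[2], 1)
      sort(sample(names(catalog$pathways), min(n, length(catalog$pathways))))
    }), mags)
  } else {
    mags <- names(profile)
    unknown <- setdiff(unlist(profile), names(catalog$pathways))
    if (length(unknown) > 0L) {
      stop(sprintf("presence profile names unknown pathway '%s'", unknown[1]),
           call. = FALSE)
    }
  }

  multipliers <- config$activity_multiplier
  if (is.null(multipliers)) {
    multipliers <- setNames(lapply(mags, function(m) {
      p <- profile[[m]]
      setNames(exp(rnorm(length(p), 0, 1)), p)
    }), mags)
  }

  catalog_kos <- unique(unlist(lapply(catalog$pathways, pathway_kos)))

  # structural layer: genes implementing one chosen variant per step
  rows <- list()
  for (m in mags) {
    set.seed(sub_seed(config$seed, 100 + match(m, mags)))
    for (pid in profile[[m]]) {
      p <- catalog$pathways[[pid]]
      mult <- multipliers[[m]][[pid]]
      if (is.null(mult) || is.na(mult)) mult <- 1
      for (s in p$steps) {
        variant <- s$variants[[sample.int(length(s$variants), 1)]]
        for (ko in variant$required) {
          n_copies <- sample(config$copies_per_ko[1]:config$copies_per_ko[2], 1)
          for (cp in seq_len(n_copies)) {
            rows[[length(rows) + 1L]] <- list(
              mag_id = m, pathway_id = pid, step_id = s$step_id, ko = ko,
              length_nt = sample(
                config$gene_length_range[1]:config$gene_length_range[2], 1),
              multiplier = mult
            )
          }
        }
      }
    }
    # decoys: transcribed background outside every encoded pathway
    if (config$n_decoys_per_mag > 0) {
      n_ko_decoys <- round(config$n_decoys_per_mag * config$decoy_ko_fraction)
      for (d in seq_len(config$n_decoys_per_mag)) {
        decoy_ko <- NA_character_
        if (d <= n_ko_decoys) {
          repeat {
            decoy_ko <- sprintf("K9%04d", sample.int(9999, 1))
            if (!decoy_ko %in% catalog_kos) break
          }
        }
        rows[[length(rows) + 1L]] <- list(
          mag_id = m, pathway_id = NA_character_, step_id = NA_character_,
          ko = decoy_ko,
          length_nt = sample(
            config$gene_length_range[1]:config$gene_length_range[2], 1),
          multiplier = 1
        )
      }
    }
  }
  if (length(rows) == 0L) {
    stop("infeasible simulation config: no genes generated", call. = FALSE)
  }
  truth_genes <- dplyr::bind_rows(lapply(rows, tibble::as_tibble_row))
  truth_genes$gene_id <- sprintf("%s_g%04d", truth_genes$mag_id,
                                 stats::ave(seq_len(nrow(truth_genes)),
                                            truth_genes$mag_id,
                                            FUN = seq_along))

  set.seed(sub_seed(config$seed, 2))
  partial <- ifelse(
    runif(nrow(truth_genes)) < config$full_length_prob, "00",
    sample(c("01", "10", "11"), nrow(truth_genes), replace = TRUE)
  )
  dropped <- runif(nrow(truth_genes)) < config$annotation_dropout
  observed_ko <- ifelse(is.na(truth_genes$ko) | dropped, NA_character_,
                        truth_genes$ko)

  genes <- new_gene_table(
    gene_id = truth_genes$gene_id, mag_id = truth_genes$mag_id,
    length_nt = truth_genes$length_nt, partial = partial,
    kos = lapply(observed_ko, function(k) {
      if (is.na(k)) character(0) else k
    })
  )

  # count layer: one stream per sample for stable partial regeneration
  sheet <- tidyr::expand_grid(condition = config$conditions,
                              replicate = seq_len(config$n_replicates))
  sheet$sample_id <- sprintf("%s_r%d", sheet$condition, sheet$replicate)
  sheet <- sheet[, c("sample_id", "condition", "replicate")]

  base_mu <- config$baseline_mean * truth_genes$length_nt / 1000 *
    truth_genes$multiplier
  counts <- matrix(0, nrow = nrow(truth_genes), ncol = nrow(sheet),
                   dimnames = list(truth_genes$gene_id, sheet$sample_id))
  mu_matrix <- counts
  for (j in seq_len(nrow(sheet))) {
    mu <- base_mu
    ce <- config$condition_effect
    if (!is.null(ce)) {
      idx <- match(truth_genes$pathway_id, rownames(ce))
      eff <- ce[cbind(idx, match(sheet$condition[j], colnames(ce)))]
      eff[is.na(eff)] <- 1
      mu <- mu * eff
    }
    set.seed(sub_seed(config$seed, 1000 + j))
    counts[, j] <- rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    mu_matrix[, j] <- mu
  }

  true_presence <- tidyr::expand_grid(
    mag_id = sort(names(profile)), pathway_id = sort(names(catalog$pathways))
  )
  true_presence$present <- mapply(function(m, p) p %in% profile[[m]],
                                  true_presence$mag_id,
                                  true_presence$pathway_id)

  structure(
    list(
      genes = genes, counts = counts, sample_sheet = sheet,
      truth = list(
        presence_profile = profile,
        presence = true_presence,
        multipliers = multipliers,
        gene_truth = dplyr::mutate(truth_genes, true_ko = .data$ko,
                                   dropped = dropped),
        mu = mu_matrix
      ),
      config = config
    ),
    class = "mf_simulation"
  )
}

#' Write a simulation to the pipeline's input formats
#'
#' Emits `genes.tsv` (gene table without KO assignments), `ko.tsv`
#' (GhostKOALA-style two-column annotation, blank KO for unannotated genes),
#' `counts.tsv` (gene-by-sample matrix), `samples.tsv` (sample sheet), and
#' `truth.yaml` (presence profile and activity multipliers). Output is
#' byte-deterministic for a fixed config.
#'
#' @param sim A `mf_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mf_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  blank <- sim$genes
  blank$kos <- rep(list(character(0)), nrow(blank))
  write_gene_table(blank, file.path(dir, "genes.tsv"))
  ko_out <- tibble(
    gene_id = sim$genes$gene_id,
    ko = vapply(sim$genes$kos, function(k) {
      if (length(k) == 0L) "" else paste(k, collapse = ";")
    }, character(1))
  )
  readr::write_tsv(ko_out, file.path(dir, "ko.tsv"), col_names = FALSE)
  counts_out <- tibble::as_tibble(sim$counts, rownames = "gene_id")
  readr::write_tsv(counts_out, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$sample_sheet, file.path(dir, "samples.tsv"))
  yaml::write_yaml(
    list(
      seed = sim$config$seed,
      presence_profile = sim$truth$presence_profile,
      multipliers = lapply(sim$truth$multipliers, as.list)
    ),
    file.path(dir, "truth.yaml")
  )
  invisible(dir)
}

#' Degrade a MAG by deleting the genes of random pathway steps
#'
#' Emulates MAG incompleteness: a fraction of the pathway's steps is chosen
#' uniformly and every gene of the MAG carrying any KO of those steps is
#' removed.
#'
#' @param genes A `mf_gene_table`.
#' @param pathway A `mf_pathway` whose steps are degraded.
#' @param mag_id MAG to degrade.
#' @param fraction_steps_removed Fraction of steps to remove, in `[0, 1]`;
#'   the step count removed is `round(fraction * n_steps)`.
#' @param seed Integer seed for the uniform step choice.
#' @return The degraded `mf_gene_table`.
#' @export
degrade_mag <- function(genes, pathway, mag_id, fraction_steps_removed, seed) {
  stopifnot(inherits(pathway, "mf_pathway"),
            fraction_steps_removed >= 0, fraction_steps_removed <= 1)
  n_remove <- round(length(pathway$steps) * fraction_steps_removed)
  if (n_remove == 0L) return(genes)
  set.seed(as.integer(seed))
  removed_steps <- sample(pathway$steps, n_remove)
  removed_kos <- unique(unlist(lapply(removed_steps, function(s) {
    unlist(lapply(s$variants, function(v) c(v$required, v$optional)))
  })))
  drop <- genes$mag_id == mag_id &
    vapply(genes$kos, function(k) any(k %in% removed_kos), logical(1))
  out <- genes[!drop, , drop = FALSE]
  class(out) <- class(genes)
  out
}
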