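#' Read a gene-by-sample count matrix
#'
#' Expects a TSV whose first column is `gene_id` and remaining columns are
#' samples holding RSEM-style expected counts (non-negative, possibly
#' fractional).
#'
#' @param path Path to the matrix TSV.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_count_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$gene_id
  validate_count_matrix(m)
  m
}

#' Read per-sample RSEM-style count files
#'
#' Each file is a TSV with columns `gene_id`, `length`, `expected_count`
#' (extra RSEM columns are ignored). Files are joined on `gene_id`; genes
#' missing from a sample get count 0.
#'
#' @param paths Named character vector: `sample_id = file path`.
#' @return A numeric gene-by-sample matrix.
#' @export
read_rsem_counts <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("read_rsem_counts: paths must be named by sample_id", call. = FALSE)
  }
  per_sample <- lapply(paths, function(p) {
    tbl <- readr::read_tsv(p, col_types = readr::cols(
      gene_id = readr::col_character(),
      length = readr::col_double(),
      expected_count = readr::col_double(),
      .default = readr::col_skip()
    ))
    setNames(tbl$expected_count, tbl$gene_id)
  })
  genes <- sort(unique(unlist(lapply(per_sample, names), use.names = FALSE)))
  m <- vapply(per_sample, function(v) {
    out <- setNames(numeric(length(genes)), genes)
    out[names(v)] <- v
    out
  }, numeric(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, names(paths)))
  validate_count_matrix(m)
  m
}

validate_count_matrix <- function(m) {
  if (anyNA(m)) stop("count matrix contains NA values", call. = FALSE)
  if (any(m < 0)) stop("count matrix contains negative values", call. = FALSE)
  if (anyDuplicated(rownames(m))) {
    stop("count matrix has duplicated gene ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("count matrix has duplicated sample ids", call. = FALSE)
  }
  invisible(m)
}

#' Transcripts per million from expected counts
#'
#' Per sample, each gene's count is first divided by its length in kilobases
#' (length normalization), then the length-normalized rates are scaled to sum
#' to one million (depth normalization):
#' `TPM_i = (count_i / length_i) / sum_j (count_j / length_j) * 1e6`.
#'
#' @param counts Gene-by-sample numeric matrix of expected counts.
#' @param lengths Gene lengths in nucleotides: a named numeric vector or a
#'   `mf_gene_table` from which lengths are taken.
#' @return A gene-by-sample TPM matrix with the same dimnames; every column
#'   sums to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  validate_count_matrix(counts)
  if (inherits(lengths, "mf_gene_table")) {
    lengths <- setNames(as.numeric(lengths$length_nt), lengths$gene_id)
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0L) {
    stop(sprintf("compute_tpm: no length for gene '%s'", missing[1]),
         call. = FALSE)
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) {
    stop("compute_tpm: non-positive gene length", call. = FALSE)
  }
  rate <- counts / len
  totals <- colSums(rate)
  zero <- which(totals == 0)
  if (length(zero) > 0L) {
    stop(sprintf("compute_tpm: sample '%s' has no mapped reads",
                 colnames(counts)[zero[1]]), call. = FALSE)
  }
  sweep(rate, 2, totals, "/") * 1e6
}

# gene ids of one MAG carrying a given KO
genes_with_ko <- function(genes, mag_id, ko) {
  sel <- genes$mag_id == mag_id &
    vapply(genes$kos, function(k) ko %in% k, logical(1))
  genes$gene_id[sel]
}

#' Summed KO expression within a MAG
#'
#' Total TPM over every gene of the MAG annotated with the KO (a gene carrying
#' several KOs contributes its full TPM to each). Multiple gene copies are
#' summed; an unannotated KO contributes 0.
#'
#' @param mag_id MAG label.
#' @param ko KO identifier.
#' @param expr TPM matrix from [compute_tpm()].
#' @param genes A `mf_gene_table`.
#' @param sample_id Sample (column) to evaluate.
#' @return A non-negative TPM value.
#' @export
ko_expression <- function(mag_id, ko, expr, genes, sample_id) {
  ids <- intersect(genes_with_ko(genes, mag_id, ko), rownames(expr))
  if (length(ids) == 0L) return(0)
  sum(expr[ids, sample_id])
}

#' Step-level expression within a MAG
#'
#' For each variant of the step, the expression is the arithmetic mean over
#' its required subunits of the summed KO expression (an unexpressed or
#' unannotated subunit enters the mean as 0, penalizing incompletely
#' expressed complexes); alternative enzymes/complexes are then summed, so a
#' reaction served by multiple enzymes or gene copies accumulates their total
#' expression. Optional subunits are excluded.
#'
#' @param mag_id MAG label.
#' @param step A `mf_step`.
#' @inheritParams ko_expression
#' @return A non-negative TPM value.
#' @export
step_expression <- function(mag_id, step, expr, genes, sample_id) {
  stopifnot(inherits(step, "mf_step"))
  sum(vapply(step$variants, function(v) {
    mean(vapply(v$required, function(ko) {
      ko_expression(mag_id, ko, expr, genes, sample_id)
    }, numeric(1)))
  }, numeric(1)))
}

#' Pathway-level expression within a MAG
#'
#' The transcriptional expression of a pathway in a MAG is the arithmetic
#' mean of the step expressions over ALL steps (key and non-key); steps with
#' no expressed gene enter as 0.
#'
#' @param mag_id MAG label.
#' @param pathway A `mf_pathway`.
#' @inheritParams ko_expression
#' @return A one-row tibble: `mag_id`, `pathway_id`, `sample_id`, `value`,
#'   `n_steps`.
#' @export
pathway_expression <- function(mag_id, pathway, expr, genes, sample_id) {
  stopifnot(inherits(pathway, "mf_pathway"))
  values <- vapply(pathway$steps, function(s) {
    step_expression(mag_id, s, expr, genes, sample_id)
  }, numeric(1))
  tibble(
    mag_id = mag_id, pathway_id = pathway$pathway_id, sample_id = sample_id,
    value = mean(values), n_steps = length(pathway$steps)
  )
}

# Precompute summed TPM per (mag, ko) across all samples: a matrix keyed
# "mag\rko" x sample. Genes with k KOs contribute full TPM to each KO.
mag_ko_tpm <- function(expr, genes) {
  n_kos <- lengths(genes$kos)
  keep <- n_kos > 0L
  if (!any(keep)) {
    return(matrix(numeric(0), nrow = 0, ncol = ncol(expr),
                  dimnames = list(character(0), colnames(expr))))
  }
  gene_idx <- rep(which(keep), n_kos[keep])
  kos <- unlist(genes$kos[keep], use.names = FALSE)
  keys <- paste(genes$mag_id[gene_idx], kos, sep = "\r")
  rows <- match(genes$gene_id[gene_idx], rownames(expr))
  ok <- !is.na(rows)
  rowsum(expr[rows[ok], , drop = FALSE], group = keys[ok])
}

#' Pathway activity for every MAG, pathway, and sample
#'
#' Vectorized application of the step and pathway aggregation rules (see
#' [step_expression()], [pathway_expression()]) over an entire community.
#'
#' @param expr TPM matrix.
#' @param genes A `mf_gene_table`.
#' @param catalog A `mf_catalog`.
#' @return A long tibble: `mag_id`, `pathway_id`, `sample_id`, `value`,
#'   `n_steps`, sorted by (pathway_id, mag_id, sample_id).
#' @export
pathway_activity <- function(expr, genes, catalog) {
  stopifnot(inherits(catalog, "mf_catalog"))
  lookup <- mag_ko_tpm(expr, genes)
  mags <- sort(unique(genes$mag_id))
  samples <- colnames(expr)
  n_s <- length(samples)
  zero <- numeric(n_s)
  ko_row <- function(mag, ko) {
    key <- paste(mag, ko, sep = "\r")
    i <- match(key, rownames(lookup))
    if (is.na(i)) zero else lookup[i, ]
  }
  out <- vector("list", length(catalog$pathways) * length(mags))
  k <- 0L
  for (p in catalog$pathways) {
    for (mag in mags) {
      step_vals <- vapply(p$steps, function(s) {
        variant_sums <- vapply(s$variants, function(v) {
          subunit_rows <- vapply(v$required, function(ko) ko_row(mag, ko),
                                 numeric(n_s))
          # vapply over subunits gives samples x subunits
          rowMeans(matrix(subunit_rows, nrow = n_s))
        }, numeric(n_s))
        rowSums(matrix(variant_sums, nrow = n_s))
      }, numeric(n_s))
      k <- k + 1L
      out[[k]] <- tibble(
        mag_id = mag, pathway_id = p$pathway_id, sample_id = samples,
        value = rowMeans(matrix(step_vals, nrow = n_s)),
        n_steps = length(p$steps)
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$pathway_id, .data$mag_id,
                 .data$sample_id)
}

#' Relative transcriptional expression of a MAG
#'
#' The MAG's share of a sample's transcriptome: summed TPM of its genes
#' divided by 1e6. Over all MAGs (plus any unbinned genes) the shares sum
#' to 1 per sample.
#'
#' @param mag_id MAG label.
#' @param expr TPM matrix.
#' @param genes A `mf_gene_table`.
#' @param sample_id Sample to evaluate.
#' @return A fraction in `[0, 1]`.
#' @export
mag_relative_expression <- function(mag_id, expr, genes, sample_id) {
  if (!mag_id %in% genes$mag_id) {
    stop(sprintf("unknown mag_id '%s'", mag_id), call. = FALSE)
  }
  ids <- intersect(genes$gene_id[genes$mag_id == mag_id], rownames(expr))
  if (length(ids) == 0L) return(0)
  sum(expr[ids, sample_id]) / 1e6
}

#' Relative expression of every MAG in every sample
#'
#' @param expr TPM matrix.
#' @param genes A `mf_gene_table`.
#' @return A MAG-by-sample matrix of fractions.
#' @export
mag_relative_expression_matrix <- function(expr, genes) {
  rows <- match(genes$gene_id, rownames(expr))
  ok <- !is.na(rows)
  m <- rowsum(expr[rows[ok], , drop = FALSE], group = genes$mag_id[ok]) / 1e6
  mags <- sort(unique(genes$mag_id))
  full <- matrix(0, nrow = length(mags), ncol = ncol(expr),
                 dimnames = list(mags, colnames(expr)))
  full[rownames(m), ] <- m
  full
}
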