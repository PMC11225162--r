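# Shared fixtures and independent brute-force oracles.

# gene table built in code (exercises the same validator as the readers)
make_genes <- function(gene_id, mag_id, length_nt, partial = "00", kos) {
  n <- length(gene_id)
  magflux:::new_gene_table(
    gene_id = gene_id,
    mag_id = rep_len(mag_id, n),
    length_nt = rep_len(length_nt, n),
    partial = rep_len(partial, n),
    kos = kos
  )
}

random_kos <- function(n, pool = 200) {
  sprintf("K%05d", sample.int(pool, n))
}

random_step <- function(pool = 40, max_variants = 3, max_subunits = 3) {
  n_var <- sample.int(max_variants, 1)
  variants <- replicate(n_var, {
    kos <- unique(random_kos(sample.int(max_subunits, 1), pool))
    paste(kos, collapse = "+")
  })
  parse_step_expression(paste(variants, collapse = ","))
}

random_pathway <- function(id = "P1", n_steps = sample(2:4, 1), pool = 40,
                           threshold = 1.0) {
  steps <- lapply(seq_len(n_steps), function(i) {
    s <- random_step(pool)
    s$step_id <- paste0("S", i)
    s
  })
  magflux:::new_pathway(id, id, "central_carbon", steps,
                        threshold = threshold)
}

# Independent oracle for step expression: enumerate every
# (variant, required subunit, gene copy) triple and accumulate
# tpm(copy) / n_required(variant). Structurally unlike step_expression.
oracle_step_expression <- function(mag_id, step, expr, genes, sample_id) {
  total <- 0
  for (v in step$variants) {
    n_req <- length(v$required)
    for (ko in v$required) {
      for (i in seq_len(nrow(genes))) {
        if (genes$mag_id[i] == mag_id && ko %in% genes$kos[[i]] &&
            genes$gene_id[i] %in% rownames(expr)) {
          total <- total + expr[genes$gene_id[i], sample_id] / n_req
        }
      }
    }
  }
  total
}

# Independent oracle for step detection / completeness.
oracle_detect_step <- function(mag_kos, step) {
  for (v in step$variants) {
    hit <- TRUE
    for (ko in v$required) if (!ko %in% mag_kos) hit <- FALSE
    if (hit) return(TRUE)
  }
  FALSE
}

oracle_completeness <- function(mag_kos, pathway) {
  key <- Filter(function(s) s$key, pathway$steps)
  sum(vapply(key, function(s) oracle_detect_step(mag_kos, s), logical(1))) /
    length(key)
}

# One KO set per MMC step such that the sets are pairwise disjoint and each
# set completes exactly one variant of exactly one step (checked in tests).
mmc_disjoint_step_kos <- function() {
  list(
    S1 = "K01895",
    S2 = c("K01965", "K01966"),
    S3 = "K05606",
    S4 = "K01849",
    S5 = c("K01902", "K01903"),
    S6 = c("K00244", "K00245"),
    S7 = "K01676",
    S8 = "K00024",
    S9 = "K01596",
    S10 = "K03737",
    S11 = c("K00625", "K00925")
  )
}

# small two-pathway catalog written to a temp YAML file
write_mini_catalog <- function(path) {
  writeLines(c(
    "pathways:",
    "- id: P_one",
    "  name: toy one",
    "  category: sugar",
    "  steps:",
    "  - {step_id: S1, expr: \"K00001\"}",
    "- id: P_two",
    "  name: toy two",
    "  category: central_carbon",
    "  threshold: 0.5",
    "  steps:",
    "  - {step_id: S1, expr: \"K01902+K01903,K22224\"}",
    "  - {step_id: S2, key: false, expr: \"K00248+-K99999\"}",
    "  - {step_id: S3, expr: \"K00134\"}"
  ), path)
  path
}
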