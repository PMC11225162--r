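tpm_fixture <- function(counts, lengths, gene_ids = paste0("g", seq_along(counts))) {
  m <- matrix(counts, ncol = 1, dimnames = list(gene_ids, "s1"))
  compute_tpm(m, setNames(lengths, gene_ids))
}

test_that("TPM normalization matches hand-computed values", {
  # single gene: whole library
  expect_equal(unname(tpm_fixture(5, 100)[1, 1]), 1e6)

  # equal length-normalized rates -> equal TPM
  tpm <- tpm_fixture(c(10, 20, 30), c(100, 200, 300))
  expect_equal(unname(tpm[, 1]), rep(1e6 / 3, 3))

  # rates 0.01 and 1/300 -> 750000 / 250000
  tpm <- tpm_fixture(c(1, 1), c(100, 300))
  expect_equal(unname(tpm[, 1]), c(750000, 250000))
})

test_that("TPM errors name the offending sample or gene", {
  m <- matrix(c(1, 2, 0, 0), nrow = 2,
              dimnames = list(c("g1", "g2"), c("ok", "dead")))
  expect_error(compute_tpm(m, c(g1 = 100, g2 = 100)),
               "sample 'dead' has no mapped reads")
  m2 <- m[, 1, drop = FALSE]
  expect_error(compute_tpm(m2, c(g1 = 100)), "no length for gene 'g2'")
})

test_that("TPM columns conserve 1e6 and are scale-equivariant", {
  set.seed(42)
  for (i in 1:50) {
    n_genes <- sample(2:30, 1)
    n_samples <- sample(1:5, 1)
    counts <- matrix(rpois(n_genes * n_samples, lambda = 20) + 1,
                     nrow = n_genes,
                     dimnames = list(paste0("g", seq_len(n_genes)),
                                     paste0("s", seq_len(n_samples))))
    lengths <- setNames(sample(100:5000, n_genes), rownames(counts))
    tpm <- compute_tpm(counts, lengths)
    expect_true(all(abs(colSums(tpm) - 1e6) <= 1e-6 * 1e6))

    # multiplying one sample's counts by c > 0 leaves its TPM unchanged
    scaled <- counts
    scaled[, 1] <- scaled[, 1] * 7.3
    expect_equal(compute_tpm(scaled, lengths)[, 1], tpm[, 1])
  }
})

expr_fixture <- function() {
  genes <- make_genes(
    paste0("g", 1:6), c("A", "A", "A", "A", "B", "A"), 300,
    kos = list("K00001", "K00001", "K00002", "K00003", "K00001", character(0))
  )
  expr <- matrix(c(5, 5, 20, 30, 100, 7), ncol = 1,
                 dimnames = list(paste0("g", 1:6), "s1"))
  list(genes = genes, expr = expr)
}

test_that("KO expression sums gene copies within one MAG", {
  f <- expr_fixture()
  # two copies with TPM 5 and 5
  expect_equal(ko_expression("A", "K00001", f$expr, f$genes, "s1"), 10)
  # single gene
  expect_equal(ko_expression("A", "K00002", f$expr, f$genes, "s1"), 20)
  # absent KO -> 0
  expect_equal(ko_expression("A", "K09999", f$expr, f$genes, "s1"), 0)
  # other MAG's copies are not counted
  expect_equal(ko_expression("B", "K00001", f$expr, f$genes, "s1"), 100)
})

test_that("step expression follows subunit-mean then variant-sum rules", {
  f <- expr_fixture()
  # complex of two subunits with KO sums 10 and 20 -> mean 15
  s <- parse_step_expression("K00001+K00002")
  expect_equal(step_expression("A", s, f$expr, f$genes, "s1"), 15)

  # two variants: complex with subunit sums (20,30) plus a single enzyme
  # whose two copies sum to 10 -> mean(20,30) + 10 = 35
  s <- parse_step_expression("K00002+K00003,K00001")
  expect_equal(step_expression("A", s, f$expr, f$genes, "s1"), 35)

  # complex with subunit sums (10,20) plus single-enzyme copies (5,5) -> 25
  genes2 <- make_genes(paste0("c", 1:4), "A", 300,
                       kos = list("K00010", "K00011", "K00012", "K00012"))
  expr2 <- matrix(c(10, 20, 5, 5), ncol = 1,
                  dimnames = list(paste0("c", 1:4), "s1"))
  s2 <- parse_step_expression("K00010+K00011,K00012")
  expect_equal(step_expression("A", s2, expr2, genes2, "s1"), 25)

  # unexpressed subunit enters the mean as zero: (30,0) -> 15
  s <- parse_step_expression("K00003+K09999")
  expect_equal(step_expression("A", s, f$expr, f$genes, "s1"), 15)

  # optional subunits are excluded from the mean
  s <- parse_step_expression("K00003+-K00002")
  expect_equal(step_expression("A", s, f$expr, f$genes, "s1"), 30)
})

test_that("pathway expression averages over all steps with zero-fill", {
  f <- expr_fixture()
  genes <- make_genes(paste0("c", 1:4), "A", 300,
                      kos = list("K00010", "K00011", "K00012", "K00012"))
  expr <- matrix(c(10, 20, 5, 5), ncol = 1,
                 dimnames = list(paste0("c", 1:4), "s1"))
  p <- magflux:::new_pathway("toy", "toy", "sugar", list(
    parse_step_expression("K00010+K00011,K00012", "S1"),  # 15 + 10 = 25
    parse_step_expression("K00010+K00011", "S2"),         # 15
    parse_step_expression("K00011", "S3")                 # 20
  ))
  rec <- pathway_expression("A", p, expr, genes, "s1")
  expect_equal(rec$value, 20)
  expect_equal(rec$n_steps, 3)

  # all steps silent -> 0
  p0 <- magflux:::new_pathway("silent", "x", "sugar", list(
    parse_step_expression("K09990", "S1"), parse_step_expression("K09991", "S2")
  ))
  expect_equal(pathway_expression("A", p0, f$expr, f$genes, "s1")$value, 0)

  # 11 steps, one expressed at 11: mean 1.0
  steps11 <- lapply(1:11, function(i) {
    parse_step_expression(sprintf("K%05d", 90000 + i), paste0("S", i))
  })
  p11 <- magflux:::new_pathway("p11", "x", "sugar", steps11)
  genes11 <- make_genes("h1", "M", 300, kos = list("K90001"))
  expr11 <- matrix(11, ncol = 1, dimnames = list("h1", "s1"))
  expect_equal(pathway_expression("M", p11, expr11, genes11, "s1")$value, 1.0)
})

test_that("pathway expression is invariant under step-order permutation", {
  f <- expr_fixture()
  steps <- list(
    parse_step_expression("K00001", "S1"),
    parse_step_expression("K00002+K00003", "S2"),
    parse_step_expression("K00003,K00001", "S3")
  )
  p <- magflux:::new_pathway("perm", "x", "sugar", steps)
  p_rev <- magflux:::new_pathway("perm", "x", "sugar", rev(steps))
  expect_equal(pathway_expression("A", p, f$expr, f$genes, "s1")$value,
               pathway_expression("A", p_rev, f$expr, f$genes, "s1")$value)
})

test_that("step expression matches the brute-force enumerator on random instances", {
  set.seed(7)
  for (i in 1:200) {
    n_genes <- sample(3:12, 1)
    genes <- make_genes(
      paste0("g", seq_len(n_genes)),
      sample(c("A", "B"), n_genes, replace = TRUE), 300,
      kos = lapply(seq_len(n_genes), function(j) {
        unique(random_kos(sample.int(2, 1), pool = 15))
      })
    )
    expr <- matrix(runif(n_genes, 0, 100), ncol = 1,
                   dimnames = list(genes$gene_id, "s1"))
    step <- random_step(pool = 15)
    got <- step_expression("A", step, expr, genes, "s1")
    want <- oracle_step_expression("A", step, expr, genes, "s1")
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("adding an expressed gene copy never decreases step expression", {
  set.seed(11)
  for (i in 1:100) {
    n_genes <- sample(2:8, 1)
    genes <- make_genes(paste0("g", seq_len(n_genes)), "A", 300,
                        kos = lapply(seq_len(n_genes), function(j) {
                          random_kos(1, pool = 10)
                        }))
    expr <- matrix(runif(n_genes, 0, 50), ncol = 1,
                   dimnames = list(genes$gene_id, "s1"))
    step <- random_step(pool = 10)
    before <- step_expression("A", step, expr, genes, "s1")
    # add a copy of a KO used by the step
    new_ko <- sample(unlist(lapply(step$variants, `[[`, "required")), 1)
    genes2 <- merge_gene_tables(
      genes, make_genes("gnew", "A", 300, kos = list(new_ko))
    )
    expr2 <- rbind(expr, gnew = runif(1, 0, 50))
    after <- step_expression("A", step, expr2, genes2, "s1")
    expect_gte(after, before - 1e-12)
  }
})

test_that("vectorized pathway activity equals scalar aggregation", {
  set.seed(21)
  sim <- simulate_community(sim_config(
    n_mags = 3, seed = 5, pathways_per_mag = c(2, 4),
    conditions = "C1", n_replicates = 2
  ))
  catalog <- default_catalog()
  tpm <- compute_tpm(sim$counts, sim$genes)
  act <- pathway_activity(tpm, sim$genes, catalog)
  pick <- act[sample.int(nrow(act), 25), ]
  for (i in seq_len(nrow(pick))) {
    scalar <- pathway_expression(
      pick$mag_id[i], catalog$pathways[[pick$pathway_id[i]]],
      tpm, sim$genes, pick$sample_id[i]
    )
    expect_equal(pick$value[i], scalar$value, tolerance = 1e-9)
  }
})

test_that("MAG relative expression partitions the transcriptome", {
  f <- expr_fixture()
  # equal lengths: TPM fractions equal count fractions; A owns 67 of 167
  tpm <- compute_tpm(f$expr, setNames(rep(300, 6), rownames(f$expr)))
  a <- mag_relative_expression("A", tpm, f$genes, "s1")
  b <- mag_relative_expression("B", tpm, f$genes, "s1")
  expect_equal(a, 67 / 167)
  expect_equal(b, 100 / 167)
  expect_error(mag_relative_expression("Z", tpm, f$genes, "s1"),
               "unknown mag_id")

  # MAG owning every gene accounts for the whole transcriptome
  solo <- make_genes(rownames(f$expr), "A", 300,
                     kos = rep(list(character(0)), 6))
  expect_equal(mag_relative_expression("A", tpm, solo, "s1"), 1.0)

  m <- mag_relative_expression_matrix(tpm, f$genes)
  expect_equal(unname(m["A", 1] + m["B", 1]), 1, tolerance = 1e-12)
})
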