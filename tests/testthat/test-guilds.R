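guild_fixture <- function(activities_by_mag, present_mags = names(activities_by_mag),
                          pathway_id = "P", sample_id = "s1") {
  activities <- tibble::tibble(
    mag_id = names(activities_by_mag), pathway_id = pathway_id,
    sample_id = sample_id, value = unname(unlist(activities_by_mag)),
    n_steps = 3L
  )
  calls <- tibble::tibble(
    mag_id = names(activities_by_mag), pathway_id = pathway_id,
    present = names(activities_by_mag) %in% present_mags
  )
  list(activities = activities, calls = calls)
}

test_that("guild shares are proportional and sum to 100 over eligible MAGs", {
  f <- guild_fixture(list(A = 60, B = 30, C = 10))
  g <- guild_shares("P", f$activities, f$calls, "s1")
  expect_equal(g$share, c(60, 30, 10))
  expect_equal(sum(g$share), 100, tolerance = 1e-6)

  # single eligible expressing MAG takes 100%
  f1 <- guild_fixture(list(A = 42))
  expect_equal(guild_shares("P", f1$activities, f1$calls, "s1")$share, 100)

  # symmetric activities split evenly
  f4 <- guild_fixture(list(A = 1, B = 1, C = 1, D = 1))
  expect_equal(guild_shares("P", f4$activities, f4$calls, "s1")$share,
               rep(25, 4))

  expect_error(guild_shares("nope", f$activities, f$calls, "s1"),
               "unknown pathway")
})

test_that("non-encoding MAGs are excluded and silent guilds are flagged", {
  f <- guild_fixture(list(A = 60, B = 40, C = 900), present_mags = c("A", "B"))
  g <- guild_shares("P", f$activities, f$calls, "s1")
  expect_setequal(g$mag_id, c("A", "B"))
  expect_equal(g$share[g$mag_id == "A"], 60)

  f0 <- guild_fixture(list(A = 0, B = 0))
  g0 <- guild_shares("P", f0$activities, f0$calls, "s1")
  expect_true(all(g0$zero_guild))
  expect_equal(g0$share, c(0, 0))
})

test_that("replicate aggregation computes mean and n-1 standard deviation", {
  shares <- tibble::tibble(
    pathway_id = "P",
    sample_id = c("r1", "r2", "r3"),
    mag_id = "A", activity = c(4, 4.4, 4.2), share = c(40, 44, 42),
    zero_guild = FALSE
  )
  sheet <- tibble::tibble(sample_id = c("r1", "r2", "r3"),
                          condition = "H1", replicate = 1:3)
  agg <- replicate_aggregate(shares, sheet)
  expect_equal(agg$mean_share, 42)
  expect_equal(agg$sd_share, 2)

  # identical replicates: sd 0
  shares$share <- 10
  expect_equal(replicate_aggregate(shares, sheet)$sd_share, 0)

  # single replicate: sd undefined
  agg1 <- replicate_aggregate(shares[1, ], sheet[1, ])
  expect_equal(agg1$mean_share, 10)
  expect_true(is.na(agg1$sd_share))

  # unknown sample -> error
  bad <- shares
  bad$sample_id[1] <- "r9"
  expect_error(replicate_aggregate(bad, sheet), "absent from the sample sheet")
})

test_that("active-population ranking is deterministic with id tie-break", {
  agg <- tibble::tibble(
    pathway_id = "P", condition = "H1",
    mag_id = c("C", "A", "B"),
    mean_share = c(20, 50, 30), sd_share = 0, mean_activity = 1,
    n_replicates = 3L
  )
  expect_equal(rank_active(agg, "P", "H1")$mag_id, c("A", "B", "C"))

  agg$mean_share <- c(20, 40, 40)
  expect_equal(rank_active(agg, "P", "H1")$mag_id, c("A", "B", "C"))

  expect_equal(nrow(rank_active(agg, "P", "H9")), 0)

  # permuting rows does not change the ranking
  perm <- agg[c(2, 3, 1), ]
  expect_equal(rank_active(perm, "P", "H1"), rank_active(agg, "P", "H1"))
})

test_that("methanogenesis route shares normalize to 100% across routes", {
  routes <- c("R_hyd", "R_ace", "R_methanol")
  activities <- tibble::tibble(
    mag_id = rep(c("arc1", "arc2", "bac1"), times = 3),
    pathway_id = rep(routes, each = 3),
    sample_id = "s1",
    value = c(80, 2, 500, 10, 0, 0, 8, 0, 0),
    n_steps = 2L
  )
  calls <- tibble::tibble(
    mag_id = rep(c("arc1", "arc2", "bac1"), times = 3),
    pathway_id = rep(routes, each = 3),
    present = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  rs <- methanogenesis_route_shares(activities, calls,
                                    archaeal_mags = c("arc1", "arc2"),
                                    sample_id = "s1", routes = routes)
  # bac1's 500 TPM is excluded (not archaeal); arc totals: 82, 10, 8
  expect_equal(rs$total_activity, c(82, 10, 8))
  expect_equal(rs$share, c(82, 10, 8))
  expect_equal(sum(rs$share), 100, tolerance = 1e-6)

  # single expressed route takes 100%
  one <- activities
  one$value[one$pathway_id != "R_hyd"] <- 0
  rs1 <- methanogenesis_route_shares(one, calls, c("arc1", "arc2"), "s1",
                                     routes)
  expect_equal(rs1$share, c(100, 0, 0))

  expect_error(
    methanogenesis_route_shares(activities, calls, character(0), "s1", routes),
    "no archaeal MAGs"
  )
})

test_that("flux totals sum eligible MAGs' mean replicate activity", {
  catalog <- load_catalog(
    write_mini_catalog(withr::local_tempfile(fileext = ".yaml"))
  )
  sheet <- tibble::tibble(sample_id = c("r1", "r2", "r3"),
                          condition = "H1", replicate = 1:3)
  activities <- tidyr::expand_grid(
    mag_id = c("A", "B"), pathway_id = c("P_one", "P_two"),
    sample_id = sheet$sample_id
  )
  activities$value <- ifelse(activities$mag_id == "A", 20, 5)
  activities$n_steps <- 1L
  calls <- tidyr::expand_grid(mag_id = c("A", "B"),
                              pathway_id = c("P_one", "P_two"))
  calls$present <- calls$pathway_id == "P_one"

  fx <- flux_table(catalog, activities, calls, sheet)
  expect_equal(fx$total_expression[fx$pathway_id == "P_one"], 25)
  # no eligible MAG -> total 0, row still present
  expect_equal(fx$total_expression[fx$pathway_id == "P_two"], 0)

  # additivity over disjoint MAG subsets
  only_a <- calls
  only_a$present <- calls$present & calls$mag_id == "A"
  only_b <- calls
  only_b$present <- calls$present & calls$mag_id == "B"
  fa <- flux_table(catalog, activities, only_a, sheet)
  fb <- flux_table(catalog, activities, only_b, sheet)
  expect_equal(fa$total_expression + fb$total_expression,
               fx$total_expression)
})

test_that("the active-population filter uses a strict percent threshold", {
  rel <- matrix(
    c(0.012, 0.002,   # over 1% once -> kept
      0.010, 0.010,   # exactly 1% everywhere -> excluded
      0.000, 0.0001), # trace -> excluded at 1%, kept at 0
    nrow = 3, byrow = TRUE,
    dimnames = list(c("M1", "M2", "M3"), c("s1", "s2"))
  )
  expect_equal(active_population_filter(rel, 1.0), "M1")
  # threshold 0: every MAG with any expression is retained
  expect_setequal(active_population_filter(rel, 0), c("M1", "M2", "M3"))
})
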