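#!/usr/bin/env Rscript
# Community-level carbon flux: summed pathway expression per condition
# (the connector-thickness quantity of a carbon-flux map), aggregated by
# pathway category, and the methanogenesis route shares in the archaeal
# community along the loading gradient.

suppressMessages({
  library(magflux)
  library(dplyr)
  library(readr)
  library(tidyr)
})

conditions <- c("H15", "H7", "H4", "H2", "H1")
flux <- read_tsv("results/pipeline/flux_table.tsv", show_col_types = FALSE)
routes <- read_tsv("results/pipeline/route_shares.tsv", show_col_types = FALSE)
sheet <- read_tsv("results/sim_input/samples.tsv", show_col_types = FALSE)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

category_flux <- flux |>
  group_by(category, condition) |>
  summarise(total_expression = sum(total_expression), .groups = "drop") |>
  pivot_wider(names_from = condition, values_from = total_expression) |>
  select(category, all_of(conditions))
write_tsv(category_flux, "results/tables/category_flux.tsv")

cat("summed pathway expression (TPM) per category and condition:\n")
print(as.data.frame(category_flux), digits = 3, row.names = FALSE)

route_by_condition <- routes |>
  inner_join(sheet, by = "sample_id") |>
  group_by(pathway_id, condition) |>
  summarise(mean_share = mean(share), sd_share = sd(share), .groups = "drop") |>
  mutate(condition = factor(condition, levels = conditions)) |>
  arrange(pathway_id, condition)
write_tsv(route_by_condition, "results/tables/route_shares_by_condition.tsv")

cat("\nmethanogenesis route shares (% of archaeal route activity):\n")
wide <- route_by_condition |>
  select(pathway_id, condition, mean_share) |>
  pivot_wider(names_from = condition, values_from = mean_share)
print(as.data.frame(wide), digits = 3, row.names = FALSE)

cat("\ntables written to results/tables/\n")
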