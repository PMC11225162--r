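#!/usr/bin/env Rscript
# Rank active populations within the key functional guilds: who performs LCFA
# beta-oxidation, syntrophic propionate oxidation (MMC), and each
# methanogenesis route, and how their within-guild shares (mean +/- sd over
# replicates) change along the loading gradient.

suppressMessages({
  library(magflux)
  library(dplyr)
  library(readr)
})

agg <- read_tsv("results/pipeline/ranked_populations.tsv",
                show_col_types = FALSE)
conditions <- c("H15", "H7", "H4", "H2", "H1")
guilds <- c("lcfa_beta_oxidation", "MMC",
            "hydrogenotrophic_methanogenesis", "aceticlastic_methanogenesis")

top <- agg |>
  filter(pathway_id %in% guilds, rank <= 3) |>
  mutate(condition = factor(condition, levels = conditions)) |>
  arrange(pathway_id, condition, rank)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write_tsv(top, "results/tables/top_guild_members.tsv")

for (g in guilds) {
  cat(sprintf("\n%s — top performers (mean share %% ± sd across replicates):\n", g))
  sub <- top[top$pathway_id == g, ]
  for (cond in intersect(conditions, unique(sub$condition))) {
    rows <- sub[sub$condition == cond, ]
    cat(sprintf("  %-4s %s\n", cond, paste(
      sprintf("%s %.1f±%.1f", rows$mag_id, rows$mean_share, rows$sd_share),
      collapse = "  ")))
  }
}
cat("\ntable written to results/tables/top_guild_members.tsv\n")
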