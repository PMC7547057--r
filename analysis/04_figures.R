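#!/usr/bin/env Rscript
# Stage 4 — figures.
#
# Plots the ROI statistic of record against CT dose per algorithm, the ROI
# COV against dose, and the QSD-exceedance fraction against dose, from the
# CSV tables written by stages 2-3. Writes PNGs under results/figures/.

suppressPackageStartupMessages({
  library(ggplot2)
})

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
suv <- read.csv("results/tables/fig_suv_vs_ctdi.csv")
exc <- read.csv("results/tables/fig_exceedance_vs_ctdi.csv")

p1 <- ggplot(suv, aes(ctdi_mGy, value_of_record, colour = algorithm)) +
  geom_point(alpha = 0.8) + geom_line(linewidth = 0.3) +
  facet_wrap(~region, scales = "free_y") +
  labs(x = "CTDI (mGy)", y = "ROI SUV (statistic of record)",
       title = "ROI SUV vs CT dose per reconstruction algorithm") +
  theme_bw()
ggsave("results/figures/fig_suv_vs_ctdi.png", p1, width = 8, height = 6, dpi = 150)

p2 <- ggplot(suv[suv$statistic == "mean", ],
             aes(ctdi_mGy, cov, colour = algorithm)) +
  geom_point(alpha = 0.8) + facet_wrap(~region) +
  labs(x = "CTDI (mGy)", y = "SUV COV (%)",
       title = "ROI noise (COV) vs CT dose") +
  theme_bw()
ggsave("results/figures/fig_cov_vs_ctdi.png", p2, width = 8, height = 3.5, dpi = 150)

p3 <- ggplot(exc, aes(ctdi_mGy, pct_gt_qsd, colour = algorithm,
                      shape = factor(kVp))) +
  geom_point(size = 2) +
  labs(x = "CTDI (mGy)", y = "% voxels > QSD", shape = "kVp",
       title = "Voxels beyond the quantitatively significant difference") +
  theme_bw()
ggsave("results/figures/fig_exceedance_vs_ctdi.png", p3, width = 6, height = 4, dpi = 150)

message("Figures written to results/figures/")
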