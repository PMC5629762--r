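#!/usr/bin/env Rscript
# Stage 4: turn the Model 5 posterior into the headline economics:
# first differences, output elasticities, volume-quintile contrasts, and
# smearing-retransformed cost curves per country.

library(imcost)

tab <- read_site_table("results/site_table.csv")
best <- readRDS("results/model5_fit.rds")

fd <- rbind(
  country_first_differences(best, tab),
  do.call(rbind, lapply(
    intersect(best$spec$predictors,
              c("govt_owned", "hospital", "rural", "fraction_outreach",
                "fraction_mgmt", "dtp3_per_dose", "anc4", "wealth_ratio")),
    function(p) first_difference(best, p))),
  volume_doubling_difference(best, tab))
write.csv(fd, "results/table4_analogue.csv", row.names = FALSE)
cat("first differences (percent change in cost per dose):\n")
print(transform(fd, percent_change = round(percent_change, 1),
                ci_low = round(ci_low, 1), ci_high = round(ci_high, 1)),
      row.names = FALSE)

el <- output_elasticity(best, tab)
write.csv(el, "results/elasticity.csv", row.names = FALSE)
cat("\noutput elasticity (>1 means economies of scale):\n")
print(transform(el, elasticity = round(elasticity, 2),
                ci_low = round(ci_low, 2), ci_high = round(ci_high, 2)),
      row.names = FALSE)

qc <- volume_quintile_contrast(best, tab)
write.csv(qc, "results/quintile_contrast.csv", row.names = FALSE)
cat("\npredicted cost/dose: largest vs smallest volume quintile (% lower):\n")
print(transform(qc, percent_lower = round(percent_lower, 1)),
      row.names = FALSE)

curves <- do.call(rbind, lapply(unique(tab$country), function(cc) {
  v <- tab$doses[tab$country == cc]
  grid <- exp(seq(log(min(v)), log(max(v)), length.out = 50))
  predict_cost_curve(best, site_profile(tab, cc), grid)
}))
write.csv(curves, "results/fig1_data.csv", row.names = FALSE)
cat(sprintf("\nsmearing factor (pooled): %.3f\n",
            mean(smearing_factor(residuals(best)))))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(curves, aes(volume, avg_mean)) +
    geom_ribbon(aes(ymin = avg_lo, ymax = avg_hi), alpha = 0.25) +
    geom_line() +
    facet_wrap(~country, scales = "free") +
    scale_x_log10() +
    labs(x = "doses per year", y = "cost per dose (2011 USD)",
         title = "Average cost per dose vs service volume") +
    theme_minimal()
  ggsave("results/fig1_average_cost.pdf", p, width = 9, height = 6)
  cat("wrote results/fig1_average_cost.pdf\n")
}
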