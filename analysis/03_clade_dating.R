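#!/usr/bin/env Rscript
# Stage 3: founder-age estimation of simulated clades.
#
# Dates 500 Yule clades of known age (8,000 yr) under the complete-
# mitogenome clock with both estimators — rho with the Saillard sigma,
# and maximum-likelihood under a strict Poisson clock — and summarises
# bias, CI coverage and the agreement between the two methods. A star
# run is included as the regime where the rho CI is near-nominal.

suppressPackageStartupMessages(library(mitophylogeo))

set.seed(20260923L)
dir.create("results", showWarnings = FALSE)
true_age <- 8000
clock <- clock_model("complete")

date_clades <- function(topology, n_rep = 500L) {
  out <- lapply(seq_len(n_rep), function(i) {
    g <- simulate_clade(simulation_config(
      seed = NULL, clade_age_years = true_age, n_samples = 10,
      topology = topology))$genealogy
    a <- age_from_rho(g, clock)
    m <- ml_tmrca(g, clock, ci = FALSE)
    data.frame(topology = topology, rho = a$rho_or_ml, sigma = a$sigma,
               rho_age = a$age_years, lo = a$ci95_low, hi = a$ci95_high,
               ml_age = m$age_years,
               covered = a$ci95_low <= true_age & true_age <= a$ci95_high)
  })
  do.call(rbind, out)
}

tab <- rbind(date_clades("yule"), date_clades("star"))
utils::write.table(tab, "results/clade_dating.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (tp in c("yule", "star")) {
  s <- tab[tab$topology == tp, ]
  cat(sprintf(
    "%4s: mean rho-age %.0f yr (bias %+.1f%%), CI coverage %.1f%%, median |ML-rho| %.1f%% of truth\n",
    tp, mean(s$rho_age), 100 * (mean(s$rho_age) - true_age) / true_age,
    100 * mean(s$covered), 100 * median(abs(s$ml_age - s$rho_age)) / true_age))
}
cat("note: on non-star genealogies of this age the rho CI sits below\n")
cat("nominal coverage (few shared branches, small Poisson counts);\n")
cat("see the methods vignette for the discussion.\n")
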