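#!/usr/bin/env Rscript
# Pool per-animal coefficients to site level by inverse-variance weighting
# and build the two-site comparison table (log relative selection strength
# with 95% CIs; terms significant at both sites marked).
source("analysis/_common.R")

fits <- utils::read.csv(file.path(RESULTS, "fits.csv"))
pooled <- pool_fits(tibble::as_tibble(fits))
utils::write.csv(pooled, file.path(RESULTS, "pooled.csv"), row.names = FALSE)

cmp <- compare_sites(
  pooled[pooled$site == "A", ],
  pooled[pooled$site == "B", ]
)
utils::write.csv(cmp, file.path(RESULTS, "site_comparison.csv"),
  row.names = FALSE)

cat("significant pooled terms (95% CI excluding zero):\n")
sig <- pooled[isTRUE_v <- !is.na(pooled$significant) & pooled$significant, ]
for (i in seq_len(nrow(sig))) {
  cat(sprintf(
    "  %s / %-20s %-24s beta = %+.3f [%+.3f, %+.3f] (n = %d)\n",
    sig$site[i], sig$state[i], sig$term[i], sig$beta_bar[i],
    sig$ci_low[i], sig$ci_high[i], sig$n_individuals[i]
  ))
}
both <- cmp[cmp$both_significant, c("state", "term")]
if (nrow(both)) {
  cat("terms significant at BOTH sites:\n")
  print(as.data.frame(both), row.names = FALSE)
}
dev_rows <- cmp[cmp$term == "dist_developed_log", ]
cat("\ndistance-to-development (log) contrast by state:\n")
print(as.data.frame(dev_rows[, c("state", "beta_bar_a", "significant_a",
  "beta_bar_b", "significant_b")]), digits = 3, row.names = FALSE)
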