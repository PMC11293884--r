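# shared configuration for the analysis drivers
# (run each numbered script from the repository root, in order)
library(dispssa)

RESULTS <- "results"
SEED <- 2026L

# two synthetic study sites on 60 x 60 km landscapes, 200 m grid
SITES <- list(
  A = list(seed = SEED + 1L, label = "site A (development avoided)"),
  B = list(seed = SEED + 2L, label = "site B (development-neutral)")
)

# true standardized selection coefficients per site; site A avoids proximity
# to development (positive coefficient on log distance-to-developed)
TRUE_BETA <- list(
  A = c(dist_forest_log = -0.5, tri = 0.25, dist_developed_log = 0.4),
  B = c(dist_forest_log = -0.5, tri = 0.25, dist_developed_log = 0.0)
)

N_ANIMALS <- 6 # per site
FIX_INTERVAL_MIN <- 240

site_stack <- function(site) {
  cfg <- landscape_config(
    extent_m = 60000, cell_m = 200,
    patch_density = c(
      forest = 0.6, shrub = 0.6, water = 0.15,
      hay_crop = 0.15, developed = 0.15, road4wd = 0.02
    ),
    elevation_relief_m = 600,
    patch_radius_m = 1000,
    seed = SITES[[site]]$seed
  )
  build_covariates(generate_landscape(cfg))
}

dir.create(RESULTS, showWarnings = FALSE)
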