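#!/usr/bin/env Rscript
# Stage 5: kriged haplogroup-frequency surface.
#
# Interpolates a clade's frequency over the Europe-to-Iran study window
# by ordinary kriging: synthetic sampling sites carry a frequency field
# that decays westward from a Near-East focus (the geographic pattern a
# source-region clade shows), the empirical variogram is fitted by
# weighted least squares, and the surface is written as a plain grid.

suppressPackageStartupMessages(library(mitophylogeo))

set.seed(20260925L)
dir.create("results", showWarnings = FALSE)

# sampling sites across the study window, frequency highest near the
# 50E focus and decaying west, plus sampling noise
n_sites <- 24L
lon <- runif(n_sites, 5, 55)
lat <- runif(n_sites, 32, 50)
focus_lon <- 50; focus_lat <- 35
d_focus <- geosphere::distHaversine(cbind(lon, lat),
                                    c(focus_lon, focus_lat)) / 1000
freq <- pmin(1, pmax(0, 0.45 * exp(-d_focus / 1800) +
                        rnorm(n_sites, 0, 0.02)))
sites <- geo_samples(lon, lat, freq, is_frequency = TRUE)

emp <- empirical_variogram(sites, n_bins = 10L)
model <- fit_variogram(emp, "exponential")
cat(sprintf("fitted exponential variogram: nugget %.4f, sill %.4f, range %.0f km\n",
            model$nugget, model$sill, model$range))

surf <- ordinary_krige(sites, model, grid = make_grid(sites, 60, 40),
                       clip_frequency = TRUE)
write_surface(surf, "results/u7a4_like_surface.tsv")
cat(sprintf("surface: %d x %d cells, values %.3f-%.3f, max weight error %.1e\n",
            length(surf$lon), length(surf$lat), min(surf$values),
            max(surf$values), surf$max_weight_error))

# the eastern third of the grid should carry the higher frequencies
east <- surf$lon > quantile(surf$lon, 2 / 3)
west <- surf$lon < quantile(surf$lon, 1 / 3)
cat(sprintf("mean frequency: eastern third %.3f vs western third %.3f\n",
            mean(surf$values[east, ]), mean(surf$values[west, ])))
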