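#!/usr/bin/env Rscript
# Collagen organization: simulate immunofluorescence sections with a
# peripheral ring of collagen (control-like) versus scattered puncta of
# equal total signal (mutant-like), profile each with concentric-circle
# (Sholl) counts, and compare the pooled radial distributions with a
# Mann-Whitney U test.

suppressPackageStartupMessages(library(organoidmech))
dir.create("results", showWarnings = FALSE)

n_per <- 3   # sections per condition
ring_profiles <- lapply(1:n_per, function(s)
  sholl_counts(gen_collagen_image("ring", seed = s)))
scat_profiles <- lapply(1:n_per, function(s)
  sholl_counts(gen_collagen_image("scattered", seed = 100 + s)))

prof_tab <- do.call(rbind, c(
  lapply(seq_along(ring_profiles), function(i) data.frame(
    condition = "ring", section = i,
    radius_norm = ring_profiles[[i]]$radii,
    count = ring_profiles[[i]]$counts)),
  lapply(seq_along(scat_profiles), function(i) data.frame(
    condition = "scattered", section = i,
    radius_norm = scat_profiles[[i]]$radii,
    count = scat_profiles[[i]]$counts))))
write.csv(prof_tab, "results/sholl_profiles.csv", row.names = FALSE)

res <- compare_profiles(ring_profiles, scat_profiles)
jsonlite::write_json(res, "results/sholl_test.json", auto_unbox = TRUE,
                     digits = NA)

ring_mass <- with(subset(prof_tab, condition == "ring"),
                  sum(count[abs(radius_norm - 0.8) <= 0.04]) / sum(count))
cat(sprintf("Ring sections: %.0f%% of intersections within 2 increments of r = 0.8\n",
            100 * ring_mass))
cat(sprintf("Scattered sections: intersections spread over %d of %d circles\n",
            sum(tapply(prof_tab$count[prof_tab$condition == "scattered"],
                       prof_tab$radius_norm[prof_tab$condition == "scattered"],
                       sum) > 0),
            length(ring_profiles[[1]]$radii)))
cat(sprintf("Mann-Whitney U = %g, two-sided p = %.3g (n1 = %d, n2 = %d circles)\n",
            res$U, res$p_value, res$n1, res$n2))
cat("\nThe circularly organized deposition concentrates its radial profile\n")
cat("at the ring radius while the scattered phenotype spreads across the\n")
cat("section; the rank-sum test separates the two decisively.\n")
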