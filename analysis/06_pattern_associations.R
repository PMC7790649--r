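#!/usr/bin/env Rscript
# Do the growth patterns map onto the canopy? Monte-Carlo independence
# tests of pattern vs canopy layer and pattern vs species (fixed-margin
# chi-square permutation), and stratified permutation F-tests comparing
# growth attributes, DBH and height between patterns.

library(ringpatterns)

asg <- utils::read.csv("results/pattern_assignments.csv")
inv <- utils::read.csv("results/inventory_layers.csv")
attrs <- utils::read.csv("results/growth_attributes.csv")
m <- merge(merge(asg, inv, by = "tree_id"), attrs, by = "tree_id")
alive <- m[m$vitality == "alive" & !is.na(m$canopy_layer), ]

layer_tab <- table(alive$pattern, alive$canopy_layer)
res_layer <- pattern_association_test(layer_tab, n_permutations = 9999L,
                                      seed = 1L)
species_tab <- table(alive$pattern, alive$species)
res_species <- pattern_association_test(species_tab, n_permutations = 9999L,
                                        seed = 2L)
cat("pattern x canopy layer:\n"); print(res_layer)
cat("pattern x species:\n"); print(res_species)

tests <- list()
for (v in c("age", "mean_rw", "sd_rw", "p5_rw", "p95_rw", "dbh_cm")) {
  r <- attribute_group_test(m[[v]], m$pattern, strata = m$plot_id,
                            n_permutations = 999L, seed = 3L)
  tests[[v]] <- data.frame(attribute = v, F = r$statistic, p = r$p_value)
  cat(sprintf("%-8s F = %6.2f  p = %.4g  letters: %s\n", v, r$statistic,
              r$p_value, paste(names(r$letters), r$letters, sep = "=",
                               collapse = " ")))
}
# height compared on intact crowns only (broken tops bias measured height)
intact <- m[m$crown_status == "intact", ]
r <- attribute_group_test(intact$height_m, intact$pattern,
                          strata = intact$plot_id, n_permutations = 999L,
                          seed = 4L)
tests$height <- data.frame(attribute = "height_m (intact crowns)",
                           F = r$statistic, p = r$p_value)
cat(sprintf("%-8s F = %6.2f  p = %.4g\n", "height", r$statistic, r$p_value))

assoc <- data.frame(test = c("pattern_x_layer", "pattern_x_species"),
                    chisq = c(res_layer$statistic, res_species$statistic),
                    p = c(res_layer$p_value, res_species$p_value))
utils::write.csv(assoc, "results/association_tests.csv", row.names = FALSE)
utils::write.csv(do.call(rbind, tests), "results/attribute_tests.csv",
                 row.names = FALSE)
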