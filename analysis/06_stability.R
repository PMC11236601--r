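#!/usr/bin/env Rscript
# Stage 6 — parent stability within the main environment cluster: Shukla's
# stability variance of per-site additive effects and the mean-vs-stability
# quadrant classification that flags stable positive contributors.

suppressMessages(library(heteropool))
out <- "results/analysis"

gebv <- read.csv(file.path(out, "gebv.csv"))
clusters <- read.csv(file.path(out, "site_clusters.csv"))
member <- read.csv(file.path(out, "admixture_Q.csv"))

main <- clusters$site[clusters$cluster == clusters$cluster[1]]
g <- gebv[gebv$site %in% main, ]
parents <- unique(g$parent); sites <- unique(g$site)
eff <- matrix(NA_real_, length(parents), length(sites),
              dimnames = list(parents, sites))
eff[cbind(match(g$parent, parents), match(g$site, sites))] <- g$gebv

st <- suppressWarnings(shukla_variance(eff, complete = !anyNA(eff)))
st$subgroup <- member$assigned[match(st$genotype, member$id)]
st <- quadrant_classify(st)
write.csv(st, file.path(out, "stability.csv"), row.names = FALSE)

sp <- st[st$quadrant == "stable-positive", ]
cat(sprintf(paste0(
  "Shukla stability over the %d sites of cluster %d: %d of %d parents are ",
  "stable-positive (mean additive effect > 0, sqrt stability below the ",
  "panel median); they come from subgroup(s) {%s}.\n"),
  length(main), clusters$cluster[1], nrow(sp), nrow(st),
  paste(sort(unique(sp$subgroup)), collapse = ", ")))
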