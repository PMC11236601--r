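#!/usr/bin/env Rscript
# Stage 1 — generate the desk-scale synthetic study: a structured inbred
# parent panel, a genetic map, a sparse p-rep testcross MET and plot-level
# yields with known ground truth. All later stages read these files.

suppressMessages(library(heteropool))
cfg <- desk_config()
seed <- 1
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- simulate_founders(cfg$K, cfg$n_per_group, cfg$n_markers, cfg$fst, seed)
map <- simulate_map(cfg$n_chrom, cfg$n_markers / cfg$n_chrom,
                    cfg$chrom_length_cM, marker_ids = colnames(panel$dosage),
                    seed = seed)
ids <- rownames(panel$dosage)
plan <- make_cross_plan(ids[seq_len(cfg$n_males)],
                        ids[(cfg$n_males + 1):length(ids)],
                        cfg$n_hybrids, cfg$sites, cfg$hybrids_per_site,
                        cfg$checks, seed)
truth <- truth_params(cfg$sites, sigma2_a = cfg$sigma2_a,
                      sigma2_s = cfg$sigma2_s, sigma2_e = cfg$sigma2_e,
                      site_corr = site_cluster_corr(cfg$site_cluster,
                                                    cfg$corr_within,
                                                    cfg$corr_between),
                      site_mean = cfg$site_mean)
met <- simulate_met(panel, plan, truth, seed = seed, prep_frac = cfg$prep_frac)

write_dosage_csv(panel$dosage, file.path(out, "dosage.csv"))
write_vcf(panel$dosage, file.path(out, "parents.vcf"), map = map)
write_map_csv(map, file.path(out, "map.csv"))
write.csv(met$pheno, file.path(out, "pheno.csv"), row.names = FALSE)
write_dosage_csv(met$true_gca, file.path(out, "true_gca.csv"))
write.csv(data.frame(id = names(panel$membership),
                     subgroup = panel$membership),
          file.path(out, "true_membership.csv"), row.names = FALSE)

cat(sprintf(paste0(
  "Simulated %d inbred parents in %d subgroups at %d SNPs, %d hybrids over ",
  "%d sites (%d plots total; %.0f%% p-rep), true additive variance %.2f in ",
  "two environment clusters (r = %.1f within, %.1f between).\n"),
  nrow(panel$dosage), cfg$K, cfg$n_markers, cfg$n_hybrids, cfg$sites,
  nrow(met$pheno), 100 * cfg$prep_frac, cfg$sigma2_a, cfg$corr_within,
  cfg$corr_between))
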