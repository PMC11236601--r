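#' Desk-scale pipeline configuration
#'
#' A reduced-scale preset of the full analysis: 40 inbred parents (30 male,
#' 10 female) in 3 subgroups, 300 mapped SNPs on 10 chromosomes, 200 F1
#' test hybrids over 8 p-rep trial sites falling in two environment
#' clusters (additive correlation 0.8 within, -0.2 between), additive
#' variance 0.5, SCA variance 0.1, residual variance 1.0.
#'
#' @return a named list of stage parameters for \code{\link{run_pipeline}}.
#' @export
desk_config <- function() {
  list(preset = "desk",
       K = 3, n_per_group = c(14, 13, 13), n_markers = 300, fst = 0.15,
       n_chrom = 10, chrom_length_cM = 150,
       n_males = 30, n_hybrids = 200, sites = 8, hybrids_per_site = 100,
       checks = paste0("CHK", 1:3), prep_frac = 0.3,
       site_cluster = rep(1:2, each = 4), corr_within = 0.8,
       corr_between = -0.2,
       sigma2_a = 0.5, sigma2_s = 0.1, sigma2_e = 1.0, site_mean = 6,
       qc_max_het = 0.5, qc_max_missing = 0.1,
       k_min = 2, k_max = 5, cv_folds = 3,
       fa_k = 2, n_dh = 100, sel_p = 0.10, sel_h = 1.0,
       uc_sites = 2)
}

## hash of an R object (via a serialized temp file)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full heterotic-pool analysis pipeline
#'
#' Executes the stages simulate -> qc -> structure -> trial-fit -> met-fa ->
#' gblup -> stability -> usefulness in dependency order, writing every
#' intermediate as CSV/JSON under \code{out_dir} and a checksummed run
#' manifest. A stage whose recorded hash (config + seed + upstream outputs)
#' matches the previous run is skipped and its cached outputs reused.
#'
#' @param config a configuration list (see \code{\link{desk_config}}).
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = desk_config(), seed = 1,
                         out_dir = "results/desk") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  manifest <- list(config = config, seed = seed, stages = list())
  state <- new.env()

  run_stage <- function(name, inputs_hash, outputs, fun) {
    stage_hash <- object_hash(list(config, seed, name, inputs_hash))
    paths <- file.path(out_dir, outputs)
    cached <- !is.null(old_manifest) &&
      !is.null(old_manifest$stages[[name]]) &&
      identical(old_manifest$stages[[name]]$hash, stage_hash) &&
      all(file.exists(paths))
    t0 <- proc.time()[3]
    if (cached) {
      message(sprintf("[%s] cached, skipping", name))
      fun(cached = TRUE)
    } else {
      message(sprintf("[%s] running", name))
      ok <- tryCatch({ fun(cached = FALSE); TRUE },
                     error = function(e) {
                       stop(sprintf("pipeline stage '%s' failed: %s",
                                    name, conditionMessage(e)), call. = FALSE)
                     })
    }
    manifest$stages[[name]] <<- list(
      hash = stage_hash, cached = cached,
      elapsed_s = round(proc.time()[3] - t0, 2),
      files = as.list(tools::md5sum(paths)))
    stage_hash
  }

  ## -- simulate ------------------------------------------------------------
  h_sim <- run_stage("simulate", NULL,
    c("dosage.csv", "map.csv", "pheno.csv", "true_gca.csv"),
    function(cached) {
      if (!cached) {
        panel <- simulate_founders(config$K, config$n_per_group,
                                   config$n_markers, config$fst, seed)
        map <- simulate_map(config$n_chrom,
                            ceiling(config$n_markers / config$n_chrom),
                            config$chrom_length_cM,
                            marker_ids = colnames(panel$dosage), seed = seed)
        ids <- rownames(panel$dosage)
        plan <- make_cross_plan(ids[seq_len(config$n_males)],
                                ids[(config$n_males + 1):length(ids)],
                                config$n_hybrids, config$sites,
                                config$hybrids_per_site, config$checks, seed)
        corr <- site_cluster_corr(config$site_cluster, config$corr_within,
                                  config$corr_between)
        truth <- truth_params(config$sites, sigma2_a = config$sigma2_a,
                              sigma2_s = config$sigma2_s,
                              sigma2_e = config$sigma2_e,
                              site_corr = corr, site_mean = config$site_mean)
        met <- simulate_met(panel, plan, truth, seed = seed,
                            prep_frac = config$prep_frac)
        write_dosage_csv(panel$dosage, file.path(out_dir, "dosage.csv"))
        write_map_csv(map, file.path(out_dir, "map.csv"))
        utils::write.csv(met$pheno, file.path(out_dir, "pheno.csv"),
                         row.names = FALSE)
        write_dosage_csv(met$true_gca, file.path(out_dir, "true_gca.csv"))
        state$membership <- panel$membership
        state$plan <- plan
      }
      state$dosage <- read_dosage_csv(file.path(out_dir, "dosage.csv"))
      state$map <- read_map_csv(file.path(out_dir, "map.csv"))
      state$pheno <- utils::read.csv(file.path(out_dir, "pheno.csv"),
                                     stringsAsFactors = FALSE)
    })

  ## -- qc ------------------------------------------------------------------
  h_qc <- run_stage("qc", h_sim, "qc_dosage.csv", function(cached) {
    if (!cached) {
      g <- filter_markers(state$dosage, config$qc_max_het, config$qc_max_missing)
      g <- prune_complete_ld(g)
      write_dosage_csv(g, file.path(out_dir, "qc_dosage.csv"))
    }
    state$geno <- read_dosage_csv(file.path(out_dir, "qc_dosage.csv"))
  })

  ## -- structure -----------------------------------------------------------
  h_str <- run_stage("structure", h_qc,
    c("pcoa.csv", "admixture_Q.csv", "structure.json"),
    function(cached) {
      if (!cached) {
        d <- rogers_distance(state$geno)
        pc <- pcoa_coords(d, n_axes = 2)
        cv <- select_K_cv(state$geno, config$k_min, config$k_max,
                          config$cv_folds, seed)
        fit <- suppressWarnings(admixture_fit(state$geno, cv$K, seed))
        utils::write.csv(data.frame(id = rownames(pc$coords), pc$coords),
                         file.path(out_dir, "pcoa.csv"), row.names = FALSE)
        utils::write.csv(data.frame(id = rownames(fit$Q), fit$Q,
                                    assigned = max.col(fit$Q)),
                         file.path(out_dir, "admixture_Q.csv"), row.names = FALSE)
        jsonlite::write_json(list(K = cv$K, cv_error = as.list(cv$cv_error),
                                  loglik = fit$loglik),
                             file.path(out_dir, "structure.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      q <- utils::read.csv(file.path(out_dir, "admixture_Q.csv"),
                           stringsAsFactors = FALSE)
      state$subgroup <- stats::setNames(q$assigned, q$id)
    })

  ## -- trial-fit -----------------------------------------------------------
  h_tf <- run_stage("trial-fit", h_sim, c("blups.csv", "varcomp.csv"),
    function(cached) {
      if (!cached) {
        sites <- unique(state$pheno$site)
        blups <- list(); vc <- list()
        for (s in sites) {
          fit <- suppressWarnings(
            fit_trial(state$pheno[state$pheno$site == s, ], genetic = "additive"))
          blups[[s]] <- cbind(site = s, fit$effects)
          vc[[s]] <- data.frame(site = s, component = names(fit$sigma2),
                                estimate = unname(fit$sigma2),
                                loglik = fit$loglik, h2 = fit$h2)
        }
        utils::write.csv(do.call(rbind, blups), file.path(out_dir, "blups.csv"),
                         row.names = FALSE)
        utils::write.csv(do.call(rbind, vc), file.path(out_dir, "varcomp.csv"),
                         row.names = FALSE)
      }
      state$blups <- utils::read.csv(file.path(out_dir, "blups.csv"),
                                     stringsAsFactors = FALSE)
    })

  ## -- met-fa --------------------------------------------------------------
  h_fa <- run_stage("met-fa", h_tf,
    c("fa_loadings.csv", "genetic_corr.csv", "site_clusters.csv", "fa.json"),
    function(cached) {
      if (!cached) {
        b <- state$blups[state$blups$observed_at_site, ]
        sites <- sort(unique(b$site))
        parents <- sort(unique(b$level))
        eff <- matrix(NA_real_, length(parents), length(sites),
                      dimnames = list(parents, sites))
        eff[cbind(match(b$level, parents), match(b$site, sites))] <- b$blup
        w <- matrix(NA_real_, length(parents), length(sites))
        w[cbind(match(b$level, parents), match(b$site, sites))] <-
          1 / pmax(b$pev, 1e-6)
        w <- w / mean(w, na.rm = TRUE)
        fa <- suppressWarnings(fit_fa(eff, k = config$fa_k, weights = w,
                                      max_iter = 500, tol = 1e-6))
        corr <- genetic_correlation(fa)
        cl <- cluster_sites(corr)
        ve <- variance_explained(fa, min(2, config$fa_k))
        utils::write.csv(data.frame(site = rownames(fa$loadings), fa$loadings,
                                    psi = fa$psi),
                         file.path(out_dir, "fa_loadings.csv"), row.names = FALSE)
        utils::write.csv(data.frame(site = rownames(corr), corr),
                         file.path(out_dir, "genetic_corr.csv"), row.names = FALSE)
        utils::write.csv(data.frame(site = names(cl$labels),
                                    cluster = unname(cl$labels)),
                         file.path(out_dir, "site_clusters.csv"), row.names = FALSE)
        jsonlite::write_json(
          list(k = fa$k, n_clusters = cl$n_clusters,
               pct_var_first2_mean = ve$overall,
               pct_var_first2_weighted = ve$overall_weighted),
          file.path(out_dir, "fa.json"), auto_unbox = TRUE, digits = NA)
      }
      state$clusters <- utils::read.csv(file.path(out_dir, "site_clusters.csv"),
                                        stringsAsFactors = FALSE)
    })

  ## -- gblup ---------------------------------------------------------------
  h_gb <- run_stage("gblup", object_hash(c(h_qc, h_tf)),
    c("grm.csv", "gebv.csv", "marker_effects.csv"),
    function(cached) {
      if (!cached) {
        grm <- compute_grm(state$geno)
        sites <- unique(state$pheno$site)
        gebv <- list(); me <- list()
        for (s in sites) {
          ph <- state$pheno[state$pheno$site == s, ]
          fit <- suppressWarnings(fit_trial(ph, genetic = "hybrid"))
          hy <- fit$effects
          crosses <- unique(ph[!ph$is_check, c("entry", "male", "female")])
          names(crosses)[1] <- "hybrid"
          design <- build_hybrid_additive_design(crosses, rownames(grm$K))
          design <- design[hy$level, , drop = FALSE]
          gb <- suppressWarnings(gblup_solve(hy$blup, grm, design))
          al <- backsolve_markers(gb$gebv, grm)
          gebv[[s]] <- data.frame(site = s, parent = names(gb$gebv),
                                  gebv = unname(gb$gebv))
          me[[s]] <- cbind(site = s, effect_profile(al, map = state$map))
        }
        utils::write.csv(data.frame(id = rownames(grm$K), grm$K),
                         file.path(out_dir, "grm.csv"), row.names = FALSE)
        utils::write.csv(do.call(rbind, gebv), file.path(out_dir, "gebv.csv"),
                         row.names = FALSE)
        utils::write.csv(do.call(rbind, me),
                         file.path(out_dir, "marker_effects.csv"),
                         row.names = FALSE)
      }
      state$gebv <- utils::read.csv(file.path(out_dir, "gebv.csv"),
                                    stringsAsFactors = FALSE)
      state$marker_effects <- utils::read.csv(
        file.path(out_dir, "marker_effects.csv"), stringsAsFactors = FALSE)
    })

  ## -- stability -----------------------------------------------------------
  h_st <- run_stage("stability", object_hash(c(h_gb, h_fa)), "stability.csv",
    function(cached) {
      if (!cached) {
        main <- state$clusters$site[state$clusters$cluster ==
                                      state$clusters$cluster[1]]
        g <- state$gebv[state$gebv$site %in% main, ]
        sites <- unique(g$site)
        parents <- unique(g$parent)
        eff <- matrix(NA_real_, length(parents), length(sites),
                      dimnames = list(parents, sites))
        eff[cbind(match(g$parent, parents), match(g$site, sites))] <- g$gebv
        st <- suppressWarnings(shukla_variance(eff, complete = !anyNA(eff)))
        st$subgroup <- unname(state$subgroup[st$genotype])
        st <- quadrant_classify(st)
        utils::write.csv(st, file.path(out_dir, "stability.csv"),
                         row.names = FALSE)
      }
    })

  ## -- usefulness ----------------------------------------------------------
  run_stage("usefulness", object_hash(c(h_gb, h_str)),
    c("uc.csv", "uc_summary.json"),
    function(cached) {
      if (!cached) {
        panel <- structure(list(dosage = state$geno,
                                membership = state$subgroup[rownames(state$geno)],
                                K = length(unique(state$subgroup))),
                           class = "founder_panel")
        anchor <- as.integer(names(which.max(table(panel$membership))))
        uc_sites <- utils::head(unique(state$marker_effects$site),
                                config$uc_sites)
        effs <- lapply(uc_sites, function(s) {
          m <- state$marker_effects[state$marker_effects$site == s, ]
          stats::setNames(m$effect, m$marker)
        })
        names(effs) <- uc_sites
        site_means <- vapply(uc_sites, function(s)
          mean(state$pheno$yield[state$pheno$site == s]), numeric(1))
        uc <- compare_cross_sets(panel, anchor, effs, state$map,
                                 site_means = site_means, n = config$n_dh,
                                 p = config$sel_p, h = config$sel_h,
                                 seed = seed)
        utils::write.csv(uc, file.path(out_dir, "uc.csv"), row.names = FALSE)
        agg <- stats::aggregate(uc ~ category + site, data = uc, stats::median)
        jsonlite::write_json(
          list(anchor_group = anchor,
               median_uc = split(agg$uc, paste(agg$site, agg$category))),
          file.path(out_dir, "uc_summary.json"), auto_unbox = TRUE, digits = NA)
      }
    })

  manifest$finished <- TRUE
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
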