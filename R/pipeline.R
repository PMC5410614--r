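#' Run the full association-mapping pipeline
#'
#' Wires the stages in workflow order -- diversity, structure (admixture over
#' a K range with Evanno delta-K, assignment, NJ tree, PCoA, kinship, AMOVA),
#' phenotype statistics, marker scans over all twelve datasets per trait,
#' favorable-allele mining and cross proposals -- and writes each stage's
#' tables under `out_dir` along with a manifest recording the seed and
#' parameters. Every random draw derives from `seed`.
#'
#' @param panel a [genotype_panel()].
#' @param pheno a `phenotype_table`.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed.
#' @param k_range K values for admixture inference.
#' @param restarts EM restarts per K (also the Evanno replicates).
#' @param n_perm permutations for AMOVA and LD p-values.
#' @param min_effect ppm threshold for cross-planning alleles.
#' @param max_iter,tol EM stopping rule.
#' @param top_n_crosses crosses to report.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(panel, pheno, out_dir, seed = 1L,
                         k_range = 1:6, restarts = 5, n_perm = 199,
                         min_effect = 0, max_iter = 500, tol = 1e-4,
                         top_n_crosses = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message("[", name, "] ...")
    v <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message("[", name, "] done in ",
            round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
            " s")
    v
  }

  div <- stage("diversity", allele_summary(panel))
  write_report(div, file.path(out_dir, "diversity.tsv"))

  runs_by_K <- stage("structure", lapply(k_range, function(K)
    fit_admixture(panel, K, restarts = restarts, max_iter = max_iter,
                  tol = tol, seed = seed + K)))
  names(runs_by_K) <- paste0("K", k_range)
  ev <- evanno_delta_k(runs_by_K)
  best_K <- attr(ev, "best_K")
  write_report(ev, file.path(out_dir, "evanno_delta_k.tsv"))
  Q <- runs_by_K[[paste0("K", best_K)]][[1]]$Q
  write_q_matrix(Q, file.path(out_dir, "q_matrix.csv"))
  assignment <- assign_subpopulations(Q)
  write_report(assignment, file.path(out_dir, "subpopulations.tsv"))

  D <- stage("distance", nei_distance(panel))
  tree <- nj_tree(D)
  ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
  pc <- pcoa(D, n_axes = 3)
  write_report(data.frame(line = rownames(pc$coords), pc$coords),
               file.path(out_dir, "pcoa.csv"))
  km <- kinship(panel)
  write_kinship(km$k, file.path(out_dir, "kinship.csv"))

  am <- stage("amova", amova(panel, assignment, n_perm = n_perm, seed = seed))
  write_report(am$components, file.path(out_dir, "amova.tsv"))

  ld <- stage("ld", ld_matrix(panel, n_perm = n_perm, seed = seed + 1L))
  write_report(ld, file.path(out_dir, "ld_pairs.tsv"))

  thr <- bonferroni_threshold(nrow(panel$markers))
  scans <- list(); descr <- list(); mined <- list()
  for (tr in .traits) {
    descr[[tr]] <- stage(paste0("pheno-stats-", tr),
                         describe_datasets(pheno, tr))
    write_report(descr[[tr]], file.path(out_dir, paste0("pheno_", tr, ".tsv")))
    ds <- build_datasets(pheno, tr)
    recs <- stage(paste0("mlm-", tr), do.call(rbind, lapply(names(ds),
      function(nm) mlm_scan(ds[[nm]], panel, Q, km, trait = tr,
                            dataset_name = nm))))
    scans[[tr]] <- recs
    sig <- recs[recs$p < thr$p_threshold, , drop = FALSE]
    if (nrow(sig)) {
      eff <- do.call(rbind, lapply(unique(sig$dataset), function(nm)
        allele_effects(panel, ds[[nm]], unique(sig$marker_id[sig$dataset == nm]),
                       trait = tr, dataset_name = nm)))
      mined[[tr]] <- eff
    }
  }
  all_recs <- do.call(rbind, scans)
  write_report(all_recs[, setdiff(names(all_recs), "allele_effects")],
               file.path(out_dir, "mta_records.tsv"))
  freq <- mta_frequency(all_recs, thr$p_threshold)
  write_report(freq, file.path(out_dir, "mta_frequency.tsv"))

  crosses <- NULL
  if (length(mined)) {
    eff <- do.call(rbind, mined)
    fav <- favorable_alleles(eff, min_effect = min_effect)
    if (nrow(fav)) {
      write_report(fav, file.path(out_dir, "favorable_alleles.tsv"))
      inv <- stage("crosses", genotype_allele_inventory(panel, fav))
      crosses <- propose_crosses(inv, top_n = top_n_crosses)
      write_report(crosses, file.path(out_dir, "crosses.tsv"))
    }
  }

  manifest <- c(sprintf("seed: %d", seed),
                sprintf("stages: %s", paste(
                  c("diversity", "structure", "distance", "amova", "ld",
                    "pheno-stats", "association", "mining"), collapse = ", ")),
                sprintf("k_range: %s", paste(range(k_range), collapse = "..")),
                sprintf("restarts: %d", restarts),
                sprintf("n_perm: %d", n_perm),
                sprintf("best_K: %d", best_K),
                sprintf("p_threshold: %.6g", thr$p_threshold))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(diversity = div, evanno = ev, best_K = best_K, Q = Q,
                 assignment = assignment, amova = am, ld = ld, kinship = km,
                 tree = tree, pcoa = pc, descriptives = descr,
                 mta = all_recs, mta_frequency = freq, crosses = crosses))
}
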