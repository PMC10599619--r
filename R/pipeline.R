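# End-to-end orchestration: synthetic (or file) inputs -> ordination and
# dimension selection -> parameterization chains -> mini chains -> species and
# clade scores -> orthogonality -> distribution statistics -> PGLS suite.
# Every artifact embeds the config hash and master seed; re-running the same
# config is byte-identical.

# Small polynomial rolling hash of a deparsed R object (stays in double
# precision; no external digest dependency).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' All knobs of the end-to-end run in one validated list. When `trees_path`,
#' `traits_path` and `hierarchy_path` are `NULL`, synthetic demo inputs are
#' generated (a Yule tree, branch-length-perturbed tree set, carved clades and
#' nested-Brownian traits with recorded ground truth).
#'
#' @param trees_path,traits_path,hierarchy_path optional input files (Newick,
#'   CSV, CSV); all three or none.
#' @param n_tips,k,n_clades,min_size,n_trees,birth_rate,jitter_sd synthetic
#'   input sizes: tips, trait dimension, clades per level, clade-size
#'   threshold, number of trees, Yule rate, branch jitter.
#' @param minichains a [minichain_config()] (demo-scale by default here:
#'   short parameterization chains and as many mini chains as trees).
#' @param clade_threshold per-clade variance fraction for dimension selection.
#' @param ci_level,chisq_df axis extent options (see [major_axis()]).
#' @param n_bins histogram bins for [bhattacharyya()].
#' @param cor_method correlation type for [posterior_correlation()].
#' @param lambda_mode PGLS lambda mode (see [table1_suite()]).
#' @param seed master seed for every source of randomness.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(trees_path = NULL, traits_path = NULL,
                            hierarchy_path = NULL,
                            n_tips = 64L, k = 4L, n_clades = 3L,
                            min_size = 8L, n_trees = 20L, birth_rate = 1,
                            jitter_sd = 0.1,
                            minichains = minichain_config(
                              param_generations = 400L, n_trees = n_trees,
                              samples_per_tree = 10L, minichain_thin = 2L),
                            clade_threshold = 0.95, ci_level = 0.95,
                            chisq_df = NULL, n_bins = 100L,
                            cor_method = "pearson",
                            lambda_mode = "fixed-1", seed = 42L) {
  paths <- c(trees_path, traits_path, hierarchy_path)
  if (length(paths) %in% c(1L, 2L))
    stop("supply all three input paths, or none for synthetic inputs")
  if (length(paths) == 3L) {
    gone <- paths[!file.exists(paths)]
    if (length(gone)) stop("input file(s) not found: ", paste(gone, collapse = ", "))
  }
  structure(list(trees_path = trees_path, traits_path = traits_path,
                 hierarchy_path = hierarchy_path, n_tips = as.integer(n_tips),
                 k = as.integer(k), n_clades = as.integer(n_clades),
                 min_size = as.integer(min_size), n_trees = as.integer(n_trees),
                 birth_rate = birth_rate, jitter_sd = jitter_sd,
                 minichains = minichains, clade_threshold = clade_threshold,
                 ci_level = ci_level, chisq_df = chisq_df, n_bins = n_bins,
                 cor_method = cor_method, lambda_mode = lambda_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Report writer: CSV with a provenance comment line (config hash + seed).
write_report <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# macroaxes run config=%s seed=%d", hash, seed), con)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writing each stage's outputs under
#' `output_dir`. All randomness derives from the config's master seed through
#' a counter-based splitter, and no artifact contains a timestamp, so two runs
#' from one config produce byte-identical files. When `resume = TRUE`, stages
#' whose output files already exist with a matching config hash are skipped.
#'
#' @param config a [pipeline_config()].
#' @param output_dir run directory (created if needed).
#' @param resume skip completed stages of a previous identical run.
#' @return invisibly, the output directory path.
#' @export
run_pipeline <- function(config, output_dir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  seed <- config$seed
  pth <- function(f) file.path(output_dir, f)
  final_reports <- c("dimension_selection.csv", "scores_ordinated.csv",
                     "parameterization.csv", "ess.csv", "scores_species.csv",
                     "scores_clade.csv", "orthogonality.csv",
                     "bhattacharyya.csv", "correlations.csv",
                     "pagels_lambda.csv", "pgls_table.csv")
  if (resume && all(file.exists(pth(final_reports))) &&
      all(vapply(pth(final_reports), function(f) {
        l1 <- tryCatch(readLines(f, n = 1), error = function(e) "")
        grepl(hash, l1, fixed = TRUE)
      }, logical(1)))) {
    message("all reports present for this config hash; nothing to do")
    return(invisible(output_dir))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[3] - t0))
    out
  }

  ## stage 1: inputs ---------------------------------------------------------
  inputs <- stage("inputs", {
    if (!is.null(config$trees_path)) {
      trees <- read_newick(config$trees_path)
      if (inherits(trees, "phylo")) trees <- list(trees)
      traits <- read_traits(config$traits_path)
      hierarchy <- read_hierarchy(config$hierarchy_path,
                                  min_size = config$min_size)
      validate_inputs(trees[[1]], traits, hierarchy)
      list(trees = trees, traits = traits, hierarchy = hierarchy,
           truth = NULL)
    } else {
      base <- simulate_yule_tree(config$n_tips, config$birth_rate,
                                 seed = derive_seed(seed, 1))
      hierarchy <- carve_clades(base, config$n_clades,
                                min_size = config$min_size,
                                seed = derive_seed(seed, 2))
      trees <- simulate_tree_set(base, config$n_trees, config$jitter_sd,
                                 seed = derive_seed(seed, 3))
      k <- config$k
      evs <- 4 * 0.5^(seq_len(k) - 1)
      clades <- hierarchy_clades(hierarchy)
      clade_R <- stats::setNames(lapply(seq_along(clades), function(i)
        make_rate_matrix(evs, orientation_seed = derive_seed(seed, 10 + i))),
        clades)
      truth <- ground_truth(
        class_R = make_rate_matrix(evs, planar_angle = 0),
        clade_R = clade_R, residual_E = 0.05 * diag(k),
        hierarchy = hierarchy)
      traits <- simulate_traits(base, hierarchy, truth,
                                seed = derive_seed(seed, 4))
      write_newick(trees, pth("trees.nwk"))
      write_traits(traits, pth("traits.csv"))
      utils::write.csv(hierarchy$assignment, pth("hierarchy.csv"),
                       row.names = FALSE)
      yaml::write_yaml(list(config_hash = hash, seed = seed,
                            class_R = unname(as.data.frame(truth$class_R)),
                            residual_E = unname(as.data.frame(truth$residual_E)),
                            clade_R = lapply(truth$clade_R, function(M)
                              unname(as.data.frame(M)))),
                       pth("ground_truth.yml"))
      list(trees = trees, traits = traits, hierarchy = hierarchy,
           truth = truth)
    }
  })
  trees <- inputs$trees; hierarchy <- inputs$hierarchy

  ## stage 2: ordination and dimension selection -----------------------------
  ord <- stage("ordinate", {
    p <- pca_ordinate(inputs$traits)
    m <- select_dimensions(p, hierarchy, config$clade_threshold)
    m <- max(m, 2L)
    scores <- p$scores[, seq_len(m), drop = FALSE]
    write_report(data.frame(axis = seq_along(p$variance_explained),
                            variance_explained = p$variance_explained,
                            retained = seq_along(p$variance_explained) <= m),
                 pth("dimension_selection.csv"), hash, seed)
    write_report(data.frame(label = rownames(scores), scores,
                            check.names = FALSE),
                 pth("scores_ordinated.csv"), hash, seed)
    scores
  })

  ## stage 3: parameterization chains on the consensus tree ------------------
  par_out <- stage("parameterize", {
    cons <- consensus_tree(trees)
    pc <- run_parameterization_chains(ord, cons, hierarchy,
                                      config = config$minichains,
                                      seed = derive_seed(seed, 5))
    write_report(data.frame(chain = seq_along(pc$first_crossings),
                            first_crossing = pc$first_crossings,
                            burnin = pc$burnin),
                 pth("parameterization.csv"), hash, seed)
    pc
  })

  ## stage 4: mini chains ----------------------------------------------------
  mc <- stage("mini-chains", {
    m <- run_mini_chains(ord, trees, hierarchy, config = config$minichains,
                         priors = par_out$priors, burnin = par_out$burnin,
                         seed = derive_seed(seed, 6))
    write_report(m$ess, pth("ess.csv"), hash, seed)
    m
  })
  posteriors <- mc$posteriors
  deepest <- length(hierarchy$levels)

  ## stage 5: species and clade scores ---------------------------------------
  sc <- stage("score", {
    ssp <- score_all(ord, posteriors, hierarchy, mode = "species",
                     reference = deepest, level = config$ci_level,
                     df = config$chisq_df)
    scl <- score_all(ord, posteriors, hierarchy, mode = "clade",
                     reference = "parent", level = config$ci_level,
                     df = config$chisq_df)
    write_report(summary(ssp), pth("scores_species.csv"), hash, seed)
    write_report(summary(scl), pth("scores_clade.csv"), hash, seed)
    list(species = ssp, clade = scl)
  })

  ## stage 6: orthogonality --------------------------------------------------
  stage("orthogonality", {
    rep <- orthogonality_report(posteriors, hierarchy,
                                seed = derive_seed(seed, 7))
    write_report(rep, pth("orthogonality.csv"), hash, seed)
  })

  ## stage 7: distribution statistics ----------------------------------------
  stage("stats", {
    bc <- data.frame(
      comparison = c("elaboration_species_vs_clade",
                     "innovation_species_vs_clade"),
      bhattacharyya = c(
        bhattacharyya(scale_by_group_max(sc$species$elaboration,
                                         sc$species$reference),
                      scale_by_group_max(sc$clade$elaboration,
                                         sc$clade$entity),
                      config$n_bins),
        bhattacharyya(scale_by_group_max(sc$species$innovation,
                                         sc$species$reference),
                      scale_by_group_max(sc$clade$innovation,
                                         sc$clade$entity),
                      config$n_bins)),
      n_bins = config$n_bins)
    write_report(bc, pth("bhattacharyya.csv"), hash, seed)

    cors <- do.call(rbind, lapply(names(hierarchy$levels[[deepest]]), function(cl) {
      d <- sc$species[sc$species$reference == cl, , drop = FALSE]
      if (length(unique(d$entity)) < 3) return(NULL)
      pc <- posterior_correlation(d, method = config$cor_method)
      data.frame(clade = cl, median_r = pc$median,
                 r_q25 = pc$ci50[1], r_q75 = pc$ci50[2],
                 r_q025 = pc$ci95[1], r_q975 = pc$ci95[2],
                 class = pc$class)
    }))
    write_report(cors, pth("correlations.csv"), hash, seed)

    base_tree <- trees[[1]]
    lam <- do.call(rbind, lapply(c("elaboration", "innovation"), function(w) {
      med <- tapply(sc$species[[w]],
                    sc$species$entity, stats::median)
      tr <- ape::keep.tip(base_tree, names(med))
      pl <- pagels_lambda(med[tr$tip.label], tr)
      data.frame(score = w, lambda = pl$lambda, logLik = pl$logLik,
                 flat = pl$flat)
    }))
    write_report(lam, pth("pagels_lambda.csv"), hash, seed)
  })

  ## stage 8: PGLS suite -----------------------------------------------------
  stage("pgls", {
    ssum <- summary(sc$species); csum <- summary(sc$clade)
    d <- data.frame(row.names = ssum$entity,
                    elab_species = ssum$elab_median,
                    innov_species = ssum$innov_median)
    d$elab_clade <- csum$elab_median[match(
      vapply(rownames(d), function(tp) {
        a <- hierarchy$assignment
        as.character(a[[deepest + 1L]][match(tp, a[[1]])])
      }, character(1)), csum$entity)]
    d$innov_clade <- csum$innov_median[match(
      vapply(rownames(d), function(tp) {
        a <- hierarchy$assignment
        as.character(a[[deepest + 1L]][match(tp, a[[1]])])
      }, character(1)), csum$entity)]
    dist_all <- distance_to_centroid(ord)
    d$distance <- dist_all[rownames(d)]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    tr <- ape::keep.tip(trees[[1]], rownames(d))
    suite <- table1_suite(d, tr, lambda_mode = config$lambda_mode)
    write_report(as.data.frame(suite), pth("pgls_table.csv"), hash, seed)
    jsonlite::write_json(list(config_hash = hash, seed = seed,
                              models = as.data.frame(suite)),
                         pth("pgls.json"), digits = NA, auto_unbox = TRUE)
  })

  jsonlite::write_json(list(config_hash = hash, seed = seed,
                            stages = c("inputs", "ordinate", "parameterize",
                                       "mini-chains", "score", "orthogonality",
                                       "stats", "pgls")),
                       pth("run_info.json"), auto_unbox = TRUE)
  invisible(output_dir)
}
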