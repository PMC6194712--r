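#' Default pipeline configuration
#'
#' One block per stage; all seeds explicit so a rerun with the same
#' config reproduces identical outputs. Any element supplied in `...`
#' overrides the corresponding default; `simulate` options are passed to
#' [sim_config()].
#'
#' @param seed Master seed; stage seeds default to small offsets of it.
#' @param ... Named overrides, e.g. `simulate = list(n_proteins = 200)`.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    simulate = list(seed = seed),
    similarity = list(r_threshold = 0),
    complex_stats = list(alpha = 0.05, n_perm = 500L, seed = seed + 1L),
    enrich = list(detect_prob_within = 0.8, detect_prob_cross = 0.5,
                  seed = seed + 2L, n_boot = 500L),
    subset = list(thresholds = c(1, 1e-2, 1e-6, 1e-10)),
    gini = list(housekeeping_cv = 0.2, specific_cv = 1.5, seed = seed + 3L),
    predict = list(n_folds = 10L, seed = seed + 4L,
                   precisions = c(0.5, 0.75, 0.9))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
  }
  cfg
}

pipe_log <- function(stage, ..., verbose = TRUE) {
  if (verbose) message("[", stage, "] ", ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the whole synthetic-study pipeline
#'
#' Executes simulate -> similarity -> complex-stats -> enrich -> subset
#' -> gini -> predict on synthetic data, writing per-stage TSV outputs,
#' a JSON summary and a run manifest with MD5 checksums under
#' `out_dir`. Stages run in dependency order and a stage failure stops
#' the run with the owning stage named. Reruns with an identical config
#' produce byte-identical outputs.
#'
#' @param config Configuration list from [default_pipeline_config()], or
#'   a path to a YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @param verbose Emit stage-tagged progress messages.
#' @return The run manifest (list), invisibly; the `summary` element
#'   holds the headline numbers.
#' @export
run_all <- function(config = default_pipeline_config(), out_dir,
                    verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summary <- list()
  stage <- function(name, expr) {
    pipe_log(name, "running", verbose = verbose)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    sc <- do.call(sim_config, config$simulate)
    s <- generate_dataset(sc)
    for (d in s$datasets) {
      paths <- c(paths, write_chromatograms(
        d, file.path(out_dir, paste0(d$dataset_id, ".csv"))))
    }
    paths <- c(paths, write_complex_db(s$db, file.path(out_dir, "complexes.tsv")))
    s
  })
  datasets <- lapply(sim$datasets, filter_min_fractions)

  sim_tab <- stage("similarity", {
    gold <- complex_to_pairs(sim$db)
    tabs <- lapply(datasets, function(ds) {
      prot <- rownames(ds$mat)
      cand <- protein_pairs(rep(prot, each = length(prot)),
                            rep(prot, times = length(prot)))
      pair_similarity_table(ds, cand, gold)
    })
    tab <- do.call(rbind, tabs)
    paths <- c(paths, write_tsv(tab, file.path(out_dir, "similarity.tsv")))
    af_gold <- anticorrelated_fraction(tab[tab$label == "gold", ],
                                       config$similarity$r_threshold)
    af_non <- anticorrelated_fraction(tab[tab$label == "non-gold", ],
                                      config$similarity$r_threshold)
    summary$anticorrelated_fraction_gold <- af_gold$fraction
    summary$anticorrelated_fraction_nongold <- af_non$fraction
    tab
  })

  cstats <- stage("complex-stats", {
    st <- complex_significance(datasets, sim$db,
                               alpha = config$complex_stats$alpha,
                               n_perm = config$complex_stats$n_perm,
                               seed = config$complex_stats$seed)
    paths <- c(paths, write_tsv(st, file.path(out_dir, "complex_stats.tsv")))
    summary$n_complexes_observed <- nrow(st)
    summary$n_enriched <- sum(st$class == "enriched")
    summary$n_depleted <- sum(st$class == "depleted")
    st
  })

  enr <- stage("enrich", {
    intx <- generate_interactomes(
      sim, detect_prob_within = config$enrich$detect_prob_within,
      detect_prob_cross = config$enrich$detect_prob_cross,
      seed = config$enrich$seed)
    records <- lapply(intx, enrich_complexes, db = sim$db)
    rec_tab <- do.call(rbind, records)
    paths <- c(paths, write_tsv(rec_tab, file.path(out_dir, "enrichment.tsv")))
    techniques <- vapply(intx, `[[`, "", "technique")
    chance <- technique_specific_chance(records, techniques, "CF",
                                        n_boot = config$enrich$n_boot,
                                        seed = config$enrich$seed)
    summary$cf_specific_complexes_observed <- chance$observed
    summary$cf_specific_complexes_chance <- chance$expected
    summary$cf_specific_chance_p <- chance$p
    list(interactomes = intx, records = records)
  })

  subsets <- stage("subset", {
    cf_labels <- names(enr$interactomes)[
      vapply(enr$interactomes, `[[`, "", "technique") == "CF"][4:6]
    recs <- enr$records[cf_labels]
    subs <- lapply(config$subset$thresholds, function(th) {
      cf_specific_subset(sim$db, recs, th)
    })
    paths <- c(paths, export_subset(subs, sim$db,
                                     file.path(out_dir, "subsets.tsv")))
    summary$subset_sizes <- vapply(subs, function(s) length(s$complex_ids), 0)
    subs
  })

  stage("gini", {
    expr_mat <- generate_expression(
      sim, housekeeping_cv = config$gini$housekeeping_cv,
      specific_cv = config$gini$specific_cv, seed = config$gini$seed)
    paths <- c(paths, write_expression(expr_mat,
                                        file.path(out_dir, "expression.tsv")))
    cf_ids <- subsets[[2L]]$complex_ids
    if (length(cf_ids) < 2L) cf_ids <- subsets[[1L]]$complex_ids
    cf_prot <- unique(unlist(sim$db$complexes[cf_ids]))
    other_prot <- setdiff(unique(unlist(sim$db$complexes)), cf_prot)
    gc <- group_gini_comparison(expr_mat, cf_prot, other_prot)
    summary$mean_gini_cf_specific <- unname(gc$mean_gini["cf_specific"])
    summary$mean_gini_other <- unname(gc$mean_gini["other_complex"])
    summary$gini_welch_p <- gc$p
    gc
  })

  stage("predict", {
    clean <- subsets[[1L]]
    prot <- Reduce(union, lapply(datasets, function(d) rownames(d$mat)))
    cand <- protein_pairs(rep(prot, each = length(prot)),
                          rep(prot, times = length(prot)))
    feats <- build_features(datasets, cand)
    sizes <- list()
    for (what in c("clean", "random")) {
      pair_pool <- if (what == "clean") {
        db_sub <- sim$db
        db_sub$complexes <- sim$db$complexes[clean$complex_ids]
        db_sub
      } else {
        rnd <- random_subset(complex_to_pairs(sim$db), nrow(clean$pairs),
                             seed = config$predict$seed)
        pairs_to_db(rnd)
      }
      labels <- label_pairs(feats[, c("a", "b")], pair_pool)
      scored <- train_score_cv(feats, labels,
                               n_folds = config$predict$n_folds,
                               seed = config$predict$seed)
      ranked <- precision_recall(scored)
      sizes[[what]] <- vapply(config$predict$precisions, function(tp) {
        interactome_at_precision(ranked, tp)$size
      }, 0L)
      if (what == "clean") {
        paths <- c(paths, write_tsv(
          ranked[, c("a", "b", "score", "label", "precision", "recall")],
          file.path(out_dir, "ranked_pairs.tsv")))
      }
    }
    summary$interactome_size_at_precision <-
      stats::setNames(sizes$clean, paste0("p", config$predict$precisions))
    summary$interactome_size_random_subset <-
      stats::setNames(sizes$random, paste0("p", config$predict$precisions))
    sizes
  })

  manifest <- list(config = config,
                   outputs = basename(paths),
                   checksums = as.list(unname(tools::md5sum(paths))),
                   summary = summary)
  names(manifest$checksums) <- basename(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log("done", length(paths), " output files in ", out_dir,
           verbose = verbose)
  invisible(manifest)
}

# Gold-pair set -> minimal complex_db whose complexes are the pairs
# themselves, restricted to proteins of the reference database. Used to
# treat a random pair subset as a gold standard (TP = pair in subset; FP
# = both proteins in the reference database but pair not in subset).
pairs_to_db <- function(pairs) {
  members <- lapply(seq_len(nrow(pairs)), function(i) {
    c(pairs$a[i], pairs$b[i])
  })
  names(members) <- sprintf("PAIR%05d", seq_len(nrow(pairs)))
  complex_db(members, source_label = "pair-subset")
}
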