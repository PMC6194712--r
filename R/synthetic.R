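#' Simulation configuration
#'
#' Parameters of the synthetic co-fractionation study. Profiles are sums
#' of one or two Gaussian peaks over the fraction axis with truncated
#' Gaussian noise (SILAC ratios are nonnegative) and uniformly missing
#' cells. Complexes planted as co-eluting share a peak center (jitter at
#' most a quarter peak width); disrupted complexes split their members
#' between two anti-phased centers at opposite ends of the gradient.
#'
#' @param n_proteins Number of proteins (default 500).
#' @param n_fractions Number of fractions (default 50).
#' @param n_complexes Number of database complexes (default 60).
#' @param complex_size_range Inclusive size range (default 2-10).
#' @param frac_coeluting Share of complexes planted as truly co-eluting
#'   (default 0.6).
#' @param frac_disrupted Share of complexes planted as disrupted
#'   (anti-phased members); the remainder are neutral complexes whose
#'   members elute independently, like background proteins. Default
#'   `1 - frac_coeluting`, i.e. no neutral complexes.
#' @param peak_width Gaussian peak SD in fractions (default 2).
#' @param peak_height Peak amplitude on the ratio scale (default 10).
#' @param noise_sd Additive noise SD (default 1, i.e. a tenth of the
#'   peak height).
#' @param missing_rate Probability a cell is missing (default 0.2).
#' @param baseline_frac Upper bound of the per-protein shared-envelope
#'   amplitude, as a fraction of `peak_height` (default 0.3). Real
#'   chromatograms share a broad elution envelope that makes random
#'   pairs positively correlated on average; 0 turns it off.
#' @param n_datasets Number of replicate datasets (default 3).
#' @param n_tissues Tissues for the expression matrix (default 7).
#' @param second_peak_prob Probability a protein carries a secondary
#'   random peak (default 0.3).
#' @param jitter Half-width of the uniform jitter applied to co-eluting
#'   members' shared peak center, in fractions (default `peak_width / 4`;
#'   0 gives exact co-elution).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500L, n_fractions = 50L,
                       n_complexes = 60L, complex_size_range = c(2L, 10L),
                       frac_coeluting = 0.6,
                       frac_disrupted = 1 - frac_coeluting, peak_width = 2,
                       peak_height = 10, noise_sd = 1, missing_rate = 0.2,
                       baseline_frac = 0.3, n_datasets = 3L, n_tissues = 7L,
                       second_peak_prob = 0.3, jitter = peak_width / 4,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_fractions = as.integer(n_fractions),
              n_complexes = as.integer(n_complexes),
              complex_size_range = as.integer(complex_size_range),
              frac_coeluting = frac_coeluting,
              frac_disrupted = frac_disrupted, peak_width = peak_width,
              peak_height = peak_height, noise_sd = noise_sd,
              missing_rate = missing_rate, baseline_frac = baseline_frac,
              n_datasets = as.integer(n_datasets),
              n_tissues = as.integer(n_tissues),
              second_peak_prob = second_peak_prob, jitter = jitter,
              seed = as.integer(seed))
  rates <- c(cfg$frac_coeluting, cfg$frac_disrupted, cfg$missing_rate,
             cfg$second_peak_prob)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$frac_coeluting + cfg$frac_disrupted > 1) {
    stop("frac_coeluting + frac_disrupted must not exceed 1")
  }
  if (cfg$n_fractions < 2L || cfg$n_proteins < 2L) stop("degenerate config")
  if (cfg$complex_size_range[1L] < 2L) stop("complexes need >= 2 members")
  structure(cfg, class = "sim_config")
}

sim_protein_ids <- function(n) sprintf("SP%04d", seq_len(n))

gauss_peak <- function(frac, center, width, height) {
  height * exp(-(frac - center)^2 / (2 * width^2))
}

#' Generate synthetic co-fractionation data with planted truth
#'
#' Builds the complex database (disjoint member sets drawn from the
#' protein pool), plants each complex as co-eluting or disrupted, and
#' simulates `n_datasets` chromatogram datasets. Co-eluting members
#' share a dataset-specific peak center plus jitter; disrupted members
#' are split between two anti-phased centers in the first and last
#' quarter of the gradient; background proteins peak at random
#' positions. Also draws per-technique detectability masks (CF =
#' co-eluting status; AP-MS and Y2H random) and housekeeping flags
#' (members of co-eluting complexes) used by the downstream generators.
#'
#' @param config A [sim_config].
#' @return List with `datasets` (list of [cf_dataset]), `db`
#'   ([complex_db]) and `truth` (list: `complex_status`, `technique_mask`,
#'   `housekeeping`, `config`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sim_protein_ids(config$n_proteins)
  sizes <- sample(seq(config$complex_size_range[1L],
                      config$complex_size_range[2L]),
                  config$n_complexes, replace = TRUE)
  if (sum(sizes) > config$n_proteins) {
    stop("protein pool too small for the requested complexes")
  }
  pool <- sample(ids)
  complexes <- vector("list", config$n_complexes)
  names(complexes) <- sprintf("CPX%03d", seq_len(config$n_complexes))
  offset <- 0L
  for (i in seq_len(config$n_complexes)) {
    complexes[[i]] <- sort(pool[offset + seq_len(sizes[i])])
    offset <- offset + sizes[i]
  }
  n_coel <- round(config$frac_coeluting * config$n_complexes)
  n_disr <- round(config$frac_disrupted * config$n_complexes)
  status <- rep("neutral", config$n_complexes)
  pick <- sample.int(config$n_complexes, n_coel + n_disr)
  status[pick[seq_len(n_coel)]] <- "coeluting"
  status[pick[n_coel + seq_len(n_disr)]] <- "disrupted"
  names(status) <- names(complexes)

  frac <- seq_len(config$n_fractions)
  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    centers <- stats::runif(config$n_proteins, 1, config$n_fractions)
    names(centers) <- ids
    for (i in seq_len(config$n_complexes)) {
      members <- complexes[[i]]
      if (status[i] == "coeluting") {
        c0 <- stats::runif(1, 1, config$n_fractions)
        centers[members] <- c0 + stats::runif(length(members),
                                              -config$jitter, config$jitter)
      } else if (status[i] == "disrupted") {
        # anti-phased: members spaced evenly over the gradient (random
        # order, small jitter), so no within-complex pair co-elutes
        m <- length(members)
        spaced <- (sample.int(m) - 0.5) * config$n_fractions / m +
          stats::runif(m, -config$peak_width / 4, config$peak_width / 4)
        centers[members] <- pmin(pmax(spaced, 1), config$n_fractions)
      }  # neutral complexes keep independent background centers
    }
    envelope <- gauss_peak(frac, config$n_fractions / 2,
                           config$n_fractions / 3, 1)
    mat <- t(vapply(ids, function(p) {
      y <- gauss_peak(frac, centers[[p]], config$peak_width,
                      config$peak_height) +
        stats::runif(1, 0, config$baseline_frac * config$peak_height) *
        envelope
      if (stats::runif(1) < config$second_peak_prob) {
        y <- y + gauss_peak(frac, stats::runif(1, 1, config$n_fractions),
                            config$peak_width,
                            config$peak_height * stats::runif(1, 0.3, 0.8))
      }
      pmax(y + stats::rnorm(config$n_fractions, 0, config$noise_sd), 0)
    }, numeric(config$n_fractions)))
    if (config$missing_rate > 0) {
      mat[stats::runif(length(mat)) < config$missing_rate] <- NA_real_
    }
    datasets[[d]] <- cf_dataset(mat, sprintf("sim%02d", d))
  }

  technique_mask <- cbind(
    CF = status == "coeluting",
    `AP-MS` = stats::runif(config$n_complexes) < 0.5,
    Y2H = stats::runif(config$n_complexes) < 0.5)
  rownames(technique_mask) <- names(complexes)
  housekeeping <- ids %in% unlist(complexes[status == "coeluting"])
  names(housekeeping) <- ids

  list(datasets = datasets,
       db = complex_db(complexes, source_label = "synthetic"),
       truth = list(complex_status = status,
                    technique_mask = technique_mask,
                    housekeeping = housekeeping,
                    config = config))
}

#' Generate synthetic published interactomes
#'
#' Emits edge-list interactomes per technique. Within-complex pairs of
#' complexes detectable by an interactome's technique (per the truth's
#' mask) become edges with probability `detect_prob_within`; noise edges
#' between random protein pairs appear at rate `detect_prob_cross`. CF
#' interactomes carry a quantified roster, Y2H interactomes a bait list.
#'
#' @param sim Full result of [generate_dataset()] (supplies the complex
#'   database and the planted truth).
#' @param n_per_technique Named integer vector of interactome counts
#'   (default 6 CF, 3 AP-MS, 3 Y2H, mirroring a typical published-study
#'   panel).
#' @param detect_prob_within Edge probability for detectable
#'   within-complex pairs (default 0.8).
#' @param detect_prob_cross Noise-edge probability per random pair draw;
#'   `3 * n_proteins` cross pairs are attempted per interactome, so the
#'   edge list covers most of the proteome as real published
#'   interactomes do (default 0.5).
#' @param seed Integer seed.
#' @return List of [interactome] objects.
#' @export
generate_interactomes <- function(sim,
                                  n_per_technique = c(CF = 6L, `AP-MS` = 3L,
                                                      Y2H = 3L),
                                  detect_prob_within = 0.8,
                                  detect_prob_cross = 0.5, seed = 1L) {
  stopifnot(all(c(detect_prob_within, detect_prob_cross) >= 0),
            all(c(detect_prob_within, detect_prob_cross) <= 1))
  db <- sim$db
  truth <- sim$truth
  ids <- names(truth$housekeeping)
  set.seed(seed)
  out <- list()
  for (tech in names(n_per_technique)) {
    detectable <- rownames(truth$technique_mask)[truth$technique_mask[, tech]]
    for (j in seq_len(n_per_technique[[tech]])) {
      edges <- lapply(detectable, function(cid) {
        p <- complex_to_pairs(complex_db(db$complexes[cid]))
        p[stats::runif(nrow(p)) < detect_prob_within, , drop = FALSE]
      })
      edges <- do.call(rbind, c(edges, list(
        data.frame(a = character(0), b = character(0),
                   stringsAsFactors = FALSE))))
      n_cross <- 3L * length(ids)
      cross <- data.frame(a = sample(ids, n_cross, replace = TRUE),
                          b = sample(ids, n_cross, replace = TRUE),
                          stringsAsFactors = FALSE)
      cross <- cross[stats::runif(n_cross) < detect_prob_cross, ,
                     drop = FALSE]
      all_edges <- protein_pairs(c(edges$a, cross$a), c(edges$b, cross$b))
      label <- paste0(sub("-MS", "", tech), j)
      baits <- if (tech == "Y2H") {
        unique(c(sample(ids, round(length(ids) / 4)),
                 unlist(db$complexes[detectable])))
      } else NULL
      quantified <- if (tech == "CF") {
        sample(ids, round(0.9 * length(ids)))
      } else NULL
      out[[label]] <- interactome(all_edges, label = label, technique = tech,
                                  baits = baits, quantified = quantified)
    }
  }
  out
}

#' Generate a synthetic tissue expression matrix
#'
#' Housekeeping proteins (per the planted truth) get low across-tissue
#' dispersion, other proteins high dispersion; each row is lognormal
#' around a protein-specific base level with the group's coefficient of
#' variation.
#'
#' @param sim Result of [generate_dataset()] (or any list with
#'   `truth$housekeeping`).
#' @param n_tissues Number of tissue columns (default from the config).
#' @param housekeeping_cv Across-tissue CV for housekeeping proteins
#'   (default 0.2).
#' @param specific_cv CV for tissue-specific proteins (default 1.5);
#'   must exceed `housekeeping_cv`.
#' @param seed Integer seed.
#' @return Numeric matrix, proteins x tissues.
#' @export
generate_expression <- function(sim, n_tissues = NULL,
                                housekeeping_cv = 0.2, specific_cv = 1.5,
                                seed = 1L) {
  if (housekeeping_cv >= specific_cv) {
    stop("housekeeping_cv must be below specific_cv")
  }
  hk <- sim$truth$housekeeping
  if (is.null(n_tissues)) n_tissues <- sim$truth$config$n_tissues
  set.seed(seed)
  cv <- ifelse(hk, housekeeping_cv, specific_cv)
  sdlog <- sqrt(log(1 + cv^2))
  base <- stats::rlnorm(length(hk), meanlog = 3, sdlog = 1)
  mat <- vapply(seq_len(n_tissues), function(t) {
    base * stats::rlnorm(length(hk), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }, numeric(length(hk)))
  dimnames(mat) <- list(names(hk), paste0("tissue", seq_len(n_tissues)))
  mat
}
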