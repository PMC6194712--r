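test_that("upper-tail hypergeometric matches exhaustive enumeration", {
  expect_equal(hypergeometric_upper_tail(0, 4, 3, 10), 1)
  expect_equal(hypergeometric_upper_tail(3, 4, 3, 10), choose(4, 3) / choose(10, 3))
  expect_error(hypergeometric_upper_tail(5, 4, 3, 10), "invalid")
  expect_error(hypergeometric_upper_tail(1, 4, 11, 10), "invalid")

  set.seed(30)
  for (i in 1:120) {
    N <- sample(4:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeometric_upper_tail(k, K, n, N),
                 oracle_hyper_upper(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("edge-to-complex mapping counts pairs over the universe", {
  db <- complex_db(list(C1 = c("A", "B", "C"), C2 = c("X", "Y")))
  ix <- interactome(data.frame(a = c("A", "C"), b = c("B", "Q")),
                    label = "i", technique = "AP-MS")
  m <- map_edges_to_complexes(ix, db)
  # universe = {A, B, C}; C2 wholly absent -> unobserved
  expect_equal(m$complex_id, "C1")
  expect_equal(m$n_pairs_possible, 3L)
  expect_equal(m$n_pairs_predicted, 1L)

  # random fixtures vs a pair-by-pair oracle
  set.seed(31)
  prot <- sprintf("P%02d", 1:25)
  for (rep in 1:10) {
    cpx <- lapply(1:8, function(i) sample(prot, sample(2:6, 1)))
    names(cpx) <- paste0("C", 1:8)
    dbr <- complex_db(cpx)
    e <- data.frame(a = sample(prot, 40, TRUE), b = sample(prot, 40, TRUE))
    e <- e[e$a != e$b, ]
    ixr <- interactome(e, label = "r", technique = "AP-MS")
    got <- map_edges_to_complexes(ixr, dbr)
    uni <- intersect(unique(c(ixr$edges$a, ixr$edges$b)), unlist(cpx))
    ek <- paste(pmin(ixr$edges$a, ixr$edges$b),
                pmax(ixr$edges$a, ixr$edges$b))
    for (cid in names(dbr$complexes)) {
      mm <- intersect(dbr$complexes[[cid]], uni)
      npos <- 0L; npred <- 0L
      if (length(mm) >= 2) {
        for (x in mm) for (y in mm) {
          if (x < y) {
            npos <- npos + 1L
            if (paste(x, y) %in% ek) npred <- npred + 1L
          }
        }
      }
      row <- got[got$complex_id == cid, ]
      if (npos == 0) expect_equal(nrow(row), 0L)
      else {
        expect_equal(row$n_pairs_possible, npos)
        expect_equal(row$n_pairs_predicted, npred)
      }
    }
  }
})

test_that("complex enrichment p-values compare to the database-wide rate", {
  # toy: one complex holds all the edges
  db <- complex_db(list(C1 = c("A", "B", "C"), C2 = c("D", "E", "F")))
  ix <- interactome(data.frame(a = c("A", "A", "B", "D", "E"),
                               b = c("B", "C", "C", "Q", "Q")),
                    label = "t", technique = "AP-MS")
  rec <- enrich_complexes(ix, db)
  expect_lt(rec$p_hyper[rec$complex_id == "C1"],
            rec$p_hyper[rec$complex_id == "C2"])
  expect_true(all(rec$p_hyper[rec$n_pairs_predicted == 0] == 1))
  expect_equal(rec$predicted_flag, rec$n_pairs_predicted >= 1)

  # degenerate single complex: n = N and k = K forces p = 1
  db1 <- complex_db(list(C1 = c("A", "B", "C")))
  ix1 <- interactome(data.frame(a = "A", b = "B"), label = "t",
                     technique = "AP-MS")
  expect_equal(enrich_complexes(ix1, db1)$p_hyper, 1)

  # monotone decreasing in k with the other parameters fixed
  p <- vapply(0:6, function(k) hypergeometric_upper_tail(k, 10, 6, 30), 0)
  expect_true(all(diff(p) <= 0))
})

test_that("could-be-predicted rules depend on the technique rosters", {
  members <- c("A", "B", "C", "D", "E")
  cf <- interactome(data.frame(a = "A", b = "Q"), label = "cf",
                    technique = "CF", quantified = c("A", "B", "Z"))
  expect_true(could_predict(members, cf))
  cf2 <- interactome(data.frame(a = "A", b = "Q"), label = "cf2",
                     technique = "CF", quantified = c("A", "Z"))
  expect_false(could_predict(members, cf2))

  y2h <- interactome(data.frame(a = "A", b = "Q"), label = "y", technique = "Y2H",
                     baits = c("Z", "W"))
  expect_false(could_predict(members, y2h))
  y2h2 <- interactome(data.frame(a = "A", b = "Q"), label = "y2", technique = "Y2H",
                      baits = c("Z", "C"))
  expect_true(could_predict(members, y2h2))

  ap <- interactome(data.frame(a = c("A", "X"), b = c("Q", "Y")),
                    label = "ap", technique = "AP-MS")
  expect_false(could_predict(members, ap))  # only A among proteins
  ap2 <- interactome(data.frame(a = c("A", "B"), b = c("Q", "Y")),
                     label = "ap2", technique = "AP-MS")
  expect_true(could_predict(members, ap2))

  # monotone: adding roster proteins never flips true -> false
  set.seed(33)
  for (i in 1:25) {
    q <- sample(LETTERS, sample(2:10, 1))
    cfa <- interactome(data.frame(a = "A", b = "Q"), label = "m",
                       technique = "CF", quantified = q)
    cfb <- interactome(data.frame(a = "A", b = "Q"), label = "m",
                       technique = "CF",
                       quantified = c(q, sample(letters, 3)))
    if (could_predict(members, cfa)) expect_true(could_predict(members, cfb))
  }

  expect_error(could_predict(members,
                             interactome(data.frame(a = "A", b = "B"),
                                         label = "x", technique = "CF")),
               "quantified")
})

test_that("technique-specific selection applies the within/other rule", {
  mk_rec <- function(label, flagged, all_ids) {
    data.frame(complex_id = all_ids, interactome_label = label,
               n_members_in_universe = 3L, n_pairs_possible = 3L,
               n_pairs_predicted = ifelse(all_ids %in% flagged, 1L, 0L),
               p_hyper = 1, predicted_flag = all_ids %in% flagged,
               could_predict = TRUE, stringsAsFactors = FALSE)
  }
  ids <- paste0("C", 1:6)
  # C1 predicted by 4/6 CF, 1 AP, 0 Y2H -> CF-specific
  # C2 predicted by 4/6 CF but 2 AP -> excluded
  cf_flags <- list(c("C1", "C2"), c("C1", "C2"), c("C1", "C2"),
                   c("C1", "C2"), "C3", "C3")
  ap_flags <- list("C1", "C2", "C2")
  y_flags <- list("C4", "C4", character(0))
  recs <- c(lapply(1:6, function(i) mk_rec(paste0("CF", i), cf_flags[[i]], ids)),
            lapply(1:3, function(i) mk_rec(paste0("AP", i), ap_flags[[i]], ids)),
            lapply(1:3, function(i) mk_rec(paste0("Y", i), y_flags[[i]], ids)))
  tech <- c(rep("CF", 6), rep("AP-MS", 3), rep("Y2H", 3))
  sel <- technique_specific_complexes(recs, tech, "CF")
  expect_equal(sel, "C1")
  # Y2H-specific: C4 in 2/3 Y2H, absent elsewhere
  expect_equal(technique_specific_complexes(recs, tech, "Y2H"), "C4")

  # random flag matrices vs brute-force rule application
  set.seed(34)
  for (rep in 1:10) {
    flags <- matrix(runif(60) < 0.4, 10, 6,
                    dimnames = list(paste0("X", 1:10),
                                    c("a1", "a2", "a3", "b1", "b2", "b3")))
    tech2 <- c("CF", "CF", "CF", "Y2H", "Y2H", "Y2H")
    got <- cofracgold:::selected_from_flags(flags, tech2, "CF",
                                            min_within = 2, max_other = 1)
    want <- rownames(flags)[rowSums(flags[, 1:3]) >= 2 &
                              rowSums(flags[, 4:6]) <= 1]
    expect_equal(got, want)
  }
})

test_that("the bootstrap chance model is seeded and honest at the extremes", {
  mk_rec <- function(label, flagged, all_ids) {
    data.frame(complex_id = all_ids, interactome_label = label,
               n_members_in_universe = 3L, n_pairs_possible = 3L,
               n_pairs_predicted = ifelse(all_ids %in% flagged, 1L, 0L),
               p_hyper = 1, predicted_flag = all_ids %in% flagged,
               could_predict = TRUE, stringsAsFactors = FALSE)
  }
  ids <- paste0("C", 1:20)
  # flags identical across the technique, empty elsewhere -> extreme
  recs <- c(lapply(1:3, function(i) mk_rec(paste0("CF", i), ids[1:5], ids)),
            lapply(1:3, function(i) mk_rec(paste0("AP", i), character(0), ids)))
  tech <- c(rep("CF", 3), rep("AP-MS", 3))
  ch <- technique_specific_chance(recs, tech, "CF", min_within = 3,
                                  n_boot = 200, seed = 9)
  expect_equal(ch$observed, 5L)
  expect_lt(ch$expected, ch$observed)
  expect_lt(ch$p, 0.05)
  # deterministic under the seed
  ch2 <- technique_specific_chance(recs, tech, "CF", min_within = 3,
                                   n_boot = 200, seed = 9)
  expect_identical(ch$boot_counts, ch2$boot_counts)

  # a rule no complex can satisfy -> expected 0, p = 1
  ch0 <- technique_specific_chance(recs, tech, "CF", min_within = 4,
                                   n_boot = 100, seed = 9)
  expect_equal(ch0$observed, 0L)
  expect_equal(ch0$expected, 0)
  expect_equal(ch0$p, 1)
})

test_that("enrichment p-values are super-uniform under random edge placement", {
  set.seed(36)
  sim <- generate_dataset(sim_config(seed = 71, n_proteins = 1500,
                                     n_complexes = 150,
                                     complex_size_range = c(4, 10),
                                     frac_coeluting = 0, frac_disrupted = 0,
                                     n_datasets = 1))
  db <- sim$db
  pool <- complex_to_pairs(db)
  prot <- unique(unlist(db$complexes))
  edges <- pool[sample.int(nrow(pool), round(0.35 * nrow(pool))), ]
  cross <- data.frame(a = sample(prot, 6000, TRUE), b = sample(prot, 6000, TRUE))
  ix <- interactome(rbind(edges, cross), label = "null", technique = "AP-MS")
  rec <- enrich_complexes(ix, db)
  rej <- mean(rec$p_hyper < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(rec))
  expect_lte(rej, 0.05 + 3 * se)
})
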