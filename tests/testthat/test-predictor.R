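test_that("pair labelling follows the co-membership rule", {
  db <- complex_db(list(ribosome = c("R1", "R2", "R3"),
                        proteasome = c("S1", "S2")))
  pairs <- data.frame(a = c("R1", "R1", "R1", "S1"),
                      b = c("R2", "S1", "X9", "S2"))
  lab <- label_pairs(pairs, db)
  # within-complex, cross-complex (ribosomal x proteasomal), outside db
  expect_equal(as.vector(lab), c("TP", "FP", "unlabeled", "TP"))
  expect_equal(attr(lab, "counts"),
               c(TP = 2L, FP = 1L, unlabeled = 1L))
})

test_that("pair features agree with the similarity operations", {
  set.seed(50)
  dss <- lapply(1:2, function(i) random_cf_dataset(15, 12, missing_rate = 0.2,
                                                   dataset_id = i))
  prot <- rownames(dss[[1]]$mat)
  pairs <- protein_pairs(rep(prot, each = 15), rep(prot, times = 15))
  feats <- build_features(dss, pairs)
  expect_true(all(c("pearson_r", "euclidean_d", "coapex_d") %in% names(feats)))
  for (i in sample(nrow(feats), 15)) {
    per_ds <- vapply(dss, function(ds) {
      x <- ds$mat[feats$a[i], ]; y <- ds$mat[feats$b[i], ]
      r <- pearson_zero_fill(x, y)
      if (is.na(r)) return(c(NA, NA, NA))
      xz <- x; xz[is.na(xz)] <- 0
      yz <- y; yz[is.na(yz)] <- 0
      c(r, euclidean_minmax(x, y), abs(which.max(xz) - which.max(yz)))
    }, numeric(3))
    keep <- !is.na(per_ds[1, ])
    expect_equal(feats$pearson_r[i], mean(per_ds[1, keep]), tolerance = 1e-12)
    expect_equal(feats$euclidean_d[i], mean(per_ds[2, keep]), tolerance = 1e-12)
    expect_equal(feats$coapex_d[i], mean(per_ds[3, keep]), tolerance = 1e-12)
  }
  # identical profiles give the ideal feature vector
  m <- rbind(A = c(0, 1, 5, 1, 0, 0), B = c(0, 1, 5, 1, 0, 0))
  f1 <- build_features(cf_dataset(m, "x"), data.frame(a = "A", b = "B"))
  expect_equal(unlist(f1[1, c("pearson_r", "euclidean_d", "coapex_d")]),
               c(pearson_r = 1, euclidean_d = 0, coapex_d = 0))
  # pairs with no computable feature are dropped and counted
  m2 <- rbind(A = c(1, 2, 3), B = c(3, 3, 3), C = c(2, 1, 0))
  f2 <- build_features(cf_dataset(m2, "y"),
                       protein_pairs(c("A", "A", "B"), c("B", "C", "C")))
  expect_equal(nrow(f2), 1L)
  expect_equal(attr(f2, "n_dropped"), 2L)
})

test_that("the Gaussian naive Bayes separates separable classes", {
  set.seed(51)
  x <- rbind(matrix(rnorm(100, 2, .3), 50), matrix(rnorm(100, -2, .3), 50))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("TP", "FP"), each = 50)
  fit <- naive_bayes_fit(x, y)
  sc <- predict(fit, x)
  expect_true(all(sc[y == "TP"] > 0.5))
  expect_true(all(sc[y == "FP"] < 0.5))
  expect_output(print(fit), "Naive Bayes")

  # posterior agrees with an independent reference implementation
  if (requireNamespace("e1071", quietly = TRUE)) {
    ref <- e1071::naiveBayes(data.frame(x), factor(y))
    p_ref <- stats::predict(ref, data.frame(x), type = "raw")[, "TP"]
    expect_equal(unname(sc), unname(p_ref), tolerance = 1e-6)
  }
})

test_that("cross-validated scoring is stratified, seeded and leak-free", {
  set.seed(52)
  n <- 400
  feats <- data.frame(a = sprintf("A%03d", 1:n), b = sprintf("B%03d", 1:n),
                      pearson_r = rnorm(n), euclidean_d = rexp(n),
                      coapex_d = rpois(n, 4))
  labels <- sample(c("TP", "FP", "unlabeled"), n, TRUE, prob = c(.3, .3, .4))
  # inject signal
  feats$pearson_r[labels == "TP"] <- feats$pearson_r[labels == "TP"] + 2
  s1 <- train_score_cv(feats, labels, seed = 3)
  s2 <- train_score_cv(feats, labels, seed = 3)
  expect_identical(s1$score, s2$score)
  expect_false(anyNA(s1$score))

  # label permutation: out-of-fold AUROC ~ 0.5
  set.seed(53)
  aurocs <- replicate(25, {
    perm <- labels
    lab_idx <- which(labels != "unlabeled")
    perm[lab_idx] <- sample(labels[lab_idx])
    sp <- train_score_cv(feats, perm, seed = sample.int(1e6, 1))
    pos <- sp$score[perm == "TP"]; neg <- sp$score[perm == "FP"]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  })
  se <- sd(aurocs) / sqrt(length(aurocs))
  expect_lt(abs(mean(aurocs) - 0.5), 3 * se)

  # no label leakage: out-of-fold precision tracks held-out precision
  sim <- generate_dataset(sim_config(seed = 91, n_proteins = 250,
                                     n_complexes = 30, n_datasets = 2))
  ds <- lapply(sim$datasets, filter_min_fractions)
  prot <- Reduce(union, lapply(ds, function(d) rownames(d$mat)))
  cand <- protein_pairs(rep(prot, each = length(prot)),
                        rep(prot, times = length(prot)))
  ff <- build_features(ds, cand)
  ll <- label_pairs(ff[, c("a", "b")], sim$db)
  lab_idx <- which(ll != "unlabeled")
  set.seed(54)
  hold <- sample(lab_idx, round(length(lab_idx) / 3))
  train_lab <- ll
  train_lab[hold] <- "unlabeled"  # hide a third of the labels
  sc <- train_score_cv(ff, train_lab, seed = 8)
  # precision at a matched depth fraction, out-of-fold vs held-out
  prec_at <- function(scores, labs, idx, frac) {
    k <- max(1L, round(frac * length(idx)))
    top <- idx[order(-scores[idx])][1:k]
    sum(labs[top] == "TP") / sum(labs[top] %in% c("TP", "FP"))
  }
  oof_idx <- setdiff(lab_idx, hold)
  p_oof <- prec_at(sc$score, ll, oof_idx, 0.1)
  p_held <- prec_at(sc$score, ll, hold, 0.1)
  expect_lt(abs(p_oof - p_held), 0.05)
})

test_that("precision-recall bookkeeping matches a rank-by-rank re-scan", {
  scored <- data.frame(a = letters[1:6], b = LETTERS[1:6],
                       score = c(.9, .8, .7, .6, .5, .4),
                       label = c("TP", "TP", "unlabeled", "FP", "TP", "FP"))
  pr <- precision_recall(scored)
  expect_equal(pr$precision, c(1, 1, 1, 2/3, 3/4, 3/5))
  expect_equal(pr$recall, c(1/3, 2/3, 2/3, 2/3, 1, 1))
  expect_true(all(diff(pr$recall) >= 0))

  # random scores: curve equals an independent re-scan at every rank
  set.seed(55)
  n <- 300
  sc <- data.frame(a = sprintf("x%03d", 1:n), b = sprintf("y%03d", 1:n),
                   score = round(runif(n), 2),  # ties on purpose
                   label = sample(c("TP", "FP", "unlabeled"), n, TRUE))
  pr2 <- precision_recall(sc)
  ord <- order(-sc$score, sc$a, sc$b)
  tp <- 0; fp <- 0
  for (k in seq_len(n)) {
    lab <- sc$label[ord[k]]
    if (lab == "TP") tp <- tp + 1
    if (lab == "FP") fp <- fp + 1
    if (tp + fp > 0) expect_equal(pr2$precision[k], tp / (tp + fp))
    expect_equal(pr2$recall[k], tp / sum(sc$label == "TP"))
  }
  # precision at full depth equals labelled prevalence
  expect_equal(pr2$precision[n],
               sum(sc$label == "TP") / sum(sc$label != "unlabeled"))
})

test_that("interactome-at-precision scans to the deepest qualifying rank", {
  scored <- data.frame(a = letters[1:5], b = LETTERS[1:5],
                       score = 5:1 / 10,
                       label = c("TP", "TP", "FP", "unlabeled", "FP"))
  pr <- precision_recall(scored)
  perfect <- interactome_at_precision(pr, 1.0)
  expect_equal(perfect$size, 2L)  # up to the last TP before the first FP
  expect_equal(interactome_at_precision(pr, 0.66)$size, 4L)
  expect_equal(interactome_at_precision(pr, 0.99)$size, 2L)
  expect_equal(interactome_at_precision(pr, 0.999999)$size, 2L)
  # unreachable target: an FP outranks the only TP, precision never hits 1
  all_fp <- data.frame(a = "q", b = "r", score = 1, label = "FP")
  pr_fp <- precision_recall(rbind(scored[1, ], all_fp))
  expect_equal(interactome_at_precision(pr_fp, 1)$size, 0L)
  expect_equal(nrow(interactome_at_precision(pr_fp, 1)$pairs), 0L)

  # brute-force scan oracle on random rankings
  set.seed(56)
  for (i in 1:20) {
    n <- 50
    sc <- data.frame(a = sprintf("a%02d", 1:n), b = sprintf("b%02d", 1:n),
                     score = runif(n),
                     label = sample(c("TP", "FP", "unlabeled"), n, TRUE))
    if (!any(sc$label == "TP")) next
    pr3 <- precision_recall(sc)
    for (target in c(0.3, 0.6, 0.9)) {
      want <- 0L
      for (k in seq_len(n)) {
        d <- pr3$cum_tp[k] + pr3$cum_fp[k]
        if (d > 0 && pr3$cum_tp[k] / d >= target) want <- k
      }
      expect_equal(interactome_at_precision(pr3, target)$size, want)
    }
  }
})
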