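test_that("histogram normalization maps ranks to the uniform [-1, 1] grid", {
  m <- cbind(a = c(-3, 0, 5), b = c(10, 20, 30))
  hn <- histogram_normalize(m)
  expect_equal(unname(hn[, "a"]), c(-1, 0, 1))
  expect_equal(unname(hn[, "b"]), c(-1, 0, 1))
  # invariant under any strictly monotone per-column transform
  expect_equal(histogram_normalize(exp(m)), hn)
  expect_equal(histogram_normalize(m * 100 - 7), hn)
  # constant column degenerates to zeros
  expect_equal(unname(histogram_normalize(cbind(c(2, 2, 2)))[, 1]),
               c(0, 0, 0))
  # ties share the mean of their span
  expect_equal(unname(histogram_normalize(cbind(c(1, 1, 5)))[, 1]),
               c(-0.5, -0.5, 1))
  expect_error(histogram_normalize(m[1, , drop = FALSE]), "2 rows")
})

test_that("SOM collapses onto a shared profile", {
  x <- matrix(rep(c(1, 2, -1, 0), each = 50), 50)
  rownames(x) <- paste0("g", 1:50)
  som <- som_map(x, grid = c(4, 3), epochs = 15)
  expect_lt(som$qerror[length(som$qerror)], 1e-6)
  expect_true(all(abs(sweep(som$codebook, 2, c(1, 2, -1, 0))) < 1e-6))
})

test_that("quantization error decreases once the neighborhood narrows", {
  sim <- small_sim(n_genes = 1200)
  run_dge <- dge_timecourse(sim$counts)
  prof <- build_profiles(run_dge)
  som <- som_map(prof$normalized, grid = c(10, 8), epochs = 20)
  # after the first broad-neighborhood epoch the trace is non-increasing
  expect_true(all(diff(som$qerror[-1]) <= 1e-8))
  expect_lt(som$qerror[length(som$qerror)], som$qerror[2])
})

test_that("BMU assignment is the brute-force nearest codebook", {
  sim <- small_sim(n_genes = 1000)
  prof <- build_profiles(dge_timecourse(sim$counts))
  som <- som_map(prof$normalized, grid = c(8, 6), epochs = 10)
  set.seed(31)
  pick <- sample(nrow(prof$normalized), 50)
  for (i in pick) {
    d <- sqrt(rowSums((som$codebook -
                         rep(prof$normalized[i, ],
                             each = nrow(som$codebook)))^2))
    expect_equal(unname(som$bmu[i]), which.min(d))
  }
  # predict() reproduces the training BMUs
  expect_equal(predict(som, prof$normalized), som$bmu)
})

test_that("SOM training is deterministic and warns when overparameterized", {
  x <- matrix(rnorm(600), 75)
  rownames(x) <- paste0("g", 1:75)
  a <- som_map(x, grid = c(5, 4), epochs = 8)
  b <- som_map(x, grid = c(5, 4), epochs = 8)
  expect_identical(a$codebook, b$codebook)
  expect_warning(som_map(x[1:10, ], grid = c(5, 4), epochs = 2), "sparse")
  expect_error(som_map(x[0, ]), "empty")
  x[1, 1] <- NA
  expect_error(som_map(x, grid = c(5, 4)), "non-finite")
})

test_that("k-means on codebooks recovers point-mass structure exactly", {
  # codebooks forming 3 point masses: partition must be exact
  cb <- rbind(matrix(0, 10, 4), matrix(5, 12, 4), matrix(-5, 9, 4))
  som <- structure(list(codebook = cb), class = "som_map")
  lab <- cluster_codebooks(som, k = 3, n_restarts = 5, seed = 1)
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:22])), 1)
  expect_equal(length(unique(lab[23:31])), 1)
  expect_equal(length(unique(lab)), 3)
  expect_lt(attr(lab, "wcss"), 1e-10)
  # winning WCSS is the minimum over restarts
  expect_equal(attr(lab, "wcss"), min(attr(lab, "restart_wcss")))
})

test_that("codebook clustering is invariant to unit order and seeded", {
  # well-separated blobs, so every restart finds the same global optimum
  set.seed(12)
  cb <- matrix(rnorm(442 * 8, sd = 0.3), 442) +
    matrix(10 * (seq_len(442) %% 5), 442, 8)
  som <- structure(list(codebook = cb), class = "som_map")
  lab1 <- cluster_codebooks(som, k = 5, n_restarts = 8, seed = 4)
  lab2 <- cluster_codebooks(som, k = 5, n_restarts = 8, seed = 4)
  expect_identical(as.integer(lab1), as.integer(lab2))
  perm <- sample(442)
  somp <- structure(list(codebook = cb[perm, ]), class = "som_map")
  labp <- cluster_codebooks(somp, k = 5, n_restarts = 8, seed = 4)
  # same partition up to label names
  expect_equal(oracle_ari(as.integer(labp), as.integer(lab1)[perm]), 1)
  expect_error(cluster_codebooks(som, k = 1), "at least 2")
})

test_that("coherence filter keeps exactly the units near their centroid", {
  cb <- rbind(matrix(0, 5, 2), c(0, 10), matrix(3, 6, 2))
  som <- structure(list(codebook = cb), class = "som_map")
  labels <- c(rep(1L, 6), rep(2L, 6))
  # infinite threshold: vacuous filter
  expect_true(all(!is.na(coherence_filter(som, labels, threshold = Inf))))
  # tiny threshold: only units essentially at the centroid survive
  tight <- coherence_filter(som, labels, threshold = 1e-9)
  expect_true(all(is.na(tight[1:6])))      # outlier pulls centroid off 0
  expect_true(all(!is.na(tight[7:12])))    # exact point mass survives
  # the outlier unit is dropped at a moderate threshold
  mid <- coherence_filter(som, labels, threshold = 2)
  expect_true(is.na(mid[6]))
  expect_true(all(!is.na(mid[-6])))
  expect_error(coherence_filter(som, labels, threshold = 0), "positive")
  expect_error(coherence_filter(som, labels[1:3]), "every unit")
})

test_that("cluster summaries: medians, best-50% and tie-breaks", {
  raw <- rbind(g1 = c(1, 1), g2 = c(1, 1), g3 = c(1, 1),
               g4 = c(5, 5))
  prof <- structure(list(raw = raw, normalized = raw,
                         time_points_h = c(1, 3)),
                    class = "profile_matrix")
  som <- structure(list(codebook = matrix(0, 2, 2),
                        bmu = c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 2L)),
                   class = "som_map")
  cs <- summarize_clusters(prof, som, c(1L, 2L))
  g <- cs$genes
  # singleton cluster: median is its own profile, best50 is itself
  expect_equal(unname(cs$median_profiles[2, ]), c(5, 5))
  expect_true(g$best50[g$gene_id == "g4"])
  # identical triple: all distances 0, ceil(3/2) = 2 best50 members,
  # ties broken by gene identifier
  expect_equal(unname(cs$median_profiles[1, ]), c(1, 1))
  expect_equal(g$gene_id[g$best50 & g$cluster == 1], c("g1", "g2"))
  # labels ordered by descending size
  expect_equal(cs$sizes, c(3, 1))
})

test_that("recovery score is 1 on truth and near 0 on random labels", {
  sim <- small_sim(n_genes = 1500)
  resp <- sim$truth$genes[sim$truth$genes$archetype > 0, ]
  self <- data.frame(gene_id = resp$gene_id, cluster = resp$archetype)
  sc <- recovery_score(self, sim$truth)
  expect_equal(sc$ari, 1)
  expect_true(all(sc$purity == 1))
  set.seed(8)
  rnd <- data.frame(gene_id = resp$gene_id,
                    cluster = sample(11, nrow(resp), TRUE))
  expect_lt(abs(recovery_score(rnd, sim$truth)$ari), 0.05)
  # agrees with the contingency-table formula
  mix <- data.frame(gene_id = resp$gene_id,
                    cluster = ifelse(seq_len(nrow(resp)) %% 7 == 0,
                                     1L, resp$archetype))
  expect_equal(recovery_score(mix, sim$truth)$ari,
               oracle_ari(mix$cluster, resp$archetype))
  expect_error(recovery_score(data.frame(gene_id = "zz", cluster = 1),
                              sim$truth), "overlap")
})
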