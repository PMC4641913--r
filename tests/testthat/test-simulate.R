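test_that("library layout matches the paired time-course design", {
  sim <- small_sim(n_genes = 300)
  cm <- sim$counts
  expect_equal(ncol(cm$counts), 17)  # shared 0 h baseline + 8 paired points
  expect_equal(sum(cm$library_meta$condition == "baseline"), 1)
  expect_equal(sum(cm$library_meta$condition == "pond"), 8)
  expect_equal(sum(cm$library_meta$condition == "upland"), 8)
  expect_setequal(cm$library_meta$time_h[cm$library_meta$condition == "pond"],
                  c(1, 3, 6, 12, 24, 48, 120, 288))
  # universe closure: truth covers every simulated gene
  expect_identical(sim$truth$genes$gene_id, rownames(cm$counts))
})

test_that("identical seed gives bit-identical output", {
  a <- small_sim(seed = 7, n_genes = 400)
  b <- small_sim(seed = 7, n_genes = 400)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$true_log2_profile, b$truth$true_log2_profile)
  c2 <- small_sim(seed = 8, n_genes = 400)
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("null configuration plants no effects", {
  sim <- simulate_timecourse(sim_config(n_genes = 500, frac_responsive = 0,
                                        dispersion = 0, seed = 3))
  expect_true(all(sim$truth$true_log2_profile == 0))
  expect_true(all(sim$truth$genes$archetype == 0))
})

test_that("responsive assignment is an exact count, not Bernoulli", {
  sim <- simulate_timecourse(sim_config(n_genes = 2000, frac_responsive = 0.2,
                                        effect_scale = 2, seed = 7))
  expect_equal(sum(sim$truth$genes$archetype > 0), 400)  # 0.2 * 2000 exactly
  expect_equal(sort(unique(sim$truth$genes$archetype)), 0:11)
})

test_that("planted means are calibrated: count ratios track 2^profile", {
  sim <- simulate_timecourse(sim_config(n_genes = 800, library_size = 1e7,
                                        profile_noise_sd = 0, seed = 5))
  cm <- sim$counts
  # restrict to well-expressed responsive genes where Poisson noise is small
  base <- cm$counts[, "baseline_0h"]
  resp <- which(sim$truth$genes$archetype > 0 & base > 2000)
  expect_gt(length(resp), 50)
  for (tt in c("1", "24", "288")) {
    obs <- log2((cm$counts[resp, paste0("pond_", tt, "h")] + 0.5) /
                  (cm$counts[resp, paste0("upland_", tt, "h")] + 0.5))
    err <- obs - sim$truth$true_log2_profile[resp, tt]
    expect_lt(stats::quantile(abs(err), 0.9), 0.1)
  }
})

test_that("expressed sparsity matches the configured fraction", {
  sim <- small_sim(n_genes = 3000)
  ex <- detect_expressed(sim$counts)
  expect_equal(mean(ex$any_sample), 0.7796, tolerance = 0.02)
})

test_that("archetype templates are distinct unit-peak shapes", {
  tpl <- archetype_templates()
  expect_equal(nrow(tpl), 11)
  expect_equal(unname(apply(abs(tpl), 1, max)), rep(1, 11))
  d <- as.matrix(dist(tpl))
  diag(d) <- Inf
  expect_gt(min(d), 0.5)  # no two templates nearly coincide
})

test_that("annotation map is universe-complete and planted terms behave", {
  sim <- small_sim(n_genes = 1000)
  # degenerate limit: no background, infinite boost => planted term
  # annotates exactly its archetype's genes
  map0 <- simulate_annotation(sim$truth, n_terms = 20, background_rate = 0,
                              enrichment_boost = Inf, seed = 2)
  planted <- attr(map0, "planted_terms")
  expect_length(planted, 11)
  for (a in c(1, 5, 11)) {
    got <- sort(map0$gene_id[map0$term_id == planted[a]])
    want <- sort(sim$truth$genes$gene_id[sim$truth$genes$archetype == a])
    expect_identical(got, want)
  }
  expect_identical(attr(map0, "universe"), sim$truth$genes$gene_id)

  # 2x2 table tally: counts derived from the emitted map agree with an
  # independent tally over the pairs
  map <- simulate_annotation(sim$truth, n_terms = 50, background_rate = 0.05,
                             enrichment_boost = 10, seed = 4)
  a1 <- sim$truth$genes$gene_id[sim$truth$genes$archetype == 1]
  term <- attr(map, "planted_terms")[1]
  ann <- unique(map$gene_id[map$term_id == term])
  res <- fisher_enrichment(list(cs = a1), map,
                           universe = attr(map, "universe"))
  row <- res[res$term_id == term, ]
  expect_equal(row$k, sum(a1 %in% ann))
  expect_equal(row$K, length(ann))
  expect_equal(row$n, length(a1))
  expect_equal(row$N, length(attr(map, "universe")))
})

test_that("null annotation (boost 1) carries no archetype association", {
  sim <- small_sim(n_genes = 2000)
  map <- simulate_annotation(sim$truth, n_terms = 30, background_rate = 0.2,
                             enrichment_boost = 1, seed = 9)
  planted <- attr(map, "planted_terms")
  a1 <- sim$truth$genes$gene_id[sim$truth$genes$archetype == 1]
  in_rate <- mean(a1 %in% map$gene_id[map$term_id == planted[1]])
  # archetype rate should match the background rate within binomial noise
  expect_equal(in_rate, 0.2, tolerance = 4 * sqrt(0.2 * 0.8 / length(a1)))
})

test_that("simulation round-trips through the TSV writers", {
  sim <- small_sim(n_genes = 200)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_count_matrix(dir)
  expect_equal(back$counts, sim$counts$counts)
  expect_equal(back$gene_length_bp, sim$counts$gene_length_bp)
  expect_equal(back$library_total, sim$counts$library_total)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(time_points_h = c(0, 3, 1)), "increasing")
  expect_error(sim_config(time_points_h = c(1, 3)), "include 0")
  expect_error(sim_config(frac_responsive = 1), "frac_responsive")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(n_clusters = 12), "templates")
  sim <- small_sim(n_genes = 100)
  expect_error(simulate_annotation(sim$truth, n_terms = 5), "at least")
  expect_error(simulate_annotation(sim$truth, enrichment_boost = 0.5), ">= 1")
  expect_error(simulate_qpcr(sim$truth, "nope"), "subset")
  expect_error(simulate_qpcr(sim$truth, "G00001", noise_sd = -1), ">= 0")
})
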