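one_lake_design <- function(n_columns = 13, strata = 4, n_water = 50,
                            sediment = FALSE, marker = c(diatom = 100)) {
  build_design(list(L1 = lake_spec(n_columns, strata, n_water,
                                   sediment_per_column = sediment)),
               markers = marker)
}

test_that("identical (design, model, seed) give identical tables and truth", {
  design <- one_lake_design(n_columns = 4, strata = 2, n_water = 8,
                            sediment = TRUE)
  model <- community_model(n_otus = c(diatom = 20))
  a <- simulate_dataset(design, model, seed = 11)
  b <- simulate_dataset(design, model, seed = 11)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$truth$specialists, b$truth$specialists)
  expect_identical(a$truth$latents, b$truth$latents)
  c <- simulate_dataset(design, model, seed = 12)
  expect_false(identical(a$table$counts, c$table$counts))
})

test_that("counts are non-negative integers with the designed replication", {
  design <- one_lake_design(n_columns = 3, strata = 2, n_water = 6,
                            sediment = TRUE)
  sim <- simulate_dataset(design, community_model(n_otus = c(diatom = 15)),
                          seed = 4)
  cnt <- sim$table$counts
  expect_true(all(cnt >= 0))
  expect_true(all(cnt == round(cnt)))
  meta <- sim$table$meta
  reps <- table(meta$sample_id[!meta$is_negative_control],
                meta$marker[!meta$is_negative_control])
  expect_true(all(reps == design$n_pcr_replicates))
  expect_equal(sum(meta$is_negative_control), design$n_negative_controls)
})

test_that("without planted structure, latent correlations vanish on average", {
  design <- one_lake_design()
  model <- community_model(n_otus = c(diatom = 12))
  lat <- simulate_latents(design, model, seed = 5)$latents$diatom
  r <- cor(log(lat), method = "spearman")
  off <- abs(r[upper.tri(r)])
  # under the null, r ~ N(0, 1/sqrt(n-1)): E|r| = 0.143 * sqrt(2/pi) ~ 0.114
  expect_lt(mean(off), 0.15)
  expect_true(is.null(dim(simulate_latents(design, model, 5)$truth$modules)) ||
                nrow(simulate_latents(design, model, 5)$truth$modules) == 0)
})

test_that("a rho_within = 0.95 block of 5 OTUs shows strong latent rank correlation", {
  design <- one_lake_design()
  model <- community_model(
    n_otus = c(diatom = 12),
    modules = list(list(marker = "diatom", otus = 1:5, rho_within = 0.95)))
  mean_within <- vapply(1:20, function(s) {
    lat <- simulate_latents(design, model, seed = 1000 + s)$latents$diatom
    r <- cor(lat[, 1:5], method = "spearman")
    mean(r[upper.tri(r)])
  }, numeric(1))
  # Gaussian copula: expected Spearman r = (6/pi) asin(rho/2) ~ 0.946
  expect_gt(mean(mean_within), 0.75)
})

test_that("a 50-fold specialist is ~50x more abundant in its habitat", {
  design <- build_design(
    list(L1 = lake_spec(6, 4, sediment_per_column = TRUE)),
    markers = c(diatom = 100))
  model <- community_model(
    n_otus = c(diatom = 10),
    specialists = data.frame(marker = "diatom", otu = 1, habitat = "sediment",
                             fold_enrichment = 50))
  hab <- design$samples$habitat
  ratios <- vapply(1:20, function(s) {
    lat <- simulate_latents(design, model, seed = 2000 + s)$latents$diatom
    mean(lat[hab == "sediment", 1]) / mean(lat[hab == "water", 1])
  }, numeric(1))
  expect_gt(mean(ratios), 35)
  expect_lt(mean(ratios), 70)
})

test_that("zero contamination leaves negative controls empty", {
  design <- one_lake_design(3, 2, 6)
  model <- community_model(n_otus = c(diatom = 8), contamination_rate = 0)
  sim <- simulate_dataset(design, model, seed = 3)
  nc <- sim$table$counts[sim$table$meta$is_negative_control, , drop = FALSE]
  expect_true(all(nc == 0))
})

test_that("multinomial counts track the latent composition", {
  design <- one_lake_design(1, 1, 1)
  model <- community_model(n_otus = c(diatom = 2), depth_mean = 1e4,
                           depth_dispersion = 1e6, dropout_prob = 0,
                           contamination_rate = 0)
  lat <- simulate_latents(design, model, seed = 6)
  lat$latents$diatom[1, ] <- c(3, 1)  # force an exact 3:1 composition
  counts <- numeric(0)
  for (s in 1:30) {
    tab <- simulate_counts(lat$latents, design, model, seed = 3000 + s)
    smp <- tab$counts[!tab$meta$is_negative_control, , drop = FALSE]
    counts <- rbind(counts, colSums(smp))
  }
  ratio <- sum(counts[, 1]) / sum(counts[, 2])
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 3.2)
})

test_that("overlapping blocks that break positive definiteness are reported", {
  design <- one_lake_design(2, 2, 4)
  model <- community_model(
    n_otus = c(diatom = 3),
    modules = list(list(marker = "diatom", otus = 1:2, rho_within = 0.95),
                   list(marker = "diatom", otus = 2:3, rho_within = 0.95)))
  expect_error(simulate_latents(design, model, seed = 1),
               "not positive definite.*diatom|diatom.*not positive definite")
})

test_that("fold_enrichment 1 and flat correlation plant no truth", {
  design <- one_lake_design(3, 2, 6, sediment = TRUE)
  model <- community_model(
    n_otus = c(diatom = 10),
    specialists = data.frame(marker = "diatom", otu = 1, habitat = "water",
                             fold_enrichment = 1),
    modules = list(list(marker = "diatom", otus = 1:3, rho_within = 0)))
  sim <- simulate_dataset(design, model, seed = 9)
  expect_equal(nrow(sim$truth$specialists), 0)
  expect_equal(nrow(sim$truth$modules), 0)
})
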