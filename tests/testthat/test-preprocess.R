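test_that("negative-control subtraction clamps at zero and removes NC rows", {
  x <- toy_pcr_counts(matrix(c(10, 3), 1, 2), n_nc = 2,
                      nc_counts = rbind(c(2, 5), c(1, 2)))
  out <- subtract_negative_controls(x)
  expect_equal(unname(out$counts[1, ]), c(8, 0))
  expect_false(any(out$meta$is_negative_control))
})

test_that("subtraction is the identity without NC reads", {
  x <- toy_pcr_counts(matrix(c(10, 3, 7, 0), 2, 2))
  expect_equal(subtract_negative_controls(x)$counts, x$counts)
  y <- toy_pcr_counts(matrix(c(10, 3), 1, 2), n_nc = 3)
  expect_equal(unname(subtract_negative_controls(y)$counts[1, ]), c(10, 3))
})

test_that("low-count zeroing is per cell with an inclusive boundary", {
  x <- toy_pcr_counts(matrix(c(4, 5, 100, 0), 1, 4))
  out <- filter_low_count_otus(x, min_reads = 5)
  expect_equal(unname(out$counts[1, ]), c(0, 5, 100, 0))
  allhigh <- toy_pcr_counts(matrix(c(5, 9, 20, 6), 2, 2))
  expect_equal(filter_low_count_otus(allhigh)$counts, allhigh$counts)
  expect_error(filter_low_count_otus(x, min_reads = 0), ">= 1")
})

test_that("shallow PCRs are dropped by per-marker thresholds, boundary inclusive", {
  counts <- rbind(c(400, 99), c(300, 200))
  x <- toy_pcr_counts(counts, marker = "invertebrate")
  out <- filter_shallow_pcrs(x, c(invertebrate = 500))
  expect_equal(nrow(out$counts), 1)       # 499 total dropped, 500 kept
  expect_equal(sum(out$counts), 500)
  expect_length(attr(out, "dropped_pcrs"), 1)

  cy <- toy_pcr_counts(matrix(c(60, 40), 1, 2), marker = "cyanobacteria")
  expect_equal(nrow(filter_shallow_pcrs(cy, c(cyanobacteria = 100))$counts), 1)

  empty <- toy_pcr_counts(matrix(integer(0), 0, 2))
  expect_equal(nrow(filter_shallow_pcrs(empty, c(diatom = 100))$counts), 0)
  expect_error(filter_shallow_pcrs(x, c(diatom = 100)), "invertebrate")
})

test_that("per-PCR RRA rows sum to one and zero rows are an ordering error", {
  x <- toy_pcr_counts(rbind(c(30, 70, 0), c(5, 5, 10)))
  rra <- compute_rra(x)
  expect_equal(unname(rra[1, ]), c(0.3, 0.7, 0))
  expect_equal(unname(rra[2, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(rowSums(rra)), c(1, 1), tolerance = 1e-12)
  bad <- toy_pcr_counts(rbind(c(1, 1), c(0, 0)))
  expect_error(compute_rra(bad), "filter_shallow_pcrs")
})

test_that("replicate collapsing averages RRA and ORs incidence", {
  x <- toy_pcr_counts(rbind(c(10, 0), c(0, 10), c(0, 7)), n_rep = 3)
  # one sample, three replicates; third replicate sees only OTU 2
  rra <- compute_rra(x)
  st <- collapse_replicates(rra, x)
  expect_equal(unname(st$rra[1, ]), c(1 / 3, 2 / 3))
  expect_equal(unname(st$incidence[1, ]), c(1, 1))
  expect_equal(st$meta$n_replicates, 3)

  two <- toy_pcr_counts(rbind(c(10, 0), c(0, 10)), n_rep = 2)
  st2 <- collapse_replicates(compute_rra(two), two)
  expect_equal(unname(st2$rra[1, ]), c(0.5, 0.5))

  one <- toy_pcr_counts(matrix(c(6, 18), 1, 2))
  st1 <- collapse_replicates(compute_rra(one), one)
  expect_equal(unname(st1$rra[1, ]), c(0.25, 0.75))
})

test_that("an OTU seen in one of three replicates is marked present", {
  x <- toy_pcr_counts(rbind(c(100, 0), c(100, 7), c(100, 0)), n_rep = 3)
  st <- collapse_replicates(compute_rra(x), x)
  expect_equal(unname(st$incidence[1, 2]), 1)
})

test_that("samples losing all replicates are dropped and reported", {
  counts <- rbind(c(1000, 500), c(10, 20), c(800, 300), c(900, 100))
  x <- toy_pcr_counts(counts, n_rep = 2)  # sample 1 keeps 1 PCR, sample 2 both
  counts2 <- rbind(c(10, 20), c(30, 5))   # a sample losing everything
  y <- toy_pcr_counts(rbind(counts, counts2), n_rep = 2)
  expect_warning(st <- preprocess(y, min_depth_by_marker = c(diatom = 100)),
                 "lost all")
  expect_length(st$dropped_samples, 1)
  expect_equal(nrow(st$rra), 2)
})

test_that("the filter chain never increases totals and is idempotent", {
  design <- build_design(list(L1 = lake_spec(4, 2, sediment_per_column = TRUE)),
                         markers = c(diatom = 100))
  sim <- simulate_dataset(design, community_model(n_otus = c(diatom = 20)),
                          seed = 21)
  st <- suppressWarnings(preprocess(sim$table,
                                    min_depth_by_marker = c(diatom = 100)))
  rep <- attr(st, "report")
  expect_true(rep$reads_after_nc_subtraction <= rep$reads_input)
  expect_true(rep$reads_after_low_count_filter <= rep$reads_after_nc_subtraction)
  expect_true(rep$reads_after_depth_filter <= rep$reads_after_low_count_filter)
  # incidence 0 implies rra 0
  expect_true(all(st$rra[st$incidence == 0] == 0))
  # filter chain applied twice = applied once (no NCs remain after pass 1)
  f1 <- filter_shallow_pcrs(
    filter_low_count_otus(subtract_negative_controls(sim$table)),
    c(diatom = 100))
  f2 <- filter_shallow_pcrs(filter_low_count_otus(f1), c(diatom = 100))
  expect_identical(f1$counts, f2$counts)
})

test_that("with clean controls and no dropout, NC subtraction is the identity", {
  design <- build_design(list(L1 = lake_spec(3, 2)), markers = c(diatom = 100))
  model <- community_model(n_otus = c(diatom = 10), contamination_rate = 0,
                           dropout_prob = 0)
  sim <- simulate_dataset(design, model, seed = 8)
  out <- subtract_negative_controls(sim$table)
  smp <- !sim$table$meta$is_negative_control
  expect_identical(out$counts, sim$table$counts[smp, , drop = FALSE])
})

test_that("OTU exclusion lists are applied before RRA and reported", {
  x <- toy_pcr_counts(rbind(c(100, 100, 200), c(150, 50, 200)))
  st <- preprocess(x, min_otu_reads = 5, min_depth_by_marker = c(diatom = 100),
                   exclude_otus = "diatom_003")
  expect_false("diatom_003" %in% colnames(st$rra))
  expect_equal(unname(st$rra[1, ]), c(0.5, 0.5))
  expect_equal(attr(st, "report")$excluded_otus, "diatom_003")
})

test_that("count tables survive a TSV round trip", {
  design <- build_design(list(L1 = lake_spec(2, 2)),
                         markers = c(diatom = 100, vertebrate = 100))
  sim <- simulate_dataset(design, community_model(
    n_otus = c(diatom = 6, vertebrate = 4)), seed = 13)
  path <- tempfile(fileext = ".tsv")
  write_pcr_counts(sim$table, path)
  back <- read_pcr_counts(path)
  expect_equal(unname(back$counts), unname(sim$table$counts))
  expect_equal(back$meta$sample_id, sim$table$meta$sample_id)
  expect_equal(back$meta$is_negative_control,
               sim$table$meta$is_negative_control)
})
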