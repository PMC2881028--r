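test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_config(seed = 91)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$annotation$sequences, b$annotation$sequences)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$truth$intervals, b$truth$intervals)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$intensities$raw, b$intensities$raw)
  # a different seed changes the data
  c <- simulate_dataset(small_config(seed = 92))
  expect_false(identical(a$annotation$sequences, c$annotation$sequences))
})

test_that("planted candidates lie wholly inside sufficiently long IGRs", {
  cfg <- small_config(seed = 93)
  gen <- simulate_genome(cfg)
  igrs <- extract_igrs(gen$annotation, min_len = cfg$ncrna_len_range[1])
  iv <- gen$truth$intervals
  expect_equal(nrow(iv), cfg$n_candidates)
  expect_equal(sum(iv$expressed), cfg$n_expressed)
  for (i in seq_len(nrow(iv))) {
    host <- igrs[igrs$replicon == iv$replicon[i] &
                   igrs$start <= iv$start[i] &
                   igrs$end >= iv$end[i], ]
    expect_equal(nrow(host), 1)
  }
  # expression states follow the group map
  expr <- gen$truth$expression
  for (g in names(cfg$groups)) {
    rows <- iv$id[iv$group == g]
    if (length(rows)) {
      expect_true(all(expr[rows, cfg$groups[[g]], drop = FALSE]))
      expect_false(any(expr[rows, -cfg$groups[[g]], drop = FALSE]))
    }
  }
})

test_that("unmutated predictions are exact truth subsequences", {
  cfg <- small_config(seed = 94, mutation_rate = 0, trim_max = 0,
                      n_decoys = 0)
  gen <- simulate_genome(cfg)
  preds <- simulate_predictions(gen$truth, gen$annotation, cfg)
  iv <- gen$truth$intervals
  for (i in seq_len(min(nrow(preds), 30))) {
    tru <- igr_sequence(iv[iv$id == preds$truth_id[i], ], gen$annotation)
    expect_true(preds$sequence[i] == tru ||
                  preds$sequence[i] == revcomp(tru))
  }
})

test_that("decoy-only predictions produce no candidate regions", {
  cfg <- small_config(seed = 95)
  sim <- simulate_dataset(cfg)
  igrs <- extract_igrs(sim$annotation)
  decoys <- sim$predictions[is.na(sim$predictions$truth_id), ]
  expect_gt(nrow(decoys), 0)
  cr <- match_predictions(decoys, igrs, sim$annotation)
  expect_equal(nrow(cr$regions), 0)
})

test_that("planted copies of one truth merge into a single region", {
  cfg <- small_config(seed = 96)
  sim <- simulate_dataset(cfg)
  igrs <- extract_igrs(sim$annotation)
  cr <- match_predictions(sim$predictions, igrs, sim$annotation)
  mt <- match_truth(cr$regions, sim$truth)
  # every truth interval is recovered by exactly one region
  expect_true(all(!is.na(mt$region_id)))
  # regions supported by multiple prediction copies report them
  multi <- table(sim$predictions$truth_id)
  some_multi <- names(multi)[multi >= 2][1]
  rid <- mt$region_id[mt$truth_id == some_multi]
  expect_gte(cr$regions$n_predictions[cr$regions$id == rid], 2)
})

test_that("intensity model plants signal only where truth is expressed", {
  cfg <- small_config(seed = 97, noise_sd = 1e-4, affinity_sd = 0,
                      offset_sd = 0, bias_coef = rep(0, 5))
  sim <- simulate_dataset(cfg)
  logm <- log2_transform(sim$intensities$raw)
  iv <- sim$truth$intervals
  on <- iv[iv$expressed, ][1, ]
  probes <- probes_for_region(sim$design, on, sim$annotation)
  expect_gt(nrow(probes), 0)
  up <- colMeans(logm[probes$id, , drop = FALSE]) - cfg$baseline_mean
  expect_equal(unname(up > 1),
               unname(sim$truth$expression[on$id, ]))
  # unexpressed truth interval shows baseline everywhere
  off <- iv[!iv$expressed, ][1, ]
  probes_off <- probes_for_region(sim$design, off, sim$annotation)
  expect_lt(max(abs(logm[probes_off$id, ] - cfg$baseline_mean)), 0.01)
})

test_that("all-zero effects yield a signal-free matrix", {
  cfg <- small_config(seed = 98, effect_size = 0)
  sim <- simulate_dataset(cfg)
  logm <- log2_transform(sim$intensities$raw)
  norm <- loess_normalize(logm)
  igrs <- extract_igrs(sim$annotation)
  cr <- match_predictions(sim$predictions, igrs, sim$annotation)
  asg <- assign_probes(sim$design, cr$regions, sim$annotation)
  su <- summarize_regions(norm, asg)
  # no region stands out by anything near the usual +2 log2 effect:
  # with the signal switched off, would-be expressed regions look like
  # every other region
  mt <- match_truth(cr$regions, sim$truth)
  would_be <- mt$region_id[mt$expressed & !is.na(mt$region_id)]
  bulk_med <- median(su$summaries)
  expect_lt(max(su$summaries[would_be, ]) - bulk_med, 1.5)
  expect_lt(abs(mean(su$summaries[would_be, ]) - bulk_med), 0.2)
})

test_that("simulated target genomes embed the requested truth intervals", {
  cfg <- small_config(seed = 99)
  gen <- simulate_genome(cfg)
  tg <- simulate_target_genome(gen$truth, gen$annotation, cfg,
                               length = 1e5, conserved_fraction = 0.5)
  expressed <- gen$truth$intervals[gen$truth$intervals$expressed, ]
  expect_equal(length(tg$embedded), round(0.5 * nrow(expressed)))
  emb <- expressed[expressed$id == tg$embedded[1], ]
  seqs <- stats::setNames(igr_sequence(emb, gen$annotation), emb$id)
  scan <- conservation_scan(seqs, list(t = tg$sequence))
  expect_lt(scan$best_evalue, 1e-5)
})
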