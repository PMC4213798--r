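params_dna <- similarity_params("dna")

test_that("the central sequence maximizes summed similarity", {
  solo <- distinct_seqs(5)[1]
  expect_equal(central_representative(solo), "A")
  seqs <- distinct_seqs(c(8, 8, 8))
  stip <- similarity_params(sim_fun = table_sim_fun(data.frame(
    a = c(unclass(seqs)[1], unclass(seqs)[1], unclass(seqs)[2]),
    b = c(unclass(seqs)[2], unclass(seqs)[3], unclass(seqs)[3]),
    sim = c(0.9, 0.9, 0.5))))
  expect_equal(central_representative(seqs, stip, comparison_ledger()), "A")
  # ledger: one cold half matrix over the group
  led <- comparison_ledger()
  central_representative(seqs, stip, led)
  expect_equal(ledger_count(led), 3)
  expect_error(central_representative(seqs[0]), "non-empty")
})

test_that("central representative agrees with the exhaustive oracle", {
  for (seed in c(3, 14, 25)) {
    sim <- planted(1, 20, seed = seed, len = 80, within = 0.9,
                   between = 0.5)
    m <- half_matrix(sim$sequences, params_dna, comparison_ledger())
    expect_equal(central_representative(sim$sequences, params_dna,
                                        comparison_ledger()),
                 brute_central(m))
  }
})

test_that("almost-central representative reduces to the exact centre on small groups", {
  sim <- planted(1, 8, seed = 6, len = 60, within = 0.9, between = 0.5)
  seqs <- sim$sequences
  expect_equal(
    almost_central_representative(seqs, gc_rep = seq_ids(seqs)[1], k = 10,
                                  params = params_dna),
    central_representative(seqs, params_dna))
  expect_equal(
    almost_central_representative(seqs, gc_rep = seq_ids(seqs)[3], k = 1,
                                  params = params_dna),
    seq_ids(seqs)[3])   # k = 1 keeps only the rank-1 (most similar) member
  expect_error(almost_central_representative(seqs, gc_rep = "nope"), "nope")
})

test_that("the almost-central heuristic usually beats the greedy founder", {
  # groups as greedy clustering forms them at a loose threshold: two
  # families pooled, so the founder may sit far off-centre
  wins <- 0L
  for (trial in 1:100) {
    sim <- generate_families(family_spec(2, c(15, 35), seq_length = 80,
                                         within_identity = 0.95,
                                         between_identity = 0.80,
                                         seed = 5000 + trial))
    seqs <- sim$sequences
    led <- comparison_ledger()
    m <- half_matrix(seqs, params_dna, led)
    sums <- rowSums(m) - 1
    gc_rep <- seq_ids(order_by_decreasing_length(seqs))[1]  # greedy founder
    ac <- almost_central_representative(seqs, gc_rep = gc_rep, k = 10,
                                        params = params_dna, ledger = led)
    if (sums[ac] >= sums[gc_rep]) wins <- wins + 1L
  }
  expect_gte(wins, 90L)
})

test_that("blocks chunk the ordering without reordering it", {
  x <- sprintf("s%02d", 1:10)
  blocks <- partition_into_blocks(x, 3)
  expect_equal(lengths(blocks), c(3L, 3L, 3L, 1L))
  expect_equal(unlist(blocks), x)
  expect_length(partition_into_blocks(x, 99), 1L)
  expect_length(partition_into_blocks(x, 0), 1L)
  expect_error(partition_into_blocks(x, -1), "block_size")
})

test_that("threshold schedules rise strictly and end at the target", {
  expect_equal(as.numeric(threshold_schedule(0.95, 0.95)), 0.95)
  s <- threshold_schedule(0.95, 0.9861)
  expect_true(all(diff(s) > 0))
  expect_equal(s[length(s)], 0.9861)
  expect_gt(length(s), 2)
  expect_error(threshold_schedule(0.9, 0.8), "exceed")
  expect_error(threshold_schedule(thresholds = c(0.5, 0.5, 0.9)),
               "increasing")
  expect_error(threshold_schedule(thresholds = numeric(0)), "non-empty")
  expect_equal(as.numeric(threshold_schedule(thresholds = c(0.3, 0.9))),
               c(0.3, 0.9))
})

test_that("disabling blocks turns MLC1 into CCBC at full-matrix cost", {
  sim <- planted(5, 8, seed = 21, len = 80)
  n <- length(sim$sequences)
  led_m <- comparison_ledger()
  pm <- mlc1(sim$sequences, 0.95, mlc_config(block_size = 0), params_dna,
             led_m)
  pc <- ccbc_cluster(sim$sequences, 0.95, params_dna, comparison_ledger())
  expect_true(same_grouping(pm, pc))
  expect_equal(f_value(led_m, n), 1.0)
})

test_that("one sequence per block degenerates to CCBC over everything", {
  sim <- planted(4, 6, seed = 33, len = 80)
  p1 <- mlc1(sim$sequences, 0.95, mlc_config(block_size = 1), params_dna,
             comparison_ledger())
  pc <- ccbc_cluster(sim$sequences, 0.95, params_dna, comparison_ledger())
  expect_true(same_grouping(p1, pc))
})

test_that("MLC1 recovers planted families at a fraction of the cost", {
  sim <- planted(15, 20, seed = 44, len = 100)
  n <- length(sim$sequences)     # 300
  led <- comparison_ledger()
  part <- mlc1(sim$sequences, 0.95, mlc_config(block_size = 30), params_dna,
               led)
  expect_equal(f_measure(part, sim$truth), 1.0)
  expect_lt(ledger_count(led), n * (n - 1) / 2)
  validate_partition_ok(part, seq_ids(sim$sequences))
})

test_that("a one-level schedule on a small input reduces MLC to MLC1", {
  sim <- planted(4, 6, seed = 52, len = 80)
  cfg <- mlc_config()            # s = 300 > N
  pm <- mlc(sim$sequences, threshold_schedule(0.95, 0.95), cfg, params_dna,
            comparison_ledger())
  p1 <- mlc1(sim$sequences, 0.95, cfg, params_dna, comparison_ledger())
  expect_true(same_grouping(pm, p1))
})

test_that("MLC climbs the schedule and spares comparisons", {
  sim <- planted(10, 20, seed = 61, len = 100)
  n <- length(sim$sequences)     # 200
  cfg <- mlc_config(s = 50)
  led <- comparison_ledger()
  part <- mlc(sim$sequences, threshold_schedule(0.8, 0.95), cfg, params_dna,
              led)
  expect_equal(f_measure(part, sim$truth), 1.0)
  expect_lt(ledger_count(led), n * (n - 1) / 2)
  validate_partition_ok(part, seq_ids(sim$sequences))
})

test_that("rMLC equals MLC below the recursion cutoff and above it still recovers truth", {
  sim <- planted(8, 10, seed = 72, len = 80)
  sched <- threshold_schedule(0.8, 0.95)
  cfg <- mlc_config(s = 30, M = 1000)   # N = 80 <= M: declared base case
  pm <- mlc(sim$sequences, sched, cfg, params_dna, comparison_ledger())
  pr <- rmlc(sim$sequences, sched, cfg, params_dna, comparison_ledger())
  expect_true(same_grouping(pm, pr))
  # force recursion with a small cutoff
  cfg2 <- mlc_config(s = 20, M = 25)
  led <- comparison_ledger()
  pr2 <- rmlc(sim$sequences, sched, cfg2, params_dna, led)
  expect_equal(f_measure(pr2, sim$truth), 1.0)
  validate_partition_ok(pr2, seq_ids(sim$sequences))
})

test_that("batch limits never change a partition", {
  sim <- planted(6, 8, seed = 83, len = 80)
  sched <- threshold_schedule(0.85, 0.95)
  cfg <- mlc_config(s = 20, M = 30)
  base <- rmlc(sim$sequences, sched, cfg, params_dna,
               comparison_ledger(batch_limit = 1e6))
  for (lim in c(1, 17)) {
    led <- comparison_ledger(batch_limit = lim)
    expect_true(same_grouping(
      rmlc(sim$sequences, sched, cfg, params_dna, led), base))
  }
})

test_that("degenerate inputs yield valid partitions", {
  empty <- seq_set(character(0), ids = character(0))
  expect_equal(n_clusters(mlc1(empty, 0.9)), 0L)
  expect_equal(n_clusters(mlc(empty, threshold_schedule(0.9, 0.9))), 0L)
  one <- random_dna(1, 30, seed = 2)
  expect_equal(n_clusters(mlc1(one, 0.9, params = params_dna)), 1L)
  two <- random_dna(2, 30, seed = 3)
  p2 <- mlc(two, threshold_schedule(0.5, 0.9), params = params_dna)
  validate_partition_ok(p2, seq_ids(two))
})

test_that("runs are deterministic: same input, same cluster table", {
  sim <- planted(6, 8, seed = 97, len = 80)
  run <- function() {
    part <- rmlc(sim$sequences, threshold_schedule(0.85, 0.95),
                 mlc_config(s = 20, M = 30), params_dna, comparison_ledger())
    as.data.frame(part)
  }
  expect_identical(run(), run())
})
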