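params_dna <- similarity_params("dna")

test_that("length ordering is decreasing with deterministic tie-breaks", {
  s <- seq_set(c(x = "AAAAA", y = "CCCCCCCCC", z = "GGGGGGG"))
  expect_equal(seq_ids(order_by_decreasing_length(s)), c("y", "z", "x"))
  ties <- seq_set(c(b = "AAAA", a = "CCCC", c = "GGGG"))
  expect_equal(seq_ids(order_by_decreasing_length(ties)), c("a", "b", "c"))
  sorted <- order_by_decreasing_length(s)
  expect_identical(seq_ids(order_by_decreasing_length(sorted)),
                   seq_ids(sorted))
})

test_that("greedy clustering follows first-match representative semantics", {
  seqs <- distinct_seqs(c(10, 9, 8))   # A, B, C by decreasing length
  stip <- similarity_params(sim_fun = table_sim_fun(data.frame(
    a = c(unclass(seqs)[1], unclass(seqs)[1]),
    b = c(unclass(seqs)[2], unclass(seqs)[3]),
    sim = c(0.95, 0.2))))
  part <- greedy_cluster(seqs, 0.9, stip, comparison_ledger())
  expect_equal(canon_partition(part), c("A|B", "C"))
  expect_equal(representatives(part), c("A", "C"))
})

test_that("threshold zero pools everything; impossible threshold isolates", {
  set.seed(31)
  seqs <- random_dna(12, 40)
  p0 <- greedy_cluster(seqs, 0, params_dna, comparison_ledger())
  expect_equal(n_clusters(p0), 1L)
  led <- comparison_ledger()
  p1 <- greedy_cluster(seqs, 0.999, params_dna, led)
  expect_equal(n_clusters(p1), 12L)
  # every sequence scanned every earlier representative: the O(N m) worst case
  expect_equal(ledger_count(led), 12 * 11 / 2)
  expect_error(greedy_cluster(seqs, 1.2, params_dna), "threshold")
})

test_that("greedy members always clear the threshold to their representative", {
  sim <- planted(6, 8, seed = 41, len = 100)
  t <- 0.95
  part <- greedy_cluster(order_by_decreasing_length(sim$sequences), t,
                         params_dna, comparison_ledger())
  chk <- comparison_ledger()
  for (cl in part$clusters)
    for (m in setdiff(cl$members, cl$representative))
      expect_gte(percent_identity(sim$sequences[m],
                                  sim$sequences[cl$representative],
                                  params_dna, chk), t)
})

test_that("connectivity is transitive: chains merge, gaps isolate", {
  seqs <- distinct_seqs(c(8, 8, 8))
  stip <- similarity_params(sim_fun = table_sim_fun(data.frame(
    a = c(unclass(seqs)[1], unclass(seqs)[2], unclass(seqs)[1]),
    b = c(unclass(seqs)[2], unclass(seqs)[3], unclass(seqs)[3]),
    sim = c(0.95, 0.95, 0.5))))
  part <- ccbc_cluster(seqs, 0.9, stip, comparison_ledger())
  expect_equal(n_clusters(part), 1L)
  set.seed(55)
  rnd <- random_dna(10, 40)
  iso <- ccbc_cluster(rnd, 0.999, params_dna, comparison_ledger())
  expect_equal(n_clusters(iso), 10L)
})

test_that("CCBC equals the union-find oracle on random planted instances", {
  set.seed(77)
  for (trial in 1:20) {
    fam <- sample(2:6, 1)
    per <- sample(3:7, 1)
    within <- runif(1, 0.9, 0.99)
    between <- runif(1, 0.45, 0.7)
    sim <- planted(fam, per, seed = 1000 + trial, len = 60,
                   within = within, between = between)
    m <- half_matrix(sim$sequences, params_dna, comparison_ledger())
    t <- runif(1, 0.5, 0.99)
    part <- ccbc_cluster(sim$sequences, t, params_dna, comparison_ledger(),
                         precomputed = m)
    expect_equal(canon_partition(part), canon_groups(uf_components(m, t)))
  }
})

test_that("a precomputed matrix spares CCBC any new alignment", {
  sim <- planted(3, 5, seed = 8, len = 60)
  m <- half_matrix(sim$sequences, params_dna, comparison_ledger())
  led <- comparison_ledger()
  ccbc_cluster(sim$sequences, 0.9, params_dna, led, precomputed = m)
  expect_equal(ledger_count(led), 0)
})

test_that("every greedy cluster lies inside one connected component", {
  sim <- planted(5, 6, seed = 91, len = 80, within = 0.95, between = 0.6)
  t <- 0.85
  led <- comparison_ledger()
  m <- half_matrix(sim$sequences, params_dna, led)
  gc <- greedy_cluster(order_by_decreasing_length(sim$sequences), t,
                       params_dna, led)
  cc <- ccbc_cluster(sim$sequences, t, params_dna, led, precomputed = m)
  cc_of <- membership(cc)
  for (cl in gc$clusters)
    expect_length(unique(cc_of[cl$members]), 1L)
})

test_that("low-threshold pre-ordering makes families contiguous and is billed", {
  sim <- planted(5, 6, seed = 17, len = 80)
  led <- comparison_ledger()
  ord <- preorder_by_gc(sim$sequences, 0.85, params_dna, led)
  expect_gt(ledger_count(led), 0)      # pre-clustering cost lands on the ledger
  expect_setequal(seq_ids(ord), seq_ids(sim$sequences))
  fam <- unclass(sim$truth)[seq_ids(ord)]
  expect_equal(sum(fam[-1] != fam[-length(fam)]) + 1L, 5L)  # contiguous blocks
  # degenerate low threshold: single pre-cluster, order preserved
  ord0 <- preorder_by_gc(sim$sequences, 0, params_dna, comparison_ledger())
  expect_equal(seq_ids(ord0),
               seq_ids(order_by_decreasing_length(sim$sequences)))
})
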