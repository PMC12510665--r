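make_rec <- function(pid, pseq, rid, rseq)
  interaction_record(sequence_record(pid, pseq, "protein"),
                     sequence_record(rid, rseq, "rna"))

test_that("length filter keeps a record only when both sequences are in range", {
  recs <- list(
    make_rec("short_p", random_protein(9L), "r", random_rna(100L)),
    make_rec("ok", random_protein(10L), "r", random_rna(1024L)),
    make_rec("long_r", random_protein(50L), "r", random_rna(1025L)))
  kept <- filter_by_length(recs)
  expect_equal(vapply(kept, function(r) r$protein$id, ""), "ok")
})

test_that("greedy clustering matches a brute-force alignment oracle", {
  set.seed(41)
  fams <- make_redundant_families(4L, 5L, target_identity = 0.95,
                                  seq_len = 40L, seed = 7L)
  # add sprinkled unrelated sequences
  extra <- setNames(vapply(1:5, function(i) random_rna(35L), ""),
                    paste0("X", 1:5))
  seqs <- c(fams, extra)
  got <- greedy_cluster(seqs, 0.9)
  want <- oracle_greedy_cluster(seqs, 0.9)
  expect_equal(setNames(got$cluster_id, got$member_id), want)

  expect_equal(max(greedy_cluster(c(a = "ACGUACGUAC", b = "ACGUACGUAC"),
                                  0.9)$cluster_id), 1L)
  two <- greedy_cluster(c(a = "AAAAAAAAAA", b = "CCCCCCCCCC"), 0.9)
  expect_equal(sort(unique(two$cluster_id)), c(1L, 2L))
  expect_equal(nrow(greedy_cluster(character(), 0.5)), 0L)
})

test_that("greedy clustering is invariant to input order", {
  fams <- make_redundant_families(3L, 4L, target_identity = 0.93,
                                  seq_len = 30L, seed = 19L)
  a <- greedy_cluster(fams, 0.9)
  b <- greedy_cluster(rev(fams), 0.9)
  a <- a[order(a$member_id), ]
  b <- b[order(b$member_id), ]
  expect_equal(a$cluster_id, b$cluster_id)
  expect_equal(a$is_representative, b$is_representative)
})

test_that("complex clusters key on the (protein cluster, rna cluster) pair", {
  recs <- list(make_rec("P1", random_protein(20L), "R1", random_rna(20L)),
               make_rec("P2", random_protein(20L), "R2", random_rna(20L)),
               make_rec("P3", random_protein(20L), "R3", random_rna(20L)))
  pc <- data.frame(member_id = c("P1", "P2", "P3"), cluster_id = c(1L, 1L, 1L))
  rc <- data.frame(member_id = c("R1", "R2", "R3"), cluster_id = c(1L, 1L, 2L))
  recs <- assign_complex_clusters(recs, pc, rc)
  ids <- vapply(recs, function(r) r$complex_cluster_id, 0L)
  expect_equal(ids[1L], ids[2L])   # same protein + same rna cluster
  expect_true(ids[3L] != ids[1L])  # same protein, different rna cluster
  expect_false(anyNA(ids))         # partition covers all records
  rc_missing <- rc[1:2, ]
  expect_error(assign_complex_clusters(recs, pc, rc_missing), "no cluster")
})

test_that("inverse-cluster-size weights match the worked example and sum to 1", {
  recs <- c(
    lapply(1:10, function(i) {
      r <- make_rec(paste0("A", i), random_protein(15L), paste0("rA", i),
                    random_rna(15L)); r$complex_cluster_id <- 1L; r
    }),
    lapply(1:2, function(i) {
      r <- make_rec(paste0("B", i), random_protein(15L), paste0("rB", i),
                    random_rna(15L)); r$complex_cluster_id <- 2L; r
    }),
    lapply(1, function(i) {
      r <- make_rec("C1", random_protein(15L), "rC1", random_rna(15L))
      r$complex_cluster_id <- 3L; r
    }))
  corpus <- compute_weights(recs)
  w <- vapply(corpus$records, function(r) r$weight, 0)
  cc <- vapply(corpus$records, function(r) r$complex_cluster_id, 0L)
  expect_equal(unique(w[cc == 1L]), 0.1)
  expect_equal(unique(w[cc == 2L]), 0.5)
  expect_equal(unique(w[cc == 3L]), 1.0)
  for (k in 1:3)
    expect_lt(abs(sum(w[cc == k]) - 1), 1e-12)
})

test_that("weighted sampling equalizes cluster mass and is seed-deterministic", {
  recs <- c(
    lapply(1:9, function(i) {
      r <- make_rec(paste0("A", i), random_protein(15L), paste0("rA", i),
                    random_rna(15L)); r$complex_cluster_id <- 1L; r
    }),
    list({
      r <- make_rec("B1", random_protein(15L), "rB1", random_rna(15L))
      r$complex_cluster_id <- 2L; r
    }))
  corpus <- compute_weights(recs)
  n <- 100000L
  draws <- weighted_sample(corpus, n, seed = 4L)
  cc <- vapply(draws, function(r) r$complex_cluster_id, 0L)
  # each cluster holds total weight 1, so each expects 50% of draws (+-1%)
  expect_lt(abs(mean(cc == 1L) - 0.5), 0.01)
  draws2 <- weighted_sample(corpus, 50L, seed = 11L)
  draws3 <- weighted_sample(corpus, 50L, seed = 11L)
  expect_identical(vapply(draws2, function(r) r$rna$id, ""),
                   vapply(draws3, function(r) r$rna$id, ""))
  single <- compute_weights(list(recs[[10L]]))
  expect_equal(vapply(weighted_sample(single, 5L, seed = 1L),
                      function(r) r$rna$id, ""), rep("rB1", 5L))
})

test_that("expected draws per complex cluster stay within binomial bounds", {
  set.seed(99)
  sizes <- c(1L, 3L, 7L, 12L)
  recs <- unlist(lapply(seq_along(sizes), function(k) {
    lapply(seq_len(sizes[k]), function(i) {
      r <- make_rec(sprintf("P%d_%d", k, i), random_protein(12L),
                    sprintf("R%d_%d", k, i), random_rna(12L))
      r$complex_cluster_id <- k; r
    })
  }), recursive = FALSE)
  corpus <- compute_weights(recs)
  n <- 40000L
  draws <- weighted_sample(corpus, n, seed = 21L)
  cc <- vapply(draws, function(r) r$complex_cluster_id, 0L)
  p <- 1 / length(sizes)
  bound <- 3 * sqrt(n * p * (1 - p))
  for (k in seq_along(sizes))
    expect_lt(abs(sum(cc == k) - n * p), bound)
})
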