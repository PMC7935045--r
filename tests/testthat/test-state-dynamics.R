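test_that("fractional occupancy averages posteriors within blocks", {
  stc <- state_timecourse(rbind(c(1, 0), c(0.5, 0.5), c(0, 1),
                                c(0, 1), c(0, 1), c(0, 1)),
                          rep(c("a", "b"), each = 3))
  fo <- fractional_occupancy(stc)
  expect_equal(fo["a", ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(fo["b", ], c(0, 1), ignore_attr = TRUE)
  # hard assignment to one state is a one-hot row
  hard <- state_timecourse(matrix(rep(c(0, 1, 0), 10), 10, 3, byrow = TRUE),
                           rep("a", 10))
  expect_equal(fractional_occupancy(hard)[1, ], c(0, 1, 0),
               ignore_attr = TRUE)
  fo_r <- fractional_occupancy(random_stc())
  expect_lt(max(abs(rowSums(fo_r) - 1)), 1e-10)
})

test_that("switching rate follows the summed absolute change convention", {
  flat <- state_timecourse(matrix(0.25, 8, 4), rep("a", 8))
  expect_equal(unname(switching_rate(flat)), 0)
  # hard alternation over two frames: total change 2, divided by T = 2
  alt <- state_timecourse(rbind(c(1, 0), c(0, 1)), c("a", "a"))
  expect_equal(unname(switching_rate(alt)), 1.0)
  expect_equal(unname(switching_rate(alt, denominator = "T-1")), 2.0)
  # bounded by 2 for any valid posteriors
  expect_true(all(switching_rate(random_stc(6, 40, 7, seed = 3)) <= 2))
  single <- state_timecourse(matrix(c(0.5, 0.5), 1), "a")
  expect_error(switching_rate(single), "fewer than 2")
})

# Block transition matrix with the planted 2/9/1 metastate structure.
planted_theta <- function(blocks = list(1:2, 3:11, 12L), K = 12, w = 0.9) {
  Theta <- matrix(0, K, K)
  for (blk in blocks) {
    Theta[blk, blk] <- w / length(blk)
    Theta[blk, -blk] <- (1 - w) / (K - length(blk))
  }
  Theta
}

test_that("single-linkage clustering of the transition matrix recovers planted metastates", {
  Theta <- planted_theta()
  part <- cluster_metastates(Theta, 3)
  split_states <- unname(split(seq_len(12), part$labels))
  expect_true(setequal(lapply(split_states, sort),
                       list(1:2, 3:11, 12L)))
  # K = 2 cut to 2 clusters: two singletons
  Th2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  expect_equal(sort(unname(cluster_metastates(Th2, 2)$labels)), c(1, 2))
  # identical rows merge at height zero
  Th3 <- matrix(1 / 3, 3, 3)
  expect_true(all(cluster_metastates(Th3, 1)$tree$height == 0))
  expect_error(cluster_metastates(Th2, 3), "n_clusters")
})

test_that("metastate pooling conserves probability and commutes with FO", {
  stc <- random_stc(5, 30, 6, seed = 8)
  part <- c(1, 1, 2, 2, 2, 3)
  mstc <- metastate_timecourse(stc, part)
  expect_lt(max(abs(rowSums(mstc$probs) - 1)), 1e-10)
  # FO of a metastate equals the sum of member-state FOs
  fo <- fractional_occupancy(stc)
  mfo <- fractional_occupancy(mstc)
  for (g in 1:3)
    expect_lt(max(abs(mfo[, g] - rowSums(fo[, part == g, drop = FALSE]))),
              1e-12)
  # singleton partition is the identity
  id <- metastate_timecourse(stc, 1:6)
  expect_equal(id$probs, stc$probs, ignore_attr = TRUE)
})

test_that("metastate switching rate never exceeds the state switching rate", {
  for (s in 1:100) {
    stc <- random_stc(1, 15, 5, seed = s)
    part <- sample(1:3, 5, replace = TRUE)
    part <- match(part, sort(unique(part)))   # make labels 1..m
    if (length(unique(part)) == 1) next
    expect_lte(switching_rate(metastate_timecourse(stc, part))[1],
               switching_rate(stc)[1] + 1e-12)
  }
})

test_that("state features assemble the 17-column dynamic design at study defaults", {
  stc <- random_stc(6, 40, 12, seed = 12)
  part <- cluster_metastates(planted_theta(), 3)
  feats <- state_features(stc, part)
  expect_equal(ncol(feats), 17)
  expect_equal(colnames(feats)[13:17],
               c("fo_metastate1", "fo_metastate2", "fo_metastate3",
                 "sr_states", "sr_metastates"))
})

test_that("overlap index matches a brute-force selection oracle", {
  # 10 nodes valued 5..1, -1..-5; top 40% of each signed subset
  map <- c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5)
  brute <- function(map, network, frac) {
    pos <- which(map > 0); neg <- which(map < 0)
    sel <- c(pos[order(-map[pos])][seq_len(floor(frac * length(pos)))],
             neg[order(map[neg])][seq_len(floor(frac * length(neg)))])
    length(intersect(sel, network)) / length(network)
  }
  network <- c(1, 2, 10)   # the nodes valued 5, 4, -5
  expect_equal(overlap_index(map, network), brute(map, network, 0.4))
  expect_equal(overlap_index(map, network), 1.0)
  # selection equal to the network / disjoint from it
  expect_equal(overlap_index(map, c(1, 2, 9, 10)), 1.0)
  # mixed network: values 5 (selected), 3 (not), -4 (selected)
  expect_equal(overlap_index(map, c(1, 3, 9)), 2 / 3)
  expect_equal(overlap_index(map, c(5, 6)), 0.0)
  # invariant to positive rescaling
  set.seed(20)
  m2 <- rnorm(50)
  nw <- sample(50, 12)
  expect_equal(overlap_index(m2, nw), overlap_index(3.7 * m2, nw))
  expect_error(overlap_index(map, integer(0)), "at least one node")
})

test_that("motion QC enumerates feature-session tests with joint BH correction", {
  set.seed(30)
  n_sub <- 20
  feats <- matrix(rnorm(3 * n_sub * 17), ncol = 17)
  colnames(feats) <- paste0("f", 1:17)
  session <- rep(1:3, each = n_sub)
  fd <- rnorm(3 * n_sub, 0.15, 0.03)
  qc <- qc_confound_association(feats, fd, session)
  expect_equal(nrow(qc), 51)
  # joint BH across all 51 tests, written out stepwise as an oracle
  ord <- order(qc$p)
  bh <- qc$p[ord] * 51 / seq_len(51)
  bh <- rev(cummin(rev(bh)))
  expect_equal(qc$p_adjusted[ord], pmin(1, bh), tolerance = 1e-12)
  # a feature equal to FD correlates perfectly
  feats2 <- cbind(feats, fd = fd)
  qc2 <- qc_confound_association(feats2, fd, session)
  expect_true(all(abs(qc2$r[qc2$feature == "fd"] - 1) < 1e-12))
  # constant feature reported as missing
  feats3 <- cbind(feats, const = 1)
  qc3 <- qc_confound_association(feats3, fd, session)
  expect_true(all(is.na(qc3$r[qc3$feature == "const"])))
})

test_that("decoded FO tracks true FO in the separable regime", {
  cfg <- tiny_config(n_subjects = 8, sessions_per_subject = 2,
                     runs_per_session = 1, timepoints_per_run = 120,
                     state_mean_scale = 2.5, seed = 77)
  sim <- generate_hmm_timeseries(cfg)
  cc <- standardize_concat(sim$timeseries)
  fit <- fit_hmm(cc, K = 3, n_restarts = 2, seed = 5)
  truth_path <- unlist(sim$truth$state_paths[levels(cc$block)])
  al <- align_states(truth_path, apply(fit$stc$probs, 1, which.max), 3)
  fo <- fractional_occupancy(fit$stc)[, order(al$perm)]
  true_fo <- sim$truth$true_FO[levels(cc$block), ]
  for (k in 1:3) expect_gt(cor(fo[, k], true_fo[, k]), 0.95)
})
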