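# Shared fixtures, generated in code.

# Subject labels of the emulated study design: 23 subjects, the first 18
# with three sessions, the last 5 with two (64 subject-session rows).
study_groups <- function() {
  rep(sprintf("S%02d", 1:23), times = c(rep(3, 18), rep(2, 5)))
}

# A small, fast study configuration; override any field via ...
tiny_config <- function(...) {
  args <- list(
    n_subjects = 4, sessions_per_subject = 2, runs_per_session = 2,
    timepoints_per_run = 40, n_nodes = 6, n_states = 3,
    transition_blocks = list(1:2, 3L), state_mean_scale = 2, seed = 42)
  over <- list(...)
  args[names(over)] <- over   # replace wholesale (no nested-list merging)
  if ("n_states" %in% names(over) && !("transition_blocks" %in% names(over)))
    args$transition_blocks <- NULL
  do.call(synth_config, args)
}

# Random valid state time course (rows on the simplex), fixed seed.
random_stc <- function(n_blocks = 4, len = 30, K = 5, seed = 1) {
  set.seed(seed)
  P <- matrix(stats::rexp(n_blocks * len * K), ncol = K)
  P <- P / rowSums(P)
  state_timecourse(P, rep(seq_len(n_blocks), each = len))
}

# Hard-assignment state time course from integer paths.
onehot_stc <- function(paths, K) {
  probs <- do.call(rbind, lapply(paths, function(p) {
    diag(K)[p, , drop = FALSE]
  }))
  state_timecourse(probs, rep(names(paths), lengths(paths)))
}

# Dynamic-arm feature matrix and factor scores from ground truth: state
# features computed from the true paths through the real pipeline, factor
# scores from the generated behavior table.
planted_cca_inputs <- function(cfg) {
  sim <- generate_hmm_timeseries(cfg)
  truth <- sim$truth
  beh <- generate_behavior(truth, cfg)
  stc <- onehot_stc(truth$state_paths, cfg$n_states)
  part <- cluster_metastates(truth$true_model$transition,
                             length(cfg$transition_blocks))
  X <- state_features(stc, part)
  sol <- suppressMessages(fit_factors(beh, 8))
  list(X = X, Y = sol$scores, groups = truth$block_ids$subject,
       truth = truth, behavior = beh)
}

# Plain log multivariate normal density (test oracle helper).
mvtnorm_log <- function(x, mu, S) {
  d <- length(x)
  as.numeric(-0.5 * (d * log(2 * pi) + determinant(S)$modulus +
                       t(x - mu) %*% solve(S) %*% (x - mu)))
}
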