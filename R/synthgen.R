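#' Configuration for the synthetic multi-subject study generator
#'
#' Bundles the shape and signal parameters of a simulated resting-state
#' study: subjects scanned over repeated sessions (with third-session
#' dropout), two runs per session, node-by-time BOLD-like signals driven by
#' a K-state Gaussian hidden Markov chain with block-structured transitions,
#' and a behavioral battery coupled to state occupancies through one planted
#' canonical mode.
#'
#' The defaults mirror the emulated study design: 23 subjects of whom the
#' first 18 complete three sessions and the remaining 5 two sessions, two
#' 180-volume runs per session at TR = 2 s, and a 12-state chain whose
#' transition matrix has a planted 2/9/1 block (metastate) structure with
#' 0.9 within-block transition mass.
#'
#' @param n_subjects Number of subjects.
#' @param sessions_per_subject Integer vector (length `n_subjects`, or a
#'   scalar recycled) of sessions completed by each subject; 2 or 3 at the
#'   study defaults.
#' @param runs_per_session Runs acquired per session.
#' @param timepoints_per_run Volumes per run.
#' @param tr Repetition time in seconds.
#' @param n_nodes Number of nodes (parcels). Small by default; the
#'   `full_scale` preset uses 439.
#' @param n_states Number of hidden states K.
#' @param transition_blocks List of integer vectors partitioning
#'   `1:n_states` into blocks of preferentially inter-transitioning states.
#'   Default for K = 12 is the 2/9/1 partition; otherwise one block.
#' @param within_block_mass Total transition probability mass a state keeps
#'   inside its own block, in \[0, 1\].
#' @param state_mean_scale Scale of state mean activity patterns, in signal
#'   units; state separability grows with `state_mean_scale / noise_sd`.
#' @param behavior_coupling Planted canonical correlation in \[0, 1\]
#'   between a linear combination of true fractional occupancies and one
#'   behavioral latent factor.
#' @param noise_sd Observation noise standard deviation (shared spherical
#'   state covariance), in signal units.
#' @param seed Integer seed making all generation reproducible.
#' @param full_scale If `TRUE`, override `n_nodes` to the full 439-node
#'   parcellation.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 23,
                         sessions_per_subject = c(rep(3L, 18), rep(2L, 5)),
                         runs_per_session = 2,
                         timepoints_per_run = 180,
                         tr = 2,
                         n_nodes = 20,
                         n_states = 12,
                         transition_blocks = NULL,
                         within_block_mass = 0.9,
                         state_mean_scale = 1,
                         behavior_coupling = 0.85,
                         noise_sd = 1,
                         seed = 1,
                         full_scale = FALSE) {
  if (isTRUE(full_scale)) n_nodes <- 439L
  counts <- c(n_subjects = n_subjects, runs_per_session = runs_per_session,
              timepoints_per_run = timepoints_per_run, n_nodes = n_nodes,
              n_states = n_states)
  stop_if(any(counts < 1) || any(counts != round(counts)),
          "all counts must be integers >= 1")
  if (length(sessions_per_subject) == 1L)
    sessions_per_subject <- rep(sessions_per_subject, n_subjects)
  stop_if(length(sessions_per_subject) != n_subjects,
          "sessions_per_subject must have one entry per subject")
  stop_if(any(sessions_per_subject < 1),
          "every subject needs at least one session")
  stop_if(within_block_mass < 0 || within_block_mass > 1,
          "within_block_mass must lie in [0, 1]")
  stop_if(behavior_coupling < 0 || behavior_coupling > 1,
          "behavior_coupling must lie in [0, 1]")
  stop_if(noise_sd < 0, "noise_sd must be non-negative")
  stop_if(tr <= 0, "tr must be positive")
  if (is.null(transition_blocks)) {
    transition_blocks <- if (n_states == 12) list(1:2, 3:11, 12L)
                         else list(seq_len(n_states))
  }
  members <- sort(unlist(transition_blocks))
  stop_if(!identical(as.integer(members), seq_len(as.integer(n_states))),
          "transition_blocks must partition 1:n_states exactly once")
  structure(list(
    n_subjects = as.integer(n_subjects),
    sessions_per_subject = as.integer(sessions_per_subject),
    runs_per_session = as.integer(runs_per_session),
    timepoints_per_run = as.integer(timepoints_per_run),
    tr = tr,
    n_nodes = as.integer(n_nodes),
    n_states = as.integer(n_states),
    transition_blocks = lapply(transition_blocks, as.integer),
    within_block_mass = within_block_mass,
    state_mean_scale = state_mean_scale,
    behavior_coupling = behavior_coupling,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d subjects, sessions per subject: %s\n", x$n_subjects,
              paste(rle(x$sessions_per_subject)$values, "x",
                    rle(x$sessions_per_subject)$lengths, collapse = ", ")))
  cat(sprintf("  %d run(s)/session x %d volumes at TR = %g s; %d nodes\n",
              x$runs_per_session, x$timepoints_per_run, x$tr, x$n_nodes))
  cat(sprintf("  %d states, blocks {%s}, within-block mass %.2f\n",
              x$n_states,
              paste(vapply(x$transition_blocks, length, 1L), collapse = "/"),
              x$within_block_mass))
  cat(sprintf("  mean scale %g, noise sd %g, behavior coupling %.2f, seed %d\n",
              x$state_mean_scale, x$noise_sd, x$behavior_coupling, x$seed))
  invisible(x)
}

#' One run of node-by-time signals
#'
#' @param data Numeric matrix, timepoints x nodes.
#' @param subject,session,run Identifiers.
#' @param tr Repetition time in seconds.
#' @return An object of class `node_timeseries`.
#' @export
node_timeseries <- function(data, subject, session, run, tr) {
  data <- as.matrix(data)
  stop_if(nrow(data) < 2, "a run needs at least 2 timepoints")
  structure(list(data = data, subject = as.character(subject),
                 session = as.integer(session), run = as.integer(run),
                 tr = tr),
            class = "node_timeseries")
}

#' @export
print.node_timeseries <- function(x, ...) {
  cat(sprintf("node_timeseries: subject %s session %d run %d, %d x %d, TR %g s\n",
              x$subject, x$session, x$run, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

# Block-structured row-stochastic transition matrix: each state keeps
# `within_block_mass` spread uniformly over its own block and distributes the
# remainder uniformly over the other states.
build_transition_matrix <- function(config) {
  K <- config$n_states
  w <- config$within_block_mass
  Theta <- matrix(0, K, K)
  for (blk in config$transition_blocks) {
    m <- length(blk)
    if (m == K) {
      Theta[blk, blk] <- 1 / m
    } else {
      Theta[blk, blk] <- w / m
      Theta[blk, -blk] <- (1 - w) / (K - m)
    }
  }
  Theta
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' a probability vector.
#'
#' @param Theta Row-stochastic square matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(Theta) {
  stop_if(nrow(Theta) != ncol(Theta), "Theta must be square")
  stop_if(max(abs(rowSums(Theta) - 1)) > 1e-8, "Theta rows must sum to 1")
  e <- eigen(t(Theta))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# State mean patterns on an orthogonal grid: K mutually orthogonal
# directions of norm sqrt(d), scaled by state_mean_scale, so every pair of
# states is separated by state_mean_scale * sqrt(2 d).
state_mean_grid <- function(K, d, scale) {
  if (K <= d) {
    Q <- qr.Q(qr(matrix(stats::rnorm(d * K), d, K)))
    mu <- t(Q) * sqrt(d)
  } else {
    mu <- matrix(stats::rnorm(K * d), K, d)
    mu <- mu / sqrt(rowSums(mu^2)) * sqrt(d)
  }
  mu * scale
}

block_label <- function(subject, session) sprintf("%s.%d", subject, session)

subject_ids <- function(config) sprintf("S%02d", seq_len(config$n_subjects))

#' Generate multi-subject HMM-driven node time series
#'
#' Simulates, for every subject-session, a first-order Markov chain over
#' `n_states` hidden states (one chain per session, spanning the session's
#' concatenated runs) and draws observations from the active state's
#' multivariate Gaussian: mean `mu_k` on an orthogonal grid scaled by
#' `state_mean_scale`, shared spherical covariance `noise_sd^2 I`.
#'
#' @param config A [synth_config()].
#' @return A list with components:
#'   \describe{
#'     \item{timeseries}{List of [node_timeseries()] objects, one per run.}
#'     \item{truth}{A `ground_truth` object: `state_paths` (one integer
#'       sequence per subject-session), `true_model` (the generating
#'       [hmm_model()]), `true_FO` (subject-sessions x K empirical
#'       fractional occupancies of the true paths), `planted_weights`
#'       (weights of the planted canonical mode on the FO features), and
#'       `block_ids` (subject/session per row of `true_FO`).}
#'   }
#' @export
generate_hmm_timeseries <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  stop_if(config$noise_sd <= 0,
          "noise_sd must be positive: a zero observation covariance is degenerate")
  with_seed(config$seed, {
    K <- config$n_states
    d <- config$n_nodes
    Theta <- build_transition_matrix(config)
    pi0 <- stationary_distribution(Theta)
    mu <- state_mean_grid(K, d, config$state_mean_scale)
    Sigma <- lapply(seq_len(K), function(k) diag(config$noise_sd^2, d))
    model <- hmm_model(means = mu, covariances = Sigma,
                       transition = Theta, initial = pi0)
    subs <- subject_ids(config)
    L <- config$runs_per_session * config$timepoints_per_run
    ts_list <- list()
    paths <- list()
    ids <- list()
    for (s in seq_len(config$n_subjects)) {
      for (e in seq_len(config$sessions_per_subject[s])) {
        path <- integer(L)
        path[1] <- sample.int(K, 1L, prob = pi0)
        for (t in 2:L) path[t] <- sample.int(K, 1L, prob = Theta[path[t - 1L], ])
        obs <- mu[path, , drop = FALSE] +
          config$noise_sd * matrix(stats::rnorm(L * d), L, d)
        lab <- block_label(subs[s], e)
        paths[[lab]] <- path
        ids[[lab]] <- data.frame(subject = subs[s], session = e)
        for (r in seq_len(config$runs_per_session)) {
          rows <- (r - 1L) * config$timepoints_per_run +
            seq_len(config$timepoints_per_run)
          ts_list[[length(ts_list) + 1L]] <-
            node_timeseries(obs[rows, , drop = FALSE], subs[s], e, r, config$tr)
        }
      }
    }
    true_FO <- do.call(rbind, lapply(paths, function(p) {
      tabulate(p, K) / length(p)
    }))
    colnames(true_FO) <- paste0("state", seq_len(K))
    w_x <- stats::rnorm(K)
    truth <- structure(list(
      state_paths = paths,
      true_model = model,
      true_FO = true_FO,
      planted_weights = list(x = w_x, y = NULL),
      block_ids = do.call(rbind, ids)
    ), class = "ground_truth")
    list(timeseries = ts_list, truth = truth)
  })
}

# 31-measure behavioral battery: task, measure name, generating factor and
# loading sign, plus plausible reporting units (centre/scale) for realism.
behavior_catalogue <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  rbind(
    df(name = c("dsst_rt_median_match", "dsst_rt_median_nonmatch",
                "dsst_rt_sd_match", "dsst_rt_sd_nonmatch",
                "box_completion_time"),
       factor = 1L, sign = 1, centre = c(900, 950, 250, 260, 120),
       scale = c(150, 150, 60, 60, 20)),
    df(name = c("swm_acc_match", "swm_acc_nonmatch",
                "stroop_acc_incongruent", "stroop_rt_diff_median",
                "stroop_rt_diff_sd"),
       factor = 2L, sign = c(1, 1, 1, -1, -1),
       centre = c(85, 84, 92, 90, 70), scale = c(8, 8, 6, 35, 25)),
    df(name = c("swm_rt_median_match", "swm_rt_median_nonmatch",
                "swm_rt_sd_match", "swm_rt_sd_nonmatch"),
       factor = 3L, sign = 1, centre = c(820, 860, 220, 230),
       scale = c(140, 140, 55, 55)),
    df(name = c("cwm_rt_median", "cwm_rt_sd",
                "cwm_error_median", "cwm_error_sd"),
       factor = 4L, sign = 1, centre = c(1400, 420, 18, 14),
       scale = c(250, 90, 6, 5)),
    df(name = c("vas_sad", "vas_happy", "vas_anxious"),
       factor = 5L, sign = c(1, -1, 1), centre = c(1.5, 6.5, 2.2),
       scale = c(1.2, 1.6, 1.5)),
    df(name = c("dsst_acc_match", "dsst_acc_nonmatch"),
       factor = 6L, sign = 1, centre = c(94, 93), scale = c(4, 4)),
    df(name = c("vas_drowsy", "vas_jittery", "vas_fatigued",
                "vas_nauseous", "vas_dizzy"),
       factor = 7L, sign = 1, centre = c(3.5, 2.0, 3.8, 0.8, 0.9),
       scale = c(1.8, 1.4, 1.9, 0.8, 0.9)),
    df(name = c("bis_attentional", "bis_motor", "bis_nonplanning"),
       factor = 8L, sign = 1, centre = c(16, 21, 23), scale = c(3.5, 4, 4.5))
  )
}

#' Generate a behavioral battery coupled to state occupancies
#'
#' Draws, per subject-session, 8 latent behavioral factors and 31 observed
#' measures loading 0.8 (in standardized units) on their assigned factor.
#' The first factor's score is `behavior_coupling * z + sqrt(1 - coupling^2)
#' * noise`, where `z` is the standardized planted linear combination of the
#' true fractional occupancies, so the population correlation between the
#' planted brain and behavior combinations equals `behavior_coupling`.
#'
#' @param truth `ground_truth` from [generate_hmm_timeseries()].
#' @param config The [synth_config()] used to generate `truth`.
#' @param measure_noise Scale applied to each measure's uniqueness noise
#'   (1 = unit-variance measures in standardized units; 0 = noise-free
#'   rank-8 measures).
#' @return A data.frame with `subject`, `session` and 31 measure columns.
#'   Attribute `"planted"` records the ground-truth scores defining the
#'   planted canonical mode: `brain_score` (standardized FO combination),
#'   `behavior_score` (the coupled factor's score), the full latent factor
#'   matrix and the 31 x 8 loading matrix.
#' @export
generate_behavior <- function(truth, config, measure_noise = config$noise_sd) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "synth_config"))
  rho <- config$behavior_coupling
  stop_if(rho < 0 || rho > 1, "behavior_coupling must lie in [0, 1]")
  stop_if(measure_noise < 0, "measure_noise must be non-negative")
  with_seed(config$seed + 1L, {
    FO <- truth$true_FO
    n <- nrow(FO)
    raw <- as.vector(FO %*% truth$planted_weights$x)
    if (stats::sd(raw) == 0) {
      stop_if(rho > 0,
              "true FO combination is constant; cannot plant a coupled mode")
      brain <- rep(0, n)
    } else {
      brain <- as.vector(scale(raw))
    }
    f1 <- rho * brain + sqrt(1 - rho^2) * stats::rnorm(n)
    Fmat <- cbind(f1, matrix(stats::rnorm(n * 7), n, 7))
    colnames(Fmat) <- paste0("factor", 1:8)
    cat31 <- behavior_catalogue()
    Lambda <- matrix(0, nrow(cat31), 8)
    Lambda[cbind(seq_len(nrow(cat31)), cat31$factor)] <- 0.8 * cat31$sign
    uniq_sd <- sqrt(pmax(0, 1 - rowSums(Lambda^2)))
    Z <- Fmat %*% t(Lambda) +
      measure_noise * sweep(matrix(stats::rnorm(n * nrow(cat31)), n),
                            2, uniq_sd, `*`)
    M <- sweep(sweep(Z, 2, cat31$scale, `*`), 2, cat31$centre, `+`)
    colnames(M) <- cat31$name
    out <- cbind(truth$block_ids, as.data.frame(M))
    rownames(out) <- rownames(FO)
    attr(out, "planted") <- list(brain_score = brain, behavior_score = f1,
                                 factors = Fmat, loadings = Lambda,
                                 measure_names = cat31$name)
    out
  })
}

#' Generate head-motion parameter traces
#'
#' Six smooth random-walk parameters (3 translations in mm, 3 rotations in
#' radians) per run, with occasional single-frame spikes.
#'
#' @param config A [synth_config()].
#' @param translation_step,rotation_step Random-walk innovation SDs
#'   (mm / radians per frame).
#' @param spike_prob Per-frame probability of a one-frame motion spike.
#' @param spike_translation,spike_rotation Spike amplitudes (mm / radians).
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return A list of timepoints x 6 matrices (columns `trans_x..rot_z`),
#'   one per run, with `subject`/`session`/`run` attributes, in the same
#'   order as the runs from [generate_hmm_timeseries()].
#' @export
generate_motion <- function(config, translation_step = 0.03,
                            rotation_step = 6e-4, spike_prob = 0.01,
                            spike_translation = 0.5, spike_rotation = 0.005,
                            seed = config$seed + 2L) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    subs <- subject_ids(config)
    Tn <- config$timepoints_per_run
    out <- list()
    for (s in seq_len(config$n_subjects)) {
      for (e in seq_len(config$sessions_per_subject[s])) {
        for (r in seq_len(config$runs_per_session)) {
          m <- cbind(
            matrix(stats::rnorm(Tn * 3, 0, translation_step), Tn, 3),
            matrix(stats::rnorm(Tn * 3, 0, rotation_step), Tn, 3)
          )
          m <- apply(m, 2, cumsum)
          if (spike_prob > 0 && Tn > 2) {
            spikes <- which(stats::runif(Tn) < spike_prob)
            spikes <- spikes[spikes > 1 & spikes < Tn]
            for (t in spikes) {
              m[t, 1:3] <- m[t, 1:3] +
                spike_translation * stats::rnorm(3) / sqrt(3)
              m[t, 4:6] <- m[t, 4:6] +
                spike_rotation * stats::rnorm(3) / sqrt(3)
            }
          }
          colnames(m) <- c("trans_x", "trans_y", "trans_z",
                           "rot_x", "rot_y", "rot_z")
          attr(m, "subject") <- subs[s]
          attr(m, "session") <- e
          attr(m, "run") <- r
          out[[length(out) + 1L]] <- m
        }
      }
    }
    out
  })
}

#' Phase-randomized surrogate of a node time series
#'
#' Replaces each node's Fourier phases with independent uniform draws while
#' preserving the amplitude spectrum exactly (conjugate-symmetric, so the
#' surrogate is real). The zero-frequency component is untouched, so the
#' mean of every node is preserved; at even lengths the Nyquist component
#' keeps its magnitude up to a random sign. Phases are drawn independently
#' per node, so cross-node phase relations (and hence cross-correlations)
#' are destroyed while each node's autocorrelation is preserved.
#'
#' @param ts A [node_timeseries()] or plain timepoints x nodes matrix.
#' @param seed Optional seed.
#' @return Same type as `ts`.
#' @export
phase_randomize <- function(ts, seed = NULL) {
  x <- if (inherits(ts, "node_timeseries")) ts$data else as.matrix(ts)
  check_finite(x, "time series")
  with_seed(seed, {
    n <- nrow(x)
    m <- floor((n - 1) / 2)             # strictly positive, non-Nyquist freqs
    out <- apply(x, 2, function(col) {
      X <- stats::fft(col)
      if (m > 0) {
        phi <- stats::runif(m, 0, 2 * pi)
        idx <- 1L + seq_len(m)
        X[idx] <- Mod(X[idx]) * exp(1i * phi)
        X[n + 2L - idx] <- Conj(X[idx])
      }
      if (n %% 2 == 0)
        X[n / 2 + 1L] <- X[n / 2 + 1L] * sample(c(-1, 1), 1L)
      Re(stats::fft(X, inverse = TRUE)) / n
    })
    if (inherits(ts, "node_timeseries")) {
      node_timeseries(out, ts$subject, ts$session, ts$run, ts$tr)
    } else out
  })
}
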