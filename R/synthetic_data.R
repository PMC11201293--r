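#' Simulation configuration for a synthetic two-group resting-state cohort
#'
#' Builds and validates the parameter set the cohort generator works from.
#' The defaults emulate a case-control resting-state study: two groups,
#' 240 volumes at TR = 2 s, 90 parcels, six recurring brain states, a higher
#' state switching rate in patients (0.08 vs 0.06 transitions per step),
#' patient fractional-occupancy shifts (state 1 up, states 3 and 6 down), and
#' reduced signal amplitude plus extra noise in a set of affected parcels.
#'
#' @param n_patients,n_controls subjects per group.
#' @param n_parcels number of parcels (nodes).
#' @param n_volumes time points acquired per subject (before any dropping).
#' @param tr_seconds repetition time in seconds.
#' @param n_states number of recurring states.
#' @param patient_switch_rate,control_switch_rate expected fraction of
#'   consecutive time-point pairs at which the state changes, per group.
#' @param fo_patient,fo_control stationary fractional-occupancy targets
#'   (length `n_states`, each summing to 1). Defaults: controls uniform;
#'   patients shifted by `fo_shift`.
#' @param fo_shift additive patient occupancy shift applied to the uniform
#'   profile when `fo_patient` is not given; default raises state 1 by 0.06
#'   and lowers states 3 and 6 by 0.03 each (zero elsewhere).
#' @param affected_parcels integer parcel ids carrying the planted static
#'   deficit in patients; default: the first fifth of parcels.
#' @param effect_amplitude multiplicative signal-amplitude factor (< 1 is a
#'   deficit) for affected parcels in patients.
#' @param effect_extra_noise_sd extra independent noise SD added to affected
#'   parcels in patients (lowers local coherence as well as amplitude).
#' @param state_mean_scale amplitude of the state-specific spatial patterns.
#' @param noise_sd observation noise SD; split between white and band-limited
#'   (0.01-0.1 Hz) components so the series carry low-frequency content.
#' @param sr_jitter_sd optional between-subject SD of a logit-scale jitter on
#'   the switch rate (0 = all subjects share the group rate).
#' @param voxel_grid integer length-3 lattice dims for volume rendering, or
#'   `NULL` to pick the smallest cube hosting 27 voxels per parcel.
#' @param voxel_noise_sd independent voxel-level noise SD used when rendering
#'   volumes.
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 110L, n_controls = 106L,
                       n_parcels = 90L, n_volumes = 240L, tr_seconds = 2,
                       n_states = 6L,
                       patient_switch_rate = 0.08, control_switch_rate = 0.06,
                       fo_patient = NULL, fo_control = NULL, fo_shift = NULL,
                       affected_parcels = NULL, effect_amplitude = 0.6,
                       effect_extra_noise_sd = 0.8,
                       state_mean_scale = 1, noise_sd = 1, sr_jitter_sd = 0,
                       voxel_grid = NULL, voxel_noise_sd = 0.5,
                       seed = 1L) {
  stopifnot(n_patients >= 0, n_controls >= 0, n_parcels >= 1,
            n_volumes >= 2, tr_seconds > 0, n_states >= 1,
            effect_amplitude >= 0, effect_extra_noise_sd >= 0,
            noise_sd >= 0, sr_jitter_sd >= 0, voxel_noise_sd >= 0)
  for (r in c(patient_switch_rate, control_switch_rate))
    if (r < 0 || r > 1) stop("switch rates must lie in [0, 1]")
  if (is.null(fo_control)) fo_control <- rep(1 / n_states, n_states)
  if (is.null(fo_patient)) {
    if (is.null(fo_shift)) {
      fo_shift <- numeric(n_states)
      if (n_states >= 3) {
        fo_shift[1] <- 0.06
        down <- intersect(c(3L, n_states), seq_len(n_states))
        fo_shift[down] <- -0.06 / length(down)
      }
    }
    fo_patient <- rep(1 / n_states, n_states) + fo_shift
  }
  for (fo in list(fo_patient, fo_control)) {
    if (length(fo) != n_states) stop("occupancy vector length must equal n_states")
    if (any(fo < 0)) stop("occupancy targets must be non-negative")
    if (abs(sum(fo) - 1) > 1e-8) stop("occupancy targets must sum to 1")
  }
  if (is.null(affected_parcels)) {
    affected_parcels <- seq_len(max(1L, round(n_parcels / 5)))
  }
  affected_parcels <- as.integer(affected_parcels)
  if (length(affected_parcels) &&
      (min(affected_parcels) < 1 || max(affected_parcels) > n_parcels))
    stop("affected_parcels must be parcel ids in 1..n_parcels")
  if (!is.null(voxel_grid)) {
    voxel_grid <- as.integer(voxel_grid)
    stopifnot(length(voxel_grid) == 3, all(voxel_grid >= 1))
  }
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_parcels = as.integer(n_parcels), n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds, n_states = as.integer(n_states),
    patient_switch_rate = patient_switch_rate,
    control_switch_rate = control_switch_rate,
    fo_patient = fo_patient, fo_control = fo_control,
    affected_parcels = affected_parcels,
    effect_amplitude = effect_amplitude,
    effect_extra_noise_sd = effect_extra_noise_sd,
    state_mean_scale = state_mean_scale, noise_sd = noise_sd,
    sr_jitter_sd = sr_jitter_sd,
    voxel_grid = voxel_grid, voxel_noise_sd = voxel_noise_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' Transition matrix with a prescribed stationary distribution and switch rate
#'
#' Off-diagonal mass proportional to the target stationary distribution,
#' uniformly scaled to hit the target expected switch rate:
#' `A[i, j] = alpha * pi[j]` for `j != i` and
#' `A[i, i] = 1 - alpha * (1 - pi[i])`. Then `pi` is stationary for any
#' `alpha`, and the stationary switch rate is
#' `sum_i pi[i] * (1 - A[i, i]) = alpha * (1 - sum(pi^2))`, so
#' `alpha = rate / (1 - sum(pi^2))`.
#'
#' @param fo stationary occupancy target (sums to 1).
#' @param rate target expected switch rate in \[0, 1\].
#' @return a stochastic matrix.
#' @export
switching_transition_matrix <- function(fo, rate) {
  K <- length(fo)
  if (K == 1) {
    if (rate > 0) stop("a single state cannot switch: rate must be 0")
    return(matrix(1, 1, 1))
  }
  denom <- 1 - sum(fo^2)
  if (denom <= 0) stop("degenerate occupancy target: no switching possible")
  if (rate == 0 && any(fo > 0 & fo < 1)) {
    # constant-state chains: start states drawn from fo still realize it
    return(diag(K))
  }
  alpha <- rate / denom
  A <- alpha * matrix(fo, K, K, byrow = TRUE)
  diag(A) <- 1 - alpha * (1 - fo)
  if (any(diag(A) < -1e-12))
    stop(sprintf(
      "infeasible switch rate %.3g for this occupancy profile (max feasible %.3g)",
      rate, denom / max(1 - fo)))
  diag(A) <- pmax(diag(A), 0)
  A / rowSums(A)
}

#' Sample per-subject hidden-state paths for one group
#'
#' Markov-chain sequences whose expected transition frequency equals the
#' group's switch rate and whose stationary occupancy matches the group's
#' fractional-occupancy profile (see [switching_transition_matrix()]).
#'
#' @param cfg a [sim_config()].
#' @param group `"patient"` or `"control"`.
#' @param n_subjects,n_time overrides for subject count and path length
#'   (default: from `cfg`, path length `n_volumes`).
#' @return integer matrix, subjects x time, states in `1..n_states`.
#' @export
generate_state_paths <- function(cfg, group = c("patient", "control"),
                                 n_subjects = NULL, n_time = NULL) {
  group <- match.arg(group)
  fo <- if (group == "patient") cfg$fo_patient else cfg$fo_control
  rate <- if (group == "patient") cfg$patient_switch_rate else cfg$control_switch_rate
  if (is.null(n_subjects))
    n_subjects <- if (group == "patient") cfg$n_patients else cfg$n_controls
  if (is.null(n_time)) n_time <- cfg$n_volumes
  K <- cfg$n_states
  paths <- matrix(1L, n_subjects, n_time)
  if (n_subjects == 0) return(paths)
  for (s in seq_len(n_subjects)) {
    r <- rate
    if (cfg$sr_jitter_sd > 0 && rate > 0 && rate < 1) {
      lo <- stats::qlogis(rate) + stats::rnorm(1, 0, cfg$sr_jitter_sd)
      r <- stats::plogis(lo)
    }
    A <- switching_transition_matrix(fo, r)
    paths[s, 1] <- sample.int(K, 1, prob = fo)
    if (n_time > 1) {
      for (t in 2:n_time)
        paths[s, t] <- sample.int(K, 1, prob = A[paths[s, t - 1], ])
    }
  }
  paths
}

#' State-specific spatial mean patterns
#'
#' Distinct +/- amplitude patterns per state, drawn once per cohort so every
#' subject shares the same state geometry.
#' @param cfg a [sim_config()].
#' @return `n_states` x `n_parcels` matrix.
#' @export
state_mean_patterns <- function(cfg) {
  K <- cfg$n_states
  N <- cfg$n_parcels
  m <- matrix(sample(c(-1, 1), K * N, replace = TRUE), K, N) *
    cfg$state_mean_scale
  # guarantee distinct rows even at tiny N
  if (K > 1) for (k in 2:K) {
    while (any(apply(m[seq_len(k - 1), , drop = FALSE], 1,
                     function(r) all(r == m[k, ])))) {
      m[k, ] <- sample(c(-1, 1), N, replace = TRUE) * cfg$state_mean_scale
    }
  }
  m
}

#' Band-limited noise matrix
#'
#' White Gaussian noise restricted to the 0.01-0.1 Hz band by an ideal FFT
#' filter and rescaled to unit column SD, so generated series carry realistic
#' low-frequency content.
#' @keywords internal
bandlimited_noise <- function(n_time, n_cols, tr_seconds,
                              low = 0.01, high = 0.1) {
  x <- matrix(stats::rnorm(n_time * n_cols), n_time, n_cols)
  nyq <- 1 / (2 * tr_seconds)
  hi <- min(high, nyq)
  if (low >= hi || n_time < 8) return(x)  # band unresolvable: leave white
  y <- bandpass(structure(list(data = x, tr_seconds = tr_seconds),
                          class = "ts_matrix"),
                low_hz = low, high_hz = hi)$data
  sds <- apply(y, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(y, 2, sds, "/")
}

#' Render parcel time series from state paths
#'
#' Emission model: the subject's state-specific mean pattern at each time
#' point, plus noise split evenly (in variance) between white and band-limited
#' (0.01-0.1 Hz) components. In patients, affected parcels have their signal
#' scaled by `effect_amplitude` and receive `effect_extra_noise_sd` extra
#' independent noise.
#'
#' @param paths subjects x time integer state matrix.
#' @param cfg a [sim_config()].
#' @param group group label for the planted effects.
#' @param means optional precomputed state mean patterns (from
#'   [state_mean_patterns()]); drawn fresh otherwise.
#' @return list of `n_parcels` x ... no: list of time x parcels matrices, one
#'   per subject.
#' @export
render_node_series <- function(paths, cfg, group = c("patient", "control"),
                               means = NULL) {
  group <- match.arg(group)
  if (is.null(means)) means <- state_mean_patterns(cfg)
  N <- cfg$n_parcels
  Tn <- ncol(paths)
  amp <- rep(1, N)
  extra <- rep(0, N)
  if (group == "patient" && length(cfg$affected_parcels)) {
    amp[cfg$affected_parcels] <- cfg$effect_amplitude
    extra[cfg$affected_parcels] <- cfg$effect_extra_noise_sd
  }
  lapply(seq_len(nrow(paths)), function(s) {
    sig <- means[paths[s, ], , drop = FALSE]  # time x parcels
    if (cfg$noise_sd > 0) {
      w <- matrix(stats::rnorm(Tn * N), Tn, N)
      b <- bandlimited_noise(Tn, N, cfg$tr_seconds)
      noise <- cfg$noise_sd * sqrt(0.5) * (w + b)
    } else noise <- 0
    x <- sweep(sig, 2, amp, "*") + noise
    if (any(extra > 0))
      x <- x + sweep(matrix(stats::rnorm(Tn * N), Tn, N), 2, extra, "*")
    dimnames(x) <- list(NULL, sprintf("parcel%03d", seq_len(N)))
    x
  })
}

#' Default voxel lattice for a parcel count
#'
#' Smallest cube holding 27 voxels for every parcel.
#' @keywords internal
default_voxel_grid <- function(n_parcels) {
  side <- ceiling((27 * n_parcels)^(1 / 3))
  rep(as.integer(side), 3)
}

#' Build a contiguous parcellation atlas on a voxel lattice
#'
#' Voxels in lexicographic order are chunked into `n_parcels` runs of at least
#' 27 voxels; leftover voxels stay background (label 0).
#'
#' @param grid integer length-3 dims.
#' @param n_parcels parcel count.
#' @return 3D integer array with labels `0..n_parcels`.
#' @export
make_atlas <- function(grid, n_parcels) {
  V <- prod(grid)
  need <- 27L * n_parcels
  if (V < need)
    stop(sprintf(
      "voxel grid %s too small for %d parcels of >=27 voxels: need >= %d voxels (e.g. %s)",
      paste(grid, collapse = "x"), n_parcels, need,
      paste(default_voxel_grid(n_parcels), collapse = "x")))
  per <- V %/% n_parcels
  labels <- integer(V)
  for (p in seq_len(n_parcels))
    labels[((p - 1) * per + 1):(p * per)] <- p
  array(labels, dim = grid)
}

#' Render 4D voxel volumes from parcel time series
#'
#' Every voxel of an atlas region carries the region's time course plus
#' independent voxel noise.
#'
#' @param node_series list of time x parcels matrices.
#' @param cfg a [sim_config()].
#' @return list with `volumes` (list of 4D arrays x,y,z,t) and `atlas`
#'   (3D label array).
#' @export
render_volumes <- function(node_series, cfg) {
  grid <- if (is.null(cfg$voxel_grid)) default_voxel_grid(cfg$n_parcels) else cfg$voxel_grid
  atlas <- make_atlas(grid, cfg$n_parcels)
  lab <- as.vector(atlas)
  inmask <- which(lab > 0)
  volumes <- lapply(node_series, function(x) {
    Tn <- nrow(x)
    vol <- array(0, dim = c(grid, Tn))
    flat <- matrix(0, prod(grid), Tn)
    flat[inmask, ] <- t(x[, lab[inmask], drop = FALSE])
    if (cfg$voxel_noise_sd > 0)
      flat[inmask, ] <- flat[inmask, ] +
        matrix(stats::rnorm(length(inmask) * Tn, 0, cfg$voxel_noise_sd),
               length(inmask), Tn)
    vol[] <- flat
    vol
  })
  list(volumes = volumes, atlas = atlas)
}

#' Generate a full synthetic cohort
#'
#' Samples state paths per group, renders parcel time series (and optionally
#' voxel volumes), and records the ground truth (paths, per-subject switching
#' rate and fractional occupancies, planted effect map).
#'
#' @param cfg a [sim_config()].
#' @param volumes render 4D voxel volumes as well (needed for voxel-mode
#'   regional homogeneity).
#' @return a `synthetic_cohort` list: `manifest` (data.frame subject/group),
#'   `node_series` (named list of time x parcels matrices), optionally
#'   `volumes` + `atlas`, `truth` (paths, sr, fo, affected parcels, state
#'   means), and `cfg`.
#' @export
simulate_cohort <- function(cfg, volumes = FALSE) {
  set.seed(cfg$seed)
  means <- state_mean_patterns(cfg)
  groups <- c(rep("patient", cfg$n_patients), rep("control", cfg$n_controls))
  ids <- sprintf("sub%03d", seq_along(groups))
  pat_paths <- generate_state_paths(cfg, "patient")
  con_paths <- generate_state_paths(cfg, "control")
  paths <- rbind(pat_paths, con_paths)
  rownames(paths) <- ids
  series <- c(render_node_series(pat_paths, cfg, "patient", means),
              render_node_series(con_paths, cfg, "control", means))
  names(series) <- ids
  sr <- apply(paths, 1, function(p) mean(p[-1] != p[-length(p)]))
  fo <- t(apply(paths, 1, function(p)
    tabulate(p, nbins = cfg$n_states) / length(p)))
  colnames(fo) <- sprintf("state%d", seq_len(cfg$n_states))
  out <- list(
    manifest = data.frame(subject = ids, group = groups,
                          stringsAsFactors = FALSE),
    node_series = series,
    truth = list(paths = paths, sr = sr, fo = fo,
                 affected_parcels = cfg$affected_parcels,
                 state_means = means),
    cfg = cfg)
  if (volumes) {
    vol <- render_volumes(series, cfg)
    names(vol$volumes) <- ids
    out$volumes <- vol$volumes
    out$atlas <- vol$atlas
  }
  class(out) <- "synthetic_cohort"
  out
}

#' Write a synthetic cohort to disk
#'
#' Node series as TSV (rows = time, cols = parcels), manifest and truth as
#' JSON, volumes and atlas as NIfTI when present.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$node_series)) {
    utils::write.table(cohort$node_series[[id]],
                       file.path(dir, paste0(id, "_series.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows")
  truth <- cohort$truth
  truth$paths <- apply(truth$paths, 1, paste, collapse = ",")
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  if (!is.null(cohort$volumes)) {
    RNifti::writeNifti(RNifti::asNifti(cohort$atlas * 1),
                       file.path(dir, "atlas.nii.gz"))
    for (id in names(cohort$volumes))
      RNifti::writeNifti(RNifti::asNifti(cohort$volumes[[id]]),
                         file.path(dir, paste0(id, "_bold.nii.gz")))
  }
  invisible(dir)
}
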