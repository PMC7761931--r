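#' Synthetic cohorts with known phase-coupling structure
#'
#' The generator emulates resting-state source-level EEG at the pipeline's
#' working scale: two-second epochs at 1000 Hz, ~30 epochs per subject,
#' band-limited oscillations with controllable pairwise phase coupling,
#' occasional high-amplitude artifacts, and PANSS-like ordinal item scores
#' whose severities can differ between two groups.
#'
#' Coupling model: each coupled edge (i, j) in a band contributes a shared
#' carrier cos(2*pi*f0*t + phi(t)) to node i and the same carrier offset by a
#' continuous stationary Gaussian jitter eps(t) with marginal N(0, sigma^2)
#' to node j. The base phase phi(t) is a Brownian track, so distinct edges
#' and uncoupled nodes decorrelate. The expected PLV of a coupled pair is the
#' wrapped-normal resultant exp(-sigma^2 / 2), which the tests use as a
#' closed-form oracle.
#'
#' @name synthetic_cohort
NULL

#' Coupling specification for one band
#'
#' @param band band name from [band_table()].
#' @param edges matrix or data.frame with columns `i`, `j`, `sigma`
#'   (node indices and phase-jitter SD in radians).
#' @param f0 carrier frequency in Hz; must lie inside the named band; defaults
#'   to the band midpoint.
#' @return a `coupling_spec` list.
#' @export
coupling_spec <- function(band, edges, f0 = NULL) {
  b <- band_lookup(band)
  if (is.null(f0)) f0 <- (b$low + b$high) / 2
  if (f0 <= b$low || f0 >= b$high) {
    stop(sprintf("f0 = %g Hz not inside band '%s' (%g-%g Hz)",
                 f0, b$name, b$low, b$high))
  }
  edges <- as.data.frame(edges)
  names(edges) <- c("i", "j", "sigma")[seq_along(edges)]
  if (any(edges$i == edges$j)) stop("self-coupling (i == j) not allowed")
  if (any(edges$sigma < 0)) stop("jitter sigma must be >= 0")
  structure(list(band = b$name, low = b$low, high = b$high, f0 = f0,
                 edges = edges), class = "coupling_spec")
}

# Stationary unit-variance Gaussian process: white noise circularly convolved
# with a Gaussian kernel of SD tau_samples, kernel normalised to unit L2 norm
# so the marginal stays exactly N(0, 1). Correlation time ~ tau.
smooth_gauss <- function(n, tau_samples) {
  w <- stats::rnorm(n)
  if (tau_samples < 0.5) return(w)
  L <- min(as.integer(ceiling(5 * tau_samples)), n %/% 2 - 1L)
  if (L < 1L) return(w)
  k <- stats::dnorm(seq(-L, L) / tau_samples)
  k <- k / sqrt(sum(k^2))
  kpad <- numeric(n)
  kpad[1L:(L + 1L)] <- k[(L + 1L):(2L * L + 1L)]
  kpad[(n - L + 1L):n] <- k[1L:L]
  Re(stats::fft(stats::fft(w) * stats::fft(kpad), inverse = TRUE)) / n
}

# Brownian (Wiener) phase track with diffusion D (rad^2/s): the classic
# finite-linewidth oscillator; distinct tracks decorrelate within ~1/D s.
brownian_phase <- function(n, fs, diffusion) {
  stats::runif(1, -pi, pi) + cumsum(stats::rnorm(n, 0, sqrt(diffusion / fs)))
}

#' Generate one phase-coupled signal pair
#'
#' Returns two cosine carriers at `f0` sharing a Brownian base phase; the
#' second carrier is offset by a continuous stationary Gaussian jitter
#' process with marginal SD `jitter_sigma` (radians) and correlation time
#' `jitter_tau`. Because the jitter marginal is exactly N(0, sigma^2), the
#' expected phase-locking value is the wrapped-normal resultant
#' exp(-jitter_sigma^2 / 2), independent of the base-phase dynamics.
#'
#' @param fs sampling rate (Hz); must exceed `2 * f0`.
#' @param duration signal length in seconds.
#' @param f0 carrier frequency (Hz).
#' @param jitter_sigma phase-jitter SD in radians (>= 0).
#' @param seed integer seed.
#' @param jitter_tau jitter correlation time in seconds (default 0.1).
#' @param base_diffusion base-phase diffusion in rad^2/s (default 10); sets
#'   how fast uncoupled carriers decorrelate.
#' @return list with `x`, `y` (numeric vectors) and `t` (seconds).
#' @export
generate_phase_coupled_pair <- function(fs, duration, f0, jitter_sigma,
                                        seed = NULL, jitter_tau = 0.1,
                                        base_diffusion = 10) {
  if (duration <= 0) stop("duration must be positive")
  if (f0 >= fs / 2) stop("f0 must be below the Nyquist frequency fs/2")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  n <- as.integer(round(fs * duration))
  with_seed(seed, {
    phi <- brownian_phase(n, fs, base_diffusion)
    eps <- jitter_sigma * smooth_gauss(n, fs * jitter_tau)
    tt <- (seq_len(n) - 1L) / fs
    w <- 2 * pi * f0
    list(x = cos(w * tt + phi), y = cos(w * tt + phi + eps), t = tt)
  })
}

#' Cohort configuration
#'
#' Bundles the generator's parameters. Defaults reproduce the pipeline's
#' working conditions: two-second epochs at 1000 Hz, 30 epochs per subject,
#' 148 nodes.
#'
#' @param n_subjects_per_group subjects in each of the two groups.
#' @param n_nodes number of source nodes (default 148).
#' @param fs sampling rate in Hz (default 1000).
#' @param epoch_seconds epoch length in seconds (default 2).
#' @param n_epochs epochs generated per subject (default 30).
#' @param group_coupling list of length 2; each element a list of
#'   [coupling_spec] objects for that group.
#' @param osc_amplitude oscillation amplitude per band component (uV).
#' @param noise_sd additive white-noise SD (uV).
#' @param artifact_rate probability that an epoch receives an injected
#'   high-amplitude artifact.
#' @param artifact_amplitude artifact pulse amplitude (uV); should exceed the
#'   rejection limit to exercise the amplitude rule.
#' @param panss_effects list of length 2: per-group named numeric vectors of
#'   mean shifts on PANSS items (names P1..P7, N1..N7, G1..G16).
#' @param jitter_tau jitter correlation time (s), see
#'   [generate_phase_coupled_pair()].
#' @param base_diffusion base-phase diffusion (rad^2/s).
#' @param seed master seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects_per_group, n_nodes = 148, fs = 1000,
                          epoch_seconds = 2, n_epochs = 30,
                          group_coupling = list(list(), list()),
                          osc_amplitude = 10, noise_sd = 5,
                          artifact_rate = 0, artifact_amplitude = 150,
                          panss_effects = list(numeric(0), numeric(0)),
                          jitter_tau = 0.1, base_diffusion = 10, seed = 1L) {
  stopifnot(n_subjects_per_group >= 1, n_nodes >= 2, fs > 0,
            epoch_seconds > 0, n_epochs >= 1,
            artifact_rate >= 0, artifact_rate <= 1,
            length(group_coupling) == 2L, length(panss_effects) == 2L)
  for (g in 1:2) {
    for (cs in group_coupling[[g]]) {
      stopifnot(inherits(cs, "coupling_spec"))
      if (any(cs$edges$i > n_nodes | cs$edges$j > n_nodes |
              cs$edges$i < 1 | cs$edges$j < 1)) {
        stop("coupling edge node index out of range")
      }
    }
  }
  structure(list(
    n_subjects_per_group = n_subjects_per_group, n_nodes = n_nodes, fs = fs,
    epoch_seconds = epoch_seconds, n_epochs = n_epochs,
    group_coupling = group_coupling, osc_amplitude = osc_amplitude,
    noise_sd = noise_sd, artifact_rate = artifact_rate,
    artifact_amplitude = artifact_amplitude, panss_effects = panss_effects,
    jitter_tau = jitter_tau, base_diffusion = base_diffusion,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# One subject's epochs under a group's coupling specs.
generate_subject_epochs <- function(config, specs, seed) {
  ns <- as.integer(round(config$fs * config$epoch_seconds))
  tau_n <- config$fs * config$jitter_tau
  nn <- config$n_nodes
  ne <- config$n_epochs
  tt <- (seq_len(ns) - 1L) / config$fs
  data <- array(0, dim = c(ne, nn, ns))
  with_seed(seed, {
    for (e in seq_len(ne)) {
      ep <- matrix(stats::rnorm(nn * ns, 0, config$noise_sd), nrow = nn)
      for (cs in specs) {
        w <- 2 * pi * cs$f0
        coupled <- unique(c(cs$edges$i, cs$edges$j))
        for (r in seq_len(nrow(cs$edges))) {
          phi <- brownian_phase(ns, config$fs, config$base_diffusion)
          eps <- cs$edges$sigma[r] * smooth_gauss(ns, tau_n)
          ep[cs$edges$i[r], ] <- ep[cs$edges$i[r], ] +
            config$osc_amplitude * cos(w * tt + phi)
          ep[cs$edges$j[r], ] <- ep[cs$edges$j[r], ] +
            config$osc_amplitude * cos(w * tt + phi + eps)
        }
        # uncoupled nodes get an independent oscillator in the same band so
        # that band-limited signals are never degenerate
        for (u in setdiff(seq_len(nn), coupled)) {
          phi <- brownian_phase(ns, config$fs, config$base_diffusion)
          ep[u, ] <- ep[u, ] + config$osc_amplitude * cos(w * tt + phi)
        }
      }
      if (config$artifact_rate > 0 &&
          stats::runif(1) < config$artifact_rate) {
        node <- sample.int(nn, 1L)
        len <- min(50L, ns)
        start <- sample.int(ns - len + 1L, 1L)
        ep[node, start:(start + len - 1L)] <- config$artifact_amplitude
      }
      data[e, , ] <- ep
    }
  })
  epoch_set(data, fs = config$fs, epoch_seconds = config$epoch_seconds)
}

#' Generate PANSS-like item scores
#'
#' Items are drawn from a normal distribution centred at a baseline of 3
#' (SD 1.5), shifted per item by `effects`, rounded and clipped to the ordinal
#' range 1-7.
#'
#' @param effects named numeric vector of per-item mean shifts; unnamed items
#'   get zero shift.
#' @param seed integer seed.
#' @param baseline baseline item mean (default 3).
#' @param sd item SD before discretisation (default 1.5).
#' @return named integer vector of the 30 PANSS items (P1..P7, N1..N7,
#'   G1..G16), each in 1..7.
#' @export
generate_panss_items <- function(effects = numeric(0), seed = NULL,
                                 baseline = 3, sd = 1.5) {
  items <- panss_item_names()
  shift <- stats::setNames(numeric(length(items)), items)
  if (length(effects)) {
    unknown <- setdiff(names(effects), items)
    if (length(unknown)) stop("unknown PANSS item(s): ",
                              paste(unknown, collapse = ", "))
    shift[names(effects)] <- effects
  }
  with_seed(seed, {
    raw <- stats::rnorm(length(items), baseline + shift, sd)
    stats::setNames(as.integer(pmin(7, pmax(1, round(raw)))), items)
  })
}

#' Generate a two-group synthetic cohort
#'
#' Produces, for every subject, an [epoch_set] realised under the subject's
#' group coupling specification plus a PANSS record. All randomness derives
#' from `config$seed` through documented per-subject substreams, so identical
#' configurations give bit-identical cohorts.
#'
#' @param config a [cohort_config].
#' @return list of subjects; each a list with `id`, `group` (1 or 2),
#'   `epochs` ([epoch_set]) and `panss` (named integer vector).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- list()
  k <- 0L
  for (g in 1:2) {
    for (s in seq_len(config$n_subjects_per_group)) {
      k <- k + 1L
      subjects[[k]] <- list(
        id = sprintf("g%d_s%03d", g, s),
        group = g,
        epochs = generate_subject_epochs(
          config, config$group_coupling[[g]],
          seed = derive_seed(config$seed, g, s, 1L)),
        panss = generate_panss_items(
          config$panss_effects[[g]],
          seed = derive_seed(config$seed, g, s, 2L))
      )
    }
  }
  subjects
}

#' Write a cohort to disk
#'
#' One directory per subject: `epoch_###.tsv` (nodes x samples, tab-delimited)
#' plus `subject.json` (fs, epoch length, node labels, group, PANSS items).
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort) {
    sd_ <- file.path(dir, subj$id)
    dir.create(sd_, showWarnings = FALSE)
    ep <- subj$epochs
    for (e in seq_len(n_epochs(ep))) {
      m <- matrix(ep$data[e, , ], nrow = dim(ep$data)[2L])
      utils::write.table(m, file.path(sd_, sprintf("epoch_%03d.tsv", e)),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
    meta <- list(id = subj$id, group = subj$group, fs = ep$fs,
                 epoch_seconds = ep$epoch_seconds,
                 node_labels = ep$node_labels,
                 panss = as.list(subj$panss))
    jsonlite::write_json(meta, file.path(sd_, "subject.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read one subject directory written by [write_cohort()]
#'
#' @param path subject directory.
#' @return list with `id`, `group`, `epochs`, `panss`.
#' @export
read_subject <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "subject.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "^epoch_\\d+\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no epoch files in ", path)
  mats <- lapply(files, function(f) as.matrix(utils::read.table(f, sep = "\t")))
  nn <- nrow(mats[[1L]]); ns <- ncol(mats[[1L]])
  data <- array(0, dim = c(length(mats), nn, ns))
  for (e in seq_along(mats)) data[e, , ] <- mats[[e]]
  panss <- unlist(meta$panss)
  list(id = meta$id, group = meta$group,
       epochs = epoch_set(data, fs = meta$fs,
                          node_labels = meta$node_labels,
                          epoch_seconds = meta$epoch_seconds),
       panss = stats::setNames(as.integer(panss), names(panss)))
}
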