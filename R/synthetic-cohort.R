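#' Phenotype parameters for the synthetic cohort generator
#'
#' Encodes one surgical-outcome phenotype as a set of generative parameters:
#' implant geometry, SOZ labelling, per-contact background fast-ripple (FR)
#' rates, log-normal peak-frequency structure, and cross-contact coupling
#' through latent "mother" Poisson processes with independent thinning.
#'
#' Defaults for the two phenotypes are exposed through
#' [responder_params()] and [nonresponder_params()]. Responders carry a
#' hub-centred coupling graph (all SOZ contacts share one mother process)
#' with FR activity concentrated in a spatially compact SOZ; non-responders
#' carry a decentralized graph (several mothers shared predominantly among
#' non-SOZ contacts) with elevated widespread non-SOZ rates. Peak spectral
#' frequency is log-normal,
#' `exp(N(logfreq_intercept + logfreq_soz_shift * SOZ + patient_intercept,
#' logfreq_sd))`, truncated by rejection to `freq_band` (Hz) for FR
#' subtypes; the responder/non-responder intercepts and SOZ shifts default
#' to the fitted mixed-model values for fRonO frequency (responders
#' 5.470 / +0.178 log-Hz, non-responders 5.646 / -0.352 log-Hz).
#'
#' @param n_electrodes Number of depth electrodes (8-16).
#' @param contacts_per_electrode Contacts per electrode (7-15).
#' @param soz_fraction Fraction of contacts labelled SOZ; the SOZ count is
#'   `round(soz_fraction * n_contacts)`.
#' @param soz_layout `"clustered"` (SOZ confined to 1-2 electrodes) or
#'   `"distributed"` (spread over >= 3 electrodes).
#' @param base_rate_soz,base_rate_nonsoz Background FR rates, events/min.
#' @param logfreq_intercept,logfreq_soz_shift,logfreq_sd Log-Hz location,
#'   SOZ shift, and residual SD of peak frequency.
#' @param patient_intercept_sd SD of the per-patient random intercept (log-Hz).
#' @param freq_band Length-2 Hz band to truncate FR frequencies into, or
#'   `NULL` for no truncation.
#' @param coupling_graph `"hub"` (one mother shared by all contacts, SOZ
#'   strongly coupled) or `"decentralized"` (`n_mothers` mothers, non-SOZ
#'   strongly coupled).
#' @param n_mothers Number of latent mother processes when decentralized.
#' @param mother_rate Mother-process rate, events/min.
#' @param thinning_prob_soz,thinning_prob_nonsoz Probability that a mother
#'   event is copied to a SOZ / non-SOZ contact.
#' @param jitter_ms SD of Gaussian propagation jitter applied to copied
#'   events, milliseconds.
#' @param contact_spacing_mm Inter-contact spacing along an electrode.
#' @param p_frons Fraction of FR events labelled `fRonS` (rest `fRonO`).
#' @param duration_min Analyzed recording duration, minutes.
#' @return A list of class `phenotype_params`.
#' @export
phenotype_params <- function(n_electrodes = 8, contacts_per_electrode = 7,
                             soz_fraction = 0.1, soz_layout = "clustered",
                             base_rate_soz = 1.5, base_rate_nonsoz = 0.2,
                             logfreq_intercept = 5.470,
                             logfreq_soz_shift = 0.178,
                             logfreq_sd = 0.15,
                             patient_intercept_sd = 0.05,
                             freq_band = c(250, 600),
                             coupling_graph = c("hub", "decentralized"),
                             n_mothers = 3,
                             mother_rate = 1.0,
                             thinning_prob_soz = 0.4,
                             thinning_prob_nonsoz = 0.05,
                             jitter_ms = 10,
                             contact_spacing_mm = 5,
                             p_frons = 0.15,
                             duration_min = 60) {
  coupling_graph <- match.arg(coupling_graph)
  soz_layout <- match.arg(soz_layout, c("clustered", "distributed"))
  if (n_electrodes < 8 || n_electrodes > 16)
    stop("n_electrodes must be within 8-16")
  if (contacts_per_electrode < 7 || contacts_per_electrode > 15)
    stop("contacts_per_electrode must be within 7-15")
  probs <- c(soz_fraction, thinning_prob_soz, thinning_prob_nonsoz, p_frons)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  rates <- c(base_rate_soz, base_rate_nonsoz, mother_rate)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (duration_min <= 0) stop("duration_min must be positive")
  structure(as.list(environment()), class = "phenotype_params")
}

#' @rdname phenotype_params
#' @export
responder_params <- function(...) {
  p <- phenotype_params(...)
  p
}

#' @rdname phenotype_params
#' @export
nonresponder_params <- function(...) {
  defaults <- list(soz_layout = "distributed",
                   base_rate_soz = 0.8, base_rate_nonsoz = 0.8,
                   logfreq_intercept = 5.646, logfreq_soz_shift = -0.352,
                   coupling_graph = "decentralized",
                   thinning_prob_soz = 0.1, thinning_prob_nonsoz = 0.3)
  user <- list(...)
  # keep.null so callers can disable options (e.g. freq_band = NULL)
  do.call(phenotype_params, utils::modifyList(defaults, user,
                                              keep.null = TRUE))
}

#' Specification of a synthetic cohort
#'
#' @param n_responders,n_nonresponders Patient counts per phenotype.
#' @param responder_params,nonresponder_params [phenotype_params()] objects.
#' @param seed Integer seed; a fixed seed makes the whole cohort (and every
#'   file written from it) reproducible.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders, n_nonresponders,
                        responder_params = frnet::responder_params(),
                        nonresponder_params = frnet::nonresponder_params(),
                        seed = 1L) {
  stopifnot(n_responders >= 0, n_nonresponders >= 0)
  structure(list(n_responders = n_responders,
                 n_nonresponders = n_nonresponders,
                 responder_params = responder_params,
                 nonresponder_params = nonresponder_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Read a cohort specification from a JSON or YAML config file
#'
#' The config carries `n_responders`, `n_nonresponders`, `seed`, and
#' optional `responder_params` / `nonresponder_params` blocks whose entries
#' override the corresponding [phenotype_params()] defaults (the
#' non-responder block overrides [nonresponder_params()] defaults).
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (k in c("n_responders", "n_nonresponders"))
    if (is.null(cfg[[k]])) stop_schema("cohort config missing key: ", k)
  rp <- do.call(responder_params, as.list(cfg$responder_params))
  np <- do.call(nonresponder_params, as.list(cfg$nonresponder_params))
  cohort_spec(cfg$n_responders, cfg$n_nonresponders, rp, np,
              cfg$seed %||% 1L)
}

#' Generate stereo-EEG implant geometry
#'
#' Lays contacts along linear electrode trajectories with fixed
#' inter-contact spacing inside a +/-70 mm MNI bounding box, assigns one
#' anatomical region per electrode, and labels SOZ contacts either
#' clustered on 1-2 electrodes or distributed over at least 3, according to
#' the phenotype. The SOZ count is `round(soz_fraction * n_contacts)`.
#'
#' @param params A [phenotype_params()].
#' @return Contact data frame (`contact_id`, `x`, `y`, `z`, `region`,
#'   `is_soz`); draws from the current RNG state.
#' @export
generate_geometry <- function(params) {
  ne <- params$n_electrodes
  k <- params$contacts_per_electrode
  sp <- params$contact_spacing_mm
  half <- sp * (k - 1) / 2
  if (half > 70) stop("electrode span exceeds the 70 mm bounding box")
  lim <- 70 - half
  regions <- region_codes()$region
  rows <- vector("list", ne)
  for (e in seq_len(ne)) {
    center <- runif(3, -lim, lim)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    offs <- (seq_len(k) - (k + 1) / 2) * sp
    xyz <- t(center + outer(dir, offs))
    rows[[e]] <- data.frame(
      contact_id = sprintf("E%02d-%02d", e, seq_len(k)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      region = sample(regions, 1), is_soz = FALSE)
  }
  contacts <- do.call(rbind, rows)
  n <- nrow(contacts)
  n_soz <- round(params$soz_fraction * n)
  if (n_soz > 0) {
    elec <- rep(seq_len(ne), each = k)
    if (params$soz_layout == "clustered") {
      picked <- sample(ne, min(2L, ne))
      # contiguous contacts from the start of each picked electrode
      idx <- unlist(lapply(picked, function(e) which(elec == e)))
      soz <- idx[seq_len(min(n_soz, length(idx)))]
    } else {
      m <- max(3L, min(ne, ceiling(n_soz / 2)))
      picked <- sample(ne, m)
      idx <- unlist(lapply(picked, function(e) which(elec == e)))
      # round-robin across the picked electrodes so the SOZ is spread out
      ord <- order(rep(seq_len(k), length(picked))[seq_along(idx)])
      soz <- idx[ord][seq_len(min(n_soz, length(idx)))]
    }
    contacts$is_soz[soz] <- TRUE
  }
  rownames(contacts) <- NULL
  contacts
}

# Draw log-normal peak frequencies, rejection-truncated to params$freq_band.
draw_freqs <- function(n, mu, params) {
  if (n == 0L) return(numeric(0))
  f <- exp(rnorm(n, mu, params$logfreq_sd))
  band <- params$freq_band
  if (!is.null(band)) {
    bad <- which(f < band[1] | f > band[2])
    guard <- 0L
    while (length(bad) && guard < 1000L) {
      f[bad] <- exp(rnorm(length(bad), mu, params$logfreq_sd))
      bad <- bad[f[bad] < band[1] | f[bad] > band[2]]
      guard <- guard + 1L
    }
    if (length(bad)) f[bad] <- pmin(pmax(f[bad], band[1]), band[2])
  }
  f
}

#' Generate coupled fast-ripple event trains for one patient
#'
#' Each contact's FR train is the superposition of (a) an independent
#' Poisson background at its base rate and (b) events copied from one or
#' more latent mother Poisson processes by independent thinning with the
#' contact's coupling probability, plus Gaussian timing jitter. Under a hub
#' coupling graph every contact listens to a single mother (SOZ contacts
#' with the SOZ thinning probability); under a decentralized graph each
#' contact is attached to one of `n_mothers` mothers. The expected rate of
#' a contact is therefore `base_rate + thinning_prob * mother_rate`.
#' Peak frequency is drawn per event from the phenotype's log-normal model;
#' power and duration are log-normal nuisance marks.
#'
#' @param contacts Contact data frame from [generate_geometry()].
#' @param params A [phenotype_params()].
#' @param patient_intercept Per-patient random intercept added to the
#'   log-frequency location (log-Hz).
#' @return Event data frame in [patient_record()] catalog form; draws from
#'   the current RNG state.
#' @export
generate_event_trains <- function(contacts, params, patient_intercept = 0) {
  dur_s <- params$duration_min * 60
  n <- nrow(contacts)
  n_mothers <- if (params$coupling_graph == "hub") 1L else params$n_mothers
  mothers <- lapply(seq_len(n_mothers), function(i)
    sort(runif(rpois(1, params$mother_rate * params$duration_min), 0, dur_s)))
  # mother assignment: hub = everyone on mother 1; decentralized = random
  assignment <- if (n_mothers == 1L) rep(1L, n) else
    sample.int(n_mothers, n, replace = TRUE)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    soz <- contacts$is_soz[i]
    base <- if (soz) params$base_rate_soz else params$base_rate_nonsoz
    p_thin <- if (soz) params$thinning_prob_soz else params$thinning_prob_nonsoz
    bg <- runif(rpois(1, base * params$duration_min), 0, dur_s)
    mom <- mothers[[assignment[i]]]
    copied <- mom[runif(length(mom)) < p_thin]
    if (length(copied)) {
      copied <- copied + rnorm(length(copied), 0, params$jitter_ms / 1000)
      copied <- pmin(pmax(copied, 0), dur_s)
    }
    onset <- sort(c(bg, copied))
    m <- length(onset)
    if (m == 0L) { out[[i]] <- NULL; next }
    mu <- params$logfreq_intercept + params$logfreq_soz_shift * soz +
      patient_intercept
    out[[i]] <- data.frame(
      contact_id = contacts$contact_id[i],
      onset_s = onset,
      subtype = ifelse(runif(m) < params$p_frons, "fRonS", "fRonO"),
      peak_freq_hz = draw_freqs(m, mu, params),
      peak_power = exp(rnorm(m, 2, 0.5)),
      duration_ms = exp(rnorm(m, 3, 0.3)))
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(contact_id = character(0), onset_s = numeric(0),
                      subtype = character(0), peak_freq_hz = numeric(0),
                      peak_power = numeric(0), duration_ms = numeric(0))
  rownames(out) <- NULL
  out
}

#' Generate a reproducible synthetic cohort
#'
#' Produces `n_responders` + `n_nonresponders` patient records from the two
#' phenotype parameter sets. All randomness derives from the spec's seed
#' (one child seed per patient), so the same spec yields a byte-identical
#' cohort on every call.
#'
#' @param spec A [cohort_spec()].
#' @return List of [patient_record()] objects, responders first.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_responders + spec$n_nonresponders
  if (n == 0L) return(list())
  seeds <- child_seeds(spec$seed, n)
  lapply(seq_len(n), function(i) {
    resp <- i <= spec$n_responders
    params <- if (resp) spec$responder_params else spec$nonresponder_params
    outcome <- if (resp) "responder" else "non_responder"
    pid <- sprintf("S%03d_%s", i, if (resp) "R" else "NR")
    with_seed(seeds[i], {
      contacts <- generate_geometry(params)
      pint <- rnorm(1, 0, params$patient_intercept_sd)
      events <- generate_event_trains(contacts, params, pint)
      patient_record(pid, contacts, events, params$duration_min, outcome)
    })
  })
}
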