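#' @rdname flow_spec
#' @export
FLOW_CHANNELS <- c("CD45", "CD11b", "CD11c", "MHCII", "Ly6C", "Ly6G",
                   "F480", "CD38", "CD206", "PI")

FLOW_POPULATIONS <- c("macrophage", "dc", "gmdsc", "mmdsc",
                      "other_cd45", "non_cd45")

## which markers each latent population expresses ("pos"); everything
## else stays at the negative state
POPULATION_PROFILES <- list(
  macrophage = c("CD45", "CD11b", "F480", "MHCII"),
  dc         = c("CD45", "CD11c", "MHCII"),
  gmdsc      = c("CD45", "CD11b", "Ly6G"),
  mmdsc      = c("CD45", "CD11b", "Ly6C"),
  other_cd45 = c("CD45"),
  non_cd45   = character(0))

#' Default two-state log-normal intensity model per channel
#'
#' Each marker has a negative and a positive state; intensities are drawn
#' log-normal within state.  Values are in arbitrary fluorescence units
#' comparable to a 5-decade digital cytometer.
#'
#' @param neg_meanlog,pos_meanlog log-scale locations of the two states.
#' @param neg_sdlog,pos_sdlog log-scale spreads.
#' @return named list per channel of `list(neg = c(meanlog, sdlog),
#'   pos = c(meanlog, sdlog))`.
#' @export
default_channel_params <- function(neg_meanlog = log(60), neg_sdlog = 0.5,
                                   pos_meanlog = log(4000), pos_sdlog = 0.45) {
  p <- lapply(FLOW_CHANNELS, function(ch)
    list(neg = c(meanlog = neg_meanlog, sdlog = neg_sdlog),
         pos = c(meanlog = pos_meanlog, sdlog = pos_sdlog)))
  names(p) <- FLOW_CHANNELS
  p
}

#' Specification for a synthetic flow-cytometry event mixture
#'
#' Events are drawn from a labelled mixture over six latent populations
#' (the four myeloid populations of the panel, other CD45+ cells, and
#' CD45- cells); macrophages additionally carry a CD38/CD206 quadrant
#' label (M0/M1/M2/co-expressing).  Marker intensities are two-state
#' log-normal and are then mixed through the spillover matrix.  A PI
#' viability channel is always present so live-gating can be exercised.
#'
#' @param n_events number of events.
#' @param population_fractions named fractions over
#'   `macrophage, dc, gmdsc, mmdsc, other_cd45, non_cd45`; must sum to 1.
#' @param macrophage_quadrant_fractions named fractions over
#'   `M0, M1, M2, co`; must sum to 1.
#' @param channel_params per-channel intensity model, see
#'   [default_channel_params()].
#' @param spillover square spillover matrix over [FLOW_CHANNELS]
#'   (unit diagonal); identity means no mixing.
#' @param live_fraction fraction of events that are live (PI-negative).
#' @param seed RNG seed.
#' @return a `flow_spec` object.
#' @export
flow_spec <- function(n_events = 10000L,
                      population_fractions = c(macrophage = 0.1350,
                                               dc = 0.0360, gmdsc = 0.0450,
                                               mmdsc = 0.0315,
                                               other_cd45 = 0.2025,
                                               non_cd45 = 0.5500),
                      macrophage_quadrant_fractions = c(M0 = 0.45, M1 = 0.13,
                                                        M2 = 0.15, co = 0.27),
                      channel_params = default_channel_params(),
                      spillover = NULL,
                      live_fraction = 0.85,
                      seed = 1L) {
  if (is.null(spillover)) {
    spillover <- diag(length(FLOW_CHANNELS))
    dimnames(spillover) <- list(FLOW_CHANNELS, FLOW_CHANNELS)
  }
  spec <- list(n_events = as.integer(n_events),
               population_fractions = population_fractions,
               macrophage_quadrant_fractions = macrophage_quadrant_fractions,
               channel_params = channel_params, spillover = spillover,
               live_fraction = live_fraction, seed = as.integer(seed))
  validate_flow_spec(spec)
  structure(spec, class = "flow_spec")
}

validate_flow_spec <- function(s) {
  pf <- s$population_fractions
  if (!setequal(names(pf), FLOW_POPULATIONS))
    stop("population_fractions must name exactly: ",
         paste(FLOW_POPULATIONS, collapse = ", "))
  if (abs(sum(pf) - 1) > 1e-9) stop("population fractions must sum to 1")
  qf <- s$macrophage_quadrant_fractions
  if (!setequal(names(qf), c("M0", "M1", "M2", "co")))
    stop("quadrant fractions must name M0, M1, M2, co")
  if (abs(sum(qf) - 1) > 1e-9) stop("quadrant fractions must sum to 1")
  if (any(pf < 0) || any(qf < 0)) stop("fractions must be non-negative")
  sp <- s$spillover
  if (!is.matrix(sp) || nrow(sp) != ncol(sp) ||
      nrow(sp) != length(FLOW_CHANNELS))
    stop("spillover must be square over the panel channels")
  if (any(abs(diag(sp) - 1) > 1e-12)) stop("spillover diagonal must be 1")
  if (s$n_events < 1) stop("n_events must be positive")
  if (s$live_fraction < 0 || s$live_fraction > 1)
    stop("live_fraction must lie in [0, 1]")
  invisible(TRUE)
}

#' A mild non-identity spillover preset
#'
#' Unit diagonal with small spill between spectrally adjacent detector
#' pairs, for exercising compensation.
#'
#' @param amount off-diagonal spill fraction.
#' @return spillover matrix over [FLOW_CHANNELS].
#' @export
spillover_preset <- function(amount = 0.06) {
  n <- length(FLOW_CHANNELS)
  S <- diag(n)
  for (i in seq_len(n - 1)) {
    S[i, i + 1] <- amount
    S[i + 1, i] <- amount / 2
  }
  dimnames(S) <- list(FLOW_CHANNELS, FLOW_CHANNELS)
  S
}

#' Generate a labelled synthetic event table
#'
#' @param spec a [flow_spec()].
#' @return list with `events` (data.frame, one column per panel channel),
#'   and `truth` (latent `population` labels, macrophage `quadrant`
#'   labels, logical `dead` flags, and the realized fractions).
#' @export
generate_flow_events <- function(spec) {
  validate_flow_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_events
    pops <- sample(FLOW_POPULATIONS, n, replace = TRUE,
                   prob = spec$population_fractions[FLOW_POPULATIONS])
    dead <- runif(n) >= spec$live_fraction
    quad <- rep(NA_character_, n)
    is_mac <- pops == "macrophage"
    if (any(is_mac))
      quad[is_mac] <- sample(names(spec$macrophage_quadrant_fractions),
                             sum(is_mac), replace = TRUE,
                             prob = spec$macrophage_quadrant_fractions)

    X <- matrix(0, n, length(FLOW_CHANNELS),
                dimnames = list(NULL, FLOW_CHANNELS))
    for (ch in FLOW_CHANNELS) {
      pos <- vapply(pops, function(p) ch %in% POPULATION_PROFILES[[p]],
                    logical(1))
      if (ch == "CD38") pos <- is_mac & quad %in% c("M1", "co")
      if (ch == "CD206") pos <- is_mac & quad %in% c("M2", "co")
      if (ch == "PI") pos <- dead
      pr <- spec$channel_params[[ch]]
      ml <- ifelse(pos, pr$pos["meanlog"], pr$neg["meanlog"])
      sl <- ifelse(pos, pr$pos["sdlog"], pr$neg["sdlog"])
      X[, ch] <- rlnorm(n, ml, sl)
    }
    mixed <- X %*% spec$spillover[FLOW_CHANNELS, FLOW_CHANNELS]
    events <- as.data.frame(mixed)

    live_cd45 <- !dead & pops != "non_cd45"
    frac_of_cd45 <- if (any(live_cd45))
      table(factor(pops[live_cd45], FLOW_POPULATIONS[1:5])) / sum(live_cd45)
    else setNames(rep(NA_real_, 5), FLOW_POPULATIONS[1:5])
    live_mac <- is_mac & !dead
    quad_frac <- if (any(live_mac))
      table(factor(quad[live_mac], c("M0", "M1", "M2", "co"))) / sum(live_mac)
    else setNames(rep(NA_real_, 4), c("M0", "M1", "M2", "co"))

    list(events = events,
         truth = list(population = pops, quadrant = quad, dead = dead,
                      fraction_of_cd45 = c(frac_of_cd45),
                      quadrant_fractions = c(quad_frac),
                      n_live_cd45 = sum(live_cd45),
                      n_live_macrophage = sum(live_mac)))
  })
}
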