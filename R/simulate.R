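#' Simulate class I (interference-sensitive) crossover positions
#'
#' Places events on an interval of given relative SC length as a gamma
#' renewal process: inter-event gaps are i.i.d. Gamma(shape = `nu`,
#' mean = 1/`mu`), so the expected number of events is `mu * length` and the
#' gap coefficient of variation is `1/sqrt(nu)`. With `nu = 1` the process is
#' homogeneous Poisson (no interference); larger `nu` spaces events more
#' evenly. By default the first event is drawn from the equilibrium
#' (residual-life) distribution, making the process stationary so that
#' interior gaps are exactly gamma-distributed — the property the
#' interference fit relies on.
#'
#' @param nu Gamma shape (interference parameter), >= 1.
#' @param mu Expected events per unit SC length, >= 0.
#' @param length Relative SC length of the interval, > 0.
#' @param start `"stationary"` (equilibrium first event) or `"ordinary"`
#'   (renewal starts at the origin).
#' @return Sorted numeric vector of event positions in (0, `length`).
#' @export
#' @examples
#' set.seed(1)
#' simulate_class1_positions(nu = 8.39, mu = 2, length = 1)
simulate_class1_positions <- function(nu, mu, length = 1,
                                      start = c("stationary", "ordinary")) {
  start <- match.arg(start)
  if (!is.numeric(nu) || !is.finite(nu) || nu < 1)
    stop("'nu' must be finite and >= 1")
  if (!is.numeric(mu) || !is.finite(mu) || mu < 0)
    stop("'mu' must be finite and >= 0")
  if (!is.numeric(length) || !is.finite(length) || length <= 0)
    stop("'length' must be finite and > 0")
  if (mu == 0) return(numeric(0))
  rate <- nu * mu  # gap ~ Gamma(nu, rate) has mean 1/mu
  # first arrival: residual life = U * (length-biased gap), length-biased
  # Gamma(nu, rate) is Gamma(nu + 1, rate)
  pos <- if (start == "stationary") {
    runif(1L) * rgamma(1L, shape = nu + 1, rate = rate)
  } else {
    rgamma(1L, shape = nu, rate = rate)
  }
  if (pos >= length) return(numeric(0))
  out <- pos
  repeat {
    # draw gaps in blocks to limit loop iterations
    gaps <- rgamma(max(4L, ceiling((length - out[base::length(out)]) * mu) + 4L),
                   shape = nu, rate = rate)
    cum <- out[base::length(out)] + cumsum(gaps)
    keep <- cum < length
    out <- c(out, cum[keep])
    if (!all(keep)) break
  }
  out
}

#' Simulate class II (interference-free) crossover positions
#'
#' Homogeneous Poisson process on `[0, length]`: the event count is
#' Poisson(`rate * length`) and positions are uniform. Models the
#' interference-insensitive crossover pathway, whose per-cell counts are
#' expected to follow a Poisson distribution.
#'
#' @param rate Expected events per unit SC length, >= 0.
#' @param length Relative SC length, > 0.
#' @return Sorted numeric vector of positions in (0, `length`).
#' @export
simulate_class2_positions <- function(rate, length = 1) {
  if (!is.numeric(rate) || !is.finite(rate) || rate < 0)
    stop("'rate' must be finite and >= 0")
  if (!is.numeric(length) || !is.finite(length) || length <= 0)
    stop("'length' must be finite and > 0")
  n <- rpois(1L, rate * length)
  if (n == 0L) return(numeric(0))
  sort(runif(n, 0, length))
}

# shape class from the total event count on one bivalent
shape_from_count <- function(n) {
  c("univalent_pair", "rod", "ring")[pmin(n, 2L) + 1L]
}

#' Simulate one pollen mother cell
#'
#' Draws class I and class II crossover positions independently on every
#' bivalent, derives the metaphase I shape class from the total event count
#' (0 events: pair of univalents; 1: rod; >= 2: ring), and emits the class I
#' positions as the bright-focus channel (`"bright"`), mirroring prominent
#' recombination-protein foci that mark class I crossover sites. Positions
#' are stored as fractions of each bivalent's own SC length.
#'
#' Uses the current RNG state; seed management is done by
#' [simulate_meiosis()].
#'
#' @param config A [sim_config()] object.
#' @param cell_id Identifier used in the output tables.
#' @return List with `cells` (one row per bivalent: `cell_id`, `genotype`,
#'   `bivalent_id`, `sc_length`, `shape_class`, `n_class1`, `n_class2`) and
#'   `foci` (`cell_id`, `bivalent_id`, `channel`, `position_frac`).
#' @export
simulate_cell <- function(config, cell_id = "cell_1") {
  stopifnot(inherits(config, "sim_config"))
  nb <- config$n_bivalents
  n1 <- integer(nb); n2 <- integer(nb)
  foci_pos <- vector("list", nb)
  for (i in seq_len(nb)) {
    L <- config$sc_lengths[[i]]
    p1 <- simulate_class1_positions(config$class1_nu, config$class1_mu, L,
                                    start = config$start)
    p2 <- simulate_class2_positions(config$class2_rate, L)
    n1[[i]] <- length(p1); n2[[i]] <- length(p2)
    foci_pos[[i]] <- p1 / L  # bright foci at class I sites, as fractions
  }
  cells <- data.frame(
    cell_id = cell_id, genotype = config$genotype,
    bivalent_id = names_or_index(config$sc_lengths),
    sc_length = as.numeric(config$sc_lengths),
    shape_class = shape_from_count(n1 + n2),
    n_class1 = n1, n_class2 = n2,
    stringsAsFactors = FALSE, row.names = NULL)
  nf <- lengths(foci_pos)
  foci <- data.frame(
    cell_id = rep(cell_id, sum(nf)),
    bivalent_id = rep(cells$bivalent_id, nf),
    channel = rep("bright", sum(nf)),
    position_frac = unlist(foci_pos, use.names = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  list(cells = cells, foci = foci)
}

names_or_index <- function(x) {
  if (!is.null(names(x)) && all(nzchar(names(x)))) names(x)
  else sprintf("biv%02d", seq_along(x))
}

#' Simulate a cell population
#'
#' Seeds the RNG from `config$seed` and simulates `config$n_cells` cells with
#' [simulate_cell()]. Reruns with the same config are byte-identical.
#'
#' @param config A [sim_config()] object.
#' @return List with stacked `cells` and `foci` data frames (the tab-delimited
#'   table dialect written by [write_cells_table()] / [write_foci_table()]).
#' @export
#' @examples
#' sim <- simulate_meiosis(sim_config("hei10", n_cells = 20, seed = 42))
#' head(sim$cells)
simulate_meiosis <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sprintf("cell_%04d", seq_len(config$n_cells))
  sims <- lapply(ids, function(id) simulate_cell(config, id))
  list(cells = do.call(rbind, lapply(sims, `[[`, "cells")),
       foci = do.call(rbind, lapply(sims, `[[`, "foci")))
}

#' Simulate a dual-immunostaining experiment from shared focus positions
#'
#' Both channels observe the same underlying foci, each with its own
#' independent dropout (a focus missed by that antibody), independent Gaussian
#' positional jitter (clamped to `[0, 1]`), and independent Poisson
#' background extras per chromosome. Asymmetric dropout produces the
#' asymmetric directional colocalization fractions seen in dual-staining
#' data: the fraction of channel A foci containing a channel B focus is
#' approximately `1 - dropout_b` when jitter is small relative to the
#' matching tolerance.
#'
#' The defaults (`dropout_a = 0.025`, `dropout_b = 0.069`, `jitter_sd =
#' 0.002`) calibrate the generator so channel A recovers ~93.1% overlap with
#' B and channel B ~97.5% with A at the default 1%-of-SC matching tolerance.
#'
#' @param base A foci-like data frame (`cell_id`, `bivalent_id`,
#'   `position_frac`) of shared underlying focus positions.
#' @param jitter_sd SD of positional jitter (fraction of SC length), >= 0.
#' @param dropout_a,dropout_b Per-focus dropout probability per channel, in
#'   `[0, 1]`.
#' @param extra_rate Expected background foci per chromosome per channel,
#'   >= 0.
#' @param channels Labels of the two output channels.
#' @return Foci data frame (`cell_id`, `bivalent_id`, `channel`,
#'   `position_frac`) with both channels stacked.
#' @export
simulate_dual_channel <- function(base, jitter_sd = 0.002,
                                  dropout_a = 0.025, dropout_b = 0.069,
                                  extra_rate = 0,
                                  channels = c("A", "B")) {
  stopifnot(is.data.frame(base),
            all(c("cell_id", "bivalent_id", "position_frac") %in% names(base)))
  if (!is.finite(jitter_sd) || jitter_sd < 0)
    stop("'jitter_sd' must be finite and >= 0")
  for (d in c(dropout_a, dropout_b))
    if (!is.finite(d) || d < 0 || d > 1)
      stop("dropout fractions must lie in [0, 1]")
  if (!is.finite(extra_rate) || extra_rate < 0)
    stop("'extra_rate' must be finite and >= 0")
  if (length(channels) != 2L) stop("'channels' must have length 2")

  one_channel <- function(label, dropout) {
    keep <- runif(nrow(base)) >= dropout
    obs <- base[keep, c("cell_id", "bivalent_id", "position_frac")]
    if (nrow(obs) > 0 && jitter_sd > 0) {
      obs$position_frac <- pmin(pmax(
        obs$position_frac + rnorm(nrow(obs), 0, jitter_sd), 0), 1)
    }
    if (extra_rate > 0) {
      chroms <- unique(base[c("cell_id", "bivalent_id")])
      n_extra <- rpois(nrow(chroms), extra_rate)
      if (sum(n_extra) > 0) {
        extras <- data.frame(
          cell_id = rep(chroms$cell_id, n_extra),
          bivalent_id = rep(chroms$bivalent_id, n_extra),
          position_frac = runif(sum(n_extra)),
          stringsAsFactors = FALSE)
        obs <- rbind(obs, extras)
      }
    }
    obs$channel <- label
    obs[c("cell_id", "bivalent_id", "channel", "position_frac")]
  }

  out <- rbind(one_channel(channels[[1]], dropout_a),
               one_channel(channels[[2]], dropout_b))
  row.names(out) <- NULL
  out
}
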