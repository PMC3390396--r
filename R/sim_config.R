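#' Relative synaptonemal-complex lengths of the twelve rice bivalents
#'
#' Relative SC lengths for the n = 12 bivalents of rice, proportional to the
#' Nipponbare pseudomolecule sizes and normalised to mean 1, so that a rate
#' expressed "per unit SC length" is also a per-average-bivalent rate.
#' Chromosome 9 is the shortest; interference analyses that pool "the shortest
#' chromosome" use `which.min()` on this vector.
#'
#' @return Named numeric vector of length 12, mean exactly 1.
#' @export
#' @examples
#' rice_sc_lengths()
rice_sc_lengths <- function() {
  mb <- c(chr01 = 43.27, chr02 = 35.94, chr03 = 36.41, chr04 = 35.50,
          chr05 = 29.96, chr06 = 31.25, chr07 = 29.70, chr08 = 28.44,
          chr09 = 23.01, chr10 = 23.21, chr11 = 29.02, chr12 = 27.53)
  mb / mean(mb)
}

#' Expected capped chiasma score of a Poisson placement process
#'
#' For interference-free (class II only) genotypes the number of crossovers on
#' a bivalent of relative length L is Poisson(r L); the cytological score is
#' min(count, 2) because a bivalent cannot display more than two chiasmata
#' (ring shape). The expectation has the closed form
#' `2 - 2 exp(-rL) - rL exp(-rL)` per bivalent.
#'
#' @param rate Events per unit SC length.
#' @param sc_lengths Relative SC lengths of the bivalents.
#' @return Expected per-cell scored chiasma count.
#' @keywords internal
expected_capped_poisson_score <- function(rate, sc_lengths) {
  lam <- rate * sc_lengths
  sum(2 - 2 * exp(-lam) - lam * exp(-lam))
}

#' Calibrate the class II rate to a target scored chiasma mean
#'
#' Inverts [expected_capped_poisson_score()] so that a class-II-only genotype
#' reproduces a printed per-cell chiasma mean in expectation, accounting for
#' the two-chiasma cap imposed by shape scoring.
#'
#' @param target_mean Target per-cell scored chiasma mean (e.g. 6.5).
#' @param sc_lengths Relative SC lengths.
#' @return Rate per unit SC length.
#' @export
calibrate_class2_rate <- function(target_mean, sc_lengths = rice_sc_lengths()) {
  stopifnot(is.numeric(target_mean), length(target_mean) == 1L,
            target_mean > 0, target_mean < 2 * length(sc_lengths))
  uniroot(function(r) expected_capped_poisson_score(r, sc_lengths) - target_mean,
          lower = 1e-9, upper = 100, tol = 1e-10)$root
}

.genotypes <- c("WT", "hei10", "mer3", "mer3hei10", "zep1", "pair3")

# Pathway parameters per genotype. Class I: gamma-renewal density of bright
# foci per unit SC (WT ~2.0/bivalent => ~24 foci/cell; zep1 36.2/cell;
# pair3 1.2/cell residual bright spots). Class II rates are calibrated so the
# scored (capped) chiasma mean matches the printed per-cell mean for the
# class-II-only mutants; for WT/zep1 the class II event rate is the ~4
# residual crossovers/cell implied by 28.3 total minus 24.3 class I.
genotype_defaults <- function(genotype, sc_lengths = rice_sc_lengths()) {
  genotype <- match.arg(genotype, .genotypes)
  total_len <- sum(sc_lengths)
  switch(genotype,
    WT        = list(class1_nu = 8.39, class1_mu = 2.0,
                     class2_rate = 4.0 / total_len),
    zep1      = list(class1_nu = 8.39, class1_mu = 36.2 / total_len,
                     class2_rate = 4.0 / total_len),
    hei10     = list(class1_nu = 8.39, class1_mu = 0,
                     class2_rate = calibrate_class2_rate(6.5, sc_lengths)),
    mer3      = list(class1_nu = 8.39, class1_mu = 0,
                     class2_rate = calibrate_class2_rate(5.8, sc_lengths)),
    mer3hei10 = list(class1_nu = 8.39, class1_mu = 0,
                     class2_rate = calibrate_class2_rate(2.1, sc_lengths)),
    pair3     = list(class1_nu = 8.39, class1_mu = 1.2 / total_len,
                     class2_rate = 0)
  )
}

#' Simulation configuration for one genotype
#'
#' Bundles the generative parameters of the two crossover pathways for a cell
#' population of one genotype. Class I events follow a stationary gamma
#' renewal process with shape `class1_nu` (the interference parameter; 1 means
#' no interference) and density `class1_mu` events per unit SC length; class
#' II events are a homogeneous Poisson process with `class2_rate` events per
#' unit SC length. The `hei10` and `mer3hei10` genotypes knock the class I
#' pathway out (`class1_mu` forced to 0). Unspecified rates default to
#' genotype-specific calibrations reproducing the published per-cell chiasma
#' means and bright-focus counts.
#'
#' @param genotype One of `"WT"`, `"hei10"`, `"mer3"`, `"mer3hei10"`,
#'   `"zep1"`, `"pair3"`.
#' @param n_cells Number of cells (pollen mother cells) to simulate.
#' @param seed Integer seed; mandatory, so every dataset is reproducible.
#' @param sc_lengths Relative SC lengths, one per bivalent.
#' @param n_bivalents Number of bivalents (default 12, rice).
#' @param class1_nu Gamma shape of class I inter-event gaps, >= 1.
#' @param class1_mu Class I events per unit SC length, >= 0.
#' @param class2_rate Class II events per unit SC length, >= 0.
#' @param start First-event convention of the class I renewal process:
#'   `"stationary"` draws the first event from the equilibrium (residual-life)
#'   distribution so interior gaps are exactly gamma; `"ordinary"` starts the
#'   renewal at the origin.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config("hei10", n_cells = 50, seed = 1)
#' cfg$class1_mu  # 0: class I pathway knocked out
sim_config <- function(genotype = "WT", n_cells = 130, seed,
                       sc_lengths = rice_sc_lengths(),
                       n_bivalents = length(sc_lengths),
                       class1_nu = NULL, class1_mu = NULL, class2_rate = NULL,
                       start = c("stationary", "ordinary")) {
  genotype <- match.arg(genotype, .genotypes)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' is mandatory and must be a single finite integer")
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("'n_cells' must be a positive integer")
  if (n_bivalents != length(sc_lengths))
    stop("'n_bivalents' must equal length(sc_lengths)")
  if (any(!is.finite(sc_lengths)) || any(sc_lengths <= 0))
    stop("'sc_lengths' must be positive and finite")
  defaults <- genotype_defaults(genotype, sc_lengths)
  if (is.null(class1_nu)) class1_nu <- defaults$class1_nu
  if (is.null(class1_mu)) class1_mu <- defaults$class1_mu
  if (is.null(class2_rate)) class2_rate <- defaults$class2_rate
  if (genotype %in% c("hei10", "mer3hei10") && class1_mu != 0) {
    class1_mu <- 0  # class I pathway absent in these genotypes
  }
  if (!is.finite(class1_nu) || class1_nu < 1)
    stop("'class1_nu' must be finite and >= 1")
  if (!is.finite(class1_mu) || class1_mu < 0)
    stop("'class1_mu' must be finite and >= 0")
  if (!is.finite(class2_rate) || class2_rate < 0)
    stop("'class2_rate' must be finite and >= 0")
  structure(
    list(genotype = genotype, n_cells = as.integer(n_cells),
         seed = as.integer(seed), sc_lengths = sc_lengths,
         n_bivalents = as.integer(n_bivalents),
         class1_nu = class1_nu, class1_mu = class1_mu,
         class2_rate = class2_rate, start = match.arg(start)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Meiosis simulation config\n")
  cat(sprintf("  genotype: %s   cells: %d   bivalents: %d   seed: %d\n",
              x$genotype, x$n_cells, x$n_bivalents, x$seed))
  cat(sprintf("  class I : nu = %.3g, mu = %.4g events/unit SC (%s start)\n",
              x$class1_nu, x$class1_mu, x$start))
  cat(sprintf("  class II: rate = %.4g events/unit SC\n", x$class2_rate))
  invisible(x)
}

#' Read a simulation configuration from a flat key-value file
#'
#' The file holds one `key = value` (or `key<TAB>value`) pair per line; `#`
#' starts a comment. Recognised keys are the arguments of [sim_config()];
#' `sc_lengths` may be a comma-separated list. `seed` is mandatory.
#'
#' @param path Path to the config file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  kv <- read_key_values(path)
  args <- list()
  num <- function(x) as.numeric(x)
  if (!is.null(kv$genotype)) args$genotype <- kv$genotype
  if (!is.null(kv$n_cells)) args$n_cells <- num(kv$n_cells)
  if (is.null(kv$seed)) stop("config file must specify 'seed'")
  args$seed <- num(kv$seed)
  if (!is.null(kv$sc_lengths))
    args$sc_lengths <- num(strsplit(kv$sc_lengths, ",")[[1]])
  for (k in c("class1_nu", "class1_mu", "class2_rate"))
    if (!is.null(kv[[k]])) args[[k]] <- num(kv[[k]])
  if (!is.null(kv$start)) args$start <- kv$start
  do.call(sim_config, args)
}

# shared flat key-value parser (also used by the pipeline config)
read_key_values <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "=|\t", perl = TRUE)[[1]]
    if (length(parts) < 2)
      stop(sprintf("malformed config line %d: '%s'", i, lines[[i]]))
    key <- trimws(parts[[1]])
    out[[key]] <- trimws(paste(parts[-1], collapse = "="))
  }
  out
}
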