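#' Read a pipeline run configuration
#'
#' Flat `key = value` text format (one pair per line, `#` comments). Keys:
#' `seed` (mandatory), `genotypes` (comma list), `n_cells.<genotype>`
#' (optional per-genotype cell counts), `analyses` (comma subset of
#' `gof,ttest,interference,coloc`), `coloc_tolerance`, `schema_version`.
#'
#' @param path Config file path.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  kv <- read_key_values(path)
  if (is.null(kv$seed)) stop("run config must specify 'seed'")
  genotypes <- if (is.null(kv$genotypes)) c("WT", "hei10", "mer3hei10")
               else trimws(strsplit(kv$genotypes, ",")[[1]])
  analyses <- if (is.null(kv$analyses)) c("gof", "ttest", "interference", "coloc")
              else trimws(strsplit(kv$analyses, ",")[[1]])
  if (length(analyses) == 0L) stop("at least one analysis must be enabled")
  n_cells <- lapply(genotypes, function(g) {
    v <- kv[[paste0("n_cells.", g)]]
    if (is.null(v)) default_n_cells(g) else as.integer(v)
  })
  names(n_cells) <- genotypes
  structure(list(
    seed = as.integer(as.numeric(kv$seed)),
    genotypes = genotypes, n_cells = n_cells, analyses = analyses,
    coloc_tolerance = if (is.null(kv$coloc_tolerance)) 0.01
                      else as.numeric(kv$coloc_tolerance),
    schema_version = if (is.null(kv$schema_version)) "1" else kv$schema_version),
    class = "run_config")
}

# published sample sizes per genotype where stated; 100 otherwise
default_n_cells <- function(genotype) {
  switch(genotype, WT = 130L, hei10 = 130L, mer3 = 83L, mer3hei10 = 121L,
         zep1 = 36L, 100L)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates one synthetic cell population per genotype, then runs every
#' enabled analysis and writes a consolidated tab-delimited report:
#'
#' * `cells_<genotype>.tsv`, `foci_<genotype>.tsv` — the simulated tables;
#' * `summary.tsv` — per genotype: n, chiasma mean and SD, Poisson
#'   goodness-of-fit chi-square, df, and p;
#' * `ttests.tsv` — pooled two-sample t for every genotype pair;
#' * `interference.tsv` — gamma-model fit of adjacent bright-focus distances
#'   pooled over the shortest chromosome;
#' * `coloc.tsv` — dual-channel colocalization fractions from a simulated
#'   dual-immunostaining experiment on the first genotype's bright foci;
#' * `report.txt` — header with package version, seed, full configuration,
#'   and the rounded display summary (mean +/- SD to one decimal, as
#'   conventionally printed).
#'
#' All numbers in the `.tsv` files are written at full precision; the report
#' header carries the rounded display. Reruns with the same config are
#' byte-identical.
#'
#' @param config A `run_config` (from [read_run_config()]) or a list with the
#'   same fields.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the computed result objects.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(is.list(config), !is.null(config$seed))
  if (is.null(config$genotypes)) config$genotypes <- c("WT", "hei10", "mer3hei10")
  if (is.null(config$analyses))
    config$analyses <- c("gof", "ttest", "interference", "coloc")
  if (is.null(config$coloc_tolerance)) config$coloc_tolerance <- 0.01
  if (is.null(config$n_cells))
    config$n_cells <- setNames(lapply(config$genotypes, default_n_cells),
                               config$genotypes)
  genotypes <- config$genotypes
  analyses <- config$analyses
  if (length(analyses) == 0L) stop("at least one analysis must be enabled")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  sims <- list(); summaries <- list(); gofs <- list()
  for (i in seq_along(genotypes)) {
    g <- genotypes[[i]]
    cfg <- sim_config(g, n_cells = config$n_cells[[g]],
                      seed = config$seed + i)
    say("simulating ", g, " (n = ", cfg$n_cells, ", seed = ", cfg$seed, ")")
    sims[[g]] <- simulate_meiosis(cfg)
    write_cells_table(sims[[g]]$cells,
                      file.path(out_dir, paste0("cells_", g, ".tsv")))
    write_foci_table(sims[[g]]$foci,
                     file.path(out_dir, paste0("foci_", g, ".tsv")))
    counts <- chiasma_counts(sims[[g]]$cells)
    summaries[[g]] <- summarize_genotype(counts)
    if ("gof" %in% analyses)
      gofs[[g]] <- poisson_gof(counts$chiasma_count)
  }

  sum_tab <- data.frame(
    genotype = genotypes,
    n = vapply(summaries, `[[`, 0, "n"),
    mean = vapply(summaries, `[[`, 0, "mean"),
    sd = vapply(summaries, `[[`, 0, "sd"),
    stringsAsFactors = FALSE, row.names = NULL)
  if ("gof" %in% analyses) {
    sum_tab$chi2 <- vapply(gofs, `[[`, 0, "chi2")
    sum_tab$df <- vapply(gofs, `[[`, 0L, "df")
    sum_tab$p <- vapply(gofs, `[[`, 0, "p_value")
  }
  write.table(sum_tab, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  results <- list(summary = sum_tab, sims = sims)

  if ("ttest" %in% analyses && length(genotypes) >= 2) {
    pairs <- utils::combn(genotypes, 2, simplify = FALSE)
    tt <- do.call(rbind, lapply(pairs, function(p) {
      s1 <- summaries[[p[[1]]]]; s2 <- summaries[[p[[2]]]]
      r <- pooled_t_test(s1$mean, s1$sd, s1$n, s2$mean, s2$sd, s2$n)
      data.frame(group1 = p[[1]], group2 = p[[2]], t = r$t, df = r$df,
                 p = r$p_value, stringsAsFactors = FALSE)
    }))
    write.table(tt, file.path(out_dir, "ttests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$ttests <- tt
  }

  if ("interference" %in% analyses) {
    fit <- NULL
    for (g in genotypes) {
      short_id <- shortest_bivalent(sims[[g]]$cells)
      bright <- sims[[g]]$foci
      bright <- bright[bright$channel == "bright" &
                         bright$bivalent_id == short_id, ]
      d <- interfocus_distances(bright)
      if (d$n >= 3) {
        say("interference fit on ", g, " shortest chromosome (",
            d$n, " gaps)")
        fit <- fit_interference(d, method = "mle")
        itab <- data.frame(genotype = g, chromosome = short_id,
                           method = fit$method, nu_hat = fit$nu,
                           se_nu = fit$se_nu, scale_hat = fit$scale,
                           n = fit$n, loglik = fit$loglik,
                           stringsAsFactors = FALSE)
        write.table(itab, file.path(out_dir, "interference.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        results$interference <- fit
        break  # first genotype with enough bright-focus gaps (typically WT)
      }
    }
    if (is.null(fit)) say("interference: no genotype with enough bright foci")
  }

  if ("coloc" %in% analyses) {
    base <- sims[[genotypes[[1]]]]$foci
    base <- base[base$channel == "bright", ]
    if (nrow(base) > 0) {
      set.seed(config$seed + 1000L)
      dual <- simulate_dual_channel(base)
      co <- coloc_fractions(dual[dual$channel == "A", ],
                            dual[dual$channel == "B", ],
                            tolerance = config$coloc_tolerance)
      ctab <- data.frame(channel_a = "A", channel_b = "B",
                         fraction_a_with_b = co$fraction_a_with_b,
                         fraction_b_with_a = co$fraction_b_with_a,
                         tolerance = co$tolerance, n_a = co$n_a, n_b = co$n_b,
                         stringsAsFactors = FALSE)
      write.table(ctab, file.path(out_dir, "coloc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      results$coloc <- co
    } else {
      say("coloc: first genotype has no bright foci; block skipped")
    }
  }

  # self-describing report header with the rounded display table
  hdr <- c(
    sprintf("chiasma pipeline report (package version %s)",
            as.character(packageVersion("chiasma"))),
    sprintf("seed: %d   schema_version: %s", config$seed,
            if (is.null(config$schema_version)) "1" else config$schema_version),
    sprintf("genotypes: %s", paste(genotypes, collapse = ", ")),
    sprintf("analyses: %s", paste(analyses, collapse = ", ")),
    sprintf("coloc_tolerance: %g", config$coloc_tolerance),
    "",
    "per-genotype chiasma frequency (mean +/- SD, one decimal):",
    sprintf("  %-10s %5.1f +/- %.1f  (n = %d)", sum_tab$genotype,
            sum_tab$mean, sum_tab$sd, sum_tab$n))
  writeLines(hdr, file.path(out_dir, "report.txt"))
  say("report written to ", out_dir)
  invisible(results)
}

# bivalent_id with the smallest sc_length in a cells table
shortest_bivalent <- function(cells) {
  per_biv <- tapply(cells$sc_length, cells$bivalent_id, min)
  names(per_biv)[which.min(per_biv)]
}
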