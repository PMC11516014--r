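#' Per-region dataset summary table
#'
#' Counts of dates, sites and mean dates per site, overall and split by
#' site type (settlement / burial), per region plus a meta-region row
#' covering the whole dataset.
#'
#' @param dates canonical (filtered) date table.
#' @param regions region codes to tabulate; default: those present.
#' @return data.frame with one row per region (plus `Meta`), columns
#'   `n_dates`, `n_dates_settlement`, `n_dates_burial`, `n_sites`,
#'   `n_sites_settlement`, `n_sites_burial`, `mean_dates_site`,
#'   `mean_dates_site_settlement`, `mean_dates_site_burial`.
#' @export
summarize_dataset <- function(dates, regions = NULL) {
  if (is.null(regions)) regions <- sort(unique(dates$region))
  one <- function(d) {
    cnt <- function(dd) {
      n <- nrow(dd); s <- length(unique(dd$site_id))
      c(n = n, sites = s, mean = if (s > 0) round(n / s, 2) else 0)
    }
    a <- cnt(d)
    s <- cnt(d[d$site_type == "settlement", , drop = FALSE])
    b <- cnt(d[d$site_type == "burial", , drop = FALSE])
    data.frame(
      n_dates = a["n"], n_dates_settlement = s["n"], n_dates_burial = b["n"],
      n_sites = a["sites"], n_sites_settlement = s["sites"],
      n_sites_burial = b["sites"],
      mean_dates_site = a["mean"],
      mean_dates_site_settlement = s["mean"],
      mean_dates_site_burial = b["mean"]
    )
  }
  rows <- lapply(regions, function(r) one(dates[dates$region == r, , drop = FALSE]))
  out <- do.call(rbind, c(list(one(dates)), rows))
  out <- cbind(region = c("Meta", regions), out)
  rownames(out) <- NULL
  out
}

#' Run the full multi-proxy analysis
#'
#' Wires the pipeline end to end: date filters, per-region SPD and
#' composite KDE models with growth rates and event detection, the
#' aoristic artifact series, regional openness scores, and the pairwise
#' correlation tables over the three canonical windows (full 2850--1700,
#' MNB 2850--2350, LN 2350--1700 BCE). Proxy inputs that are `NULL` are
#' skipped with a notice, so a dates-only run still produces the
#' radiocarbon outputs.
#'
#' @param dates canonical date table, or `NULL`.
#' @param artifacts artifact table, or `NULL`.
#' @param pollen pollen sample table, or `NULL`.
#' @param curve calibration curve.
#' @param config list of analysis parameters; see
#'   [default_analysis_config()]. Missing entries take defaults.
#' @param out_dir optional directory: CSV outputs are written there, each
#'   carrying a provenance header (config and seed).
#' @param seed RNG seed applied before any stochastic stage.
#' @return list bundle: `config`, `audit`, `summary_table`, `spd`,
#'   `kde` / `growth` / `events` (per region), `nulltest`, `aoristic`,
#'   `openness`, `correlations`, `skipped`.
#' @export
run_full_analysis <- function(dates = NULL, artifacts = NULL, pollen = NULL,
                              curve, config = list(), out_dir = NULL,
                              seed = NULL) {
  cfg <- utils::modifyList(default_analysis_config(), config)
  if (!is.null(seed)) set.seed(seed)
  bundle <- list(config = cfg, skipped = character(0))
  axis <- cal_axis(cfg$window_pad[1], cfg$window_pad[2], 1)
  obs_window <- cfg$window
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (partial bundle: %s)", name,
                   conditionMessage(e),
                   paste(names(bundle), collapse = ", ")), call. = FALSE)
    })
  }

  if (!is.null(dates)) {
    dates_f <- stage("filters", apply_filters(
      dates, curve, error_max = cfg$error_max, window_bce = cfg$window_pad
    ))
    bundle$audit <- attr(dates_f, "audit")
    bundle$summary_table <- stage("summary", summarize_dataset(dates_f))
    bundle$spd <- stage("spd", spd(dates_f, curve, axis,
                                   normalized = cfg$normalized))
    bundle$nulltest <- stage("nulltest", exp_null_test(
      dates_f, curve, axis, n_sim = cfg$null_n_sim
    ))
    regions <- sort(unique(dates_f$region))
    bundle$kde <- list(); bundle$growth <- list(); bundle$events <- list()
    for (r in regions) {
      d <- dates_f[dates_f$region == r, , drop = FALSE]
      if (nrow(d) < 2) next
      bundle$kde[[r]] <- stage(paste0("kde_", r), composite_kde(
        d, curve, axis, bandwidth = cfg$bandwidth, n_sim = cfg$n_sim
      ))
      bundle$growth[[r]] <- stage(paste0("growth_", r),
                                  kde_growth(bundle$kde[[r]],
                                             window = cfg$growth_window))
      bundle$events[[r]] <- stage(paste0("events_", r), detect_events(
        bundle$growth[[r]], k = cfg$event_k
      ))
    }
    bundle$correlations <- stage("correlations", correlation_tables(
      bundle$kde, bundle$growth, cfg$windows
    ))
  } else {
    bundle$skipped <- c(bundle$skipped, "radiocarbon")
    message("no dates supplied: radiocarbon stages skipped")
  }

  if (!is.null(artifacts)) {
    bundle$aoristic <- stage("aoristic", aoristic_sum(
      artifacts, cal_axis(cfg$window_pad[1], cfg$window_pad[2], 1),
      group_by = intersect(cfg$aoristic_group_by, names(artifacts)),
      typology = cfg$typology, contexts = cfg$contexts
    ))
  } else {
    bundle$skipped <- c(bundle$skipped, "aoristic")
    message("no artifacts supplied: aoristic stage skipped")
  }

  if (!is.null(pollen)) {
    pca <- stage("openness_pca", openness_pca(
      pollen, window = cfg$openness_window, open_taxa = cfg$open_taxa
    ))
    bundle$openness_pca <- pca
    rm_ids <- unique(pollen$record_id)
    rmap <- cfg$region_map
    if (is.null(rmap)) rmap <- stats::setNames(rep("ALL", length(rm_ids)), rm_ids)
    bundle$openness <- stage("openness_regional", regional_openness(
      pca, rmap, axis = cal_axis(cfg$openness_window[1],
                                 cfg$openness_window[2], cfg$openness_step),
      smooth = cfg$openness_smooth
    ))
  } else {
    bundle$skipped <- c(bundle$skipped, "openness")
    message("no pollen supplied: openness stage skipped")
  }

  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir, cfg, seed)
  }
  bundle
}

#' Default analysis configuration
#'
#' The tunable parameters of [run_full_analysis()] with their defaults:
#' observation window 2850--1700 BCE padded by 100 years, error cutoff
#' 100 14C yr, KDE bandwidth 50 yr with 1000 simulations, 25-yr growth
#' window, event threshold 1 SD, openness window 4800--700 BCE at 50-yr
#' resolution.
#'
#' @return named list of parameters.
#' @export
default_analysis_config <- function() {
  list(
    window = c(2850, 1700),
    window_pad = c(2950, 1600),
    windows = list(full = c(2850, 1700), MNB = c(2850, 2350),
                   LN = c(2350, 1700)),
    error_max = 100,
    normalized = TRUE,
    bandwidth = 50,
    n_sim = 1000,
    null_n_sim = 200,
    growth_window = 25,
    event_k = 1,
    aoristic_group_by = c("region", "category"),
    contexts = "grave",
    typology = default_typochronology(),
    openness_window = c(4800, 700),
    openness_step = 50,
    openness_smooth = TRUE,
    open_taxa = default_taxa_config()$open_taxa,
    region_map = NULL
  )
}

# pairwise correlation tables (detrended KDE | growth) per window
correlation_tables <- function(kde, growth, windows) {
  regs <- names(kde)
  if (length(regs) < 2) return(NULL)
  out <- list()
  for (w in names(windows)) {
    win <- windows[[w]]
    mk <- matrix(NA_real_, length(regs), length(regs),
                 dimnames = list(regs, regs))
    mg <- mk
    for (i in seq_along(regs)) {
      for (j in seq_len(i)) {
        a <- detrend_window(kde[[regs[i]]], win)
        b <- detrend_window(kde[[regs[j]]], win)
        mk[i, j] <- mk[j, i] <- window_pearson(a, b, win)
        mg[i, j] <- mg[j, i] <- window_pearson(
          as_series(growth[[regs[i]]]), as_series(growth[[regs[j]]]), win
        )
      }
    }
    out[[w]] <- list(detrended_kde = mk, growth = mg)
  }
  out
}

# detrend a KDE mean curve inside a window (helper for correlation tables)
detrend_window <- function(model, window) {
  df <- as_series(model)
  df <- df[df$year_bce <= window[1] & df$year_bce >= window[2], , drop = FALSE]
  detrend(df)
}

# write every bundle component as CSV with provenance header
write_bundle <- function(bundle, out_dir, cfg, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(package = paste0("paleodem ",
                                utils::packageVersion("paleodem")),
               seed = if (is.null(seed)) "none" else seed,
               config_hash = config_hash(cfg))
  wr <- function(obj, name) {
    write_series_csv(obj, file.path(out_dir, paste0(name, ".csv")), prov)
  }
  if (!is.null(bundle$spd)) wr(bundle$spd, "spd")
  for (r in names(bundle$kde)) wr(bundle$kde[[r]], paste0("kde_", r))
  for (r in names(bundle$growth)) wr(bundle$growth[[r]], paste0("growth_", r))
  for (r in names(bundle$events)) {
    write_csv_prov(as.data.frame(bundle$events[[r]]),
                   file.path(out_dir, paste0("events_", r, ".csv")), prov)
  }
  if (!is.null(bundle$aoristic)) {
    ao <- bundle$aoristic
    if (inherits(ao, "aoristic_series")) ao <- list(all = ao)
    for (g in names(ao)) wr(ao[[g]], paste0("aoristic_", g))
  }
  for (r in names(bundle$openness)) wr(bundle$openness[[r]], paste0("openness_", r))
  if (!is.null(bundle$summary_table)) {
    write_csv_prov(bundle$summary_table,
                   file.path(out_dir, "summary_table.csv"), prov)
  }
  invisible(out_dir)
}

# stable hash of the config (md5 of its deparsed form)
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}
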