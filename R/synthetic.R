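#' Ground-truth population trajectory for simulation
#'
#' Defines the relative population density per year from which synthetic
#' datable events are drawn, embodying the dates-as-data premise that
#' more intense occupation leaves more datable material.
#'
#' Families: `constant`; `exponential` (`density ~ exp(rate * t)` with
#' forward time t from the axis start, so positive rates grow toward the
#' present); `logistic` (`K / (1 + exp(-rate * (t - t_mid)))` with
#' `midpoint_bce` the inflection year); `piecewise` (step function from a
#' `segments` data.frame with `start_bce`, `end_bce`, `level`).
#'
#' @param axis calendar axis.
#' @param family trajectory family.
#' @param rate per-year rate for `exponential` / `logistic`.
#' @param midpoint_bce inflection year for `logistic`.
#' @param capacity carrying capacity K for `logistic` (default 1).
#' @param segments data.frame for `piecewise`; years outside all segments
#'   get level 0.
#' @return Object of class `pop_trajectory`: `axis`, `density`
#'   (relative, unnormalized), `family`, `params`.
#' @export
population_trajectory <- function(axis,
                                  family = c("constant", "exponential",
                                             "logistic", "piecewise"),
                                  rate = 0.001, midpoint_bce = NULL,
                                  capacity = 1, segments = NULL) {
  family <- match.arg(family)
  t_fwd <- axis$start_bce - axis$bce
  dens <- switch(family,
    constant = rep(1, length(axis$bce)),
    exponential = exp(rate * t_fwd),
    logistic = {
      if (is.null(midpoint_bce)) midpoint_bce <- (axis$start_bce + axis$end_bce) / 2
      capacity / (1 + exp(-rate * (t_fwd - (axis$start_bce - midpoint_bce))))
    },
    piecewise = {
      if (is.null(segments)) stop("piecewise trajectory needs a segments data.frame")
      v <- rep(0, length(axis$bce))
      for (i in seq_len(nrow(segments))) {
        sel <- axis$bce <= segments$start_bce[i] & axis$bce >= segments$end_bce[i]
        v[sel] <- segments$level[i]
      }
      v
    }
  )
  if (any(dens < 0) || all(dens == 0)) {
    stop("trajectory density must be >= 0 with at least one positive cell")
  }
  structure(
    list(axis = axis, density = dens, family = family,
         params = list(rate = rate, midpoint_bce = midpoint_bce,
                       capacity = capacity, segments = segments)),
    class = "pop_trajectory"
  )
}

#' @export
print.pop_trajectory <- function(x, ...) {
  cat(sprintf("Population trajectory (%s) on %d-%d BCE\n", x$family,
              as.integer(x$axis$start_bce), as.integer(x$axis$end_bce)))
  invisible(x)
}

#' @export
as.data.frame.pop_trajectory <- function(x, ...) {
  data.frame(year_bce = x$axis$bce, value = x$density)
}

#' Simulate a radiocarbon dataset from a known trajectory
#'
#' Draws `n` calendar events with probability proportional to the
#' trajectory density, forward-models each to a measured radiocarbon age
#' via [uncalibrate()], and attaches site labels drawn from a
#' k-category site-size distribution (Dirichlet-weighted, so
#' `concentration` tunes how evenly dates spread over sites). Seeded and
#' reproducible via the caller's RNG state.
#'
#' @param traj a [population_trajectory()].
#' @param n number of dates (>= 1).
#' @param curve calibration curve covering the trajectory axis.
#' @param lab_error_model list: `list(type = "fixed", value = 30)`,
#'   `list(type = "uniform", lo = , hi = )`, or
#'   `list(type = "empirical", errors = <vector>)` to mimic a real
#'   dataset's precision mix.
#' @param site_model list `list(k = <n sites>, concentration = 1)`.
#' @param region region code stamped on every record.
#' @return canonical date table (see [read_dates_csv()]) with attribute
#'   `provenance` (family, parameters) and `true_year_bce` column kept
#'   for validation.
#' @export
simulate_dates <- function(traj, n, curve,
                           lab_error_model = list(type = "fixed", value = 30),
                           site_model = list(k = 20, concentration = 1),
                           region = "SYN") {
  if (n < 1) stop("n must be >= 1")
  years <- sample(traj$axis$bce, n, replace = TRUE, prob = traj$density)
  errs <- switch(lab_error_model$type,
    fixed = rep(lab_error_model$value, n),
    uniform = stats::runif(n, lab_error_model$lo, lab_error_model$hi),
    empirical = sample(lab_error_model$errors, n, replace = TRUE),
    stop("unknown lab_error_model type")
  )
  meas <- uncalibrate(years, curve, errs)
  k <- site_model$k
  site_p <- stats::rgamma(k, shape = site_model$concentration)
  site_p <- site_p / sum(site_p)
  sites <- paste0("site_", sample.int(k, n, replace = TRUE, prob = site_p))
  out <- data.frame(
    lab_id = sprintf("SYN-%05d", seq_len(n)),
    c14_age = meas$c14_age, error = meas$error,
    site_id = sites, region = region,
    material = "short-lived", site_type = "settlement",
    true_year_bce = years,
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- list(generator = "simulate_dates",
                                  family = traj$family,
                                  params = traj$params, n = n)
  out
}

#' Simulate a typologically dated artifact assemblage
#'
#' Draws true deposition years proportional to the trajectory, optionally
#' jitters them (misdating), and assigns each the typochronology span
#' containing the year (ties broken toward the narrowest span, i.e. the
#' most precise type). The succession of categories — battle axes giving
#' way to flint daggers with a short overlap — emerges from the spans in
#' the typochronology table. Years covered by no span are dropped and
#' counted.
#'
#' @param traj a [population_trajectory()] of deposition intensity.
#' @param n number of artifacts.
#' @param typology typochronology table (see
#'   [default_typochronology()]).
#' @param categories optional restriction to these categories' spans.
#' @param misdating_jitter SD (years) of Gaussian jitter on the true year
#'   before span assignment (default 0).
#' @param region region code stamped on every record.
#' @return artifact table (see [read_artifacts_csv()]) with
#'   `true_year_bce` kept; attributes `n_dropped` and `provenance`.
#' @export
simulate_artifacts <- function(traj, n, typology = default_typochronology(),
                               categories = NULL, misdating_jitter = 0,
                               region = "SYN") {
  if (!is.null(categories)) {
    typology <- typology[typology$category %in% categories, , drop = FALSE]
  }
  validate_typochronology(typology)
  years <- sample(traj$axis$bce, n, replace = TRUE, prob = traj$density)
  assigned <- years
  if (misdating_jitter > 0) {
    assigned <- round(years + stats::rnorm(n, 0, misdating_jitter))
  }
  width <- typology$span_start - typology$span_end
  rows <- vapply(assigned, function(y) {
    hit <- which(typology$span_start >= y & typology$span_end <= y)
    if (length(hit) == 0) return(NA_integer_)
    hit[which.min(width[hit])]
  }, integer(1))
  dropped <- sum(is.na(rows))
  keep <- !is.na(rows)
  rows <- rows[keep]
  out <- data.frame(
    artifact_id = sprintf("ART-%05d", seq_len(sum(keep))),
    category = typology$category[rows],
    type_code = typology$type_code[rows],
    span_start = typology$span_start[rows],
    span_end = typology$span_end[rows],
    region = region, context = "grave",
    true_year_bce = years[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- dropped
  attr(out, "provenance") <- list(generator = "simulate_artifacts",
                                  family = traj$family,
                                  params = traj$params, n = n,
                                  misdating_jitter = misdating_jitter)
  out
}

#' Default pollen end-member profiles
#'
#' Taxon composition of the two vegetation end members used by
#' [simulate_pollen()]: a closed-canopy forest profile and an open-land
#' profile dominated by grasses and heather. Probability vectors over the
#' default taxa list.
#'
#' @return list with named numeric vectors `forest` and `open`.
#' @export
default_pollen_profiles <- function() {
  taxa <- default_taxa_config()$taxa
  forest <- stats::setNames(rep(0, length(taxa)), taxa)
  open <- forest
  forest[c("quercus", "tilia", "ulmus", "fagus", "betula", "alnus",
           "corylus", "fraxinus")] <-
    c(0.22, 0.18, 0.12, 0.12, 0.12, 0.10, 0.10, 0.04)
  open[c("poaceae", "calluna", "plantago_lanceolata", "rumex",
         "artemisia", "cerealia")] <-
    c(0.40, 0.25, 0.12, 0.08, 0.08, 0.07)
  list(forest = forest, open = open)
}

#' Simulate pollen records from a known openness trajectory
#'
#' Generates multinomial pollen counts from a two-end-member mixture: at
#' true age t the expected taxon proportions are
#' `o(t) * open_profile + (1 - o(t)) * forest_profile` with `o(t)` in
#' [0, 1]; each sample draws `grains` grains multinomially, and its
#' reported age is the true age plus Gaussian noise (emulating age-depth
#' model uncertainty).
#'
#' @param openness function of year BCE returning openness in [0, 1], or
#'   a data.frame `year_bce`, `value` interpolated linearly.
#' @param records number of records (cores).
#' @param samples_per_record samples per record, evenly spaced over the
#'   window.
#' @param window `c(oldest, youngest)` years BCE covered by each record.
#' @param grains grains counted per sample (default 300).
#' @param forest_profile,open_profile probability vectors over a shared
#'   taxa list (must each sum to 1).
#' @param age_jitter_sd SD (years) of the age noise (default 25).
#' @return pollen sample table (see [read_pollen_csv()]) with
#'   `true_age_bce` and `true_openness` kept; attribute `provenance`.
#' @export
simulate_pollen <- function(openness, records = 3, samples_per_record = 40,
                            window = c(4800, 700), grains = 300,
                            forest_profile = default_pollen_profiles()$forest,
                            open_profile = default_pollen_profiles()$open,
                            age_jitter_sd = 25) {
  if (abs(sum(forest_profile) - 1) > 1e-8 || abs(sum(open_profile) - 1) > 1e-8) {
    stop("end-member profiles must each sum to 1")
  }
  if (!identical(names(forest_profile), names(open_profile))) {
    stop("end-member profiles must share the same taxa list")
  }
  o_fun <- if (is.function(openness)) {
    openness
  } else {
    df <- as_series(openness)
    function(y) stats::approx(df$year_bce, df$value, xout = y, rule = 2)$y
  }
  taxa <- names(forest_profile)
  out <- list()
  for (rec in seq_len(records)) {
    true_age <- seq(window[1], window[2], length.out = samples_per_record)
    o <- pmin(1, pmax(0, o_fun(true_age)))
    counts <- t(vapply(seq_along(true_age), function(i) {
      p <- o[i] * open_profile + (1 - o[i]) * forest_profile
      as.numeric(stats::rmultinom(1, grains, p))
    }, numeric(length(taxa))))
    colnames(counts) <- taxa
    age_obs <- round(true_age + stats::rnorm(samples_per_record, 0, age_jitter_sd))
    age_obs <- pmax(1, age_obs)
    out[[rec]] <- data.frame(
      record_id = sprintf("core_%02d", rec),
      sample_id = sprintf("core_%02d_s%03d", rec, seq_along(true_age)),
      age_bce = age_obs, counts,
      true_age_bce = true_age, true_openness = o,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "taxa") <- taxa
  attr(res, "provenance") <- list(generator = "simulate_pollen",
                                  records = records,
                                  samples_per_record = samples_per_record,
                                  grains = grains,
                                  age_jitter_sd = age_jitter_sd)
  res
}
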