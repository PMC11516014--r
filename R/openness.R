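#' Default taxa configuration for the openness score
#'
#' Terrestrial pollen taxa used in the openness PCA, split into forest
#' (canopy) taxa and light-demanding open-land indicators. Grasses,
#' heather and ribwort plantain are the classic anthropogenic openness
#' indicators; the forest set covers the main north-European canopy
#' formers. Both lists are config, not doctrine: pass your own vectors.
#'
#' @return list with character vectors `taxa` (all selected terrestrial
#'   taxa) and `open_taxa` (declared open-land indicators).
#' @export
default_taxa_config <- function() {
  forest <- c("quercus", "tilia", "ulmus", "fagus", "betula", "alnus",
              "corylus", "fraxinus")
  open <- c("poaceae", "calluna", "plantago_lanceolata", "rumex",
            "artemisia", "cerealia")
  list(taxa = c(forest, open), open_taxa = open)
}

#' Vegetation-openness score via principal component analysis
#'
#' Computes the first principal component of the pollen proportion matrix
#' as a vegetation-openness score. Grain counts of the selected
#' terrestrial taxa are converted to proportions of their row sum
#' (absorbing count depth), optionally square-root transformed,
#' column-centered, and decomposed by SVD. The first axis separates
#' forest taxa from light-demanding taxa; its sign is fixed by the rule
#' that the mean PC1 loading of the declared open-indicator taxa is
#' positive, so higher scores always mean more open vegetation.
#'
#' Records can be withheld from the decomposition and only projected onto
#' it afterwards (`project_only`) — appropriate when a record lacks a key
#' discriminating taxon whose absence would distort the joint loading
#' structure, while its samples can still be scored for observation.
#'
#' @param pollen pollen sample table (see [read_pollen_csv()]).
#' @param taxa character vector of taxa to use; default from
#'   [default_taxa_config()], intersected with available columns.
#' @param window optional `c(oldest, youngest)` BCE limits on sample ages
#'   entering the PCA (the canonical analysis window is 4800--700 BCE).
#' @param open_taxa declared open-land indicator taxa (sign rule).
#' @param transform `"none"` (default) or `"sqrt"`.
#' @param project_only character vector of `record_id`s excluded from the
#'   decomposition and projected afterwards.
#' @return Object of class `openness_pca`: `scores` (data.frame
#'   `record_id`, `sample_id`, `age_bce`, `score`, `projected`),
#'   `loadings` (named PC1 vector), `center`, `sdev` (component standard
#'   deviations), `var_explained` (PC1 share), `taxa`, `open_taxa`.
#' @export
openness_pca <- function(pollen, taxa = NULL, window = c(4800, 700),
                         open_taxa = default_taxa_config()$open_taxa,
                         transform = c("none", "sqrt"),
                         project_only = NULL) {
  transform <- match.arg(transform)
  if (is.null(taxa)) taxa <- intersect(default_taxa_config()$taxa, names(pollen))
  taxa <- intersect(taxa, names(pollen))
  if (length(taxa) < 2) stop("need at least 2 selected taxa present in the table")
  keep <- rep(TRUE, nrow(pollen))
  if (!is.null(window)) {
    keep <- pollen$age_bce <= window[1] & pollen$age_bce >= window[2]
  }
  pollen <- pollen[keep, , drop = FALSE]
  M <- as.matrix(pollen[taxa])
  tot <- rowSums(M)
  if (any(tot <= 0)) stop("sample(s) with zero total count over the selected taxa")
  Pm <- M / tot
  if (transform == "sqrt") Pm <- sqrt(Pm)
  zero_var <- apply(Pm, 2, stats::sd) == 0
  fit_rows <- !(pollen$record_id %in% project_only)
  if (sum(fit_rows) < 2) stop("need at least 2 samples in the decomposition")
  # taxa absent from (or constant in) all fitted samples carry no signal
  drop <- apply(Pm[fit_rows, , drop = FALSE], 2, stats::sd) == 0
  if (all(drop)) stop("degenerate PCA: proportion matrix is constant")
  if (any(drop)) {
    warning("dropping constant/absent taxa: ", paste(taxa[drop], collapse = ", "))
    Pm <- Pm[, !drop, drop = FALSE]
    taxa <- taxa[!drop]
  }
  X <- Pm[fit_rows, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  loading <- sv$v[, 1]
  names(loading) <- taxa
  open_here <- intersect(open_taxa, taxa)
  if (length(open_here) > 0 && mean(loading[open_here]) < 0) {
    loading <- -loading
  }
  score_all <- as.numeric(sweep(Pm, 2, ctr) %*% loading)
  sdev <- sv$d / sqrt(max(1, nrow(Xc) - 1))
  structure(
    list(
      scores = data.frame(
        record_id = pollen$record_id, sample_id = pollen$sample_id,
        age_bce = pollen$age_bce, score = score_all,
        projected = !fit_rows, stringsAsFactors = FALSE
      ),
      loadings = loading, center = ctr, sdev = sdev,
      var_explained = sdev[1]^2 / sum(sdev^2),
      taxa = taxa, open_taxa = open_here
    ),
    class = "openness_pca"
  )
}

#' @export
print.openness_pca <- function(x, ...) {
  cat(sprintf(
    "Openness PCA: %d samples, %d records, %d taxa; PC1 explains %.1f%% of variance\n",
    nrow(x$scores), length(unique(x$scores$record_id)), length(x$taxa),
    100 * x$var_explained
  ))
  invisible(x)
}

#' @export
#' @describeIn openness_pca Diagnostic summary: variance explained and the
#'   separation of open-indicator from forest loadings on PC1. A weak
#'   separation (overlapping loading ranges or low PC1 variance share)
#'   means the openness gradient did not project onto the first axis and
#'   the score should not be interpreted as openness for that dataset.
summary.openness_pca <- function(object, ...) {
  open <- object$loadings[names(object$loadings) %in% object$open_taxa]
  forest <- object$loadings[!names(object$loadings) %in% object$open_taxa]
  out <- list(
    n_samples = nrow(object$scores),
    var_explained = object$var_explained,
    mean_open_loading = mean(open),
    mean_forest_loading = mean(forest),
    separation = min(open) - max(forest),
    gradient_projected = length(open) > 0 && length(forest) > 0 &&
      min(open) > max(forest)
  )
  class(out) <- "summary.openness_pca"
  out
}

#' @export
print.summary.openness_pca <- function(x, ...) {
  cat(sprintf(
    paste0("Openness PCA diagnostic (%d samples)\n",
           "  PC1 variance explained: %.1f%%\n",
           "  mean loading  open: %+.3f   forest: %+.3f\n",
           "  open/forest loading separation: %+.3f\n",
           "  openness gradient projected on PC1: %s\n"),
    x$n_samples, 100 * x$var_explained, x$mean_open_loading,
    x$mean_forest_loading, x$separation,
    if (x$gradient_projected) "yes" else "NO - do not interpret the score"
  ))
  invisible(x)
}

#' Project new pollen samples onto a fitted openness PCA
#'
#' @param object fitted `openness_pca`.
#' @param newdata pollen sample table containing the fitted taxa columns.
#' @param ... unused.
#' @return numeric openness scores.
#' @export
predict.openness_pca <- function(object, newdata, ...) {
  M <- as.matrix(newdata[object$taxa])
  tot <- rowSums(M)
  if (any(tot <= 0)) stop("sample(s) with zero total count over the fitted taxa")
  Pm <- M / tot
  as.numeric(sweep(Pm, 2, object$center) %*% object$loadings)
}

#' Regional openness time series
#'
#' Aggregates per-sample openness scores to a regional series on a 50-yr
#' grid: each record's scores are interpolated linearly onto the grid,
#' restricted to the record's own age span (no extrapolation); the
#' regional series is the unweighted mean across records per bin.
#' Bins where no record contributes are missing (`NA`), not zero.
#' Optional smoothing is a centered 3-bin moving average.
#'
#' @param pca fitted `openness_pca` (or its `scores` data.frame).
#' @param region_map named character vector mapping `record_id` to region
#'   code; records absent from the map are dropped.
#' @param axis calendar axis for the output; default 4800--700 BCE at a
#'   50-yr step.
#' @param smooth apply the 3-bin moving average (default FALSE).
#' @return named list of `openness_series` (one per region): `axis`,
#'   `value`, `n_records` contributing per bin, `smooth`.
#' @export
regional_openness <- function(pca, region_map,
                              axis = cal_axis(4800, 700, 50),
                              smooth = FALSE) {
  scores <- if (inherits(pca, "openness_pca")) pca$scores else pca
  scores <- scores[scores$record_id %in% names(region_map), , drop = FALSE]
  if (nrow(scores) == 0) stop("no scored samples match the region map")
  regions <- unique(unname(region_map[scores$record_id]))
  out <- list()
  for (reg in regions) {
    recs <- names(region_map)[region_map == reg]
    recs <- intersect(recs, unique(scores$record_id))
    mat <- sapply(recs, function(rid) {
      s <- scores[scores$record_id == rid, , drop = FALSE]
      s <- s[order(-s$age_bce), , drop = FALSE]
      if (nrow(s) < 2) {
        v <- rep(NA_real_, length(axis$bce))
        v[which.min(abs(axis$bce - s$age_bce[1]))] <- s$score[1]
        v
      } else {
        stats::approx(s$age_bce, s$score, xout = axis$bce, rule = 1)$y
      }
    })
    mat <- matrix(mat, nrow = length(axis$bce))
    n_rec <- rowSums(!is.na(mat))
    val <- ifelse(n_rec > 0, rowMeans(mat, na.rm = TRUE), NA_real_)
    if (smooth) val <- moving_average3(val)
    out[[reg]] <- structure(
      list(axis = axis, value = val, n_records = n_rec, smooth = smooth),
      class = "openness_series"
    )
  }
  out
}

# centered 3-bin moving average, NA-tolerant at the edges
moving_average3 <- function(x) {
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    j <- max(1, i - 1):min(n, i + 1)
    v <- x[j]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

#' @export
print.openness_series <- function(x, ...) {
  cat(sprintf(
    "Regional openness series on %d-%d BCE (step %d%s); %d non-missing bins\n",
    as.integer(x$axis$start_bce), as.integer(x$axis$end_bce),
    as.integer(x$axis$step), if (x$smooth) ", smoothed" else "",
    sum(!is.na(x$value))
  ))
  invisible(x)
}

#' @export
as.data.frame.openness_series <- function(x, ...) {
  data.frame(year_bce = x$axis$bce, value = x$value)
}
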