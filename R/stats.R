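#' Zonal summary table of scalar diffusion metrics
#'
#' Per-label volume fraction (percent of the parcellation support) and
#' mean +/- sd of each scalar map, matching the usual "Volume %, FA, MD,
#' AD, RD" zonal-table layout.  sd is the sample (n-1) standard deviation.
#'
#' @param maps a `scalar_maps`.
#' @param parcellation a `parcellation` on the same grid.
#' @return object of class `zonal_table`: a data frame with one row per
#'   label (`code`, `zone`, `part`, `n_voxels`, `volume_pct`, then
#'   `<metric>_mean` / `<metric>_sd` for FA, MD, AD, RD).
#' @export
zonal_summary <- function(maps, parcellation) {
  stopifnot(inherits(maps, "scalar_maps"), inherits(parcellation, "parcellation"))
  lab <- parcellation$labels
  if (!identical(dim(lab), dim(maps$FA)))
    stop("scalar maps and parcellation are on different grids")
  total <- sum(lab != 0L)
  tab <- parcellation$table
  out <- tab
  out$n_voxels <- NA_integer_
  out$volume_pct <- NA_real_
  for (metric in c("FA", "MD", "AD", "RD")) {
    out[[paste0(metric, "_mean")]] <- NA_real_
    out[[paste0(metric, "_sd")]] <- NA_real_
  }
  for (i in seq_len(nrow(tab))) {
    sel <- which(lab == tab$code[i])
    out$n_voxels[i] <- length(sel)
    out$volume_pct[i] <- 100 * length(sel) / total
    if (length(sel) == 0L) {
      warning("empty label ", tab$code[i], ": summary row is NA")
      next
    }
    for (metric in c("FA", "MD", "AD", "RD")) {
      v <- maps[[metric]][sel]
      out[[paste0(metric, "_mean")]][i] <- mean(v, na.rm = TRUE)
      out[[paste0(metric, "_sd")]][i] <- sd(v, na.rm = TRUE)
    }
  }
  class(out) <- c("zonal_table", "data.frame")
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: `F = (SSB/dfB) / (SSW/dfW)` with
#' `dfB = k - 1`, `dfW = N - k`; the p-value is the upper tail of the F
#' distribution.  When both the between- and within-group sums of squares
#' are zero (all observations identical) F is defined as 0 with p = 1.
#'
#' @param groups list of numeric vectors, one per group; at least 2 groups
#'   of at least 2 observations each.
#' @return list with `F`, `p`, `df` (c(dfB, dfW)), `ss` (c(SSB, SSW)).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop("every group needs at least two observations")
  k <- length(groups)
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, 1.0)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  dfb <- k - 1L
  dfw <- N - k
  if (ssw == 0 && ssb == 0) {
    Fstat <- 0; p <- 1
  } else if (ssw == 0) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- (ssb / dfb) / (ssw / dfw)
    p <- pf(Fstat, dfb, dfw, lower.tail = FALSE)
  }
  list(F = Fstat, p = p, df = c(dfb, dfw), ss = c(ssb, ssw))
}

#' Zone-wise ANOVA of a scalar metric
#'
#' Compares a metric across parcellation labels.  The primary unit is the
#' per-specimen per-zone mean (pass a list of `zonal_table`s, one per
#' specimen); a pooled voxelwise variant is available for a single dataset
#' but is anti-conservative (voxels are not independent) and flagged as
#' such in the result.
#'
#' @param x either a list of `zonal_table`s (specimen-mean mode) or a
#'   single `scalar_maps` (voxelwise mode, requires `parcellation`).
#' @param metric one of `"FA"`, `"MD"`, `"AD"`, `"RD"`.
#' @param parcellation required in voxelwise mode.
#' @return the [one_way_anova()] result plus `unit` (`"specimen_mean"` or
#'   `"voxel_pooled"`).
#' @export
zone_anova <- function(x, metric = "FA", parcellation = NULL) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "zonal_table"))) {
    col <- paste0(metric, "_mean")
    codes <- x[[1]]$code
    groups <- lapply(codes, function(cd)
      vapply(x, function(tb) tb[[col]][tb$code == cd], 1.0))
    res <- one_way_anova(groups)
    res$unit <- "specimen_mean"
  } else if (inherits(x, "scalar_maps")) {
    if (is.null(parcellation)) stop("voxelwise mode needs a parcellation")
    lab <- parcellation$labels
    groups <- lapply(parcellation$table$code, function(cd) {
      v <- x[[metric]][lab == cd]
      v[!is.na(v)]
    })
    res <- one_way_anova(groups)
    res$unit <- "voxel_pooled"
    res$note <- "voxelwise pooling is anti-conservative: voxels are not independent"
  } else stop("x must be a list of zonal_tables or a scalar_maps")
  res
}

#' Percent change relative to a reference value
#'
#' `(value - reference) / |reference| * 100`.
#'
#' @param reference nonzero reference value.
#' @param value new value.
#' @return percent change (positive = increase).
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("domain error: reference must be nonzero")
  (value - reference) / abs(reference) * 100
}
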