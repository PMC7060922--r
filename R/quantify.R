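#' Normalised HA/GFP translocation ratios
#'
#' Computes the per-field ratio of surface (HA) to total (GFP) reporter
#' signal and normalises it so that unstimulated cells equal 1: either
#' each treatment group to its own basal mean (`"per_group"`, the
#' per-siRNA convention) or every group to the control group's basal mean
#' (`"control_basal"`, the cross-group convention that exposes basal
#' surface elevation).
#'
#' Fields with non-positive GFP are excluded; their ids are recorded in
#' the `"excluded"` attribute of the result.
#'
#' @param measurements Data frame from [measure_fields()] with columns
#'   `field_id`, `treatment`, `stimulation`, `mean_HA`, `mean_GFP`.
#' @param normalise `"per_group"` or `"control_basal"`.
#' @param control Treatment label of the control group.
#' @return The input data frame plus `ratio` and `norm_ratio` columns
#'   (excluded fields dropped).
#' @export
ha_gfp_ratio <- function(measurements,
                         normalise = c("per_group", "control_basal"),
                         control = "SCR") {
  normalise <- match.arg(normalise)
  req <- c("field_id", "treatment", "stimulation", "mean_HA", "mean_GFP")
  if (!all(req %in% names(measurements)))
    stop("measurements must contain: ", paste(req, collapse = ", "))
  bad <- !is.finite(measurements$mean_GFP) | measurements$mean_GFP <= 0
  excluded <- measurements$field_id[bad]
  if (length(excluded))
    warning(sprintf("%d field(s) excluded (non-positive GFP): %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  m <- measurements[!bad, , drop = FALSE]
  if (!any(m$stimulation == "basal"))
    stop("at least one basal field per treatment group is required")
  m$ratio <- m$mean_HA / m$mean_GFP
  if (normalise == "per_group") {
    base <- tapply(m$ratio[m$stimulation == "basal"],
                   m$treatment[m$stimulation == "basal"], mean)
    if (!all(unique(m$treatment) %in% names(base)))
      stop("every treatment group needs at least one basal field")
    m$norm_ratio <- m$ratio / base[m$treatment]
  } else {
    sel <- m$treatment == control & m$stimulation == "basal"
    if (!any(sel))
      stop(sprintf("no basal fields for control group \"%s\"", control))
    m$norm_ratio <- m$ratio / mean(m$ratio[sel])
  }
  rownames(m) <- NULL
  attr(m, "excluded") <- excluded
  m
}

#' Normalised GFP/DAPI abundance ratios
#'
#' Per-field GFP/DAPI ratio (a proxy for total reporter per cell mass),
#' normalised to the control group's mean.  Fields with non-positive DAPI
#' are excluded and recorded in the `"excluded"` attribute.
#'
#' @param measurements Data frame with `field_id`, `treatment`,
#'   `mean_GFP`, `mean_DAPI`.
#' @param control Treatment label of the control group.
#' @return The input plus `ratio` and `norm_ratio` columns.
#' @export
gfp_dapi_ratio <- function(measurements, control = "SCR") {
  req <- c("field_id", "treatment", "mean_GFP", "mean_DAPI")
  if (!all(req %in% names(measurements)))
    stop("measurements must contain: ", paste(req, collapse = ", "))
  bad <- !is.finite(measurements$mean_DAPI) | measurements$mean_DAPI <= 0
  excluded <- measurements$field_id[bad]
  if (length(excluded))
    warning(sprintf("%d field(s) excluded (non-positive DAPI): %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  m <- measurements[!bad, , drop = FALSE]
  m$ratio <- m$mean_GFP / m$mean_DAPI
  sel <- m$treatment == control
  if (!any(sel))
    stop(sprintf("no fields for control group \"%s\"", control))
  m$norm_ratio <- m$ratio / mean(m$ratio[sel])
  rownames(m) <- NULL
  attr(m, "excluded") <- excluded
  m
}

#' Colocalisation coefficients for a channel pair
#'
#' Pearson correlation over the analysed pixels and Manders coefficients:
#' `M1` is the fraction of channel-1 intensity in pixels where channel 2
#' exceeds its threshold, `M2` symmetrically.  Thresholds default to
#' per-channel Otsu.
#'
#' @param ch1,ch2 Co-registered numeric matrices of equal shape.
#' @param mask Optional logical matrix restricting the analysis.
#' @param thresholds `"otsu"`, or a numeric vector of two channel
#'   thresholds (use `c(0, 0)` for strictly-positive support).
#' @return List of class `coloc_result`: `pearson_r`, `manders_m1`,
#'   `manders_m2`, `thresholds`, `flags` (character vector, e.g. a
#'   constant channel makes Pearson undefined).
#' @export
coloc <- function(ch1, ch2, mask = NULL, thresholds = "otsu") {
  if (!is.matrix(ch1) || !is.matrix(ch2) ||
      !identical(dim(ch1), dim(ch2)))
    stop("ch1 and ch2 must be co-registered matrices of equal shape")
  sel <- if (is.null(mask)) rep(TRUE, length(ch1)) else as.vector(mask)
  v1 <- as.vector(ch1)[sel]; v2 <- as.vector(ch2)[sel]
  otsu_thr <- function(v) {
    rng <- range(v)
    if (diff(rng) <= 0) return(rng[1])
    EBImage::otsu(EBImage::Image(matrix((v - rng[1]) / diff(rng))),
                  range = c(0, 1)) * diff(rng) + rng[1]
  }
  thr <- if (identical(thresholds, "otsu")) c(otsu_thr(v1), otsu_thr(v2))
    else if (is.numeric(thresholds) && length(thresholds) == 2) thresholds
    else if (is.numeric(thresholds) && length(thresholds) == 1)
      rep(thresholds, 2)
    else stop("thresholds must be \"otsu\" or numeric")
  flags <- character(0)
  r <- if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    flags <- c(flags, "pearson undefined: constant channel")
    NA_real_
  } else stats::cor(v1, v2)
  m1 <- if (sum(v1) > 0) sum(v1[v2 > thr[2]]) / sum(v1) else NA_real_
  m2 <- if (sum(v2) > 0) sum(v2[v1 > thr[1]]) / sum(v2) else NA_real_
  structure(list(pearson_r = r, manders_m1 = m1, manders_m2 = m2,
                 thresholds = thr, flags = flags),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalisation: Pearson r = %.3f, M1 = %.3f, M2 = %.3f\n",
              x$pearson_r, x$manders_m1, x$manders_m2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Group comparison statistics
#'
#' Pairwise designs use Welch's unequal-variance two-sample t-test;
#' factorial screen designs use two-way ANOVA with interaction.
#'
#' @param values For `design = "pairwise"`: a named list of two numeric
#'   vectors.  For `design = "two_way"`: a data frame with columns
#'   `value`, `f1`, `f2`.
#' @param design `"pairwise"` or `"two_way"`.
#' @return Data frame with `term`, `statistic`, `df` (and `df2` for the
#'   ANOVA), `p`, `flag`.
#' @export
compare_groups <- function(values, design = c("pairwise", "two_way")) {
  design <- match.arg(design)
  if (design == "pairwise") {
    if (!is.list(values) || length(values) != 2)
      stop("pairwise design needs a list of two numeric vectors")
    a <- values[[1]]; b <- values[[2]]
    flag <- ""
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(term = "group", statistic = NA_real_,
                        df = NA_real_, p = NA_real_,
                        flag = "degenerate: fewer than 2 observations"))
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b))
        return(data.frame(term = "group", statistic = 0, df = NA_real_,
                          p = 1, flag = "zero variance in both groups"))
      return(data.frame(term = "group", statistic = Inf, df = NA_real_,
                        p = 0, flag = "zero variance in both groups"))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(term = "group", statistic = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, flag = flag)
  } else {
    if (!is.data.frame(values) ||
        !all(c("value", "f1", "f2") %in% names(values)))
      stop("two-way design needs a data frame with value, f1, f2")
    values$f1 <- factor(values$f1); values$f2 <- factor(values$f2)
    fit <- stats::aov(value ~ f1 * f2, data = values)
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))
    keep <- terms != "Residuals"
    data.frame(term = terms[keep], statistic = tab[keep, "F value"],
               df = tab[keep, "Df"],
               df2 = tab["Residuals", "Df"],
               p = tab[keep, "Pr(>F)"], flag = "")
  }
}
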