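#' @import ggplot2
NULL

.withPlotData <- function(p, data) {
  attr(p, "plotData") <- data
  p
}

#' Extract the machine-readable data behind a plot
#'
#' Every plotting function attaches the exact table it renders, so plots
#' can be tested and re-rendered without pixel comparison.
#'
#' @param p a plot returned by one of the `plot*` functions.
#' @return `data.frame`.
#' @export
plotData <- function(p) attr(p, "plotData")

#' Per-sample mutation frequency plot
#'
#' Bar plot of MF per group (typically per sample) with Min and Max
#' frequencies shown side by side or stacked.
#'
#' @param mf an [MFResult-class] at resolution `"none"`.
#' @param fill optional record column used for bar colour.
#' @param display `"both"`, `"min"` or `"max"`; `"stacked"` stacks the
#'   Max excess on top of Min.
#' @return `ggplot` object with a `plotData` attribute.
#' @export
plotMF <- function(mf, fill = NULL, display = c("both", "min", "max",
                                                "stacked")) {
  display <- match.arg(display)
  d <- mfData(mf)
  xvar <- mf@grouping[1L]
  long <- rbind(
    data.frame(d[mf@grouping], mf_type = "min", mf = d$mf_min,
               count = d$sum_min),
    data.frame(d[mf@grouping], mf_type = "max", mf = d$mf_max,
               count = d$sum_max))
  if (display == "min") long <- long[long$mf_type == "min", ]
  if (display == "max") long <- long[long$mf_type == "max", ]
  p <- ggplot(long, aes(x = .data[[xvar]], y = .data$mf,
                        fill = .data$mf_type)) +
    geom_col(position = if (display == "stacked") "stack" else "dodge") +
    labs(y = "mutation frequency (mutations/bp)", x = xvar) +
    theme_minimal()
  .withPlotData(p, long)
}

#' Mean mutation frequency per group with SEM error bars
#'
#' @param mf an [MFResult-class] at resolution `"none"` grouped by sample
#'   plus a group variable.
#' @param group column defining the means (e.g. `"dose"`).
#' @return `ggplot` with `plotData` containing `mean_mf_min`,
#'   `mean_mf_max` and their SEMs.
#' @export
plotMeanMF <- function(mf, group) {
  d <- mfData(mf)
  if (!group %in% names(d)) stop("group column absent: ", group)
  sem <- function(x) stats::sd(x) / sqrt(sum(!is.na(x)))
  agg <- do.call(rbind, lapply(split(d, d[[group]]), function(g) {
    data.frame(group = g[[group]][1L],
               mean_mf_min = mean(g$mf_min, na.rm = TRUE),
               sem_mf_min = sem(g$mf_min),
               mean_mf_max = mean(g$mf_max, na.rm = TRUE),
               sem_mf_max = sem(g$mf_max), n = nrow(g))
  }))
  names(agg)[1L] <- group
  rownames(agg) <- NULL
  p <- ggplot(agg, aes(x = factor(.data[[group]]),
                       y = .data$mean_mf_min)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$mean_mf_min - .data$sem_mf_min,
                      ymax = .data$mean_mf_min + .data$sem_mf_min),
                  width = 0.2) +
    labs(x = group, y = "mean MF (mutations/bp)") + theme_minimal()
  .withPlotData(p, agg)
}

#' Model-estimated mean MF plot
#'
#' @param fit a [ModelFit-class].
#' @return `ggplot` with `plotData` = the per-level estimate table.
#' @export
plotModelMF <- function(fit) {
  lev <- estimateLevels(fit)
  xvar <- names(lev)[1L]
  p <- ggplot(lev, aes(x = factor(.data[[xvar]]), y = .data$estimate)) +
    geom_col(fill = "lightblue") +
    geom_errorbar(aes(ymin = .data$estimate - .data$se,
                      ymax = .data$estimate + .data$se), width = 0.2) +
    labs(x = xvar, y = "estimated mean MF") + theme_minimal()
  .withPlotData(p, lev)
}

#' BMD confidence-interval plot
#'
#' @param bmds named list of [BmdResult-class] objects (one per endpoint
#'   or chemical).
#' @return `ggplot` with `plotData` columns `label`, `bmd`, `bmdl`,
#'   `bmdu`.
#' @export
plotCI <- function(bmds) {
  if (methods::is(bmds, "BmdResult")) bmds <- list(BMD = bmds)
  d <- do.call(rbind, lapply(names(bmds), function(nm) {
    b <- bmds[[nm]]
    data.frame(label = nm, bmd = b@bmd, bmdl = b@bmdl, bmdu = b@bmdu)
  }))
  p <- ggplot(d, aes(y = .data$label)) +
    geom_segment(aes(x = .data$bmdl, xend = .data$bmdu,
                     yend = .data$label)) +
    geom_point(aes(x = .data$bmd), size = 3) +
    geom_point(aes(x = .data$bmdl), colour = "red") +
    geom_point(aes(x = .data$bmdu), colour = "blue") +
    labs(x = "dose", y = NULL) + theme_minimal()
  .withPlotData(p, d)
}

#' Stacked mutation-spectrum plot
#'
#' Stacked bars of subtype proportion (or count / frequency) per group.
#'
#' @param mf a subtype-resolved [MFResult-class].
#' @param value `"proportion"`, `"proportion_raw"`, `"sum_min"` or
#'   `"mf_min"`.
#' @return `ggplot` with `plotData` columns group, `subtype`, `value`.
#' @export
plotSpectra <- function(mf, value = "proportion") {
  d <- mfData(mf)
  if (!value %in% names(d)) stop("value column absent: ", value)
  g <- mf@grouping[length(mf@grouping)]
  pd <- data.frame(group = d[[g]], subtype = d$subtype, value = d[[value]])
  p <- ggplot(pd, aes(x = factor(.data$group), y = .data$value,
                      fill = .data$subtype)) +
    geom_col(position = "stack") +
    labs(x = g, y = value) + theme_minimal()
  .withPlotData(p, pd)
}

#' COSMIC-style 96-channel trinucleotide spectrum plot
#'
#' One bar per canonical channel, facetted by group, coloured by the
#' six-base subtype, mirroring COSMIC trinucleotide plot aesthetics.
#'
#' @inheritParams plotSpectra
#' @return `ggplot`; `plotData` has 96 rows per group in canonical order.
#' @export
plotTrinucleotide <- function(mf, value = "proportion") {
  d <- mfData(mf)
  if (mf@resolution != "96") stop("requires an MFResult at resolution 96")
  g <- mf@grouping[length(mf@grouping)]
  d <- d[d$subtype %in% sbsChannels(), ]
  pd <- data.frame(group = d[[g]], subtype = d$subtype,
                   class = substr(d$subtype, 3, 5), value = d[[value]])
  pd$subtype <- factor(pd$subtype, levels = sbsChannels())
  pd <- pd[order(pd$group, pd$subtype), ]
  rownames(pd) <- NULL
  p <- ggplot(pd, aes(x = .data$subtype, y = .data$value,
                      fill = .data$class)) +
    geom_col() + facet_wrap(~group, ncol = 1) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, size = 4)) +
    labs(x = NULL, y = value)
  .withPlotData(p, pd)
}

#' Heatmap of 96-channel proportions
#'
#' @inheritParams plotSpectra
#' @return `ggplot` (tile heatmap); `plotData` as in
#'   [plotTrinucleotide()].
#' @export
plotTrinucleotideHeatmap <- function(mf, value = "proportion") {
  p0 <- plotTrinucleotide(mf, value)
  pd <- plotData(p0)
  p <- ggplot(pd, aes(x = .data$subtype, y = factor(.data$group),
                      fill = .data$value)) +
    geom_tile() + theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, size = 4)) +
    labs(x = NULL, y = NULL)
  .withPlotData(p, pd)
}

#' Radar plot of mutation frequency by category
#'
#' @param mf an [MFResult-class] (e.g. grouped by region and dose).
#' @param axis column plotted around the circle (e.g. `"region"`).
#' @param facet optional faceting column (e.g. `"dose"`).
#' @return `ggplot` (polar bar chart); `plotData` = the plotted table.
#' @export
plotRadar <- function(mf, axis, facet = NULL) {
  d <- mfData(mf)
  if (!axis %in% names(d)) stop("axis column absent: ", axis)
  pd <- data.frame(axis = d[[axis]], mf_min = d$mf_min)
  if (!is.null(facet)) pd$facet <- d[[facet]]
  p <- ggplot(pd, aes(x = .data$axis, y = .data$mf_min)) +
    geom_col(fill = "firebrick", alpha = 0.6) + coord_polar() +
    theme_minimal() + labs(x = NULL, y = "MF (mutations/bp)")
  if (!is.null(facet)) p <- p + facet_wrap(~facet)
  .withPlotData(p, pd)
}

#' Bubble plot of individual mutations
#'
#' One circle per mutation record, sized by `alt_depth` or VAF, so clonal
#' multiplets stand out; facetted by group.
#'
#' @param x a [MutationSet-class].
#' @param group record column used for facets (e.g. `"dose"`).
#' @param size `"alt_depth"` or `"vaf"`.
#' @param colour record column for circle colour (default the 6-base
#'   subtype / variation type).
#' @return `ggplot`; `plotData` has one row per plotted mutation.
#' @export
plotBubbles <- function(x, group = "sample", size = c("alt_depth", "vaf"),
                        colour = NULL) {
  size <- match.arg(size)
  rec <- mutData(x)
  rec <- rec[!rec$filter_mut & rec$variation_type %in% .MUTATION_TYPES, ]
  col <- if (is.null(colour)) {
    ifelse(rec$variation_type == "snv", rec$normalized_subtype,
           rec$variation_type)
  } else rec[[colour]]
  pd <- data.frame(group = rec[[group]], contig = rec$contig,
                   start = rec$start, ref = rec$ref, alt = rec$alt,
                   sample = rec$sample, size = rec[[size]], colour = col)
  p <- ggplot(pd, aes(x = .data$start, y = .data$sample,
                      size = .data$size, colour = .data$colour)) +
    geom_point(alpha = 0.6) + facet_wrap(~group) + theme_minimal() +
    labs(x = "position", size = size)
  .withPlotData(p, pd)
}
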