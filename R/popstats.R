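# Population-level analysis: fitness-distribution KDE and peak isolation,
# dip unimodality test, heterogeneity entropies, signaling classification,
# incidence tables.

#' Kernel density estimate of a fitness distribution with peak isolation
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth, evaluated on a
#' 512-point grid spanning the data range plus 3 bandwidths on each side.
#' Peaks are strict local maxima of the evaluated density; for each peak
#' the genotype sample window is all input values within two times the
#' bandwidth of the peak location.
#'
#' @param values numeric vector of fitness values (length >= 2, unless all
#'   values are identical).
#' @param bw optional bandwidth override.
#' @param gridSize number of evaluation points.
#' @return An object of class \code{"fitnessKde"}: list with \code{x},
#'   \code{y} (density curve), \code{bw}, \code{peaks} (data.frame with
#'   \code{location}, \code{density}, sorted by ascending location), and
#'   \code{samples} (list of integer index vectors into \code{values},
#'   one per peak, values within the 2-bandwidth window).
#' @export
fitnessKde <- function(values, bw = NULL, gridSize = 512) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (length(unique(values)) == 1L) {
    loc <- values[1]
    bw <- if (is.null(bw)) max(abs(loc) * 1e-6, 1e-9) else bw
    out <- list(x = loc, y = Inf, bw = bw,
                peaks = data.frame(location = loc, density = Inf),
                samples = list(seq_along(values)))
    class(out) <- "fitnessKde"
    return(out)
  }
  if (is.null(bw)) bw <- stats::bw.nrd0(values)
  d <- stats::density(values, bw = bw, n = gridSize, cut = 3)
  y <- d$y
  isMax <- which(diff(sign(diff(y))) == -2) + 1L   # strict local maxima
  if (!length(isMax)) isMax <- which.max(y)
  ord <- order(d$x[isMax])
  locs <- d$x[isMax][ord]
  out <- list(
    x = d$x, y = y, bw = bw,
    peaks = data.frame(location = locs, density = y[isMax][ord]),
    samples = lapply(locs, function(p) which(abs(values - p) <= 2 * bw)))
  class(out) <- "fitnessKde"
  out
}

#' @export
print.fitnessKde <- function(x, ...) {
  cat("Fitness KDE: bandwidth", format(x$bw, digits = 4), "with",
      nrow(x$peaks), "peak(s) at",
      paste(format(x$peaks$location, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Hartigan dip test of unimodality
#'
#' Computes the dip statistic -- the largest vertical deviation between
#' the empirical cdf and the closest unimodal (convex-then-concave) cdf --
#' and a p-value from a seeded bootstrap under the uniform null, against
#' the alternative that the distribution is multimodal.
#'
#' @param x numeric sample (n >= 4 for a meaningful test).
#' @param B number of bootstrap null samples.
#' @return A list of class \code{"htest"} with \code{statistic},
#'   \code{p.value}, \code{method} and \code{data.name}.
#' @examples
#' set.seed(1)
#' dipTest(runif(200))$p.value          # unimodal: large p
#' dipTest(c(rnorm(100), rnorm(100, 8)))$p.value  # bimodal: small p
#' @export
dipTest <- function(x, B = 500) {
  dn <- deparse(substitute(x))
  x <- x[is.finite(x)]
  stopifnot(length(x) >= 4)
  stat <- cpp_dip(x)
  n <- length(x)
  null <- vapply(seq_len(B), function(i) cpp_dip(runif(n)), numeric(1))
  p <- (1 + sum(null >= stat)) / (B + 1)
  structure(list(statistic = c(dip = stat), p.value = p,
                 method = "Hartigan dip test (uniform-null bootstrap)",
                 alternative = "multimodal",
                 data.name = dn, B = B),
            class = "htest")
}

#' Dip statistic only
#'
#' @param x numeric sample.
#' @return The dip statistic.
#' @export
dipStatistic <- function(x) cpp_dip(x[is.finite(x)])

#' Genotypic heterogeneity of a population (nats)
#'
#' Sum over the 120 genome sites of the per-site Shannon entropy of
#' instruction frequencies: for site i with instruction frequencies
#' p_j, s_i = -sum_j p_j ln p_j, and the heterogeneity is sum_i s_i.
#' Zero for a monoclonal population; at most 120 ln 32.
#'
#' @param x character vector of genome strings, or a
#'   [PopulationSnapshot-class].
#' @return Heterogeneity in nats.
#' @export
genotypicHeterogeneity <- function(x) {
  if (is(x, "PopulationSnapshot")) x <- genomes(x)
  stopifnot(length(x) >= 1)
  parseGenome(x)
  m <- matrix(unlist(strsplit(x, ""), use.names = FALSE),
              nrow = length(x), byrow = TRUE)
  sum(apply(m, 2, function(col) {
    p <- tabulate(factor(col, levels = unique(col)))
    p <- p / sum(p)
    -sum(p * log(p))
  }))
}

#' Phenotypic heterogeneity of a population (nats)
#'
#' Shannon entropy of the distribution of organisms over the 512 possible
#' phenotype classes.  Zero when the population is a single phenotype;
#' ln 512 when evenly spread over all 512 classes.
#'
#' @param x integer vector of phenotype class indices (1..512, from
#'   [phenotypeClass()]), a logical matrix with 9 columns, or a
#'   [PopulationSnapshot-class] (whose genomes are profiled with
#'   [phenotypeProfile()]).
#' @param ... passed to [phenotypeProfile()] for snapshot input.
#' @return Heterogeneity in nats, in [0, ln 512].
#' @export
phenotypicHeterogeneity <- function(x, ...) {
  if (is(x, "PopulationSnapshot")) {
    g <- genomes(x)
    ug <- unique(g)
    cls <- phenotypeProfile(ug, ...)$class[match(g, ug)]
  } else if (is.matrix(x)) {
    cls <- phenotypeClass(x)
  } else {
    cls <- as.integer(x)
    stopifnot(all(cls >= 1), all(cls <= 512))
  }
  p <- tabulate(cls, nbins = 512)
  p <- p[p > 0] / sum(p)
  -sum(p * log(p))
}

#' Threshold separating signaling from non-signaling populations
#'
#' Pools marginal utilities of messaging over genotypes, fits a KDE, and
#' identifies the peak nearest zero and the densest positive-shifted
#' peak; the threshold is the midpoint of the two peak locations.  When
#' fewer than two peaks are found the configured fallback is used, with a
#' warning.
#'
#' @param utilities numeric vector of pooled marginal utilities.
#' @param fallback threshold used when the pooled distribution does not
#'   separate into two peaks.
#' @return The threshold (numeric scalar), with attribute \code{"peaks"}.
#' @export
signalingThreshold <- function(utilities, fallback = 0.05) {
  utilities <- utilities[is.finite(utilities)]
  k <- fitnessKde(utilities)
  pk <- k$peaks
  if (nrow(pk) < 2) {
    warning("pooled utility distribution has fewer than two peaks; ",
            "using fallback threshold ", fallback)
    return(structure(fallback, peaks = pk))
  }
  zero <- which.min(abs(pk$location))
  pos <- pk[pk$location > pk$location[zero], , drop = FALSE]
  if (nrow(pos) == 0) {
    warning("no positive-shifted utility peak; using fallback threshold ",
            fallback)
    return(structure(fallback, peaks = pk))
  }
  shifted <- pos$location[which.max(pos$density)]
  structure((pk$location[zero] + shifted) / 2, peaks = pk)
}

#' Classify populations as signaling-positive or non-signaling
#'
#' Each population is summarized by the median marginal utility of
#' messaging over its genotypes; utilities from all populations are
#' pooled to locate the two-peak threshold (see [signalingThreshold()]),
#' and a population is labelled signaling-positive when its median
#' exceeds the threshold.  The classification is invariant to the order
#' of the populations.
#'
#' @param utilities a list of numeric vectors (one per population) of
#'   per-genotype marginal utilities of messaging, or a list of
#'   [PopulationSnapshot-class] objects (utilities are then computed with
#'   [marginalUtility()] on up to \code{maxGenotypes} most frequent
#'   genotypes per population).
#' @param threshold optional fixed threshold; when NULL it is derived
#'   from the pooled utilities.
#' @param fallback fallback threshold, see [signalingThreshold()].
#' @param maxGenotypes cap on genotypes assayed per snapshot population.
#' @param seed assay seed for snapshot input.
#' @return data.frame with one row per population: \code{median} utility
#'   and logical \code{signaling}; the threshold used is attached as
#'   attribute \code{"threshold"}.
#' @export
classifySignaling <- function(utilities, threshold = NULL, fallback = 0.05,
                              maxGenotypes = 5, seed = 1) {
  if (length(utilities) && is(utilities[[1]], "PopulationSnapshot")) {
    utilities <- lapply(utilities, function(s) {
      g <- genomes(s)
      tab <- sort(table(g), decreasing = TRUE)
      top <- names(tab)[seq_len(min(maxGenotypes, length(tab)))]
      marginalUtility(top, "messaging", seed = seed)
    })
  }
  stopifnot(length(utilities) >= 1)
  if (is.null(threshold)) {
    pooled <- unlist(utilities, use.names = FALSE)
    threshold <- signalingThreshold(pooled, fallback = fallback)
  }
  med <- vapply(utilities, function(u) median(u[is.finite(u)]), numeric(1))
  structure(
    data.frame(median = med, signaling = med > as.numeric(threshold)),
    threshold = as.numeric(threshold))
}

#' Incidence of signaling populations over a condition grid
#'
#' Counts signaling-positive populations per (world size, resource) cell,
#' excluding extinct runs from the denominator and reporting them
#' separately.
#'
#' @param runs data.frame with columns \code{worldSize}, \code{resource},
#'   logical \code{signaling}, and optionally logical \code{extinct}.
#' @return data.frame keyed by (worldSize, resource) with columns
#'   \code{runs}, \code{signaling}, \code{extinct}.
#' @export
incidenceTable <- function(runs) {
  stopifnot(all(c("worldSize", "resource", "signaling") %in% names(runs)))
  if (is.null(runs$extinct)) runs$extinct <- FALSE
  key <- interaction(runs$worldSize, runs$resource, drop = TRUE)
  out <- do.call(rbind, lapply(split(runs, key), function(d) {
    alive <- d[!d$extinct, , drop = FALSE]
    data.frame(worldSize = d$worldSize[1], resource = d$resource[1],
               runs = nrow(alive), signaling = sum(alive$signaling),
               extinct = sum(d$extinct))
  }))
  rownames(out) <- NULL
  out[order(out$worldSize, out$resource), ]
}

#' Standard deviation of assayed fitness within a population
#'
#' @param fitness numeric vector of per-genotype fitness values.
#' @return Standard deviation (0 for a single value).
#' @export
fitnessSd <- function(fitness) {
  f <- fitness[is.finite(fitness)]
  if (length(f) < 2) return(0)
  sd(f)
}
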