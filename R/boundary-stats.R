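#' Penetrance: classify embryos as defected or wild-type-like
#'
#' An embryo counts as defected if it has at least one defected boundary on
#' either side within the scoring range; otherwise it shows the wild-type
#' phenotype. Embryos whose phenotypes are all NA within the range are
#' excluded with a warning.
#'
#' @param table A [boundary_table()].
#' @param range Length-2 integer vector, inclusive boundary-index interval
#'   (default `c(11, 30)`).
#' @return A `penetrance_summary` data frame: one row per condition with
#'   `n_embryos`, `n_defected` and `fraction_defected`.
#' @export
classify_embryos <- function(table, range = c(11L, 30L)) {
  stopifnot(inherits(table, "boundary_table"), length(range) == 2L)
  if (!nrow(table)) stop("boundary table is empty")
  sub <- table[table$boundary_index >= range[1L] &
                 table$boundary_index <= range[2L], ]
  if (!nrow(sub)) stop("no scored boundaries within range")
  key <- paste(sub$embryo_id, sub$condition, sep = "\r")
  all_na <- tapply(sub$phenotype, key, function(p) all(is.na(p)))
  if (any(all_na)) {
    warning(sum(all_na), " embryo(s) with all-NA phenotypes excluded")
    sub <- sub[!key %in% names(all_na)[all_na], ]
    key <- paste(sub$embryo_id, sub$condition, sep = "\r")
  }
  def <- tapply(sub$phenotype, key, function(p) any(p == 1L, na.rm = TRUE))
  cond <- vapply(strsplit(names(def), "\r", fixed = TRUE), `[`, "", 2L)
  out <- do.call(rbind, lapply(split(def, cond), function(d) {
    data.frame(n_embryos = length(d), n_defected = sum(d),
               fraction_defected = mean(d))
  }))
  out <- cbind(data.frame(condition = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  class(out) <- c("penetrance_summary", "data.frame")
  out
}

#' Expressivity: per-side defective-boundary counts
#'
#' Counts defected boundaries per embryo side within the scoring range (NA
#' entries are excluded from the count and reported), then summarizes the
#' per-side counts per condition by median, quartiles and mean.
#'
#' @inheritParams classify_embryos
#' @return An `expressivity_summary` list with `counts` (one row per embryo
#'   side: `embryo_id, side, condition, n_defected, n_scored, n_na`) and
#'   `summary` (per condition: `n_sides, median, q1, q3, mean`).
#' @export
defect_counts <- function(table, range = c(11L, 30L)) {
  stopifnot(inherits(table, "boundary_table"), length(range) == 2L)
  if (!nrow(table)) stop("boundary table is empty")
  sub <- table[table$boundary_index >= range[1L] &
                 table$boundary_index <= range[2L], ]
  key <- interaction(sub$embryo_id, sub$side, sub$condition, drop = TRUE)
  counts <- do.call(rbind, lapply(split(sub, key), function(d) {
    data.frame(embryo_id = d$embryo_id[1L], side = d$side[1L],
               condition = d$condition[1L],
               n_defected = sum(d$phenotype == 1L, na.rm = TRUE),
               n_scored = sum(!is.na(d$phenotype)),
               n_na = sum(is.na(d$phenotype)),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  if (any(counts$n_na > 0L))
    warning(sum(counts$n_na), " unscorable boundary entries excluded from counts")
  summ <- do.call(rbind, lapply(split(counts, counts$condition), function(d) {
    q <- stats::quantile(d$n_defected, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(condition = d$condition[1L], n_sides = nrow(d),
               median = q[2L], q1 = q[1L], q3 = q[3L],
               mean = mean(d$n_defected), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(counts = counts, summary = summ, range = range),
            class = "expressivity_summary")
}

#' @export
print.expressivity_summary <- function(x, ...) {
  cat(sprintf("Defective boundaries per side (boundaries %d-%d)\n",
              x$range[1L], x$range[2L]))
  print.data.frame(x$summary)
  invisible(x)
}

# Pearson r with the undefined-when-constant convention used throughout:
# returns NA_real_ if either vector is constant on the complete pairs.
.pearson_or_na <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(NA_real_)
  stats::cor(a, b)
}

#' Consecutive-boundary phenotype correlation of one side
#'
#' Pearson product-moment correlation between the phenotype sequence at
#' boundaries 11--29 and its one-step shift 12--30 (lagged copies of the same
#' side), the statistic used to ask whether consecutive somites fail
#' independently. Computed on pairwise-complete entries; undefined (NA) when
#' either lagged vector is constant.
#'
#' @param v Ordered 0/1 phenotype vector covering the scoring range (at most
#'   2 NA entries).
#' @return Pearson r, or `NA` when undefined.
#' @export
consecutive_correlation <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  if (n < 4L) stop("need at least 4 boundaries (3 overlapping pairs)")
  if (sum(is.na(v)) > 2L) stop("more than 2 unscorable boundaries in side")
  .pearson_or_na(v[-n], v[-1L])
}

#' Left-right phenotype correlation of one embryo
#'
#' Pearson correlation between left- and right-side phenotype vectors at
#' matching boundary indices; undefined (NA) when either side is constant.
#'
#' @param left,right Ordered 0/1 phenotype vectors at matching boundary
#'   indices.
#' @return Pearson r, or `NA` when undefined.
#' @export
left_right_correlation <- function(left, right) {
  if (length(left) != length(right))
    stop("left and right must cover the same boundaries")
  if (length(left) < 3L) stop("need at least 3 matched boundaries")
  .pearson_or_na(as.numeric(left), as.numeric(right))
}

# ordered phenotype vector for one (embryo, side), NA-filled over the range
.side_vector <- function(table, embryo, side, range) {
  idx <- range[1L]:range[2L]
  d <- table[table$embryo_id == embryo & table$side == side, ]
  v <- rep(NA_integer_, length(idx))
  m <- match(d$boundary_index, idx)
  keep <- !is.na(m)
  v[m[keep]] <- d$phenotype[keep]
  v
}

#' Per-side and per-embryo correlation vectors for a whole table
#'
#' Applies [consecutive_correlation()] to every (embryo, side) and
#' [left_right_correlation()] to every embryo of a boundary table. The
#' headline statistic is the mean of the per-side signed r values; setting
#' `pooled = TRUE` instead concatenates the lagged boundary pairs of all
#' sides and returns a single Pearson r over the pooled pairs (an
#' alternative reading of "average cross-correlation" that trades per-side
#' resolution for a far smaller finite-sample bias).
#'
#' @inheritParams classify_embryos
#' @param pooled Pool lagged pairs across sides into one coefficient instead
#'   of returning one r per side.
#' @return Named numeric vector of r values (NA marks undefined units), or a
#'   single r when `pooled = TRUE`.
#' @export
consecutive_correlations <- function(table, range = c(11L, 30L),
                                     pooled = FALSE) {
  stopifnot(inherits(table, "boundary_table"))
  units <- unique(table[, c("embryo_id", "side")])
  if (pooled) {
    a <- b <- list()
    for (i in seq_len(nrow(units))) {
      v <- .side_vector(table, units$embryo_id[i], units$side[i], range)
      a[[i]] <- v[-length(v)]; b[[i]] <- v[-1L]
    }
    return(.pearson_or_na(unlist(a), unlist(b)))
  }
  r <- mapply(function(e, s)
    consecutive_correlation(.side_vector(table, e, s, range)),
    units$embryo_id, units$side)
  names(r) <- paste(units$embryo_id, units$side, sep = ".")
  r
}

#' @rdname consecutive_correlations
#' @export
left_right_correlations <- function(table, range = c(11L, 30L)) {
  stopifnot(inherits(table, "boundary_table"))
  embryos <- unique(table$embryo_id)
  r <- vapply(embryos, function(e) {
    have <- unique(table$side[table$embryo_id == e])
    if (!all(c("L", "R") %in% have))
      stop("embryo ", e, " is missing a side")
    left_right_correlation(.side_vector(table, e, "L", range),
                           .side_vector(table, e, "R", range))
  }, numeric(1L))
  names(r) <- embryos
  r
}

#' Summarize a collection of correlation coefficients
#'
#' Mean over defined values plus a normalized-frequency histogram with 0.1
#' bins covering \[-1, 1\]; bins are half-open \[k/10, (k+1)/10) with the
#' rightmost bin closed so r = 1 is representable. Undefined (NA) values are
#' excluded and counted.
#'
#' @param values Numeric vector of r values; NA marks undefined units.
#' @param bin_width Histogram bin width (default 0.1).
#' @return A `correlation_summary` list: `mean_r`, `n`, `n_excluded`,
#'   `histogram` (data frame `bin_lower, bin_upper, frequency`).
#' @export
summarize_correlations <- function(values, bin_width = 0.1) {
  stopifnot(is.numeric(bin_width), bin_width > 0)
  vals <- values[!is.na(values)]
  if (!length(vals)) stop("no defined correlation values to summarize")
  if (any(vals < -1 | vals > 1)) stop("correlation values outside [-1, 1]")
  lower <- seq(-1, 1 - bin_width, by = bin_width)
  upper <- lower + bin_width
  # half-open [lower, upper), rightmost closed
  bin <- findInterval(vals, c(lower, 1), rightmost.closed = TRUE)
  freq <- tabulate(bin, nbins = length(lower)) / length(vals)
  structure(list(mean_r = mean(vals), n = length(vals),
                 n_excluded = sum(is.na(values)),
                 histogram = data.frame(bin_lower = lower, bin_upper = upper,
                                        frequency = freq)),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("Correlation summary: mean r = %.4f over %d units (%d undefined excluded)\n",
              x$mean_r, x$n, x$n_excluded))
  invisible(x)
}

#' Percent change of an expressivity statistic between conditions
#'
#' `100 * (value_b - value_a) / value_a`, reported raw and rounded half-up to
#' integer percent (the convention under which 62.5 prints as 63).
#'
#' @param value_a Reference statistic (must be nonzero); e.g. the median
#'   defect count in the favorable condition.
#' @param value_b Comparison statistic.
#' @return List with `percent_raw` and `percent` (half-up integer).
#' @examples
#' expressivity_change(8, 13)    # 62.5 raw -> 63
#' expressivity_change(8.9, 11.5)  # 29
#' @export
expressivity_change <- function(value_a, value_b) {
  stopifnot(is.numeric(value_a), is.numeric(value_b),
            length(value_a) == 1L, length(value_b) == 1L)
  if (value_a == 0) stop("percent change undefined for a zero reference value")
  raw <- 100 * (value_b - value_a) / value_a
  list(percent_raw = raw, percent = .round_half_up(raw))
}

.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Dunn's rank-based multiple comparison after Kruskal-Wallis, with tie
# correction and p-value adjustment; no installed package provides it.
.dunn_pairwise <- function(values, groups, p_adjust = "holm") {
  g <- factor(groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_r <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (mean_r[[i]] - mean_r[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ], z = z,
             p_unadjusted = p,
             p_adjusted = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Hypothesis tests between phenotype conditions
#'
#' Two groups of per-side counts (or amplitudes) are compared with the
#' two-sided Mann-Whitney rank-sum test; three or more groups with the
#' Kruskal-Wallis test followed by Dunn's pairwise z comparisons
#' (Holm-adjusted); penetrance contrasts, supplied as a 2x2 count table,
#' with the two-sided Fisher exact test.
#'
#' @param x Numeric observations, or a 2x2 matrix of counts
#'   (rows = condition, columns = defected / wild-type).
#' @param g Group labels parallel to `x` (ignored for the 2x2 case).
#' @return A `condition_test` list: `method`, `statistic`, `p.value`, `n`
#'   per group, and `pairwise` (Dunn table) for >= 3 groups.
#' @export
compare_conditions <- function(x, g = NULL) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("count table must be 2x2")
    ft <- stats::fisher.test(x, alternative = "two.sided")
    return(structure(list(method = "Fisher exact (two-sided)",
                          statistic = ft$estimate, p.value = ft$p.value,
                          n = rowSums(x), pairwise = NULL),
                     class = "condition_test"))
  }
  stopifnot(is.numeric(x), !is.null(g), length(g) == length(x))
  g <- factor(g)
  n <- table(g)
  if (nlevels(g) < 2L || any(n < 2L))
    stop("need >= 2 groups with >= 2 observations each")
  if (nlevels(g) == 2L) {
    wt <- stats::wilcox.test(x[g == levels(g)[1L]], x[g == levels(g)[2L]],
                             alternative = "two.sided", exact = FALSE,
                             correct = TRUE)
    res <- list(method = "Mann-Whitney U (two-sided)",
                statistic = unname(wt$statistic), p.value = wt$p.value,
                n = as.vector(n), pairwise = NULL)
  } else {
    kw <- stats::kruskal.test(x, g)
    res <- list(method = "Kruskal-Wallis + Dunn (Holm-adjusted)",
                statistic = unname(kw$statistic), p.value = kw$p.value,
                n = as.vector(n), pairwise = .dunn_pairwise(x, g))
  }
  structure(res, class = "condition_test")
}

#' @export
print.condition_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p.value, paste(x$n, collapse = ", ")))
  if (!is.null(x$pairwise)) print.data.frame(x$pairwise)
  invisible(x)
}
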