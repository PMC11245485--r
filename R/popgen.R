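#' Windowed nucleotide diversity
#'
#' Computes nucleotide diversity (pi) for one population group in
#' non-overlapping windows tiled over a region. Per polymorphic site,
#' `pi_site = (n / (n - 1)) * 2 * p * (1 - p)` with `n` the number of
#' non-missing alleles (two per diploid) and `p` the alternate-allele
#' frequency — the unbiased mean pairwise difference. The window value
#' divides the site sum by the window length in bp (monomorphic positions
#' contribute zero), the convention of windowed-pi VCF tools; the
#' per-variant-site average is reported alongside.
#'
#' @param panel A [genotype_panel()] with group labels.
#' @param group Population group label (>= 2 accessions required).
#' @param region Optional `c(start, end)`; default spans the panel's
#'   variants, aligned to the window grid.
#' @param window Window size in bp (default 200).
#' @return A `diversity_profile` tibble: `chrom`, `start`, `end`, `group`,
#'   `pi` (per bp), `pi_per_site`, `n_sites` (polymorphic sites used),
#'   `n_alleles` (mean non-missing alleles at those sites; `NA` when none).
#' @export
windowed_pi <- function(panel, group, region = NULL, window = 200) {
  stopifnot(inherits(panel, "genotype_panel"))
  acc <- panel$accessions$accession_id[panel$accessions$group == group]
  if (length(acc) < 2L) {
    abort(sprintf("group \"%s\" needs >= 2 accessions in the panel.", group))
  }
  chrom <- panel$variants$chrom[1]
  if (is.null(region)) {
    lo <- min(panel$variants$pos); hi <- max(panel$variants$pos)
    region <- c(floor((lo - 1) / window) * window + 1,
                ceiling(hi / window) * window)
  }
  starts <- seq(region[1], region[2], by = window)
  dos <- panel$dosage[, acc, drop = FALSE]
  pos <- panel$variants$pos

  rows <- lapply(starts, function(s) {
    e <- s + window - 1
    idx <- which(pos >= s & pos <= e & panel$variants$chrom == chrom)
    if (!length(idx)) {
      return(list(pi_sum = 0, n_sites = 0L, n_alleles = NA_real_))
    }
    site <- vapply(idx, function(i) {
      g <- dos[i, ]
      nn <- 2 * sum(!is.na(g))
      if (nn < 2) return(c(0, 0))
      p <- sum(g, na.rm = TRUE) / nn
      if (p <= 0 || p >= 1) return(c(0, 0))
      c((nn / (nn - 1)) * 2 * p * (1 - p), nn)
    }, numeric(2))
    segregating <- site[2, ] > 0
    list(
      pi_sum = sum(site[1, ]),
      n_sites = sum(segregating),
      n_alleles = if (any(segregating)) mean(site[2, segregating]) else NA_real_
    )
  })
  out <- tibble(
    chrom = chrom,
    start = starts,
    end = starts + window - 1,
    group = group,
    pi = vapply(rows, function(r) r$pi_sum, numeric(1)) / window,
    pi_per_site = {
      s <- vapply(rows, function(r) r$pi_sum, numeric(1))
      k <- vapply(rows, function(r) r$n_sites, numeric(1))
      ifelse(k > 0, s / k, NA_real_)
    },
    n_sites = vapply(rows, function(r) as.integer(r$n_sites), integer(1)),
    n_alleles = vapply(rows, function(r) r$n_alleles, numeric(1))
  )
  class(out) <- c("diversity_profile", class(out))
  out
}

#' Contrast cultivated against wild diversity in a region
#'
#' Flags a candidate region as a potential selective sweep when the
#' cultivated group's windowed diversity sits well below the wild group's:
#' per cultivated group, the flag is true iff
#' `pi_cult / pi_wild < ratio_cutoff` in at least `frac_windows` of the
#' informative windows (windows with `pi_wild > 0`; windows where the wild
#' group is itself invariant carry no contrast and are excluded). With no
#' informative window the flag is indeterminate (`NA`).
#'
#' The rule is monotone: lowering cultivated diversity can only keep or
#' raise the flagged fraction.
#'
#' @param profiles A tibble combining [windowed_pi()] outputs for the wild
#'   and cultivated groups on identical windows.
#' @param wild_group Label of the wild group (default `"O.ruf"`).
#' @param cultivated_groups Labels of cultivated groups (default
#'   `c("japonica", "indica")`).
#' @param ratio_cutoff Per-window ratio below which a window counts as
#'   swept (default 0.5).
#' @param frac_windows Minimum fraction of informative windows below the
#'   cutoff (default 0.5).
#' @return A `sweep_call` tibble, one row per cultivated group: `group`,
#'   `mean_pi_wild`, `mean_pi_cult`, `ratio_of_means`, `n_windows`,
#'   `n_informative`, `frac_below`, `sweep` (logical, `NA` when
#'   indeterminate).
#' @export
sweep_contrast <- function(profiles, wild_group = "O.ruf",
                           cultivated_groups = c("japonica", "indica"),
                           ratio_cutoff = 0.5, frac_windows = 0.5) {
  need <- c(wild_group, cultivated_groups)
  missing_g <- setdiff(need, unique(profiles$group))
  if (length(missing_g)) {
    abort(paste("profiles lack group(s):", paste(missing_g, collapse = ", ")))
  }
  wide <- profiles %>%
    select("chrom", "start", "end", "group", "pi") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "pi")
  if (anyNA(wide[need])) {
    abort("groups were not profiled on identical windows.")
  }
  out <- purrr::map_dfr(cultivated_groups, function(g) {
    pw <- wide[[wild_group]]
    pc <- wide[[g]]
    informative <- pw > 0
    frac_below <- if (any(informative)) {
      mean(pc[informative] / pw[informative] < ratio_cutoff)
    } else {
      NA_real_
    }
    tibble(
      group = g,
      mean_pi_wild = mean(pw),
      mean_pi_cult = mean(pc),
      ratio_of_means = if (mean(pw) > 0) mean(pc) / mean(pw) else NA_real_,
      n_windows = length(pw),
      n_informative = sum(informative),
      frac_below = frac_below,
      sweep = if (is.na(frac_below)) NA else frac_below >= frac_windows
    )
  })
  attr(out, "ratio_cutoff") <- ratio_cutoff
  attr(out, "frac_windows") <- frac_windows
  class(out) <- c("sweep_call", class(out))
  out
}

#' Compare a trait between two genotype classes
#'
#' Two-sided two-sample t-test (Welch by default) of a trait between
#' accession classes defined at a focal variant, e.g. carriers vs
#' non-carriers of a promoter insertion (InDel+ / InDel-).
#'
#' @param pheno Tibble with `accession_id` and `value` (or a named vector).
#' @param classes Named character/factor vector or tibble
#'   (`accession_id`, `class`) with exactly two classes; both need >= 2
#'   phenotyped accessions.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return A one-row tibble: `class1`, `class2`, `mean1`, `mean2`, `n1`,
#'   `n2`, `statistic` (t), `df`, `pvalue`.
#' @export
genotype_group_test <- function(pheno, classes, var_equal = FALSE) {
  if (is.data.frame(pheno)) {
    y <- stats::setNames(pheno$value, pheno$accession_id)
  } else {
    y <- pheno
  }
  if (is.data.frame(classes)) {
    classes <- stats::setNames(as.character(classes$class), classes$accession_id)
  }
  common <- intersect(names(y), names(classes))
  y <- y[common]; cl <- as.character(classes[common])
  lev <- sort(unique(cl))
  if (length(lev) != 2L) abort("`classes` must define exactly two classes.")
  n1 <- sum(cl == lev[1]); n2 <- sum(cl == lev[2])
  if (min(n1, n2) < 2L) {
    abort(sprintf("both classes need >= 2 accessions (got %d / %d).", n1, n2))
  }
  tt <- t.test(y[cl == lev[1]], y[cl == lev[2]], var.equal = var_equal)
  tibble(
    class1 = lev[1], class2 = lev[2],
    mean1 = mean(y[cl == lev[1]]), mean2 = mean(y[cl == lev[2]]),
    n1 = n1, n2 = n2,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    pvalue = tt$p.value
  )
}

#' Z-score normalization
#'
#' `(x - mean(x)) / sd(x)` with the sample (n - 1) standard deviation, as
#' used to put expression summaries of different genes on one scale.
#'
#' @param values Numeric vector, length >= 2, nonzero variance.
#' @return Numeric vector with mean 0 and sd 1.
#' @examples
#' zscore_normalize(c(1, 2, 3))
#' @export
zscore_normalize <- function(values) {
  if (length(values) < 2L) abort("need >= 2 values to Z-normalize.")
  s <- sd(values)
  if (!is.finite(s) || s == 0) abort("zero variance: Z-scores undefined.")
  (values - mean(values)) / s
}

#' Precipitation-linked distribution of an allele
#'
#' Tests whether accessions carrying different genotype classes at a focal
#' variant come from climates with different mean precipitation: a
#' two-sided Welch t-test of precipitation between classes plus the
#' point-biserial correlation. The "precipitation-related" flag is
#' `pvalue < alpha`.
#'
#' @param geo Tibble with `accession_id` and `precip_mm` columns (the
#'   geography table of the panel).
#' @param classes Named vector or tibble (`accession_id`, `class`) with two
#'   classes, both with >= 2 accessions carrying precipitation values.
#' @param alpha Flag threshold (default 0.01).
#' @return One-row tibble: `class1`, `class2`, `mean_precip1`,
#'   `mean_precip2`, `n1`, `n2`, `statistic`, `pvalue`, `r`
#'   (point-biserial, positive when class2 sees more rain), `flagged`.
#' @export
precipitation_association <- function(geo, classes, alpha = 0.01) {
  if (is.data.frame(classes)) {
    classes <- stats::setNames(as.character(classes$class), classes$accession_id)
  }
  common <- intersect(geo$accession_id, names(classes))
  precip <- stats::setNames(geo$precip_mm, geo$accession_id)[common]
  if (mean(is.na(precip)) > 0.5) {
    abort("precipitation missing for more than half of the accessions.")
  }
  keep <- !is.na(precip)
  precip <- precip[keep]
  cl <- as.character(classes[common][keep])
  lev <- sort(unique(cl))
  if (length(lev) != 2L) abort("`classes` must define exactly two classes.")
  n1 <- sum(cl == lev[1]); n2 <- sum(cl == lev[2])
  if (min(n1, n2) < 2L) {
    abort(sprintf("both classes need >= 2 accessions (got %d / %d).", n1, n2))
  }
  tt <- t.test(precip[cl == lev[1]], precip[cl == lev[2]])
  r <- cor(as.numeric(cl == lev[2]), precip)
  tibble(
    class1 = lev[1], class2 = lev[2],
    mean_precip1 = mean(precip[cl == lev[1]]),
    mean_precip2 = mean(precip[cl == lev[2]]),
    n1 = n1, n2 = n2,
    statistic = unname(tt$statistic), pvalue = tt$p.value,
    r = r, flagged = tt$p.value < alpha
  )
}

#' Plot windowed diversity per group
#'
#' @param object A `diversity_profile` (rows from one or more groups may be
#'   bound together).
#' @param ... Unused.
#' @return A ggplot of pi per window by group.
#' @exportS3Method ggplot2::autoplot
autoplot.diversity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    (.data$start + .data$end) / 2, .data$pi, color = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "window midpoint (bp)", y = expression(pi ~ "per bp"),
                  color = "group")
}
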