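#' Build the per-genotype CNV matrix
#'
#' Aggregates the pipeline stages into one row per genotype: NLR counts by
#' architecture class, total, pseudogene count, cluster count and mean
#' cluster size, and per-chromosome NLR counts.
#'
#' @param nlr_records Row-bound `nlr_records` across genotypes (must carry
#'   `genotype`, `gene_id`, `nlr_class`).
#' @param genes Row-bound `gene_models` for the NLR genes (for chromosome
#'   placement); may be `NULL` to skip per-chromosome columns.
#' @param pseudogenes Confirmed pseudogene contigs (may have zero rows).
#' @param clusters Cluster data frame (may have zero rows).
#' @param genotypes Character vector fixing the full genotype set (so that
#'   genotypes with zero NLRs still get a row). Default: those observed.
#' @return Data frame with columns `genotype`, `NL`, `CNL`, `TNL`, `RNL`,
#'   `total`, `pseudogenes`, `n_clusters`, `mean_cluster_size` and one
#'   column per chromosome.
#' @export
build_cnv_matrix <- function(nlr_records, genes = NULL,
                             pseudogenes = empty_pseudogene_contigs(),
                             clusters = NULL, genotypes = NULL) {
  if (is.null(genotypes)) {
    genotypes <- sort(unique(c(nlr_records$genotype, pseudogenes$genotype)))
  }
  if (length(genotypes) == 0L) stop("no genotypes to summarise")
  classes <- c("NL", "CNL", "TNL", "RNL")
  rows <- lapply(genotypes, function(g) {
    rec <- nlr_records[nlr_records$genotype == g, , drop = FALSE]
    cls <- vapply(classes, function(k) sum(rec$nlr_class == k), integer(1))
    data.frame(genotype = g, as.list(cls), total = nrow(rec),
               pseudogenes = sum(pseudogenes$genotype == g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(clusters)) {
    cs <- cluster_summary(clusters)
    i <- match(out$genotype, cs$genotype)
    out$n_clusters <- ifelse(is.na(i), 0L, cs$n_clusters[i])
    out$mean_cluster_size <- cs$mean_size[i]
  }
  if (!is.null(genes)) {
    chroms <- sort(unique(genes$chrom))
    for (ch in chroms) {
      out[[ch]] <- vapply(out$genotype, function(g) {
        ids <- nlr_records$gene_id[nlr_records$genotype == g]
        sum(genes$chrom == ch & genes$genotype == g & genes$gene_id %in% ids)
      }, integer(1))
    }
    attr(out, "chrom_cols") <- chroms
  }
  rownames(out) <- NULL
  out
}

#' Split genotypes into high- and low-CNV groups
#'
#' One-dimensional 2-means on total NLR counts: totals are sorted, every cut
#' point between consecutive values is scored by within-group sum of
#' squares, and the minimising cut is taken. The larger-mean group is
#' `HighCNV`. The `gap` attribute quantifies discreteness as the gap
#' between groups divided by the total range.
#'
#' @param totals Named numeric vector of total NLR counts per genotype.
#' @return Named character vector of labels (`HighCNV`/`LowCNV`), with
#'   attributes `gap` and `cut` (the threshold between groups). When all
#'   totals are equal a single `LowCNV` group is returned with a warning.
#' @export
assign_cnv_groups <- function(totals) {
  stopifnot(length(totals) >= 2L, !is.null(names(totals)))
  if (length(unique(totals)) == 1L) {
    warning("all totals equal; no CNV split")
    out <- stats::setNames(rep("LowCNV", length(totals)), names(totals))
    attr(out, "gap") <- 0
    return(out)
  }
  o <- order(totals)
  x <- totals[o]
  n <- length(x)
  wss <- vapply(seq_len(n - 1L), function(k) {
    lo <- x[seq_len(k)]; hi <- x[(k + 1L):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  k <- which.min(wss)
  labels <- rep(c("LowCNV", "HighCNV"), c(k, n - k))
  out <- stats::setNames(labels[order(o)], names(totals))
  attr(out, "gap") <- unname((x[k + 1L] - x[k]) / (x[n] - x[1L]))
  attr(out, "cut") <- unname((x[k] + x[k + 1L]) / 2)
  out
}

#' Group means, SEMs and the high-low mean difference
#'
#' @param values Numeric vector (one value per genotype).
#' @param groups Group labels (`HighCNV`/`LowCNV`) aligned with `values`.
#' @return A `group_summary` list: per-group `n`, `mean`, `sem`
#'   (`sd/sqrt(n)`), t-based 95% CI, and `mean_difference`
#'   (High minus Low). SEM and CI are `NA` for single-member groups.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  one <- function(v) {
    n <- length(v)
    m <- mean(v)
    if (n > 1L) {
      sem <- stats::sd(v) / sqrt(n)
      half <- stats::qt(0.975, n - 1L) * sem
      ci <- c(m - half, m + half)
    } else {
      sem <- NA_real_; ci <- c(NA_real_, NA_real_)
    }
    list(n = n, mean = m, sem = sem, ci95 = ci)
  }
  hi <- one(values[groups == "HighCNV"])
  lo <- one(values[groups == "LowCNV"])
  structure(list(HighCNV = hi, LowCNV = lo,
                 mean_difference = hi$mean - lo$mean),
            class = "group_summary")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined sample sizes up to `exact_max` the
#' p-value is computed by exact enumeration of all labelings of the combined
#' sample (two-sided via distance of U from its null mean, which handles
#' ties); otherwise the normal approximation with tie correction is used
#' (no continuity correction).
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Combined size bound for the exact branch (default 12).
#' @return List `U` (statistic for `x`), `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1L, ny >= 1L)
  comb <- c(x, y)
  if (length(unique(comb)) == 1L) {
    return(list(U = nx * ny / 2, p = 1, method = "degenerate"))
  }
  r <- rank(comb)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (nx + ny <= exact_max) {
    idx <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    n <- nx + ny
    ties <- table(comb)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = unname(U), p = min(1, p), method = method)
}

#' Phenotype rating scale
#'
#' Disease-rating categories mapped to numbers: susceptible = 1, moderately
#' susceptible = 2, moderately resistant = 3, tolerant = resistant = 4.
#' A genotype's mean rating <= 2 is classed susceptible and >= 3 resistant.
#'
#' @return A `phenotype_scale` list with `mapping`, `susceptible_max`,
#'   `resistant_min`.
#' @export
phenotype_scale <- function() {
  structure(list(
    mapping = c("susceptible" = 1, "moderately susceptible" = 2,
                "moderately resistant" = 3, "tolerant" = 4,
                "resistant" = 4),
    susceptible_max = 2, resistant_min = 3),
    class = "phenotype_scale")
}

#' Score phenotype ratings
#'
#' Maps rating categories to the numeric scale, averages them, and classes
#' the mean. Records based on field disease incidence or non-discernable
#' categories (e.g. "intermediate") should be removed upstream.
#'
#' @param ratings Character vector of rating categories.
#' @param scale A [phenotype_scale()] object.
#' @return List `mean`, `class`
#'   (`susceptible`/`resistant`/`unclassified`/`no_information`).
#' @export
phenotype_score <- function(ratings, scale = phenotype_scale()) {
  if (length(ratings) == 0L) {
    return(list(mean = NA_real_, class = "no_information"))
  }
  v <- scale$mapping[tolower(ratings)]
  if (anyNA(v)) {
    stop("unknown rating category: ",
         paste(unique(ratings[is.na(v)]), collapse = ", "))
  }
  m <- mean(v)
  cls <- if (m <= scale$susceptible_max) "susceptible"
         else if (m >= scale$resistant_min) "resistant"
         else "unclassified"
  list(mean = m, class = cls)
}

#' Complete-vs-partial NLR contingency table
#'
#' Counts complete (canonical-architecture) vs partial NLRs per CNV group
#' and tests the proportions with Pearson's chi-square (1 df, no continuity
#' correction).
#'
#' @param nlr_records Row-bound `nlr_records` with a `complete` column.
#' @param groups Named group labels (`HighCNV`/`LowCNV`) per genotype.
#' @return List `table` (2x2 counts), `proportions` (complete fraction per
#'   group), `statistic`, `p` (`NA` when a margin is empty).
#' @export
complete_partial_table <- function(nlr_records, groups) {
  grp <- groups[nlr_records$genotype]
  if (anyNA(grp)) stop("genotype(s) without a group label")
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("LowCNV", "HighCNV"),
                                c("complete", "partial")))
  for (g in rownames(tab)) {
    cc <- nlr_records$complete[grp == g]
    tab[g, ] <- c(sum(cc), sum(!cc))
  }
  props <- tab[, "complete"] / rowSums(tab)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(list(table = tab, proportions = props,
                statistic = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, proportions = props,
       statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Negative-binomial GLM report on NLR counts
#'
#' Fits `count ~ group * class` by negative-binomial regression
#' (delegated to [MASS::glm.nb()]); the model mirrors the group-by-class
#' count comparisons of the analysis. Reporting only: the pipeline's
#' contribution is the counts, not the fit.
#'
#' @param counts Long data frame with columns `count`, `group`, `class`.
#' @return List `coefficients` (coefficient table), `theta`, `converged`;
#'   on non-convergence the error message under `error` and a Poisson
#'   fallback fit.
#' @export
report_glms <- function(counts) {
  stopifnot(nrow(counts) > 0L,
            all(c("count", "group", "class") %in% names(counts)))
  fml <- if (length(unique(counts$class)) > 1L) {
    count ~ group * class
  } else {
    count ~ group
  }
  fit <- tryCatch(
    MASS::glm.nb(fml, data = counts),
    error = function(e) e, warning = function(w) {
      suppressWarnings(MASS::glm.nb(fml, data = counts))
    })
  if (inherits(fit, "error")) {
    pf <- stats::glm(fml, data = counts, family = stats::poisson())
    return(list(coefficients = stats::coef(summary(pf)), theta = NA_real_,
                converged = FALSE, error = conditionMessage(fit)))
  }
  list(coefficients = stats::coef(summary(fit)), theta = fit$theta,
       converged = fit$converged)
}
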