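#' Extract one endpoint as a per-larva analysis table
#'
#' Pulls a single endpoint column out of a feature table
#' ([cohort_features()] output) for one zone and block, giving the tidy
#' larva x value table the group comparisons run on.
#'
#' @param features feature tibble.
#' @param endpoint column name, e.g. `"pct_time"`, `"transitions"`,
#'   `"mean_mpdc"`.
#' @param zone `"light"`, `"dark"` or `NULL` (keep both; sensible only for
#'   zone-invariant endpoints such as `transitions`).
#' @param block block label (default `"overall"`), ignored when the table
#'   has no block column.
#' @return tibble with columns `larva_id`, `osmolyte`, `snp`, `value`.
#' @export
endpoint_table <- function(features, endpoint, zone = "light",
                           block = "overall") {
  stopifnot(endpoint %in% names(features))
  df <- features
  if (!is.null(zone)) df <- df[df$zone == zone, , drop = FALSE]
  else df <- df[!duplicated(df$larva_id), , drop = FALSE]
  if ("block" %in% names(df)) df <- df[df$block == block, , drop = FALSE]
  tibble::tibble(larva_id = df$larva_id, osmolyte = df$osmolyte,
                 snp = df$snp, value = df[[endpoint]])
}

cell_label <- function(osmolyte, snp) {
  paste0(osmolyte, ifelse(as.logical(snp), "+SNP", ""))
}

prepare_design <- function(data) {
  stopifnot(all(c("osmolyte", "snp", "value") %in% names(data)))
  df <- data.frame(
    osmolyte = factor(data$osmolyte, levels = c("mannitol", "glucose")),
    snp = factor(ifelse(as.logical(data$snp), "SNP", "none"),
                 levels = c("none", "SNP")),
    value = as.numeric(data$value))
  if (anyNA(df$osmolyte) || anyNA(df$snp)) stop("unknown design cells")
  df <- df[is.finite(df$value), , drop = FALSE]
  df$cell <- cell_label(as.character(df$osmolyte), df$snp == "SNP")
  df
}

#' Shapiro-Wilk normality gate per design cell
#'
#' Tests each of the four design cells for normality; a warning is emitted
#' when any cell fails at the 0.05 level. The gate is reported, not acted
#' on: no automatic nonparametric fallback is applied.
#'
#' @param data tibble with columns `osmolyte`, `snp`, `value`.
#' @return tibble with one row per cell: `cell`, `n`, `W`, `p`, `normal`.
#' @export
normality_check <- function(data) {
  df <- prepare_design(data)
  out <- lapply(split(df, df$cell, drop = TRUE), function(d) {
    if (nrow(d) < 3) stop("cell ", d$cell[1], " has fewer than 3 values")
    if (sd(d$value) == 0) stop("constant values in cell ", d$cell[1])
    sw <- shapiro.test(d$value)
    tibble::tibble(cell = d$cell[1], n = nrow(d),
                   W = unname(sw$statistic), p = sw$p.value,
                   normal = sw$p.value >= 0.05)
  })
  res <- dplyr::bind_rows(out)
  if (any(!res$normal))
    warning("Shapiro-Wilk failed at 0.05 in cell(s): ",
            paste(res$cell[!res$normal], collapse = ", "))
  res
}

#' Default pairwise comparison family
#'
#' The four cell comparisons drawn in the figures: osmolyte effect without
#' SNP, the two rescue contrasts, and control versus rescued glucose.
#'
#' @return list of length-2 character vectors of cell labels.
#' @export
default_comparisons <- function() {
  list(c("mannitol", "glucose"),
       c("glucose", "glucose+SNP"),
       c("mannitol", "mannitol+SNP"),
       c("mannitol", "glucose+SNP"))
}

#' Sidak familywise adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons; the identity at
#' `m = 1`, and monotone in both `p` and `m`.
#'
#' @param p raw p-values.
#' @param m family size.
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Two-way ANOVA with Sidak-adjusted pairwise comparisons
#'
#' The study's group comparison on one endpoint: Shapiro-Wilk normality gate
#' per cell, type-II sums-of-squares two-way ANOVA on osmolyte x SNP with
#' interaction, and Sidak-adjusted pairwise cell comparisons over a
#' configured family (default the four figure-drawn comparisons;
#' `pairs = NULL` skips the post-hoc step). Type II is the default because
#' the 2x2 design is near-balanced, where types I/II/III coincide or nearly
#' so.
#'
#' @param data tibble with columns `osmolyte`, `snp`, `value` (one row per
#'   larva), e.g. from [endpoint_table()].
#' @param endpoint endpoint name carried into the result.
#' @param pairs list of cell-label pairs, or `NULL`.
#' @param alpha significance level.
#' @param check_normality run [normality_check()] and keep its table.
#' @return object of class `group_stats_result`: `anova` (term, df, F, p),
#'   `pairwise` (comparison, estimate, se, p, p_sidak, significant),
#'   `shapiro`, `alpha`, `m`.
#' @export
two_way_anova_sidak <- function(data, endpoint = "value",
                                pairs = default_comparisons(),
                                alpha = 0.05, check_normality = TRUE) {
  df <- prepare_design(data)
  counts <- table(df$osmolyte, df$snp)
  if (any(counts == 0)) {
    i <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ",
         cell_label(rownames(counts)[i[1]], colnames(counts)[i[2]] == "SNP"))
  }
  if (any(counts < 2)) stop("need at least 2 observations per cell")
  shap <- if (check_normality) normality_check(data) else NULL
  fit <- lm(value ~ osmolyte * snp, data = df)
  an <- car::Anova(fit, type = 2)
  terms <- c("osmolyte", "snp", "osmolyte:snp")
  anova_tbl <- tibble::tibble(
    term = c("osmolyte", "snp", "interaction"),
    df = an[terms, "Df"],
    F = an[terms, "F value"],
    p = an[terms, "Pr(>F)"])
  pairwise <- NULL
  m <- 0L
  if (!is.null(pairs) && length(pairs)) {
    m <- length(pairs)
    em <- emmeans::emmeans(fit, ~ osmolyte * snp)
    grid <- as.data.frame(em)
    grid_cells <- cell_label(as.character(grid$osmolyte),
                             grid$snp == "SNP")
    contrasts <- lapply(pairs, function(pr) {
      v <- as.numeric(grid_cells == pr[1]) - as.numeric(grid_cells == pr[2])
      if (sum(v != 0) != 2) stop("unknown cell in comparison: ",
                                 paste(pr, collapse = " vs "))
      v
    })
    names(contrasts) <- vapply(pairs, paste, "", collapse = " vs ")
    ct <- summary(emmeans::contrast(em, method = contrasts, adjust = "none"))
    pairwise <- tibble::tibble(
      comparison = as.character(ct$contrast),
      estimate = ct$estimate, se = ct$SE, p = ct$p.value,
      p_sidak = sidak_adjust(ct$p.value, m),
      significant = sidak_adjust(ct$p.value, m) < alpha)
  }
  structure(list(endpoint = endpoint, anova = anova_tbl, pairwise = pairwise,
                 shapiro = shap, alpha = alpha, m = m),
            class = "group_stats_result")
}

#' @export
print.group_stats_result <- function(x, ...) {
  cat(sprintf("<group_stats_result> endpoint '%s' (alpha = %g)\n",
              x$endpoint, x$alpha))
  print(x$anova)
  if (!is.null(x$pairwise)) {
    cat(sprintf("Sidak-adjusted pairwise comparisons (m = %d):\n", x$m))
    print(x$pairwise)
  }
  invisible(x)
}

#' Significance stars for p-values
#'
#' The figure-legend convention: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `****` p < 0.0001; empty when not significant.
#'
#' @param p numeric p-values.
#' @return character vector of annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else ""
  }, "")
}

#' Tidy report over one or several group-comparison results
#'
#' Stacks ANOVA terms and Sidak-adjusted comparisons into one tidy table
#' with star annotations.
#'
#' @param results a `group_stats_result` or list of them.
#' @return tibble: `endpoint`, `type` (anova/pairwise), `term`, `p`,
#'   `stars`.
#' @export
stats_report <- function(results) {
  if (inherits(results, "group_stats_result")) results <- list(results)
  dplyr::bind_rows(lapply(results, function(r) {
    an <- tibble::tibble(endpoint = r$endpoint, type = "anova",
                         term = r$anova$term, p = r$anova$p,
                         stars = significance_stars(r$anova$p))
    pw <- if (!is.null(r$pairwise))
      tibble::tibble(endpoint = r$endpoint, type = "pairwise",
                     term = r$pairwise$comparison, p = r$pairwise$p_sidak,
                     stars = significance_stars(r$pairwise$p_sidak))
    dplyr::bind_rows(an, pw)
  }))
}
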