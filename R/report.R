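#' @keywords internal
rater_pair_matrix <- function(rm1, rm2, rater) {
  subjects <- rownames(rm1)
  pair <- cbind(occasion1 = unclass(rm1)[subjects, rater],
                occasion2 = unclass(rm2)[subjects, rater])
  rating_matrix(pair, categories = attr(rm1, "categories"))
}

# Fisher pooling for report rows: coefficients at the +/-1 boundary
# (perfect agreement) are clamped infinitesimally inside so the pooled
# value stays defined and equal to 1 up to rounding.
pool_clamped <- function(x, conf = 0.95) {
  eps <- 1e-12
  fisher_pool(pmin(pmax(x, -1 + eps), 1 - eps), conf = conf)
}

result_cells <- function(res, prefix) {
  out <- list(res$estimate, res$ci_low, res$ci_high)
  names(out) <- paste0(prefix, c("", "_low", "_high"))
  out
}

pooled_cells <- function(pr, prefix) {
  out <- list(pr$estimate, pr$ci_low, pr$ci_high)
  names(out) <- paste0(prefix, c("", "_low", "_high"))
  out
}

#' Run the full reliability pipeline
#'
#' Computes, from two occasions of multi-rater ratings: per-rater
#' intra-rater coefficients (unweighted AC1 and weighted, each with
#' percent agreement and jackknife CIs); Fisher-pooled group means for
#' the full panel and any configured subgroups; inter-rater
#' coefficients per occasion, per group, plus a Fisher-pooled
#' across-occasion value; benchmark bands via the critical-value rule;
#' and the precision flags on each percent agreement. Group rows pool
#' exactly their member rows; coefficients at the boundary (exactly 1)
#' are clamped infinitesimally inside (-1, 1) before pooling.
#'
#' @param rm1,rm2 [rating_matrix()] objects for occasions 1 and 2.
#' @param weights Partial-credit [weight_matrix()] for the weighted
#'   analysis (default [schroth_weights()]).
#' @param rater_groups Optional data.frame with columns `rater_id`,
#'   `group` assigning raters to named subgroups (a rater may appear in
#'   several). Unknown rater ids are rejected.
#' @param scale A [benchmark_scale()].
#' @param conf Confidence level.
#'
#' @return A `study_report`: list with data.frames `intra` (per
#'   rater), `intra_groups` (pooled rows, always including group
#'   `"all"`), and `inter` (per occasion and pooled, per group), plus
#'   the scale used. All values at full precision; see
#'   [format_report()] for table-style rounding.
#' @export
run_pipeline <- function(rm1, rm2, weights = schroth_weights(),
                         rater_groups = NULL, scale = benchmark_scale(),
                         conf = 0.95) {
  cats <- attr(rm1, "categories")
  idw <- identity_weights(cats)
  raters <- intersect(colnames(rm1), colnames(rm2))
  if (length(raters) < 2L) {
    stop("need at least 2 raters present at both occasions",
         call. = FALSE)
  }
  groups <- list(all = raters)
  if (!is.null(rater_groups)) {
    unknown <- setdiff(rater_groups$rater_id, raters)
    if (length(unknown)) {
      stop("unknown rater ids in group file: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (g in unique(rater_groups$group)) {
      groups[[g]] <- rater_groups$rater_id[rater_groups$group == g]
    }
  }

  intra <- do.call(rbind, lapply(raters, function(r) {
    prm <- rater_pair_matrix(rm1, rm2, r)
    ac <- gwet_ac(prm, idw, conf = conf, label = r)
    wac <- gwet_ac(prm, weights, conf = conf, label = r)
    pct <- percent_agreement(prm, idw, conf = conf, label = r)
    wpct <- percent_agreement(prm, weights, conf = conf, label = r)
    bm <- benchmark_coefficient(ac$estimate, scale)
    wbm <- benchmark_coefficient(wac$estimate, scale)
    prec <- precision_metrics(pct)
    as.data.frame(c(
      list(rater = r),
      result_cells(ac, "ac1"), result_cells(pct, "pct"),
      result_cells(wac, "wac1"), result_cells(wpct, "wpct"),
      list(band = bm$band, w_band = wbm$band,
           adequate = bm$adequate, w_adequate = wbm$adequate,
           cv = prec$cv, relative_error = prec$relative_error,
           cv_ok = prec$cv_ok, rel_ok = prec$rel_ok,
           n_subjects = ac$n_subjects_used)
    ), stringsAsFactors = FALSE)
  }))

  intra_groups <- do.call(rbind, lapply(names(groups), function(g) {
    rows <- intra[intra$rater %in% groups[[g]], , drop = FALSE]
    ac <- pool_clamped(rows$ac1, conf)
    wac <- pool_clamped(rows$wac1, conf)
    pct <- pool_clamped(rows$pct, conf)
    wpct <- pool_clamped(rows$wpct, conf)
    bm <- benchmark_coefficient(ac$estimate, scale)
    wbm <- benchmark_coefficient(wac$estimate, scale)
    as.data.frame(c(
      list(group = g, n_raters = nrow(rows)),
      pooled_cells(ac, "ac1"), pooled_cells(pct, "pct"),
      pooled_cells(wac, "wac1"), pooled_cells(wpct, "wpct"),
      list(band = bm$band, w_band = wbm$band,
           adequate = bm$adequate, w_adequate = wbm$adequate)
    ), stringsAsFactors = FALSE)
  }))

  occasions <- list(`1` = rm1, `2` = rm2)
  inter <- do.call(rbind, lapply(names(groups), function(g) {
    members <- groups[[g]]
    per_occ <- lapply(names(occasions), function(o) {
      rm <- occasions[[o]]
      ac <- inter_rater(rm, idw, raters = members, conf = conf, label = g)
      wac <- inter_rater(rm, weights, raters = members, conf = conf,
                         label = g)
      sub <- rating_matrix(unclass(rm)[, members, drop = FALSE],
                           categories = cats)
      pct <- percent_agreement(sub, idw, conf = conf)
      wpct <- percent_agreement(sub, weights, conf = conf)
      as.data.frame(c(
        list(group = g, occasion = o, n_raters = length(members)),
        result_cells(ac, "ac1"), result_cells(pct, "pct"),
        result_cells(wac, "wac1"), result_cells(wpct, "wpct"),
        list(band = benchmark_coefficient(ac$estimate, scale)$band,
             w_band = benchmark_coefficient(wac$estimate, scale)$band)
      ), stringsAsFactors = FALSE)
    })
    both <- do.call(rbind, per_occ)
    ac <- pool_clamped(both$ac1, conf)
    wac <- pool_clamped(both$wac1, conf)
    pct <- pool_clamped(both$pct, conf)
    wpct <- pool_clamped(both$wpct, conf)
    pooled <- as.data.frame(c(
      list(group = g, occasion = "pooled", n_raters = length(members)),
      pooled_cells(ac, "ac1"), pooled_cells(pct, "pct"),
      pooled_cells(wac, "wac1"), pooled_cells(wpct, "wpct"),
      list(band = benchmark_coefficient(ac$estimate, scale)$band,
           w_band = benchmark_coefficient(wac$estimate, scale)$band)
    ), stringsAsFactors = FALSE)
    rbind(both, pooled)
  }))

  structure(list(intra = intra, intra_groups = intra_groups,
                 inter = inter, scale = scale),
            class = "study_report")
}

#' Format a study report as plain-text tables
#'
#' Coefficients are rounded to 2 decimals and percent agreements to 1
#' decimal, matching conventional reliability-table formatting; the
#' underlying report keeps full precision.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @return Character vector of table lines.
#' @export
format_report <- function(report) {
  ci2 <- function(e, lo, hi) {
    ifelse(is.na(lo), sprintf("%.2f", e),
           sprintf("%.2f (%.2f-%.2f)", e, lo, hi))
  }
  pc1 <- function(e, lo, hi) {
    ifelse(is.na(lo), sprintf("%.1f", 100 * e),
           sprintf("%.1f (%.1f-%.1f)", 100 * e, 100 * lo, 100 * hi))
  }
  row_fmt <- function(label, d) {
    sprintf("%-22s %-20s %-22s %-20s %-22s", label,
            ci2(d$ac1, d$ac1_low, d$ac1_high),
            pc1(d$pct, d$pct_low, d$pct_high),
            ci2(d$wac1, d$wac1_low, d$wac1_high),
            pc1(d$wpct, d$wpct_low, d$wpct_high))
  }
  header <- sprintf("%-22s %-20s %-22s %-20s %-22s", "",
                    "AC1 (95% CI)", "Percent agreement (95% CI)",
                    "Weighted AC1 (95% CI)", "Weighted percent (95% CI)")
  lines <- c("Intra-rater reliability", header)
  for (i in seq_len(nrow(report$intra))) {
    lines <- c(lines, row_fmt(report$intra$rater[i], report$intra[i, ]))
  }
  for (i in seq_len(nrow(report$intra_groups))) {
    g <- report$intra_groups[i, ]
    lines <- c(lines, row_fmt(sprintf("Mean (%s, N=%d)", g$group,
                                      g$n_raters), g))
  }
  lines <- c(lines, "", "Inter-rater reliability", header)
  for (i in seq_len(nrow(report$inter))) {
    d <- report$inter[i, ]
    lines <- c(lines, row_fmt(sprintf("%s (occasion %s, N=%d)",
                                      d$group, d$occasion, d$n_raters), d))
  }
  lines
}

#' @export
print.study_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Write a study report to CSV files
#'
#' Writes `<prefix>_intra.csv`, `<prefix>_intra_groups.csv` and
#' `<prefix>_inter.csv` at full precision so the report round-trips
#' losslessly.
#'
#' @param report A `study_report`.
#' @param prefix Path prefix for the three CSV files.
#' @return Character vector of the paths written, invisibly.
#' @export
write_report <- function(report, prefix) {
  paths <- paste0(prefix, c("_intra.csv", "_intra_groups.csv",
                            "_inter.csv"))
  utils::write.csv(report$intra, paths[1], row.names = FALSE)
  utils::write.csv(report$intra_groups, paths[2], row.names = FALSE)
  utils::write.csv(report$inter, paths[3], row.names = FALSE)
  invisible(paths)
}
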