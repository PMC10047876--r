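#' @name agreement
#' @title Multi-rater chance-corrected agreement (Gwet's AC1 family)
#'
#' @description
#' Given a subjects x raters [rating_matrix()] and a partial-credit
#' [weight_matrix()], the observed (weighted) agreement is
#' \deqn{p_a = \frac{1}{n'} \sum_{i: r_i \ge 2} \sum_k
#'   \frac{r_{ik} (r^*_{ik} - 1)}{r_i (r_i - 1)},
#'   \quad r^*_{ik} = \sum_l w_{kl} r_{il},}
#' where \eqn{r_{ik}} counts the raters placing subject \eqn{i} in
#' category \eqn{k}, \eqn{r_i} is the number of non-missing ratings of
#' subject \eqn{i}, and \eqn{n'} counts subjects with at least two
#' ratings. Chance agreement uses the category marginals
#' \eqn{\pi_k = n^{-1} \sum_i r_{ik}/r_i} over all rated subjects:
#' \deqn{p_e = \frac{T_w}{q(q-1)} \sum_k \pi_k (1 - \pi_k),
#'   \quad T_w = \sum_{k,l} w_{kl}.}
#' The coefficient is \eqn{(p_a - p_e)/(1 - p_e)}; with identity
#' weights this is the unweighted AC1. Subjects with fewer than two
#' ratings are excluded from \eqn{p_a} but their available ratings
#' still inform \eqn{\pi_k}.
NULL

# r*_ik = sum_l w_kl r_il, per subject; counts is n x q, weights q x q
weighted_counts <- function(counts, weights) {
  counts %*% t(unclass(weights))
}

agreement_components <- function(rm, weights) {
  cats <- attr(rm, "categories")
  if (!identical(rownames(weights), cats)) {
    if (setequal(rownames(weights), cats)) {
      weights <- weights[cats, cats, drop = FALSE]
    } else {
      stop("weight matrix categories do not match the rating matrix",
           call. = FALSE)
    }
  }
  counts <- category_counts(rm)
  r_i <- rowSums(counts)
  rated <- r_i >= 1
  usable <- r_i >= 2
  list(counts = counts, r_i = r_i, rated = rated, usable = usable,
       weights = weights, q = length(cats))
}

pa_from_components <- function(cp) {
  if (!any(cp$usable)) {
    stop("no subject has two or more ratings; observed agreement ",
         "is undefined", call. = FALSE)
  }
  counts <- cp$counts[cp$usable, , drop = FALSE]
  r_i <- cp$r_i[cp$usable]
  rstar <- weighted_counts(counts, cp$weights)
  mean(rowSums(counts * (rstar - 1)) / (r_i * (r_i - 1)))
}

pe_from_components <- function(cp) {
  counts <- cp$counts[cp$rated, , drop = FALSE]
  r_i <- cp$r_i[cp$rated]
  pik <- colMeans(counts / r_i)
  t_w <- sum(cp$weights)
  (t_w / (cp$q * (cp$q - 1))) * sum(pik * (1 - pik))
}

#' Observed (weighted) agreement
#'
#' @param rm A [rating_matrix()].
#' @param weights A [weight_matrix()] over the same categories; the
#'   default identity weights give the plain pairwise proportion of
#'   agreeing rater pairs.
#' @return The observed agreement, a proportion in `[0, 1]`.
#' @seealso [agreement] for the formula.
#' @export
observed_agreement <- function(rm, weights = identity_weights(attr(rm, "categories"))) {
  pa_from_components(agreement_components(rm, weights))
}

#' Chance (weighted) agreement
#'
#' @inheritParams observed_agreement
#' @return The chance agreement, a proportion.
#' @seealso [agreement] for the formula.
#' @export
chance_agreement <- function(rm, weights = identity_weights(attr(rm, "categories"))) {
  cp <- agreement_components(rm, weights)
  if (!any(cp$usable)) {
    stop("no subject has two or more ratings", call. = FALSE)
  }
  pe_from_components(cp)
}

jackknife_se <- function(rm, weights, statistic) {
  n <- nrow(rm)
  if (n < 2L) return(NA_real_)
  reps <- vapply(seq_len(n), function(i) {
    sub <- rm[-i, , drop = FALSE]
    attr(sub, "categories") <- attr(rm, "categories")
    class(sub) <- class(rm)
    tryCatch(statistic(sub, weights), error = function(e) NA_real_)
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  m <- length(reps)
  if (m < 2L) return(NA_real_)
  sqrt((m - 1) / m * sum((reps - mean(reps))^2))
}

agreement_result <- function(estimate, pa, pe, se, n_used, n_raters,
                             weighted, label, conf = 0.95) {
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci_low <- if (is.na(se)) NA_real_ else estimate - zc * se
  ci_high <- if (is.na(se)) NA_real_ else min(1, estimate + zc * se)
  structure(
    list(estimate = estimate, pa = pa, pe = pe, se = se,
         ci_low = ci_low, ci_high = ci_high,
         n_subjects_used = n_used, n_raters = n_raters,
         weighted = weighted, label = label, conf = conf),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  kind <- if (x$weighted) "Weighted agreement coefficient" else
    "Agreement coefficient (AC1)"
  cat(sprintf("%s%s: %.3f", kind,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$estimate))
  if (!is.na(x$se)) {
    cat(sprintf(" (%.0f%% CI %.3f-%.3f, se %.3f)",
                100 * x$conf, x$ci_low, x$ci_high, x$se))
  }
  cat(sprintf("\n  pa = %.3f, pe = %.3f, %d subjects, %d raters\n",
              x$pa, x$pe, x$n_subjects_used, x$n_raters))
  invisible(x)
}

#' Gwet's agreement coefficient with arbitrary weights
#'
#' Computes the chance-corrected agreement coefficient
#' `(pa - pe) / (1 - pe)` for any number of raters, with missing
#' ratings allowed. The standard error is a subject-level delete-one
#' jackknife and the confidence interval a normal approximation with
#' the upper bound truncated at 1.
#'
#' @inheritParams observed_agreement
#' @param conf Confidence level for the interval (default 0.95).
#' @param label Free-text label carried into the result (e.g. a rater
#'   id).
#'
#' @return An `agreement_result`: a list with `estimate`, `pa`, `pe`,
#'   `se`, `ci_low`, `ci_high`, `n_subjects_used`, `n_raters`,
#'   `weighted`, `label`.
#' @seealso [agreement] for the formulas; [intra_rater()],
#'   [inter_rater()] for the two study designs.
#' @export
#' @examples
#' rm <- rating_matrix(cbind(c("3c", "3cp", "4c", "4cp"),
#'                           c("3c", "3cp", "4c", "4c")))
#' gwet_ac(rm)
gwet_ac <- function(rm, weights = identity_weights(attr(rm, "categories")),
                    conf = 0.95, label = "") {
  cp <- agreement_components(rm, weights)
  pa <- pa_from_components(cp)
  pe <- pe_from_components(cp)
  if (pe >= 1 - 1e-12) {
    stop("chance agreement is 1; the coefficient is undefined",
         call. = FALSE)
  }
  est <- (pa - pe) / (1 - pe)
  se <- jackknife_se(rm, weights, function(sub, w) {
    scp <- agreement_components(sub, w)
    spe <- pe_from_components(scp)
    (pa_from_components(scp) - spe) / (1 - spe)
  })
  is_weighted <- !isTRUE(all.equal(unclass(weights),
                                   diag(cp$q), check.attributes = FALSE))
  agreement_result(est, pa, pe, se, sum(cp$usable), ncol(rm),
                   is_weighted, label, conf)
}

#' Percent agreement with jackknife confidence interval
#'
#' The observed (possibly weighted) agreement as a standalone
#' statistic, with the same subject-level jackknife se and normal CI as
#' [gwet_ac()]. Used for the percent-agreement report columns and for
#' the study precision criteria.
#'
#' @inheritParams gwet_ac
#' @return An `agreement_result` whose `estimate` equals `pa` and whose
#'   `pe` is `NA`.
#' @export
percent_agreement <- function(rm, weights = identity_weights(attr(rm, "categories")),
                              conf = 0.95, label = "") {
  cp <- agreement_components(rm, weights)
  pa <- pa_from_components(cp)
  se <- jackknife_se(rm, weights, function(sub, w) {
    pa_from_components(agreement_components(sub, w))
  })
  is_weighted <- !isTRUE(all.equal(unclass(cp$weights),
                                   diag(cp$q), check.attributes = FALSE))
  agreement_result(pa, pa, NA_real_, se, sum(cp$usable), ncol(rm),
                   is_weighted, label, conf)
}

#' Intra-rater (test-retest) agreement for one rater
#'
#' Builds a two-column rating matrix from one rater's two rating
#' occasions and computes [gwet_ac()] on it: the rater's occasion-1
#' self is one "rater", the occasion-2 self the other. Subjects missing
#' either rating are excluded from observed agreement but contribute
#' their available rating to the category marginals.
#'
#' @param rm1,rm2 [rating_matrix()] objects for occasions 1 and 2
#'   sharing subject rows.
#' @param rater Rater id (a column name of both matrices).
#' @param weights,conf As in [gwet_ac()].
#' @return An `agreement_result` labelled with the rater id.
#' @export
intra_rater <- function(rm1, rm2, rater,
                        weights = identity_weights(attr(rm1, "categories")),
                        conf = 0.95) {
  if (!rater %in% colnames(rm1) || !rater %in% colnames(rm2)) {
    stop("rater '", rater, "' not present in both occasions",
         call. = FALSE)
  }
  subjects <- rownames(rm1)
  if (!setequal(subjects, rownames(rm2))) {
    stop("the two occasions cover different subjects", call. = FALSE)
  }
  pair <- cbind(occasion1 = unclass(rm1)[subjects, rater],
                occasion2 = unclass(rm2)[subjects, rater])
  both <- rowSums(!is.na(pair)) == 2L
  if (sum(both) < 2L) {
    stop("fewer than 2 subjects rated on both occasions by '",
         rater, "'", call. = FALSE)
  }
  prm <- rating_matrix(pair, categories = attr(rm1, "categories"))
  gwet_ac(prm, weights = weights, conf = conf, label = rater)
}

#' Inter-rater agreement at one occasion
#'
#' Multi-rater [gwet_ac()] over all (or a subset of) raters at a single
#' occasion.
#'
#' @param rm A [rating_matrix()] for one occasion.
#' @param weights,conf,label As in [gwet_ac()].
#' @param raters Optional character vector restricting to a rater
#'   subset (>= 2 raters).
#' @return An `agreement_result`.
#' @export
inter_rater <- function(rm, weights = identity_weights(attr(rm, "categories")),
                        raters = NULL, conf = 0.95, label = "") {
  if (!is.null(raters)) {
    missing_r <- setdiff(raters, colnames(rm))
    if (length(missing_r)) {
      stop("unknown raters: ", paste(missing_r, collapse = ", "),
           call. = FALSE)
    }
    sub <- unclass(rm)[, raters, drop = FALSE]
    rm <- rating_matrix(sub, categories = attr(rm, "categories"),
                        occasion = attr(rm, "occasion"))
  }
  if (ncol(rm) < 2L) stop("need at least 2 raters", call. = FALSE)
  gwet_ac(rm, weights = weights, conf = conf, label = label)
}
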