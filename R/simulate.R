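#' Rater profile for the study simulator
#'
#' Three parameters summarise a simulated rater: `accuracy`, the
#' probability of assigning a subject's true category; `consistency`,
#' the probability that the occasion-2 label simply copies the
#' occasion-1 label (otherwise it is drawn afresh from the rater's
#' confusion row); and `missing_rate`, the independent probability that
#' any single rating is never recorded.
#'
#' @param id Rater identifier (character).
#' @param accuracy Probability in (0, 1] of assigning the true
#'   category.
#' @param consistency Probability in [0, 1] that the occasion-2 label
#'   copies occasion 1.
#' @param missing_rate Probability in [0, 1) of a missing rating.
#'
#' @return A `rater_profile` list.
#' @export
rater_profile <- function(id, accuracy, consistency, missing_rate = 0) {
  if (accuracy <= 0 || accuracy > 1) {
    stop("accuracy must be in (0, 1]", call. = FALSE)
  }
  if (consistency < 0 || consistency > 1) {
    stop("consistency must be in [0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(id = as.character(id), accuracy = accuracy,
                 consistency = consistency, missing_rate = missing_rate),
            class = "rater_profile")
}

#' Default rater panel
#'
#' Ten heterogeneous raters mirroring the composition of the rater pool
#' the package is designed to study: two experienced raters (accuracy
#' 0.90, consistency 0.30), four additional well-trained raters (0.75,
#' 0.25) and four less-trained raters (0.60, 0.20), each with a 1%
#' missing-rating rate. Consistency is low because the two rating
#' occasions are a blinded week apart, so most of the test-retest
#' agreement must come from accuracy rather than recall; with these
#' values the expected intra-rater percent agreement spans roughly
#' 0.55 to 0.87 across the panel. The well-trained subgroup of six
#' comprises the experienced pair plus the four well-trained raters.
#'
#' @return List of ten [rater_profile()] objects.
#' @export
default_rater_profiles <- function() {
  c(
    lapply(1:2, function(i) {
      rater_profile(paste0("experienced", i), 0.90, 0.30, 0.01)
    }),
    lapply(1:4, function(i) {
      rater_profile(paste0("trained", i), 0.75, 0.25, 0.01)
    }),
    lapply(1:4, function(i) {
      rater_profile(paste0("rater", i), 0.60, 0.20, 0.01)
    })
  )
}

#' Study configuration for the simulator
#'
#' Defaults reproduce the reference study design: 44 subjects whose
#' true curve types follow the clinic prevalence 9/44, 12/44, 6/44,
#' 17/44 over (3c, 3cp, 4c, 4cp), rated twice by the
#' [default_rater_profiles()] panel, with rating errors spread
#' according to the Schroth partial-agreement weights.
#'
#' @param n_subjects Number of subjects (>= 2; default 44).
#' @param prevalence Named probability vector over the categories
#'   (sums to 1).
#' @param raters List of [rater_profile()] objects (>= 2).
#' @param weights [weight_matrix()] guiding how misclassification mass
#'   is spread over the non-true categories.
#' @param seed Optional integer seed making the study reproducible.
#'
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 44,
                         prevalence = c("3c" = 9, "3cp" = 12,
                                        "4c" = 6, "4cp" = 17) / 44,
                         raters = default_rater_profiles(),
                         weights = schroth_weights(),
                         seed = NULL) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (length(raters) < 2) stop("need >= 2 raters", call. = FALSE)
  if (abs(sum(prevalence) - 1) > 1e-8) {
    stop("prevalence must sum to 1", call. = FALSE)
  }
  if (is.null(names(prevalence)) ||
      !setequal(names(prevalence), rownames(weights))) {
    stop("prevalence names must match the weight-matrix categories",
         call. = FALSE)
  }
  structure(list(n_subjects = n_subjects,
                 prevalence = prevalence[rownames(weights)],
                 raters = raters, weights = weights, seed = seed),
            class = "study_config")
}

#' Confusion matrix implied by a rater profile
#'
#' Row-stochastic q x q matrix: row `t` holds the distribution of the
#' assigned category given true category `t`. The diagonal is the
#' rater's accuracy; the remaining mass `1 - a` is split over the other
#' categories in proportion to their partial-agreement weight with the
#' truth, encoding that clinically similar categories are the
#' confusable ones. Zero weights are floored at `floor` so every
#' confusion stays possible.
#'
#' @param profile A [rater_profile()].
#' @param weights A [weight_matrix()].
#' @param floor Small value replacing zero off-diagonal weights
#'   (default 0.05).
#'
#' @return A q x q row-stochastic matrix with the weight-matrix
#'   dimnames.
#' @export
#' @examples
#' build_confusion(rater_profile("r", 0.7, 0.8), schroth_weights())["3c", ]
build_confusion <- function(profile, weights, floor = 0.05) {
  w <- unclass(weights)
  q <- nrow(w)
  a <- profile$accuracy
  cm <- matrix(0, q, q, dimnames = dimnames(w))
  for (t in seq_len(q)) {
    off <- w[t, -t]
    off[off == 0] <- floor
    cm[t, -t] <- (1 - a) * off / sum(off)
    cm[t, t] <- a
  }
  cm
}

#' Simulate a two-occasion multi-rater rating study
#'
#' Draws each subject's true curve type from the configured prevalence;
#' each rater's occasion-1 rating from their confusion row given the
#' truth; the occasion-2 rating as a copy of occasion 1 with
#' probability `consistency`, otherwise a fresh confusion draw; and
#' drops each rating independently at the rater's `missing_rate`. Fully
#' reproducible from the config seed.
#'
#' @param config A [study_config()].
#'
#' @return List with `truth` (named character vector of true types),
#'   `occasion1` and `occasion2` ([rating_matrix()] objects).
#' @export
simulate_study <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cats <- rownames(config$weights)
  n <- config$n_subjects
  subjects <- sprintf("s%02d", seq_len(n))
  truth <- sample(cats, n, replace = TRUE, prob = config$prevalence)
  names(truth) <- subjects

  rater_ids <- vapply(config$raters, `[[`, character(1), "id")
  occ1 <- occ2 <- matrix(NA_character_, n, length(rater_ids),
                         dimnames = list(subjects, rater_ids))
  for (j in seq_along(config$raters)) {
    p <- config$raters[[j]]
    cm <- build_confusion(p, config$weights)
    for (i in seq_len(n)) {
      row <- cm[truth[i], ]
      r1 <- sample(cats, 1, prob = row)
      r2 <- if (stats::runif(1) < p$consistency) r1 else
        sample(cats, 1, prob = row)
      if (stats::runif(1) >= p$missing_rate) occ1[i, j] <- r1
      if (stats::runif(1) >= p$missing_rate) occ2[i, j] <- r2
    }
  }
  list(
    truth = truth,
    occasion1 = rating_matrix(occ1, categories = cats, occasion = 1),
    occasion2 = rating_matrix(occ2, categories = cats, occasion = 2)
  )
}

#' Expected intra-rater percent agreement under the simulator model
#'
#' Closed form for the probability that a rater's two occasion labels
#' for a random subject coincide:
#' \deqn{\sum_t \pi_t \left[ c + (1 - c) \sum_k C_{tk}^2 \right],}
#' with \eqn{\pi} the true-type prevalence, `c` the rater's consistency
#' and `C` the confusion matrix from [build_confusion()]. Serves as the
#' analytic oracle for simulation checks.
#'
#' @param profile A [rater_profile()].
#' @param prevalence Named probability vector over the categories.
#' @param weights A [weight_matrix()].
#'
#' @return The expected proportion of agreeing occasion pairs.
#' @export
expected_intra_pa <- function(profile, prevalence, weights) {
  cm <- build_confusion(profile, weights)
  prevalence <- prevalence[rownames(cm)]
  c_ <- profile$consistency
  sum(prevalence * (c_ + (1 - c_) * rowSums(cm^2)))
}
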