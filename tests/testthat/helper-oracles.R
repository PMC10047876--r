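# Independent oracles used to cross-check the closed-form agreement
# computations, plus small random-instance generators.

# Observed agreement by exhaustive enumeration of rater pairs within
# each subject: average pair weight over subjects with >= 1 complete
# pair. Independent of the r_ik-based implementation.
pa_pair_oracle <- function(rm, weights) {
  w <- unclass(weights)
  per_subject <- apply(unclass(rm), 1, function(row) {
    row <- row[!is.na(row)]
    if (length(row) < 2) return(NA_real_)
    pairs <- utils::combn(length(row), 2)
    mean(vapply(seq_len(ncol(pairs)), function(j) {
      w[row[pairs[1, j]], row[pairs[2, j]]]
    }, numeric(1)))
  })
  mean(per_subject, na.rm = TRUE)
}

# Chance agreement recomputed naively from first principles.
pe_oracle <- function(rm, weights) {
  cats <- attr(rm, "categories")
  q <- length(cats)
  m <- unclass(rm)
  rated <- rowSums(!is.na(m)) >= 1
  m <- m[rated, , drop = FALSE]
  pik <- vapply(cats, function(k) {
    mean(apply(m, 1, function(row) {
      row <- row[!is.na(row)]
      sum(row == k) / length(row)
    }))
  }, numeric(1))
  sum(weights) / (q * (q - 1)) * sum(pik * (1 - pik))
}

random_rating_matrix <- function(n, r, miss_prob = 0.15,
                                 categories = curve_types()) {
  m <- matrix(sample(categories, n * r, replace = TRUE), n, r)
  m[stats::runif(n * r) < miss_prob] <- NA_character_
  # guarantee the agreement precondition: one subject fully rated
  m[1, ] <- sample(categories, r, replace = TRUE)
  rating_matrix(m, categories = categories)
}

# Pair matrix for one rater's two occasions, as run_pipeline builds it.
pair_of <- function(sim, rater) {
  rating_matrix(
    cbind(occasion1 = unclass(sim$occasion1)[, rater],
          occasion2 = unclass(sim$occasion2)[, rater]),
    categories = attr(sim$occasion1, "categories")
  )
}

# AC estimate without the jackknife (fast path for simulation studies).
ac_estimate <- function(rm, weights = identity_weights(attr(rm, "categories"))) {
  pa <- observed_agreement(rm, weights)
  pe <- chance_agreement(rm, weights)
  (pa - pe) / (1 - pe)
}

default_groups <- function() {
  data.frame(
    rater_id = c("experienced1", "experienced2",
                 "experienced1", "experienced2",
                 "trained1", "trained2", "trained3", "trained4"),
    group = c("experienced", "experienced", rep("well-trained", 6)),
    stringsAsFactors = FALSE
  )
}
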