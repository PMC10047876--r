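cats4 <- curve_types()

test_that("observed agreement matches hand-worked cases", {
  # two raters in perfect agreement
  perfect <- rating_matrix(cbind(rep(c("3c", "4cp"), 3),
                                 rep(c("3c", "4cp"), 3)))
  expect_equal(observed_agreement(perfect), 1.0)

  # 2 raters, 4 subjects, half the pairs agree
  half <- rating_matrix(cbind(c("3c", "3c", "3cp", "3cp"),
                              c("3c", "3cp", "3cp", "3c")))
  expect_equal(observed_agreement(half), 0.5)

  # single subject rated (3c, 3cp): weighted agreement is the weight
  one <- rating_matrix(matrix(c("3c", "3cp"), 1, 2))
  expect_equal(observed_agreement(one, schroth_weights()), 0.75)
  expect_equal(observed_agreement(one), 0)
})

test_that("chance agreement matches hand-worked cases", {
  # q = 2, balanced marginals: pe = 1/(q-1) * 2 * 0.25 = 0.5
  rm2 <- rating_matrix(cbind(c("a", "a", "b", "b"),
                             c("a", "b", "a", "b")),
                       categories = c("a", "b"))
  expect_equal(chance_agreement(rm2), 0.5)

  # everything in one category: pe = 0
  mono <- rating_matrix(matrix("4c", 3, 2))
  expect_equal(chance_agreement(mono), 0)

  # q = 4, marginals (0.25, 0.25, 0.375, 0.125): pe = 23/96
  rm4 <- rating_matrix(cbind(c("3c", "3cp", "4c", "4cp"),
                             c("3c", "3cp", "4c", "4c")))
  expect_equal(chance_agreement(rm4), 23 / 96, tolerance = 1e-12)
  expect_equal(pe_oracle(rm4, identity_weights(cats4)), 23 / 96,
               tolerance = 1e-12)
})

test_that("AC1 matches hand-worked cases and degenerate inputs error", {
  perfect <- rating_matrix(cbind(rep(c("3c", "4cp"), 3),
                                 rep(c("3c", "4cp"), 3)))
  expect_equal(gwet_ac(perfect)$estimate, 1.0)

  # the balanced two-category case: pa = pe = 0.5, coefficient 0
  half <- rating_matrix(cbind(c("a", "a", "b", "b"),
                              c("a", "b", "b", "a")),
                        categories = c("a", "b"))
  r <- gwet_ac(half)
  expect_equal(r$pa, 0.5)
  expect_equal(r$pe, 0.5)
  expect_equal(r$estimate, 0.0)

  rm4 <- rating_matrix(cbind(c("3c", "3cp", "4c", "4cp"),
                             c("3c", "3cp", "4c", "4c")))
  r4 <- gwet_ac(rm4)
  expect_equal(r4$pa, 0.75)
  expect_equal(r4$pe, 23 / 96, tolerance = 1e-12)
  expect_equal(r4$estimate, 49 / 73, tolerance = 1e-12)
  expect_equal(r4$estimate, (r4$pa - r4$pe) / (1 - r4$pe))

  # all-ones weight matrix makes pe = 1: undefined coefficient
  ones <- weight_matrix(matrix(1, 2, 2), categories = c("a", "b"))
  rm2 <- rating_matrix(cbind(c("a", "b"), c("a", "b")),
                       categories = c("a", "b"))
  expect_error(gwet_ac(rm2, ones), "undefined")
  expect_error(observed_agreement(rating_matrix(
    matrix(c("3c", NA), 2, 1), categories = cats4)), "two or more")
})

test_that("r_ik formula agrees with the pair-enumeration oracle", {
  set.seed(101)
  sw <- schroth_weights()
  idw <- identity_weights(cats4)
  for (i in 1:200) {
    rm <- random_rating_matrix(sample(2:5, 1), sample(2:3, 1))
    for (w in list(idw, sw)) {
      expect_equal(observed_agreement(rm, w), pa_pair_oracle(rm, w),
                   tolerance = 1e-12)
      expect_equal(chance_agreement(rm, w), pe_oracle(rm, w),
                   tolerance = 1e-12)
    }
    # identity-weight pipeline is bit-for-bit the unweighted one
    expect_identical(gwet_ac(rm, idw)$estimate, gwet_ac(rm)$estimate)
  }
})

test_that("estimate is invariant to subject and rater permutations", {
  set.seed(202)
  for (i in 1:20) {
    rm <- random_rating_matrix(6, 3)
    m <- unclass(rm)
    perm <- m[sample(nrow(m)), sample(ncol(m)), drop = FALSE]
    rm_p <- rating_matrix(perm, categories = cats4)
    expect_equal(gwet_ac(rm_p, schroth_weights())$estimate,
                 gwet_ac(rm, schroth_weights())$estimate,
                 tolerance = 1e-12)
  }
})

test_that("jackknife se behaves like a sampling standard error", {
  set.seed(303)
  rm <- random_rating_matrix(12, 3, miss_prob = 0)
  r <- gwet_ac(rm)
  expect_gt(r$se, 0)
  expect_lte(r$ci_high, 1)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)

  # duplicating every subject roughly shrinks se by 1/sqrt(2)
  doubled <- rating_matrix(rbind(unclass(rm), unclass(rm)),
                           categories = cats4)
  r2 <- gwet_ac(doubled)
  expect_equal(r2$estimate, r$estimate, tolerance = 1e-12)
  expect_equal(r$se / r2$se, sqrt(2), tolerance = 0.1)

  # perfect agreement: zero spread, CI collapses at 1
  perfect <- rating_matrix(cbind(rep(cats4, 2), rep(cats4, 2)))
  expect_equal(gwet_ac(perfect)$se, 0)
  expect_equal(gwet_ac(perfect)$ci_high, 1)
})

test_that("subjects with a single rating shape pe but not pa", {
  base <- cbind(c("3c", "3cp", "4c"), c("3c", "3cp", "4c"))
  with_single <- rating_matrix(rbind(base, c("4cp", NA)),
                               categories = cats4)
  r <- gwet_ac(with_single)
  expect_equal(r$pa, 1)                 # the lone 4cp rating has no pair
  expect_equal(r$n_subjects_used, 3L)
  # pi = (1/4, 1/4, 1/4, 1/4) once the single rating is counted
  expect_equal(r$pe, (1 / 3) * 4 * 0.25 * 0.75, tolerance = 1e-12)
  r_without <- gwet_ac(rating_matrix(base, categories = cats4))
  expect_false(isTRUE(all.equal(r$pe, r_without$pe)))
})

test_that("intra-rater agreement pairs one rater's two occasions", {
  set.seed(404)
  labels <- sample(cats4, 44, replace = TRUE,
                   prob = c(9, 12, 6, 17) / 44)
  rm1 <- rating_matrix(cbind(r1 = labels), categories = cats4)

  # perfect repetition
  expect_equal(intra_rater(rm1, rm1, "r1")$estimate, 1.0)

  # agrees on 37 of 44 subjects
  relabel <- labels
  flip <- 1:7
  relabel[flip] <- vapply(labels[flip], function(l) {
    sample(setdiff(cats4, l), 1)
  }, character(1))
  rm2 <- rating_matrix(cbind(r1 = relabel), categories = cats4)
  r <- intra_rater(rm1, rm2, "r1")
  expect_equal(r$pa, 37 / 44, tolerance = 1e-12)
  expect_equal(r$label, "r1")
  expect_equal(r$n_raters, 2L)

  # occasion-2 labels independent uniform: estimate near 0 on average
  set.seed(505)
  est <- replicate(300, {
    rnd <- rating_matrix(cbind(r1 = sample(cats4, 44, replace = TRUE)),
                         categories = cats4)
    ac_estimate(rating_matrix(cbind(unclass(rm1), unclass(rnd)),
                              categories = cats4))
  })
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)) + 0.02)

  expect_error(intra_rater(rm1, rm2, "nope"), "not present")
  tiny1 <- rating_matrix(cbind(r1 = c("3c", NA, "4c")), categories = cats4)
  tiny2 <- rating_matrix(cbind(r1 = c("3c", "4c", NA)), categories = cats4)
  expect_error(intra_rater(tiny1, tiny2, "r1"), "fewer than 2")
})

test_that("inter-rater agreement covers rater subsets and examples", {
  # 10 identical raters
  m <- matrix(rep(sample(cats4, 8, replace = TRUE), 10), ncol = 10)
  expect_equal(inter_rater(rating_matrix(m))$estimate, 1.0)

  # 3 raters, 2 subjects: pa = (1/3 + 1)/2
  rm <- rating_matrix(rbind(c("3c", "3c", "3cp"),
                            c("3cp", "3cp", "3cp")))
  expect_equal(inter_rater(rm)$pa, 2 / 3, tolerance = 1e-12)

  big <- rating_matrix(matrix(sample(cats4, 30, replace = TRUE), 10, 3))
  sub <- inter_rater(big, raters = colnames(big)[1:2])
  expect_equal(sub$n_raters, 2L)
  expect_error(inter_rater(big, raters = c("r1", "zzz")), "unknown")
  expect_error(inter_rater(rating_matrix(cbind(r1 = c("3c", "4c")),
                                         categories = cats4)),
               "at least 2 raters")
})
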