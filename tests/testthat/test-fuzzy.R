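test_that("default partitions carry the published centers and pass structural checks", {
  p <- default_partitions()
  expect_equal(p$inputs$hgb$centers, c(8, 10.25, 14.1, 16.6))
  expect_equal(p$inputs$pao2$centers, c(30, 47.5, 65.75, 90))
  expect_equal(p$inputs$ph$centers, c(7.35, 7.40, 7.45))
  expect_equal(p$output$centers, c(0.25, 0.75))
  expect_equal(p$output$labels, c("Low", "Normal"))
  expect_length(p$inputs$hgb$mfs, 4)
  expect_length(p$inputs$ph$mfs, 3)
  for (q in c(p$inputs, list(p$output))) {
    expect_true(check_partition(q, n_grid = 1000L))
  }
})

test_that("partition of unity holds between extreme centers", {
  p <- default_partitions()
  for (q in c(p$inputs, list(p$output))) {
    z <- seq(q$centers[1], q$centers[length(q$centers)], length.out = 500)
    s <- rowSums(nfabt:::membership_matrix(q, z))
    expect_lt(max(abs(s - 1)), 1e-9)
  }
})

test_that("triangular membership evaluates peaks, feet and midpoints exactly", {
  hgb <- default_partitions()$inputs$hgb
  expect_equal(membership(hgb, 1, 8), 1.0)        # peak
  expect_equal(membership(hgb, 1, 10.25), 0.0)    # adjacent-center foot
  expect_equal(membership(hgb, 1, 9.125), 0.5)    # linear midpoint
  expect_equal(membership(hgb, "Very Low", 7), 1.0)  # shoulder below center
  expect_equal(membership(hgb, 4, 16.6), 1.0)
  expect_error(membership(hgb, 9, 8), "out of range")
  expect_error(triangular_mf("bad", 1, 2, 3), "left_foot < center")
})

test_that("fuzzy basis functions are products of antecedent memberships", {
  p <- default_partitions()
  sys <- fbf_system(p$inputs[c("hgb", "pao2")], p$output)
  expect_equal(fuzzy_basis(sys, c(1, 4), c(8, 90)), 1.0)  # both peaks
  # both memberships one half -> product one quarter
  expect_equal(fuzzy_basis(sys, c(1, 1), c(9.125, 38.75)), 0.25)
  # outside the Very Low support in haemoglobin annihilates the product
  expect_equal(fuzzy_basis(sys, c(1, 2), c(12, 47.5)), 0.0)
  expect_error(fuzzy_basis(sys, c(1, 1, 1), c(8, 90)), "dimension mismatch")
})

test_that("rule-space size is the product of partition sizes", {
  p <- default_partitions()
  two4 <- fbf_system(p$inputs[c("hgb", "pao2")], p$output)
  expect_equal(enumerate_rule_space(two4)$count, 32L)      # 4*4*2
  mixed <- fbf_system(p$inputs[c("hgb", "ph")], p$output)
  expect_equal(enumerate_rule_space(mixed)$count, 24L)     # 4*3*2
  single <- fbf_system(p$inputs["hgb"], p$output)
  expect_equal(enumerate_rule_space(single)$count, 8L)     # 4*2
  expect_equal(nrow(enumerate_rule_space(two4)$rules), 32L)
  expect_error(fbf_system(list(), p$output), "no active inputs")
})

test_that("Wang-Mendel learning picks max-membership cells and resolves conflicts", {
  p <- default_partitions()
  sys <- fbf_system(p$inputs[c("hgb", "pao2")], p$output)

  one <- learn_rules(sys, data.frame(hgb = 8, pao2 = 47.5), 0.25)
  expect_equal(nrow(one), 1L)
  expect_equal(one$a_hgb, 1L)
  expect_equal(one$a_pao2, 2L)
  expect_equal(one$consequent, 1L)   # Low
  expect_equal(one$degree, 1.0)

  # two samples land in the same cell with conflicting consequents; the
  # higher-degree rule survives
  z <- data.frame(hgb = c(8, 8.5), pao2 = c(47.5, 47.5))
  k <- c(0.75, 0.25)
  rb <- learn_rules(sys, z, k)
  expect_equal(nrow(rb), 1L)
  # sample 1 sits on the cell peak (degree 1) and carries consequent Normal;
  # sample 2's degree is only 0.778, so Normal survives
  expect_equal(rb$consequent, 2L)
  rb2 <- learn_rules(sys, z[2:1, ], k[2:1])
  expect_equal(rb2$consequent, rb$consequent)  # order-invariant resolution

  # equal degrees tie toward the lower consequent index
  tie <- learn_rules(sys, data.frame(hgb = c(8, 8), pao2 = c(47.5, 47.5)),
                     c(0.75, 0.25))
  expect_equal(tie$consequent, 1L)

  # samples at every grid point cover every antecedent cell
  grid <- expand.grid(hgb = p$inputs$hgb$centers, pao2 = p$inputs$pao2$centers)
  full <- learn_rules(sys, grid, rep(0.25, nrow(grid)))
  expect_equal(nrow(full), 16L)

  expect_error(learn_rules(sys, data.frame(hgb = numeric(0),
                                           pao2 = numeric(0)), numeric(0)),
               "empty")
  expect_warning(learn_rules(sys, data.frame(hgb = 3, pao2 = 47.5), 0.25),
                 "clipped")
  expect_error(learn_rules(sys, data.frame(hgb = 8, pao2 = 47.5), 2),
               "output")
})

test_that("degree-based conflict keeps the stronger rule", {
  p <- default_partitions()
  sys <- fbf_system(p$inputs[c("hgb", "pao2")], p$output)
  # both samples fall in cell (Very Low, Mild Hypoxemia): degrees 0.9 vs
  # ~0.45 with conflicting consequents
  z <- data.frame(hgb = c(8.225, 8.9), pao2 = c(47.5, 43))
  d_strong <- membership(p$inputs$hgb, 1, 8.225)           # 0.9
  d_weak <- membership(p$inputs$hgb, 1, 8.9) *
    membership(p$inputs$pao2, 2, 43)                       # 0.6 * 0.743
  expect_gt(d_strong, d_weak)
  rb <- learn_rules(sys, z, c(0.25, 0.75))
  expect_equal(nrow(rb), 1L)
  expect_equal(rb$consequent, 1L)                  # strong sample's consequent
  expect_equal(rb$degree, d_strong)
})

test_that("rule-base completion fills uncovered cells from nearest neighbours", {
  p <- default_partitions()
  sys <- fbf_system(p$inputs[c("hgb", "pao2")], p$output)
  rb <- learn_rules(sys, data.frame(hgb = c(8, 16.6), pao2 = c(30, 90)),
                    c(0.25, 0.75))
  full <- complete_rule_base(sys, rb)
  expect_equal(nrow(full), 16L)
  expect_setequal(unique(full$source), c("learned", "completed"))
  # corner cell (1,1) learned Low; its neighbours inherit Low
  near <- full[full$a_hgb == 1 & full$a_pao2 == 2, ]
  expect_equal(near$consequent, 1L)
})
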