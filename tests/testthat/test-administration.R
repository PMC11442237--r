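test_that("form enumeration reproduces all 24 cluster sequences", {
  f <- enumerate_forms()
  expect_identical(nrow(f), 24L)
  expect_identical(f[, 1:5], expected_forms())
  expect_identical(unname(unlist(f[5, 2:5])),
                   c("MATH1", "MATH2", "READ1", "READ2"))
  # one ordered domain pair contributes exactly 4 forms
  expect_identical(sum(f$major == "READ" & f$minor == "MATH"), 4L)
})

test_that("form assignment spirals and reproduces under a seed", {
  a <- assign_forms(49, "spiral")
  expect_identical(a[25], 1L)
  expect_identical(a[49], 1L)
  expect_true(all(table(assign_forms(48, "spiral")) == 2))
  r1 <- assign_forms(30, "random", seed = 5)
  r2 <- assign_forms(30, "random", seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1 %in% 1:24))
})

test_that("initial abilities start at the prior and carry across domains", {
  i1 <- init_theta(1, prior_spec(0, 1))
  expect_equal(i1$value, 0)
  prev <- structure(list(value = 0.7, se = 0.3, method = "EAP",
                         n_responses = 36L), class = "hat_theta")
  i3 <- init_theta(3, previous_domain_final = prev)
  expect_equal(i3$value, 0.7)
  expect_error(init_theta(3), class = "hatcat_state_error")
  expect_error(init_theta(2, prior_spec(0, 1)),
               class = "hatcat_domain_error")
})

test_that("a blueprinted domain run hits its exact counts and audits clean", {
  set.seed(111)
  bp <- hat_blueprint_fixture("reading")
  pool <- generate_synthetic_pool(reading_pool_spec(n_units = 25, seed = 2),
                                  bp, "READ")
  pool <- label_pool_subpools(pool, bp)
  res <- run_domain(pool, bp, hat_config(), student_index = 1,
                    response_fun = function(row) simulate_response(row, 0.5))
  expect_identical(nrow(res$log), 36L)
  expect_identical(length(unique(res$log$unit_id)), 12L)
  expect_true(all(table(res$log$unit_id) == 3))
  expect_identical(nrow(check_constraints(res$log$item_id, pool, bp)), 0L)
  # spiraled link units: student 1 gets the first two pool units up front
  sp <- res$log[res$log$shadow_status == "spiraled", ]
  expect_identical(unique(sp$unit_id), pool$units$unit_id[1:2])
  expect_identical(sp$position, c(1:3, 19:21))
  # subpool ordering: cluster 1 runs A before B (spiral positions exempt)
  c1 <- res$log[res$log$cluster == 1 & res$log$shadow_status != "spiraled", ]
  first_b <- match("B", c1$subpool)
  if (!is.na(first_b))
    expect_true(all(c1$subpool[seq_len(nrow(c1)) > first_b] == "B" |
                      c1$ipe_relaxed[seq_len(nrow(c1)) > first_b]))
})

test_that("with rp=.5, no randomness and item-level units the loop is plain CAT", {
  set.seed(121)
  pool <- random_pool(20, 1)                    # 20 one-item units
  responses <- setNames(as.list(sample(0:1, 20, TRUE)),
                        pool$items$item_id)
  cfg <- hat_config(rp = 0.5, progressive = FALSE, ipe = FALSE,
                    spiral = FALSE, test_length = 10)
  res <- run_domain(pool, NULL, cfg,
                    response_fun = function(row)
                      responses[[row$item_id]])
  oracle <- oracle_max_info_cat(pool, 10, responses)
  expect_identical(res$log$item_id, oracle$sequence)
  expect_equal(res$final$value, oracle$theta, tolerance = 1e-10)
})

test_that("full forms run both domains with ability carry-over", {
  bp <- list(READ = hat_blueprint_fixture("reading"),
             MATH = hat_blueprint_fixture("mathematics"))
  pools <- list(
    READ = label_pool_subpools(
      generate_synthetic_pool(reading_pool_spec(n_units = 25, seed = 4),
                              bp$READ, "READ"), bp$READ),
    MATH = label_pool_subpools(
      generate_synthetic_pool(mathematics_pool_spec(n_units = 25, seed = 5),
                              bp$MATH, "MATH"), bp$MATH))
  run_one <- function() {
    set.seed(31)
    run_test("s1", 1, 1, pools, bp, hat_config(),
             true_theta = c(READ = 0.4, MATH = 0.1))
  }
  rec <- run_one()
  expect_identical(nrow(rec$log), 60L)
  expect_identical(as.integer(table(rec$log$cluster)),
                   c(18L, 18L, 12L, 12L))
  expect_identical(unique(rec$log$domain[rec$log$cluster <= 2]), "READ")
  expect_identical(unique(rec$log$domain[rec$log$cluster >= 3]), "MATH")
  # spiral only in the major domain
  expect_identical(sum(rec$log$shadow_status == "spiraled"), 6L)
  expect_true(all(rec$log$position == 1:60))
  # the second domain starts exactly at the first domain's final estimate
  expect_equal(unname(rec$inits["MATH"]), rec$finals$READ$value)
  expect_equal(unname(rec$inits["READ"]), 0)
  # determinism under identical seeds
  rec2 <- run_one()
  expect_identical(rec$log, rec2$log)
  # zero violations in both domains
  for (d in c("READ", "MATH"))
    expect_identical(
      nrow(check_constraints(rec$log$item_id[rec$log$domain == d],
                             pools[[d]], bp[[d]])), 0L)
})

test_that("the science blueprint supports a compliant administration", {
  set.seed(131)
  bp <- hat_blueprint_fixture("science")
  pool <- generate_synthetic_pool(science_pool_spec(seed = 55), bp, "SCIE")
  pool <- label_pool_subpools(pool, bp)
  res <- run_domain(pool, bp, hat_config(), student_index = 3,
                    response_fun = function(row)
                      simulate_response(row, -0.5))
  expect_identical(nrow(res$log), 36L)
  expect_identical(length(unique(res$log$unit_id)), 12L)
  expect_true(all(table(res$log$unit_id) >= 1 &
                    table(res$log$unit_id) <= 5))
  expect_identical(nrow(check_constraints(res$log$item_id, pool, bp)), 0L)
})
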