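# enumeration oracle for the binary program itself (no LP machinery)
enumerate_milp <- function(A, sense, b, obj) {
  n <- ncol(A)
  best <- NULL
  for (bits in 0:(2^n - 1)) {
    x <- as.numeric(intToBits(bits)[1:n])
    lhs <- as.numeric(A %*% x)
    ok <- all(ifelse(sense < 0, lhs <= b + 1e-9,
                     ifelse(sense > 0, lhs >= b - 1e-9,
                            abs(lhs - b) <= 1e-9)))
    if (ok) {
      v <- sum(obj * x)
      if (is.null(best) || v > best) best <- v
    }
  }
  best
}

test_that("the branch-and-bound solver matches exhaustive enumeration", {
  set.seed(61)
  for (inst in 1:50) {
    n <- sample(5:12, 1)
    m <- sample(2:8, 1)
    A <- matrix(sample(c(0, 0, 1, 1, -1, 2), m * n, replace = TRUE), m, n)
    sense <- sample(c(-1L, 0L, 1L), m, replace = TRUE,
                    prob = c(.5, .2, .3))
    x0 <- sample(0:1, n, replace = TRUE)
    b <- as.numeric(A %*% x0) + sample(-1:2, m, replace = TRUE)
    obj <- round(runif(n, -1, 2), 4)
    sol <- hatcat:::milp_solve_cpp(A, sense, b, obj, rep(TRUE, n),
                                   rep(0, n), rep(1, n), NULL, 10, 1e6)
    truth <- enumerate_milp(A, sense, b, obj)
    if (is.null(truth)) {
      expect_identical(sol$status, "infeasible")
    } else {
      expect_identical(sol$status, "optimal")
      expect_equal(sol$objective, truth, tolerance = 1e-7)
    }
  }
})

test_that("shadow models contain every structural row family", {
  pool <- tiny_pool()
  bp <- toy_blueprint(t = 4, n_units = c(2, 2), per_unit = c(1, 3),
                      proc_lb = 1, proc_ub = 3)
  m <- build_shadow(pool, bp, theta_hat = 0)
  expect_identical(sum(m$row_ids == "test_length"), 1L)
  expect_identical(m$rhs[m$row_ids == "test_length"], 4)
  expect_identical(m$sense[m$row_ids == "test_length"], 0L)
  expect_identical(sum(m$row_ids == "C2"), 1L)      # unit-count equality
  expect_identical(sum(grepl("^link_", m$row_ids)), nrow(pool$items))
  expect_identical(sum(grepl("^unit_ub_", m$row_ids)), nrow(pool$units))
  expect_identical(sum(grepl("^unit_lb_", m$row_ids)), nrow(pool$units))
  expect_identical(sum(m$row_ids %in% c("C4_lb", "C4_ub")), 2L)
  expect_false("administered" %in% m$row_ids)

  m2 <- build_shadow(pool, bp, 0, administered = c("T01", "T05"))
  r <- which(m2$row_ids == "administered")
  expect_identical(m2$rhs[r], 2)
  expect_identical(m2$sense[r], 0L)
  expect_equal(sum(m2$A[r, ]), 2)
  expect_error(build_shadow(pool, bp, 0, administered = "missing"),
               class = "hatcat_integrity_error")
})

test_that("reading shadow models carry the 36-item and 12-unit equalities", {
  bp <- hat_blueprint_fixture("reading")
  pool <- generate_synthetic_pool(reading_pool_spec(n_units = 20, seed = 5),
                                  domain = "READ")
  m <- build_shadow(pool, bp, 0)
  expect_identical(m$rhs[m$row_ids == "test_length"], 36)
  expect_identical(m$rhs[m$row_ids == "R02"], 12)
})

test_that("solved shadows equal the subset-enumeration oracle", {
  set.seed(71)
  for (inst in 1:10) {
    pool <- random_pool(5, 2)                       # 10 items, C(10,4) sets
    bp <- toy_blueprint(t = 4, n_units = c(1, 5), per_unit = c(0, 2),
                        proc_lb = 1, proc_ub = 3)
    theta <- rnorm(1)
    m <- build_shadow(pool, bp, theta, rp_config(0.5))
    sol <- solve_shadow(m)
    expect_identical(sol$status, "optimal")
    expect_identical(nrow(check_constraints(sol$selected_item_ids, pool,
                                            bp)), 0L)
    expect_equal(sol$objective_value,
                 oracle_best_subset(pool, bp, theta, rp = 0.5),
                 tolerance = 1e-7)
  }
})

test_that("pigeonhole-infeasible demands are reported as infeasible", {
  pool <- tiny_pool()   # 3 Scan items
  bp <- toy_blueprint(t = 5, n_units = c(1, 2), per_unit = c(0, 3),
                      proc_lb = 5, proc_ub = 6)
  sol <- solve_shadow(build_shadow(pool, bp, 0))
  expect_identical(sol$status, "infeasible")
  expect_identical(length(sol$selected_item_ids), 0L)
})

test_that("degenerate equal-information objectives still audit clean", {
  pool <- tiny_pool()
  pool$items$a <- rep(1, 6)
  pool$items$b <- rep(0, 6)
  pool$items$model <- rep("2PL", 6)
  pool$items$steps <- replicate(6, numeric(0), simplify = FALSE)
  bp <- toy_blueprint(t = 4, n_units = c(2, 2), per_unit = c(1, 3),
                      proc_lb = 1, proc_ub = 3)
  sol <- solve_shadow(build_shadow(pool, bp, 0, rp_config(0.5)))
  expect_identical(sol$status, "optimal")
  expect_identical(nrow(check_constraints(sol$selected_item_ids, pool, bp)),
                   0L)
  expect_equal(sol$objective_value, 4 * 0.25, tolerance = 1e-9)
})

test_that("relaxing a binding upper bound never lowers the optimum", {
  set.seed(81)
  pool <- random_pool(6, 2)
  bp <- toy_blueprint(t = 6, n_units = c(1, 6), per_unit = c(0, 2),
                      proc_lb = 0, proc_ub = 2)
  tight <- solve_shadow(build_shadow(pool, bp, 0.5))
  bp$ub[4] <- 4
  loose <- solve_shadow(build_shadow(pool, bp, 0.5))
  expect_gte(loose$objective_value, tight$objective_value - 1e-9)
})

test_that("no selected item ever lacks its unit variable", {
  set.seed(91)
  for (inst in 1:5) {
    pool <- random_pool(6, 3)
    bp <- toy_blueprint(t = 6, n_units = c(2, 4), per_unit = c(1, 3),
                        proc_lb = 0, proc_ub = 18)
    sol <- solve_shadow(build_shadow(pool, bp, rnorm(1)))
    expect_identical(sol$status, "optimal")
    units_of_sel <- unique(
      pool$items$unit_id[pool$items$item_id %in% sol$selected_item_ids])
    expect_setequal(units_of_sel, sol$selected_unit_ids)
  }
})

test_that("the audit reports each breach with direction and count", {
  pool <- tiny_pool()
  bp <- toy_blueprint(t = 4, n_units = c(2, 2), per_unit = c(1, 3),
                      proc_lb = 1, proc_ub = 3)
  sol <- solve_shadow(build_shadow(pool, bp, 0))
  ok <- sol$selected_item_ids
  dropped <- check_constraints(ok[-1], pool, bp)
  tl <- dropped[dropped$constraint_id == "C1" & dropped$direction == "lb", ]
  expect_identical(nrow(tl), 1L)
  expect_identical(tl$observed, 3L)
  expect_identical(tl$bound, 4)

  empty <- check_constraints(character(0), pool, bp)
  lbs <- bp$constraint_id[bp$lb > 0 & bp$level != "per_unit_count"]
  expect_true(all(lbs %in% empty$constraint_id))
})

test_that("monotone inclusion: each shadow contains the administered set", {
  set.seed(101)
  pool <- random_pool(8, 2)
  bp <- toy_blueprint(t = 6, n_units = c(2, 6), per_unit = c(0, 2),
                      proc_lb = 0, proc_ub = 6)
  administered <- character(0)
  for (k in 1:5) {
    sol <- solve_shadow(build_shadow(pool, bp, rnorm(1),
                                     administered = administered))
    expect_identical(sol$status, "optimal")
    expect_true(all(administered %in% sol$selected_item_ids))
    administered <- c(administered,
                      setdiff(sol$selected_item_ids, administered)[1])
  }
})

test_that("the IPE partition halves a compliant selection with halved bounds", {
  bp <- hat_blueprint_fixture("reading")
  pool <- generate_synthetic_pool(reading_pool_spec(n_units = 30, seed = 3),
                                  bp, "READ")
  sel <- solve_shadow(build_shadow(pool, bp, 0))$selected_item_ids
  expect_identical(length(sel), 36L)
  part <- partition_pool_ipe(sel, pool, bp)
  expect_identical(length(part$subpool_a), 18L)
  expect_identical(length(part$subpool_b), 18L)
  expect_identical(length(intersect(part$subpool_a, part$subpool_b)), 0L)
  expect_setequal(c(part$subpool_a, part$subpool_b), sel)
  items <- pool$items
  for (k in which(bp$level == "item_count" & nzchar(bp$attribute))) {
    vals <- strsplit(bp$value[k], "|", fixed = TRUE)[[1]]
    for (half in list(part$subpool_a, part$subpool_b)) {
      cnt <- sum(items[[bp$attribute[k]]][items$item_id %in% half] %in% vals)
      expect_gte(cnt, floor(bp$lb[k] / 2))
      expect_lte(cnt, ceiling(bp$ub[k] / 2))
    }
  }
})

test_that("partitioning matches enumeration on a toy set and rejects odd sets", {
  items <- data.frame(
    item_id = sprintf("P%d", 1:6), unit_id = paste0("U", 1:6),
    model = "2PL", a = 1, b = 0, stringsAsFactors = FALSE)
  items$steps <- replicate(6, numeric(0), simplify = FALSE)
  items$proc <- c("Scan", "Scan", "Scan", "Rep", "Rep", "Rep")
  pool <- hat_pool(items)
  bp <- hat_blueprint(data.frame(
    constraint_id = "Q1", description = "", level = "item_count",
    attribute = "proc", value = "Scan", lb = 2, ub = 4,
    stringsAsFactors = FALSE))
  part <- partition_pool_ipe(items$item_id, pool, bp)
  # every balanced bipartition with 1-2 Scan per half is acceptable;
  # enumerate to confirm the returned one belongs to that family
  nA <- sum(items$proc[items$item_id %in% part$subpool_a] == "Scan")
  expect_true(nA >= 1 && nA <= 2)
  expect_identical(length(part$subpool_a), 3L)
  expect_error(partition_pool_ipe(items$item_id[1:5], pool, bp),
               class = "hatcat_domain_error")
})

test_that("whole-pool labeling covers every item with halved lower bounds", {
  bp <- hat_blueprint_fixture("reading")
  pool <- generate_synthetic_pool(reading_pool_spec(n_units = 20, seed = 9),
                                  domain = "READ")
  pool <- label_pool_subpools(pool, bp)
  expect_false(anyNA(pool$items$subpool))
  expect_identical(sum(pool$items$subpool == "A"),
                   sum(pool$items$subpool == "B"))
  for (k in which(bp$level == "item_count" & nzchar(bp$attribute))) {
    vals <- strsplit(bp$value[k], "|", fixed = TRUE)[[1]]
    for (lab in c("A", "B")) {
      cnt <- sum(pool$items[[bp$attribute[k]]][
        pool$items$subpool == lab] %in% vals)
      expect_gte(cnt, floor(bp$lb[k] / 2))
    }
  }
})
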