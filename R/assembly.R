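#' Build the shadow-test mixed-integer program
#'
#' Translates the blueprint and the current administration state into a
#' 0/1 program over item variables \eqn{x_i} and unit variables
#' \eqn{z_s}: maximize the summed (RP-shifted) Fisher information of the
#' selected items at the provisional ability, subject to the test-length
#' equality, the categorical count windows, the item-unit link rows
#' \eqn{x_{i_s} - z_s \le 0}, per-unit minimum/maximum rows
#' \eqn{\sum x_{i_s} \lessgtr n_s z_s}, the unit-count row on
#' \eqn{\sum z_s}, and the administered-inclusion equality
#' \eqn{\sum_{i \in S_{k-1}} x_i = k - 1}.
#'
#' @param pool A [hat_pool()].
#' @param constraints A [hat_blueprint()].
#' @param theta_hat Provisional ability estimate.
#' @param rpconfig An [rp_config()]; rp = .5 gives the plain
#'   maximum-information objective.
#' @param administered Character vector of already-administered item ids
#'   (they are forced into every subsequent shadow test).
#' @param test_length Test length; defaults to the blueprint's test-length
#'   rule.
#' @param tie_break "lexicographic" adds a negligible (1e-9-scale)
#'   objective preference for lexicographically small item ids so that ties
#'   between equally informative selections resolve deterministically;
#'   "none" leaves the objective untouched.
#' @return An object of class `hat_shadow_model`.
#' @export
build_shadow <- function(pool, constraints, theta_hat,
                         rpconfig = rp_config(), administered = character(),
                         test_length = NULL,
                         tie_break = c("lexicographic", "none")) {
  constraints <- as_blueprint(constraints)
  tie_break <- match.arg(tie_break)
  check_blueprint_attributes(pool, constraints)
  items <- pool$items
  units <- pool$units
  ni <- nrow(items)
  nu <- nrow(units)
  nv <- ni + nu
  t <- test_length %||% blueprint_test_length(constraints)
  unknown <- setdiff(administered, items$item_id)
  if (length(unknown))
    stop_hat(paste0("administered item(s) not in pool: ",
                    paste(unknown, collapse = ", ")),
             "hatcat_integrity_error")
  if (length(administered) >= t)
    stop_hat("administered set already reaches the test length",
             "hatcat_domain_error")

  unit_index <- match(items$unit_id, units$unit_id)
  info <- pool_information(items, theta_hat, rp = rpconfig$rp)
  obj <- c(info, rep(0, nu))
  if (tie_break == "lexicographic") {
    ord <- rank(items$item_id, ties.method = "first")
    obj[seq_len(ni)] <- obj[seq_len(ni)] + 1e-9 * (ni - ord) / ni
  }

  rows <- list(); sense <- integer(0); rhs <- numeric(0); rid <- character(0)
  add_row <- function(v, s, r, id) {
    rows[[length(rows) + 1L]] <<- v
    sense <<- c(sense, s); rhs <<- c(rhs, r); rid <<- c(rid, id)
  }

  # test length
  add_row(c(rep(1, ni), rep(0, nu)), 0L, t, "test_length")

  # categorical windows and unit-count row
  for (k in seq_len(nrow(constraints))) {
    cs <- constraints[k, ]
    if (cs$level == "item_count" && nzchar(cs$attribute)) {
      v <- c(as.numeric(constraint_matches(cs, items)), rep(0, nu))
      if (cs$lb == cs$ub) add_row(v, 0L, cs$lb, cs$constraint_id)
      else {
        if (cs$lb > 0) add_row(v, 1L, cs$lb, paste0(cs$constraint_id, "_lb"))
        add_row(v, -1L, cs$ub, paste0(cs$constraint_id, "_ub"))
      }
    } else if (cs$level == "unit_count") {
      v <- c(rep(0, ni), rep(1, nu))
      if (cs$lb == cs$ub) add_row(v, 0L, cs$lb, cs$constraint_id)
      else {
        add_row(v, 1L, cs$lb, paste0(cs$constraint_id, "_lb"))
        add_row(v, -1L, cs$ub, paste0(cs$constraint_id, "_ub"))
      }
    }
  }

  # item-unit link rows: x_i - z_s <= 0
  for (i in seq_len(ni)) {
    v <- numeric(nv)
    v[i] <- 1; v[ni + unit_index[i]] <- -1
    add_row(v, -1L, 0, paste0("link_", items$item_id[i]))
  }

  # per-unit bounds, switched by the unit variable
  pu <- constraints[constraints$level == "per_unit_count", , drop = FALSE]
  if (nrow(pu)) {
    l <- pu$lb[1]; u <- pu$ub[1]
    for (s in seq_len(nu)) {
      memb <- as.numeric(unit_index == s)
      vu <- c(memb, numeric(nu)); vu[ni + s] <- -u
      add_row(vu, -1L, 0, paste0("unit_ub_", units$unit_id[s]))
      if (l > 0) {
        vl <- c(memb, numeric(nu)); vl[ni + s] <- -l
        add_row(vl, 1L, 0, paste0("unit_lb_", units$unit_id[s]))
      } else {
        # tie z to usage when no minimum applies
        vz <- c(-memb, numeric(nu)); vz[ni + s] <- 1
        add_row(vz, -1L, 0, paste0("unit_use_", units$unit_id[s]))
      }
    }
  }

  # administered inclusion
  if (length(administered)) {
    v <- c(as.numeric(items$item_id %in% administered), rep(0, nu))
    add_row(v, 0L, length(administered), "administered")
  }

  A <- do.call(rbind, rows)
  structure(list(A = A, sense = sense, rhs = rhs, row_ids = rid,
                 obj = obj, info = info, unit_index = unit_index,
                 item_ids = items$item_id, unit_ids = units$unit_id,
                 n_items = ni, n_units = nu,
                 theta_hat = theta_hat, rp = rpconfig$rp,
                 test_length = t, administered = administered),
            class = "hat_shadow_model")
}

#' @export
print.hat_shadow_model <- function(x, ...) {
  cat(sprintf(
    "<hat_shadow_model> %d item + %d unit variables, %d rows, t = %d, theta = %.3f, rp = %.2f\n",
    x$n_items, x$n_units, nrow(x$A), x$test_length, x$theta_hat, x$rp))
  invisible(x)
}

#' Solve a shadow-test model
#'
#' Runs the package's exact branch-and-bound solver (bounded-variable
#' simplex relaxations) over the binary program. The solve is
#' deterministic for a fixed model.
#'
#' @param model A [build_shadow()] model.
#' @param backend Solver backend id; `"bb"` (built-in branch and bound) is
#'   the one provided.
#' @param time_limit Seconds before the solver returns its incumbent with
#'   status `feasible_timeout`.
#' @param warm_start Optional character vector of item ids forming a known
#'   feasible selection (e.g. the previous step's shadow test); used as the
#'   initial incumbent for pruning.
#' @return An object of class `hat_shadow`: `selected_item_ids`,
#'   `selected_unit_ids`, `objective_value` (summed selection-currency
#'   information of the selected items), `status` in
#'   optimal/feasible_timeout/infeasible, and `info` (per-item objective
#'   coefficients for downstream selection).
#' @export
solve_shadow <- function(model, backend = "bb", time_limit = 5,
                         warm_start = NULL) {
  backend <- match.arg(backend, c("bb"))
  nv <- model$n_items + model$n_units
  ws <- NULL
  if (!is.null(warm_start)) {
    it <- model$item_ids %in% warm_start
    zu <- seq_len(model$n_units) %in% unique(model$unit_index[it])
    ws <- c(as.numeric(it), as.numeric(zu))
  }
  sol <- milp_solve_cpp(model$A, model$sense, model$rhs, model$obj,
                        rep(TRUE, nv), rep(0, nv), rep(1, nv),
                        ws, time_limit, 2e5)
  status <- sol$status
  if (status %in% c("timeout", "numerical")) status <- "infeasible"
  if (status == "infeasible")
    return(structure(list(selected_item_ids = character(0),
                          selected_unit_ids = character(0),
                          objective_value = NA_real_, status = "infeasible",
                          info = model$info, nodes = sol$nodes),
                     class = "hat_shadow"))
  x <- sol$x
  sel_items <- model$item_ids[x[seq_len(model$n_items)] > 0.5]
  sel_units <- model$unit_ids[x[model$n_items + seq_len(model$n_units)] > 0.5]
  structure(list(selected_item_ids = sel_items,
                 selected_unit_ids = sel_units,
                 objective_value = sum(model$info[sel_items]),
                 status = status, info = model$info, nodes = sol$nodes),
            class = "hat_shadow")
}

#' @export
print.hat_shadow <- function(x, ...) {
  cat(sprintf("<hat_shadow> status %s: %d items / %d units, objective %.4f\n",
              x$status, length(x$selected_item_ids),
              length(x$selected_unit_ids), x$objective_value))
  invisible(x)
}

#' Audit an item set against a blueprint
#'
#' Post-hoc constraint check used both inside the administration loop and
#' for study-level violation counts: for every rule the qualifying members
#' of `item_set` are counted and each breached bound is reported.
#'
#' @param item_set Character vector of item ids.
#' @param pool A [hat_pool()].
#' @param constraints A [hat_blueprint()].
#' @return Data frame of violations (zero rows when fully compliant) with
#'   columns `constraint_id`, `level`, `unit_id`, `observed`, `bound`,
#'   `direction`.
#' @export
check_constraints <- function(item_set, pool, constraints) {
  constraints <- as_blueprint(constraints)
  items <- pool$items[pool$items$item_id %in% item_set, , drop = FALSE]
  out <- list()
  vio <- function(id, level, unit, obs, bound, dir)
    data.frame(constraint_id = id, level = level, unit_id = unit,
               observed = obs, bound = bound, direction = dir,
               stringsAsFactors = FALSE)
  for (k in seq_len(nrow(constraints))) {
    cs <- constraints[k, ]
    if (cs$level == "item_count") {
      cnt <- sum(constraint_matches(cs, items))
      if (cnt < cs$lb)
        out[[length(out) + 1L]] <- vio(cs$constraint_id, cs$level, NA, cnt,
                                       cs$lb, "lb")
      if (cnt > cs$ub)
        out[[length(out) + 1L]] <- vio(cs$constraint_id, cs$level, NA, cnt,
                                       cs$ub, "ub")
    } else if (cs$level == "unit_count") {
      cnt <- length(unique(items$unit_id))
      if (cnt < cs$lb)
        out[[length(out) + 1L]] <- vio(cs$constraint_id, cs$level, NA, cnt,
                                       cs$lb, "lb")
      if (cnt > cs$ub)
        out[[length(out) + 1L]] <- vio(cs$constraint_id, cs$level, NA, cnt,
                                       cs$ub, "ub")
    } else {
      tab <- table(items$unit_id)
      for (u in names(tab)) {
        if (tab[[u]] < cs$lb)
          out[[length(out) + 1L]] <- vio(cs$constraint_id, cs$level, u,
                                         tab[[u]], cs$lb, "lb")
        if (tab[[u]] > cs$ub)
          out[[length(out) + 1L]] <- vio(cs$constraint_id, cs$level, u,
                                         tab[[u]], cs$ub, "ub")
      }
    }
  }
  if (!length(out))
    return(data.frame(constraint_id = character(0), level = character(0),
                      unit_id = character(0), observed = integer(0),
                      bound = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Item-position-effect partition of an item set
#'
#' Splits an even-sized item set into two equal subpools by a single
#' assignment MIP so that each half complies with the categorical
#' blueprint windows under halved bounds: lb' = floor(lb/2),
#' ub' = ceiling(ub/2). Unit-level rules are not imposed on the halves (a
#' half-length window is arithmetically incompatible with exact per-unit
#' counts); see the package vignette. For sets larger than a test form
#' (e.g. labeling a whole pool), set `enforce_ub = FALSE` so only the
#' halved lower bounds are required of each half.
#'
#' @param item_set Character vector of item ids (even length).
#' @param pool A [hat_pool()].
#' @param constraints A [hat_blueprint()].
#' @param enforce_ub Impose halved upper bounds as well as lower bounds.
#' @param time_limit Solver time limit (seconds).
#' @return An object of class `hat_partition` with `subpool_a` and
#'   `subpool_b` (disjoint, equal-sized, covering `item_set`).
#' @export
partition_pool_ipe <- function(item_set, pool, constraints,
                               enforce_ub = TRUE, time_limit = 10) {
  constraints <- as_blueprint(constraints)
  n <- length(item_set)
  if (n %% 2 != 0)
    stop_hat("item set must have even size for an equal partition",
             "hatcat_domain_error")
  items <- pool$items[match(item_set, pool$items$item_id), , drop = FALSE]
  if (anyNA(items$item_id))
    stop_hat("item set contains ids absent from the pool",
             "hatcat_integrity_error")
  rows <- list(); sense <- integer(0); rhs <- numeric(0)
  add_row <- function(v, s, r) {
    rows[[length(rows) + 1L]] <<- v
    sense <<- c(sense, s); rhs <<- c(rhs, r)
  }
  add_row(rep(1, n), 0L, n / 2)
  cat_rows <- constraints[constraints$level == "item_count" &
                            nzchar(constraints$attribute), , drop = FALSE]
  for (k in seq_len(nrow(cat_rows))) {
    cs <- cat_rows[k, ]
    q <- as.numeric(constraint_matches(cs, items))
    nq <- sum(q)
    lbh <- floor(cs$lb / 2); ubh <- ceiling(cs$ub / 2)
    # bounds on the A-half count; the B-half count is nq minus it
    lo <- if (enforce_ub) max(lbh, nq - ubh) else lbh
    hi <- if (enforce_ub) min(ubh, nq - lbh) else nq - lbh
    if (lo > 0) add_row(q, 1L, lo)
    if (hi < nq) add_row(q, -1L, hi)
  }
  A <- do.call(rbind, rows)
  # constant-free feasibility objective; tiny lexicographic preference for
  # early ids in subpool A makes the chosen partition deterministic
  obj <- 1e-6 * (n - rank(items$item_id, ties.method = "first")) / n
  sol <- milp_solve_cpp(A, sense, rhs, obj, rep(TRUE, n), rep(0, n),
                        rep(1, n), NULL, time_limit, 2e5)
  if (sol$status %in% c("infeasible", "timeout", "numerical"))
    stop_hat(paste0(
      "no equal partition satisfies the halved bounds; binding candidates: ",
      paste(cat_rows$constraint_id, collapse = ", ")),
      "hatcat_partition_error")
  inA <- sol$x > 0.5
  structure(list(subpool_a = items$item_id[inA],
                 subpool_b = items$item_id[!inA]),
            class = "hat_partition")
}

#' @export
print.hat_partition <- function(x, ...) {
  cat(sprintf("<hat_partition> subpool A: %d items, subpool B: %d items\n",
              length(x$subpool_a), length(x$subpool_b)))
  invisible(x)
}

#' Label a pool's items with IPE subpool membership
#'
#' Convenience wrapper: partitions all pool items (halved lower bounds
#' only) and writes "A"/"B" into the pool's `subpool` column. For an
#' odd-sized pool the lexicographically last item is assigned to subpool B
#' and the remainder partitioned.
#'
#' @param pool A [hat_pool()].
#' @param constraints A [hat_blueprint()].
#' @return The pool with `items$subpool` filled.
#' @export
label_pool_subpools <- function(pool, constraints) {
  ids <- sort(pool$items$item_id)
  leftover <- character(0)
  if (length(ids) %% 2 == 1) {
    leftover <- ids[length(ids)]
    ids <- ids[-length(ids)]
  }
  part <- partition_pool_ipe(ids, pool, constraints, enforce_ub = FALSE)
  pool$items$subpool <- ifelse(
    pool$items$item_id %in% part$subpool_a, "A", "B")
  if (length(leftover))
    pool$items$subpool[pool$items$item_id == leftover] <- "B"
  pool
}

#' Dump a shadow model as LP-format-like text (for inspection)
#'
#' @param model A [build_shadow()] model.
#' @param path Output path.
#' @export
write_model_lp <- function(model, path) {
  vn <- c(paste0("x_", model$item_ids), paste0("z_", model$unit_ids))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("Maximize", con)
  nz <- which(model$obj != 0)
  writeLines(paste(" obj:", paste(sprintf("%+.6g %s", model$obj[nz], vn[nz]),
                                  collapse = " ")), con)
  writeLines("Subject To", con)
  sym <- c(`-1` = "<=", `0` = "=", `1` = ">=")
  for (r in seq_len(nrow(model$A))) {
    nz <- which(model$A[r, ] != 0)
    writeLines(sprintf(" %s: %s %s %g", model$row_ids[r],
                       paste(sprintf("%+g %s", model$A[r, nz], vn[nz]),
                             collapse = " "),
                       sym[[as.character(model$sense[r])]],
                       model$rhs[r]), con)
  }
  writeLines("Binaries", con)
  writeLines(paste("", paste(vn, collapse = " ")), con)
  writeLines("End", con)
  invisible(NULL)
}
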