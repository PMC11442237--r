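#' Enumerate the 24 adaptive test forms
#'
#' Two clusters of a major domain followed by two clusters of a minor
#' domain; six ordered domain pairs times two orderings of each domain's
#' clusters give 24 forms. Form 1 is READ1, READ2, MATH1, MATH2.
#'
#' @return Data frame with columns `form_id`, `cluster1`..`cluster4`,
#'   `major`, `minor`.
#' @export
enumerate_forms <- function() {
  pairs <- list(c("READ", "MATH"), c("MATH", "READ"), c("SCIE", "READ"),
                c("READ", "SCIE"), c("MATH", "SCIE"), c("SCIE", "MATH"))
  variants <- list(c(1, 2, 1, 2), c(2, 1, 2, 1), c(1, 2, 2, 1),
                   c(2, 1, 1, 2))
  rows <- list()
  fid <- 0L
  for (p in pairs) for (v in variants) {
    fid <- fid + 1L
    rows[[fid]] <- data.frame(
      form_id = fid,
      cluster1 = paste0(p[1], v[1]), cluster2 = paste0(p[1], v[2]),
      cluster3 = paste0(p[2], v[3]), cluster4 = paste0(p[2], v[4]),
      major = p[1], minor = p[2], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Assign test forms to students
#'
#' @param n_students Number of students.
#' @param method "spiral" rotates through the forms in order (student j
#'   gets form ((j-1) mod K) + 1); "random" draws uniformly.
#' @param seed Seed for random assignment.
#' @param forms Form ids to rotate/draw over (default all 24).
#' @return Integer vector of form ids, one per student.
#' @export
assign_forms <- function(n_students, method = c("spiral", "random"),
                         seed = NULL, forms = 1:24) {
  method <- match.arg(method)
  if (method == "spiral") {
    forms[((seq_len(n_students) - 1L) %% length(forms)) + 1L]
  } else {
    with_local_seed(seed, sample(forms, n_students, replace = TRUE))
  }
}

#' Initial ability for a domain's first cluster
#'
#' Cluster 1 starts at the prior mean; cluster 3 (first cluster of the
#' second domain) starts at the final provisional estimate of the first
#' domain, exploiting the high correlation between the domains.
#'
#' @param cluster_index 1 or 3.
#' @param prior A [prior_spec()].
#' @param previous_domain_final Final `hat_theta` of the first domain
#'   (required for cluster 3).
#' @return A `hat_theta` usable as a starting estimate.
#' @export
init_theta <- function(cluster_index, prior = prior_spec(),
                       previous_domain_final = NULL) {
  if (!cluster_index %in% c(1, 3))
    stop_hat("domains start at cluster 1 or 3", "hatcat_domain_error")
  if (cluster_index == 1) {
    structure(list(value = prior$mean[1], se = sqrt(prior$cov[1, 1]),
                   method = "init", n_responses = 0L),
              class = "hat_theta")
  } else {
    if (is.null(previous_domain_final))
      stop_hat("cluster 3 needs the first domain's final estimate",
               "hatcat_state_error")
    structure(list(value = previous_domain_final$value,
                   se = previous_domain_final$se,
                   method = "carry_over", n_responses = 0L),
              class = "hat_theta")
  }
}

#' Administration configuration
#'
#' @param rp Target response probability for shifted item selection
#'   (default .62; .5 = plain maximum information).
#' @param estimator Provisional/final ability estimator ("EAP"; "MLE" falls
#'   back to EAP for non-finite patterns).
#' @param progressive Use progressive exposure weighting.
#' @param ipe Enforce the subpool ordering (requires labeled items).
#' @param spiral Administer two complete spiraled units in the major
#'   domain.
#' @param solver_time_limit Seconds per shadow solve.
#' @param carry_forward On an infeasible shadow solve, reuse the previous
#'   shadow test instead of failing (logged); default off (fail fast).
#' @param prior_sd Prior standard deviation for provisional EAP updates.
#' @param grid,n_grid Quadrature range and size for EAP.
#' @param test_length Domain test length when no blueprint supplies one
#'   (plain CAT mode).
#' @return A list of class `hat_config`.
#' @export
hat_config <- function(rp = 0.62, estimator = c("EAP", "MLE"),
                       progressive = TRUE, ipe = TRUE, spiral = TRUE,
                       solver_time_limit = 5, carry_forward = FALSE,
                       prior_sd = 1, grid = c(-4, 4), n_grid = 81,
                       test_length = NULL) {
  structure(list(rp = rp, estimator = match.arg(estimator),
                 progressive = progressive, ipe = ipe, spiral = spiral,
                 solver_time_limit = solver_time_limit,
                 carry_forward = carry_forward, prior_sd = prior_sd,
                 grid = grid, n_grid = n_grid, test_length = test_length),
            class = "hat_config")
}

#' Run one adaptive domain test for one student
#'
#' Executes the shadow-test loop: optionally administer the two spiraled
#' complete units first (their items join the administered set so every
#' later shadow accounts for them), then repeatedly assemble a compliant
#' shadow test at the current provisional ability, weight the
#' unadministered shadow items (RP-shifted information, progressive
#' randomization, IPE ordering), administer the pick, collect the response
#' and re-estimate ability, until the fixed test length is reached. With
#' `blueprint = NULL` the loop degenerates to unconstrained item-level CAT
#' over the whole pool (no shadow solves), which is useful for studying
#' the selection rule in isolation.
#'
#' @param pool A [hat_pool()] (subpool-labeled if `config$ipe`).
#' @param blueprint A [hat_blueprint()] or NULL.
#' @param config A [hat_config()].
#' @param student_index 1-based index driving the unit spiral.
#' @param init Starting `hat_theta` (see [init_theta()]); its value also
#'   centers the EAP prior for this domain.
#' @param response_fun Function(item_row) -> integer score; typically wraps
#'   [simulate_response()].
#' @param order1 Subpool order of the domain's first administered cluster
#'   (`c("A","B")` when cluster "1" of the domain comes first).
#' @param cluster_offset 0 for the first domain of a form, 2 for the
#'   second (cluster labels in the log become offset + 1 or 2).
#' @return List with `log` (one row per position) and `final`
#'   (`hat_theta`).
#' @export
run_domain <- function(pool, blueprint, config = hat_config(),
                       student_index = 1L, init = NULL,
                       response_fun, order1 = c("A", "B"),
                       cluster_offset = 0L) {
  items <- pool$items
  t <- if (!is.null(blueprint)) blueprint_test_length(blueprint)
       else config$test_length %||%
         stop_hat("test_length required without a blueprint",
                  "hatcat_domain_error")
  cluster_len <- ceiling(t / 2)
  init <- init %||% init_theta(1, prior_spec(0, config$prior_sd^2))
  prior <- prior_spec(init$value, config$prior_sd^2)
  rpcfg <- rp_config(config$rp)
  use_ipe <- isTRUE(config$ipe) && !is.null(blueprint) &&
    !anyNA(items$subpool)
  plan <- if (use_ipe) ipe_plan(cluster_len, order1) else NULL
  subpool <- stats::setNames(items$subpool, items$item_id)

  spiral_q <- list(character(0), character(0))
  if (isTRUE(config$spiral) && !is.null(blueprint)) {
    su <- spiral_units(pool$units$unit_id, student_index)
    spiral_q <- list(items$item_id[items$unit_id == su[1]],
                     items$item_id[items$unit_id == su[2]])
  }

  administered <- character(0)
  scores <- integer(0)
  theta <- init$value
  est <- init
  prev_sel <- NULL
  logs <- vector("list", t)

  for (p in seq_len(t)) {
    h <- p - 1L
    cl <- if (p <= cluster_len) 1L else 2L
    shadow_status <- NA_character_
    shadow_obj <- NA_real_
    ipe_relaxed <- FALSE

    sq <- setdiff(spiral_q[[cl]], administered)
    # items of a not-yet-reached spiral unit are committed but reserved:
    # every shadow must account for them, no adaptive pick may take them
    reserved <- setdiff(unlist(spiral_q), administered)
    if (length(sq)) {
      item_id <- sq[1]
      shadow_status <- "spiraled"
    } else {
      if (is.null(blueprint)) {
        cands <- setdiff(items$item_id, c(administered, reserved))
        infos <- pool_information(items, theta, rp = config$rp)[cands]
        shadow_status <- "pool"
        shadow <- NULL
      } else {
        model <- build_shadow(pool, blueprint, theta, rpcfg,
                              c(administered, reserved),
                              test_length = t)
        shadow <- solve_shadow(model,
                               time_limit = config$solver_time_limit,
                               warm_start = prev_sel)
        if (shadow$status == "infeasible") {
          if (isTRUE(config$carry_forward) && !is.null(prev_sel)) {
            shadow <- structure(list(selected_item_ids = prev_sel,
                                     selected_unit_ids = character(0),
                                     objective_value = NA_real_,
                                     status = "carried_forward",
                                     info = model$info),
                                class = "hat_shadow")
          } else {
            stop_hat(sprintf(
              "shadow test infeasible at position %d (theta %.3f)",
              p, theta), "hatcat_infeasible_error")
          }
        }
        prev_sel <- shadow$selected_item_ids
        shadow_status <- shadow$status
        shadow_obj <- shadow$objective_value
        cands <- setdiff(shadow$selected_item_ids,
                         c(administered, reserved))
        infos <- shadow$info[cands]
      }
      eligible <- NULL
      if (use_ipe) {
        in_cl <- logs_cluster_items(logs, cl)
        n_first <- sum(subpool[in_cl] == plan[[cl]]$first)
        eligible <- ipe_eligible(cands, subpool, plan[[cl]]$first,
                                 n_first, plan[[cl]]$quota)
        if (!length(eligible)) { eligible <- NULL; ipe_relaxed <- TRUE }
      }
      w <- if (isTRUE(config$progressive))
        progressive_weights(infos, h, t)$weights
      else infos
      if (is.null(blueprint)) {
        cand2 <- if (is.null(eligible)) cands else intersect(cands, eligible)
        ww <- w[cand2]
        item_id <- sort(cand2[ww >= max(ww) - 1e-12])[1]
      } else {
        item_id <- pick_item(shadow, c(administered, reserved), w, eligible)
      }
    }

    row <- items[items$item_id == item_id, , drop = FALSE]
    score <- response_fun(row)
    administered <- c(administered, item_id)
    scores <- c(scores, score)
    adm_items <- items[match(administered, items$item_id), , drop = FALSE]
    est <- tryCatch(
      estimate_theta(adm_items, scores, method = config$estimator,
                     prior = prior, grid = config$grid,
                     n_grid = config$n_grid),
      hatcat_mle_nonfinite = function(e)
        estimate_theta(adm_items, scores, method = "EAP", prior = prior,
                       grid = config$grid, n_grid = config$n_grid))
    theta <- est$value

    logs[[p]] <- data.frame(
      position = p, cluster = cluster_offset + cl, item_id = item_id,
      unit_id = row$unit_id, subpool = row$subpool %||% NA_character_,
      score = score, theta_hat = est$value, se = est$se,
      shadow_objective = shadow_obj, shadow_status = shadow_status,
      ipe_relaxed = ipe_relaxed, stringsAsFactors = FALSE)
  }

  log <- do.call(rbind, logs)
  if (!is.null(blueprint)) {
    vio <- check_constraints(administered, pool, blueprint)
    if (nrow(vio))
      stop_hat(paste0("completed administration violates constraint(s): ",
                      paste(unique(vio$constraint_id), collapse = ", ")),
               "hatcat_violation_error")
  }
  list(log = log, final = est)
}

logs_cluster_items <- function(logs, cl) {
  done <- logs[!vapply(logs, is.null, logical(1))]
  if (!length(done)) return(character(0))
  df <- do.call(rbind, done)
  df$item_id[((df$cluster - 1) %% 2) + 1 == cl]
}

#' Run a complete test form for one student
#'
#' Administers the form's first domain (clusters 1-2) then its second
#' domain (clusters 3-4), carrying the final provisional ability of the
#' first domain over as the starting ability (and EAP prior center) of the
#' second. Spiraled complete units are administered in the major (first)
#' domain only.
#'
#' @param student_id Identifier recorded in the log.
#' @param student_index 1-based counter driving unit spiraling.
#' @param form One row of [enumerate_forms()] (or a form id).
#' @param pools Named list of [hat_pool()]s by domain (e.g. READ, MATH).
#' @param blueprints Named list of [hat_blueprint()]s by domain.
#' @param config A [hat_config()].
#' @param true_theta Named numeric vector of the simulee's true abilities
#'   by domain (used by the default response generator).
#' @param response_fun Optional function(item_row, domain) -> score;
#'   defaults to model-based simulation at `true_theta`.
#' @return An object of class `hat_administration`: `student_id`,
#'   `form_id`, `log`, `finals` (named list of `hat_theta` per domain).
#' @export
run_test <- function(student_id, student_index, form, pools, blueprints,
                     config = hat_config(), true_theta = NULL,
                     response_fun = NULL) {
  if (is.numeric(form)) form <- enumerate_forms()[form, ]
  doms <- c(form$major, form$minor)
  for (d in doms)
    if (is.null(pools[[d]]))
      stop_hat(paste0("no pool for domain ", d), "hatcat_state_error")
  rf <- response_fun %||% function(row, domain)
    simulate_response(row, true_theta[[domain]])
  first_cluster <- c(form$cluster1, form$cluster3)

  logs <- list()
  finals <- list()
  inits <- numeric(0)
  prev_final <- NULL
  offset <- 0L
  pos0 <- 0L
  for (k in 1:2) {
    d <- doms[k]
    order1 <- if (grepl("1$", first_cluster[k])) c("A", "B") else c("B", "A")
    cfg <- config
    cfg$spiral <- isTRUE(config$spiral) && k == 1L
    init <- if (k == 1) init_theta(1, prior_spec(0, config$prior_sd^2))
            else init_theta(3, previous_domain_final = prev_final)
    inits[d] <- init$value
    res <- run_domain(pools[[d]], blueprints[[d]], cfg, student_index,
                      init = init,
                      response_fun = function(row) rf(row, d),
                      order1 = order1, cluster_offset = offset)
    res$log$position <- res$log$position + pos0
    res$log$domain <- d
    logs[[k]] <- res$log
    finals[[d]] <- res$final
    prev_final <- res$final
    offset <- offset + 2L
    pos0 <- max(res$log$position)
  }
  log <- do.call(rbind, logs)
  log <- cbind(data.frame(student_id = student_id, form_id = form$form_id,
                          stringsAsFactors = FALSE), log)
  structure(list(student_id = student_id, form_id = form$form_id,
                 log = log, finals = finals, inits = inits),
            class = "hat_administration")
}

#' @export
print.hat_administration <- function(x, ...) {
  cat(sprintf("<hat_administration> student %s, form %d, %d positions\n",
              x$student_id, x$form_id, nrow(x$log)))
  for (d in names(x$finals))
    cat(sprintf("  %s: final theta %.3f (se %.3f)\n", d,
                x$finals[[d]]$value, x$finals[[d]]$se))
  invisible(x)
}
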