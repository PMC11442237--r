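#' Default inter-domain ability covariance
#'
#' Unit variances with a common correlation; PISA's cognitive domains are
#' highly correlated, and 0.8 is used as the package default.
#'
#' @param rho Common correlation.
#' @param domains Domain names (dimension labels).
#' @return Named covariance matrix.
#' @export
default_sigma <- function(rho = 0.8, domains = c("READ", "MATH", "SCIE")) {
  d <- length(domains)
  s <- matrix(rho, d, d)
  diag(s) <- 1
  dimnames(s) <- list(domains, domains)
  s
}

#' Draw simulees from a multivariate normal ability distribution
#'
#' @param n Number of simulees.
#' @param mu Mean vector (named by domain if desired).
#' @param sigma Covariance matrix (symmetric positive definite).
#' @param seed Integer seed; draws are reproducible and the caller's RNG
#'   state is untouched.
#' @return An object of class `hat_simulees`: `n`, `dim`, `mu`, `sigma`,
#'   `thetas` (n x D matrix), `seed`.
#' @export
draw_simulees <- function(n, mu = rep(0, 3), sigma = default_sigma(),
                          seed = NULL) {
  sigma <- as.matrix(sigma)
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0 || max(abs(sigma - t(sigma))) > 1e-8)
    stop_hat("sigma must be symmetric positive definite",
             "hatcat_domain_error")
  th <- with_local_seed(seed, MASS::mvrnorm(n, mu, sigma))
  if (n == 1) th <- matrix(th, nrow = 1)
  colnames(th) <- colnames(sigma) %||% names(mu)
  structure(list(n = n, dim = length(mu), mu = mu, sigma = sigma,
                 thetas = th, seed = seed),
            class = "hat_simulees")
}

#' Simulate a scored response from the item response model
#'
#' Dichotomous items: Bernoulli draw at the 2PL probability. Polytomous
#' items: categorical draw from the GPCM category probabilities. Uses the
#' ambient RNG.
#'
#' @param item One-row item (as in [fisher_information()]).
#' @param theta The simulee's true ability on the item's domain dimension.
#' @return Integer score (0/1, or 0..m).
#' @export
simulate_response <- function(item, theta) {
  it <- as_item(item)
  if (it$model == "2PL") {
    as.integer(stats::runif(1) < prob_dichotomous(theta, it$a, it$b))
  } else {
    p <- prob_polytomous(theta, it$a, it$b, it$steps)
    findInterval(stats::runif(1), cumsum(p)) # 0-based category score
  }
}

#' Configuration of a simulation study
#'
#' @param pools Named list of [hat_pool()]s by domain.
#' @param blueprints Named list of [hat_blueprint()]s by domain (may be
#'   NULL inside for plain CAT).
#' @param n_students Number of simulees.
#' @param forms Form ids to rotate over; NULL with a single domain runs
#'   that domain alone (two clusters).
#' @param assignment "spiral" or "random" form assignment.
#' @param mu,sigma Simulee ability distribution (dimensions must cover the
#'   pool domains; defaults to the 3-domain prior restricted to them).
#' @param seed Master seed: drives simulee draws, form assignment and all
#'   response/selection randomness.
#' @param config A [hat_config()].
#' @return List of class `hat_sim_config`.
#' @export
sim_config <- function(pools, blueprints, n_students, forms = NULL,
                       assignment = c("spiral", "random"),
                       mu = NULL, sigma = NULL, seed = 1,
                       config = hat_config()) {
  assignment <- match.arg(assignment)
  doms <- names(pools)
  if (is.null(doms) || !length(doms))
    stop_hat("pools must be a named list (domain names)",
             "hatcat_domain_error")
  if (is.null(sigma)) {
    full <- default_sigma()
    sigma <- if (all(doms %in% colnames(full)))
      full[doms, doms, drop = FALSE] else default_sigma(0.8, doms)
  }
  mu <- mu %||% stats::setNames(rep(0, length(doms)), doms)
  structure(list(pools = pools, blueprints = blueprints,
                 n_students = n_students, forms = forms,
                 assignment = assignment, mu = mu, sigma = sigma,
                 seed = seed, config = config),
            class = "hat_sim_config")
}

#' Run a full simulation study
#'
#' Draws correlated simulees, labels pools with IPE subpools (when the
#' ordering is enabled), assigns forms, administers every student with
#' [run_test()] (or [run_domain()] for single-domain studies), and
#' aggregates the evaluation metrics. Fully reproducible from
#' `config$seed`.
#'
#' @param sc A [sim_config()].
#' @return List of class `hat_study`: `records` (list of per-student
#'   administrations), `log` (all positions, one data frame), `simulees`,
#'   `metrics` (a [compute_metrics()] report).
#' @export
run_study <- function(sc) {
  doms <- names(sc$pools)
  sim <- draw_simulees(sc$n_students, sc$mu, sc$sigma, seed = sc$seed)
  pools <- sc$pools
  if (isTRUE(sc$config$ipe)) {
    for (d in doms) {
      if (!is.null(sc$blueprints[[d]]) &&
          anyNA(pools[[d]]$items$subpool))
        pools[[d]] <- label_pool_subpools(pools[[d]], sc$blueprints[[d]])
    }
  }
  single <- length(doms) == 1 && is.null(sc$forms)
  forms_df <- enumerate_forms()
  form_ids <- if (single) NULL
    else sc$forms %||% forms_df$form_id[forms_df$major %in% doms &
                                          forms_df$minor %in% doms]
  assigned <- if (single) rep(NA_integer_, sc$n_students)
    else assign_forms(sc$n_students, sc$assignment, seed = sc$seed + 1L,
                      forms = form_ids)

  records <- vector("list", sc$n_students)
  with_local_seed(sc$seed + 2L, {
    for (j in seq_len(sc$n_students)) {
      th <- sim$thetas[j, ]
      if (is.null(names(th))) names(th) <- doms
      sid <- sprintf("S%04d", j)
      if (single) {
        d <- doms[1]
        order1 <- if (j %% 2 == 1) c("A", "B") else c("B", "A")
        res <- run_domain(pools[[d]], sc$blueprints[[d]], sc$config,
                          student_index = j,
                          response_fun = function(row)
                            simulate_response(row, th[[d]]),
                          order1 = order1)
        res$log$domain <- d
        log <- cbind(data.frame(student_id = sid, form_id = NA_integer_,
                                stringsAsFactors = FALSE), res$log)
        records[[j]] <- structure(
          list(student_id = sid, form_id = NA_integer_, log = log,
               finals = stats::setNames(list(res$final), d)),
          class = "hat_administration")
      } else {
        records[[j]] <- run_test(sid, j, forms_df[assigned[j], ],
                                 pools, sc$blueprints, sc$config,
                                 true_theta = th)
      }
    }
  })
  log <- do.call(rbind, lapply(records, `[[`, "log"))
  metrics <- compute_metrics(records, sim, pools, sc$blueprints)
  structure(list(records = records, log = log, simulees = sim,
                 metrics = metrics, pools = pools, config = sc),
            class = "hat_study")
}

#' Evaluation metrics of a set of administrations
#'
#' Per domain: RMSE and bias of the final ability estimates against truth,
#' and mean test information evaluated at the true abilities (the summed
#' Fisher information of each student's administered items at their true
#' theta). Pool-wide: item exposure rates (administrations / examinees),
#' their extremes, per-item response counts, and the count of blueprint
#' violations per administration from [check_constraints()].
#'
#' @param records List of `hat_administration` objects.
#' @param simulees A [draw_simulees()] set aligned with the records.
#' @param pools Named list of pools.
#' @param blueprints Named list of blueprints (entries may be NULL).
#' @return List of class `hat_metrics` with elements `by_domain` (data
#'   frame: domain, n, rmse, bias, mean_info), `exposure` (named rates),
#'   `max_exposure`, `min_exposure`, `response_counts`,
#'   `violations_per_admin` (integer vector), `total_violations`.
#' @export
compute_metrics <- function(records, simulees, pools, blueprints) {
  n <- length(records)
  doms <- unique(unlist(lapply(records, function(r) names(r$finals))))
  byd <- list()
  for (d in doms) {
    has <- vapply(records, function(r) d %in% names(r$finals), logical(1))
    est <- vapply(records[has], function(r) r$finals[[d]]$value, numeric(1))
    idx <- which(has)
    tru <- vapply(idx, function(j) {
      th <- simulees$thetas[j, ]
      if (!is.null(names(th)) && d %in% names(th)) th[[d]] else th[[1]]
    }, numeric(1))
    info <- vapply(idx, function(j) {
      r <- records[[j]]
      ids <- r$log$item_id[r$log$domain == d]
      it <- pools[[d]]$items
      sum(pool_information(it[match(ids, it$item_id), , drop = FALSE],
                           tru[match(j, idx)]))
    }, numeric(1))
    byd[[d]] <- data.frame(domain = d, n = sum(has),
                           rmse = sqrt(mean((est - tru)^2)),
                           bias = mean(est - tru),
                           mean_info = mean(info),
                           stringsAsFactors = FALSE)
  }
  # item ids are only unique within a domain's pool, so count per domain
  exposure <- numeric(0)
  counts <- integer(0)
  for (d in names(pools)) {
    ids <- pools[[d]]$items$item_id
    adm <- unlist(lapply(records, function(r)
      r$log$item_id[r$log$domain == d]))
    cnt <- table(factor(adm, levels = ids))
    counts <- c(counts, as.integer(cnt))
    exposure <- c(exposure,
                  stats::setNames(as.numeric(cnt) / n, paste0(d, ":", ids)))
  }
  vio <- vapply(records, function(r) {
    tot <- 0L
    for (d in names(r$finals)) {
      bp <- blueprints[[d]]
      if (is.null(bp)) next
      ids <- r$log$item_id[r$log$domain == d]
      tot <- tot + nrow(check_constraints(ids, pools[[d]], bp))
    }
    tot
  }, integer(1))
  structure(list(by_domain = do.call(rbind, byd),
                 exposure = exposure,
                 max_exposure = max(exposure),
                 min_exposure = min(exposure),
                 response_counts = counts,
                 violations_per_admin = vio,
                 total_violations = sum(vio)),
            class = "hat_metrics")
}

#' @export
print.hat_metrics <- function(x, ...) {
  cat("<hat_metrics>\n")
  print(x$by_domain, row.names = FALSE)
  cat(sprintf("exposure: max %.3f min %.3f; total violations %d\n",
              x$max_exposure, x$min_exposure, x$total_violations))
  invisible(x)
}
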